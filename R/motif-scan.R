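# Family identification by local alignment of a conserved motif.
#
# Plant UGTs are diagnosed by the ~44-residue C-terminal PSPG box; family
# membership is called by Smith-Waterman local alignment of that consensus
# against each proteome entry, scored as a fraction of the motif's self-score
# (so the threshold is scale-free). Scoring follows conventional protein
# local-alignment defaults: BLOSUM62, gap open 10, gap extend 1 (a gap of
# length k costs open + k * extend).

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

sanitize_aa <- function(x) {
  # non-standard residue codes are treated as X (neutral-ish under BLOSUM62)
  gsub("[^ARNDCQEGHILKMFPSTWYVX]", "X", toupper(x))
}

#' Locally align a motif against one protein
#'
#' Smith-Waterman local alignment (affine gaps) of a consensus motif against
#' a protein, reporting the score as a fraction of the motif aligned against
#' itself under the same scoring.
#'
#' @param sequence amino-acid string.
#' @param motif consensus motif string.
#' @param gap_open,gap_extend affine gap penalties (defaults 10 and 1).
#' @return one-row tibble: `raw_score`, `score_fraction` (capped to `[0,1]`),
#'   `start`, `end` (1-based inclusive span on the protein), and
#'   `motif_coverage` (fraction of motif positions inside the alignment).
#' @export
#' @examples
#' local_align_motif("MKV", "KV")
local_align_motif <- function(sequence, motif, gap_open = 10, gap_extend = 1) {
  hits <- scan_proteome(tibble(protein_id = "q", sequence = sequence),
                        motif, min_fraction = 0,
                        gap_open = gap_open, gap_extend = gap_extend)
  hits[, c("raw_score", "score_fraction", "start", "end", "motif_coverage")]
}

#' Scan a proteome for motif carriers
#'
#' Aligns the motif locally against every protein and returns the proteins
#' whose best local alignment scores at least `min_fraction` of the motif's
#' self-score, sorted by descending score fraction then id.
#'
#' @param proteins tibble with columns `protein_id` and `sequence` (as from
#'   [read_protein_fasta()]), or a named character vector.
#' @param motif consensus motif string (44 residues for the PSPG box).
#' @param min_fraction score-fraction cutoff in `(0, 1]`; the 0.40 default is
#'   permissive enough for a strongly diverged family. `min_fraction = 0`
#'   returns every protein's best hit.
#' @param gap_open,gap_extend affine gap penalties.
#' @param min_length,max_length optional protein-length filter (off by
#'   default; observed family length ranges are results, not filters).
#' @return tibble of [local_align_motif()] hits with `protein_id` first;
#'   attribute `n_scanned` records the proteome size.
#' @export
scan_proteome <- function(proteins, motif, min_fraction = 0.4,
                          gap_open = 10, gap_extend = 1,
                          min_length = NULL, max_length = NULL) {
  if (is.character(proteins)) {
    proteins <- tibble(protein_id = names(proteins), sequence = unname(proteins))
  }
  proteins <- as_tibble(proteins)
  if (min_fraction < 0 || min_fraction > 1) {
    abort("min_fraction must lie in [0, 1]")
  }
  if (!nzchar(motif)) abort("motif must be non-empty")
  dup <- unique(proteins$protein_id[duplicated(proteins$protein_id)])
  if (length(dup)) {
    abort(paste0("duplicate protein ids: ", paste(dup, collapse = ", ")))
  }
  if (!is.null(min_length)) proteins <- proteins[nchar(proteins$sequence) >= min_length, ]
  if (!is.null(max_length)) proteins <- proteins[nchar(proteins$sequence) <= max_length, ]
  n_scanned <- nrow(proteins)
  if (n_scanned == 0) {
    out <- tibble(protein_id = character(0), raw_score = numeric(0),
                  score_fraction = numeric(0), start = integer(0),
                  end = integer(0), motif_coverage = numeric(0))
    attr(out, "n_scanned") <- 0L
    return(out)
  }
  mat <- blosum62()
  motif_s <- sanitize_aa(motif)
  seqs <- Biostrings::AAStringSet(setNames(sanitize_aa(proteins$sequence),
                                           proteins$protein_id))
  self <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(motif_s), Biostrings::AAString(motif_s),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    seqs, Biostrings::AAString(motif_s),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  prot_rng <- as.data.frame(Biostrings::pattern(aln)@range)
  motif_rng <- as.data.frame(Biostrings::subject(aln)@range)
  out <- tibble(
    protein_id = proteins$protein_id,
    raw_score = Biostrings::score(aln),
    score_fraction = pmin(pmax(Biostrings::score(aln) / self, 0), 1),
    start = prot_rng$start,
    end = prot_rng$end,
    motif_coverage = motif_rng$width / nchar(motif_s)
  )
  out <- out[out$score_fraction >= min_fraction, ]
  out <- out[order(-out$score_fraction, out$protein_id), ]
  attr(out, "n_scanned") <- n_scanned
  out
}
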