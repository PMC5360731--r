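# Disk round-trip for synthetic family bundles: FASTA via Biostrings, GFF3
# via rtracklayer, tables as TSV, tree as Newick. Writing then re-parsing the
# bundle is the round-trip contract the gene_structure tests rely on.

#' Write a synthetic family bundle to disk
#'
#' Writes `genome.fa`, `proteins.faa`, `msa.faa`, `models.gff3`,
#' `truth_genes.tsv`, `truth_introns.tsv`, `truth_events.tsv` and `tree.nwk`
#' under `dir`. Output is byte-reproducible for a fixed simulation seed.
#'
#' @param sim a [simulate_family()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_family_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "family_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome),
                              file.path(dir, "genome.fa"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sim$proteins),
                              file.path(dir, "proteins.faa"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sim$msa),
                              file.path(dir, "msa.faa"))
  export_gff3(sim$models, file.path(dir, "models.gff3"))
  readr::write_tsv(sim$truth_genes, file.path(dir, "truth_genes.tsv"))
  readr::write_tsv(sim$truth_introns, file.path(dir, "truth_introns.tsv"))
  readr::write_tsv(sim$truth_events, file.path(dir, "truth_events.tsv"))
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  invisible(dir)
}

# models tibble (gene_id, chromosome, strand, exon, start, end; transcription
# order) -> GFF3 with gene/mRNA/CDS features, 1-based inclusive, GFF3 phase
# convention (bases to skip to the next codon start)
export_gff3 <- function(models, path) {
  per_gene <- split(models, models$gene_id)
  feats <- lapply(per_gene, function(gm) {
    gm <- gm[order(gm$exon), , drop = FALSE]
    widths <- gm$end - gm$start + 1L
    cum_before <- c(0L, cumsum(widths))[seq_along(widths)]
    gff_phase <- (3L - cum_before %% 3L) %% 3L
    gid <- gm$gene_id[1]
    span <- c(min(gm$start), max(gm$end))
    tibble(
      seqnames = gm$chromosome[1],
      start = c(span[1], span[1], gm$start),
      end = c(span[2], span[2], gm$end),
      strand = gm$strand[1],
      type = c("gene", "mRNA", rep("CDS", nrow(gm))),
      ID = c(gid, paste0(gid, ".1"), paste0(gid, ".1.cds", gm$exon)),
      Parent = c(NA_character_, gid, rep(paste0(gid, ".1"), nrow(gm))),
      phase = c(NA_integer_, NA_integer_, gff_phase)
    )
  })
  feats <- dplyr::bind_rows(feats)
  gr <- GenomicRanges::GRanges(
    seqnames = feats$seqnames,
    ranges = IRanges::IRanges(feats$start, feats$end),
    strand = feats$strand)
  S4Vectors::mcols(gr)$source <- "glycofam"
  S4Vectors::mcols(gr)$type <- feats$type
  S4Vectors::mcols(gr)$ID <- feats$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(feats$Parent), "", feats$Parent)
  S4Vectors::mcols(gr)$phase <- feats$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a protein FASTA into a tibble
#'
#' @param path FASTA file of amino-acid sequences.
#' @return tibble with columns `protein_id`, `sequence`.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  tibble(protein_id = ids, sequence = as.character(aa))
}

#' Read an aligned protein FASTA (MSA)
#'
#' @param path aligned FASTA; all rows must have equal length.
#' @return named character vector of aligned rows.
#' @export
read_msa_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  rows <- setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  if (length(unique(nchar(rows))) > 1) {
    abort("alignment rows have unequal lengths; not a valid MSA")
  }
  rows
}
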