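# Exon-intron architecture: intron extraction and phase classification from
# gene models, projection of intron positions onto the protein alignment,
# detection of conserved insertion events, and the group-level summary
# tables (intron-count-by-group, chromosome distribution).
#
# Phase rule: an intron after L coding nucleotides has phase L mod 3 --
# phase 0 between two codons, phase 1 after the first base of a codon,
# phase 2 after the second. Phase is always computed from cumulative CDS
# length, never read from the GFF3 phase column (which encodes
# bases-to-skip, a different convention).

#' Parse gene models from a GFF3 file
#'
#' Reads gene/mRNA/CDS features and returns one row per CDS segment, ordered
#' in transcription order within each gene (descending genomic coordinate on
#' the minus strand). When a gene has several mRNAs the longest-CDS
#' transcript is chosen and a message emitted. Genes whose CDS length is not
#' divisible by three are flagged partial and excluded (with a warning) from
#' downstream phase analysis.
#'
#' @param gff3 path to a GFF3 file.
#' @param genome optional path to the matching genome FASTA; when given, each
#'   spliced CDS is translated and checked for internal stop codons.
#' @return tibble with columns `gene_id`, `chromosome`, `strand`, `exon`
#'   (1-based transcription order), `start`, `end` (1-based inclusive
#'   genomic). Attributes: `partial` (character vector of flagged genes) and,
#'   if `genome` was given, `proteins` (named character of translations).
#' @export
parse_gene_models <- function(gff3, genome = NULL) {
  gr <- rtracklayer::import(gff3, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) abort("no CDS features in GFF3")
  parent_chr <- vapply(cds$Parent, function(p) as.character(p)[1], character(1))
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  mrna_gene <- setNames(vapply(mrna$Parent, function(p) as.character(p)[1],
                               character(1)), mrna$ID)
  cds$mrna_id <- parent_chr
  cds$gene_id <- unname(mrna_gene[parent_chr])
  cds$gene_id[is.na(cds$gene_id)] <- parent_chr[is.na(cds$gene_id)]

  # one transcript per gene: keep the longest total CDS
  tx_len <- cds |>
    dplyr::group_by(.data$gene_id, .data$mrna_id) |>
    dplyr::summarise(len = sum(.data$width), .groups = "drop")
  multi <- tx_len |> dplyr::count(.data$gene_id) |> dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0) {
    inform(sprintf("%d gene(s) with multiple mRNAs; keeping longest CDS each",
                   nrow(multi)))
  }
  keep_tx <- tx_len |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice_max(.data$len, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  cds <- cds[cds$mrna_id %in% keep_tx$mrna_id, , drop = FALSE]

  models <- cds |>
    dplyr::transmute(gene_id = .data$gene_id,
                     chromosome = as.character(.data$seqnames),
                     strand = as.character(.data$strand),
                     start = .data$start, end = .data$end) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(dplyr::if_else(.data$strand == "-", -.data$start, .data$start),
                   .by_group = TRUE) |>
    dplyr::mutate(exon = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "chromosome", "strand", "exon", "start", "end")

  # overlapping CDS segments within a gene are malformed input
  bad <- models |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(ovl = dplyr::n() > 1 &&
                       any(utils::head(.data$end, -1) >= utils::tail(.data$start, -1)),
                     .groups = "drop")
  if (any(bad$ovl)) {
    abort(paste0("overlapping CDS segments in: ",
                 paste(bad$gene_id[bad$ovl], collapse = ", ")))
  }

  len_by_gene <- models |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(len = sum(.data$end - .data$start + 1L), .groups = "drop")
  partial <- len_by_gene$gene_id[len_by_gene$len %% 3L != 0L]
  if (length(partial)) {
    warn(sprintf("%d gene(s) flagged partial (CDS not divisible by 3): %s",
                 length(partial), paste(partial, collapse = ", ")))
  }
  attr(models, "partial") <- partial

  if (!is.null(genome)) {
    prot <- splice_and_translate(models, genome)
    internal_stop <- vapply(prot, function(p) {
      grepl("\\*", substr(p, 1, nchar(p) - 1))
    }, logical(1))
    if (any(internal_stop)) {
      warn(paste0("internal stop codon(s) in: ",
                  paste(names(prot)[internal_stop], collapse = ", ")))
    }
    attr(models, "proteins") <- prot
  }
  models
}

#' Splice CDS segments and translate
#'
#' @param models gene-model tibble as returned by [parse_gene_models()].
#' @param genome genome FASTA path, named character vector, or
#'   `DNAStringSet`.
#' @return named character vector of protein translations, one per
#'   non-partial gene.
#' @export
splice_and_translate <- function(models, genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  partial <- attr(models, "partial") %||% character(0)
  per_gene <- split(models, models$gene_id)
  per_gene <- per_gene[setdiff(names(per_gene), partial)]
  out <- vapply(per_gene, function(gm) {
    gm <- gm[order(gm$exon), , drop = FALSE]
    chr <- genome[[gm$chromosome[1]]]
    segs <- vapply(seq_len(nrow(gm)), function(k) {
      s <- as.character(Biostrings::subseq(chr, gm$start[k], gm$end[k]))
      if (gm$strand[1] == "-") {
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      }
      s
    }, character(1))
    cds <- paste(segs, collapse = "")
    as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                       no.init.codon = TRUE,
                                       if.fuzzy.codon = "solve"))
  }, character(1))
  out
}

#' Extract introns and classify their phases
#'
#' One record per gap between consecutive CDS segments (transcription
#' order). `cds_offset` is the number of coding nucleotides upstream of the
#' intron; `phase = cds_offset mod 3`. `residue_index` is the host (split)
#' codon's residue for phase-1/2 introns and the residue upstream of the
#' insertion point for phase 0; `anchor_residue` is the projection anchor
#' (the split-codon residue, or for phase 0 the residue immediately
#' following the insertion point).
#'
#' @param models gene-model tibble from [parse_gene_models()] or
#'   `simulate_family()$models`; genes flagged partial are skipped.
#' @return tibble with columns `gene_id`, `ordinal`, `chromosome`, `strand`,
#'   `intron_start`, `intron_end`, `length`, `cds_offset`, `phase`,
#'   `residue_index`, `anchor_residue`.
#' @export
extract_introns <- function(models) {
  partial <- attr(models, "partial") %||% character(0)
  per_gene <- split(models, models$gene_id)
  per_gene <- per_gene[setdiff(names(per_gene), partial)]
  recs <- lapply(per_gene, function(gm) {
    gm <- gm[order(gm$exon), , drop = FALSE]
    n_seg <- nrow(gm)
    if (n_seg < 2) return(NULL)
    widths <- gm$end - gm$start + 1L
    L <- cumsum(widths)[-n_seg]
    minus <- gm$strand[1] == "-"
    istart <- if (minus) gm$end[-1] + 1L else gm$end[-n_seg] + 1L
    iend <- if (minus) gm$start[-n_seg] - 1L else gm$start[-1] - 1L
    phase <- L %% 3L
    tibble(
      gene_id = gm$gene_id[1], ordinal = seq_len(n_seg - 1L),
      chromosome = gm$chromosome[1], strand = gm$strand[1],
      intron_start = istart, intron_end = iend,
      length = iend - istart + 1L,
      cds_offset = L, phase = phase,
      residue_index = L %/% 3L + ifelse(phase > 0L, 1L, 0L),
      anchor_residue = L %/% 3L + 1L
    )
  })
  dplyr::bind_rows(recs)
}

#' Project introns onto a protein multiple alignment
#'
#' Maps each intron's anchor residue to its column in the gene's aligned row
#' (counting non-gap positions). Fails if an anchor residue exceeds the
#' ungapped row length, which signals an MSA/gene-model mismatch.
#'
#' @param introns tibble from [extract_introns()].
#' @param msa named character vector of aligned rows (see
#'   [read_msa_fasta()]), covering every gene in `introns`.
#' @return `introns` with an added `alignment_column`.
#' @export
project_introns <- function(introns, msa) {
  if (is.data.frame(msa)) {
    msa <- setNames(msa[[2]], msa[[1]])
  }
  missing <- setdiff(unique(introns$gene_id), names(msa))
  if (length(missing)) {
    abort(paste0("genes absent from MSA: ", paste(missing, collapse = ", ")))
  }
  col_of <- function(gene, residue) {
    chars <- strsplit(msa[[gene]], "")[[1]]
    nongap <- chars != "-"
    cum <- cumsum(nongap)
    if (residue > max(cum)) {
      abort(sprintf(
        "anchor residue %d beyond ungapped length %d for %s (MSA/gene-model mismatch)",
        residue, max(cum), gene))
    }
    which(nongap & cum == residue)[1]
  }
  introns$alignment_column <- vapply(seq_len(nrow(introns)), function(i) {
    as.integer(col_of(introns$gene_id[i], introns$anchor_residue[i]))
  }, integer(1))
  introns
}

#' Detect conserved intron-insertion events
#'
#' Clusters projected introns by alignment column (single linkage, merging
#' neighbours at gap `<= window` columns) and numbers the clusters I-1,
#' I-2, ... by increasing column. With a correct alignment, introns derived
#' from one ancestral insertion co-project, so the default window is 0.
#'
#' @param introns projected introns from [project_introns()].
#' @param window maximum column gap merged into one event (default 0).
#' @param min_members events with fewer member genes are kept but flagged.
#' @return tibble of class `insertion_events`: `event_id`, `col_lo`,
#'   `col_hi`, `column` (member-count-weighted modal column), `n_introns`,
#'   `n_genes`, `phase0`, `phase1`, `phase2`, `dominant_phase`, `flagged`,
#'   and list-column `members` (gene ids). Attribute `introns` carries the
#'   input with an `event_id` column added.
#' @export
detect_events <- function(introns, window = 0, min_members = 2) {
  stopifnot(window >= 0)
  if (!"alignment_column" %in% names(introns)) {
    abort("introns must be projected first (see project_introns)")
  }
  introns <- dplyr::arrange(introns, .data$alignment_column, .data$gene_id)
  if (nrow(introns) == 0) {
    ev <- tibble(event_id = character(0), col_lo = integer(0),
                 col_hi = integer(0), column = integer(0),
                 n_introns = integer(0), n_genes = integer(0),
                 phase0 = integer(0), phase1 = integer(0), phase2 = integer(0),
                 dominant_phase = integer(0), flagged = logical(0),
                 members = list())
    class(ev) <- c("insertion_events", class(ev))
    attr(ev, "introns") <- introns
    return(ev)
  }
  cols <- introns$alignment_column
  new_cluster <- c(TRUE, diff(cols) > window)
  cluster <- cumsum(new_cluster)
  introns$event_id <- sprintf("I-%d", cluster)
  ev <- introns |>
    dplyr::group_by(.data$event_id) |>
    dplyr::summarise(
      col_lo = min(.data$alignment_column),
      col_hi = max(.data$alignment_column),
      column = as.integer(names(which.max(table(.data$alignment_column)))),
      n_introns = dplyr::n(),
      n_genes = dplyr::n_distinct(.data$gene_id),
      phase0 = sum(.data$phase == 0L),
      phase1 = sum(.data$phase == 1L),
      phase2 = sum(.data$phase == 2L),
      members = list(sort(unique(.data$gene_id))),
      .groups = "drop") |>
    dplyr::arrange(.data$col_lo)
  ev$event_id <- sprintf("I-%d", seq_len(nrow(ev)))
  phase_mat <- as.matrix(ev[, c("phase0", "phase1", "phase2")])
  ev$dominant_phase <- as.integer(max.col(phase_mat, ties.method = "first") - 1L)
  ev$flagged <- ev$n_genes < min_members
  ev <- ev[, c("event_id", "col_lo", "col_hi", "column", "n_introns",
               "n_genes", "phase0", "phase1", "phase2", "dominant_phase",
               "flagged", "members")]
  class(ev) <- c("insertion_events", class(ev))
  # re-key the per-intron event ids to the column-ordered numbering
  key <- setNames(ev$event_id, ev$col_lo)
  introns$event_id <- vapply(cluster, function(cl) {
    lo <- min(cols[cluster == cl]); unname(key[as.character(lo)])
  }, character(1))
  attr(ev, "introns") <- introns
  ev
}

#' Summarise insertion events as carrier and phase shares
#'
#' For each event: the percentage of intron-bearing family genes that carry
#' it, and the percentage of its introns in the dominant phase. Percentages
#' are rounded half away from zero.
#'
#' @param events an [detect_events()] result.
#' @param n_carrier_genes total number of intron-bearing genes in the family
#'   (the denominator for carrier share).
#' @return tibble: `event_id`, `column`, `n_genes`, `carrier_pct`,
#'   `dominant_phase`, `dominant_phase_pct`.
#' @export
event_summary <- function(events, n_carrier_genes) {
  dom_n <- as.matrix(events[, c("phase0", "phase1", "phase2")])
  dom_count <- dom_n[cbind(seq_len(nrow(events)), events$dominant_phase + 1L)]
  tibble(
    event_id = events$event_id,
    column = events$column,
    n_genes = events$n_genes,
    carrier_pct = vapply(events$n_genes, pct_of, numeric(1),
                         total = n_carrier_genes),
    dominant_phase = events$dominant_phase,
    dominant_phase_pct = round_half_up(100 * dom_count / events$n_introns)
  )
}

#' Tabulate intron counts by phylogenetic group
#'
#' The group-by-intron-number contingency table of a gene family: cell
#' (g, c) is the number of genes in group g with exactly c introns, with
#' row and column totals.
#'
#' @param genes tibble with columns `gene_id`, `n_introns` (e.g.
#'   `simulate_family()$truth_genes`, or built from [extract_introns()]
#'   output via [count_gene_introns()]).
#' @param assignment optional tibble with `gene_id`, `group`; without it a
#'   single "all" row is produced.
#' @return wide tibble: one row per group plus a `Total` row; one column per
#'   observed intron count plus a `Total` column.
#' @export
intron_count_table <- function(genes, assignment = NULL) {
  genes <- as_tibble(genes)
  if (!is.null(assignment)) {
    genes <- dplyr::left_join(genes, as_tibble(assignment), by = "gene_id")
    genes$group[is.na(genes$group)] <- "unassigned"
  } else {
    genes$group <- "all"
  }
  counts_seen <- sort(unique(genes$n_introns))
  tab <- table(factor(genes$group, levels = sort(unique(genes$group))),
               factor(genes$n_introns, levels = counts_seen))
  m <- as.matrix(unclass(tab))
  m <- rbind(m, Total = colSums(m))
  m <- cbind(m, Total = rowSums(m))
  out <- as_tibble(m, rownames = "group")
  out
}

#' Per-gene intron counts from an intron table
#'
#' @param introns [extract_introns()] output.
#' @param gene_ids all family gene ids (genes without introns get 0).
#' @return tibble `gene_id`, `n_introns`.
#' @export
count_gene_introns <- function(introns, gene_ids) {
  n <- table(factor(introns$gene_id, levels = gene_ids))
  tibble(gene_id = gene_ids, n_introns = as.integer(n))
}

#' Share of genes with a given intron count
#'
#' Convenience on top of the group-by-count table: the rounded percentage of
#' genes in `group` (or overall) carrying exactly `n_introns` introns.
#'
#' @param genes,assignment as in [intron_count_table()].
#' @param n_introns intron count of interest.
#' @param group optional group label; default pools all genes.
#' @return integer percentage (rounded half away from zero).
#' @export
intron_share <- function(genes, n_introns, assignment = NULL, group = NULL) {
  genes <- as_tibble(genes)
  if (!is.null(group)) {
    stopifnot(!is.null(assignment))
    genes <- dplyr::semi_join(
      genes, dplyr::filter(as_tibble(assignment), .data$group == !!group),
      by = "gene_id")
  }
  pct_of(sum(genes$n_introns == n_introns), nrow(genes))
}

#' Chromosome distribution of family genes
#'
#' Counts genes per chromosome, with scaffold-resident genes pooled into an
#' `unplaced` bucket, optionally broken down by phylogenetic group.
#'
#' @param genes tibble with `gene_id`, `chromosome`.
#' @param assignment optional tibble with `gene_id`, `group`.
#' @param chromosome_pattern regex recognising placed chromosomes (default
#'   `"^chr"`); anything else counts as unplaced.
#' @return tibble of per-chromosome counts (`chromosome`, `n`), or a wide
#'   group-by-chromosome table when `assignment` is given (plus `Total`s).
#' @export
chromosome_summary <- function(genes, assignment = NULL,
                               chromosome_pattern = "^chr") {
  genes <- as_tibble(genes)
  chrom <- ifelse(grepl(chromosome_pattern, genes$chromosome),
                  genes$chromosome, "unplaced")
  lev <- c(sort(unique(chrom[chrom != "unplaced"])),
           if (any(chrom == "unplaced")) "unplaced")
  if (is.null(assignment)) {
    return(tibble(chromosome = lev,
                  n = as.integer(table(factor(chrom, levels = lev)))))
  }
  genes$group <- dplyr::left_join(genes, as_tibble(assignment),
                                  by = "gene_id")$group
  genes$group[is.na(genes$group)] <- "unassigned"
  tab <- table(factor(genes$group), factor(chrom, levels = lev))
  m <- as.matrix(unclass(tab))
  m <- rbind(m, Total = colSums(m))
  m <- cbind(m, Total = rowSums(m))
  as_tibble(m, rownames = "group")
}
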