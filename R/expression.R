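# Expression-pattern summaries: row z-scores (the -2..2 heatmap scale),
# hierarchical clustering for heatmap row order, tissue-max calls, and
# paired treated/control induction calls.

#' Z-score matrix rows
#'
#' Centers and scales each gene's profile to mean 0, sd 1 using the
#' population (n-denominator) standard deviation, the convention of common
#' heatmap tools. Constant rows map to all zeros and are flagged.
#'
#' @param m wide tibble (`gene_id` + sample columns) or numeric matrix with
#'   rownames.
#' @return tibble of the same shape; attribute `constant` names flagged
#'   rows.
#' @export
zscore_rows <- function(m) {
  mm <- as_id_matrix(m)
  if (ncol(mm) < 2) abort("need at least 2 samples")
  mu <- rowMeans(mm)
  sdp <- sqrt(rowMeans((mm - mu)^2))
  const <- sdp == 0
  z <- (mm - mu) / ifelse(const, 1, sdp)
  z[const, ] <- 0
  if (any(const)) {
    warn(paste0("constant row(s) set to zero: ",
                paste(rownames(mm)[const], collapse = ", ")))
  }
  out <- matrix_to_tibble(z)
  attr(out, "constant") <- rownames(mm)[const]
  out
}

#' Hierarchically cluster matrix rows for heatmap ordering
#'
#' Agglomerative clustering with average linkage on a 1 - Pearson
#' correlation distance. Rows with zero variance (correlation undefined)
#' are excluded from clustering, placed after the ordered rows, and
#' flagged.
#'
#' @param m wide tibble or matrix as in [zscore_rows()].
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return list: `order` (row ids, dendrogram leaf order, flagged rows
#'   last), `hclust` (the merge tree), `flagged` (constant row ids).
#' @export
cluster_rows <- function(m, linkage = "average") {
  mm <- as_id_matrix(m)
  if (nrow(mm) < 2) abort("need at least 2 rows")
  sds <- apply(mm, 1, stats::sd)
  flagged <- rownames(mm)[sds == 0]
  keep <- mm[sds > 0, , drop = FALSE]
  if (nrow(keep) < 2) {
    return(list(order = c(rownames(keep), flagged), hclust = NULL,
                flagged = flagged))
  }
  d <- as.dist(1 - cor(t(keep)))
  hc <- hclust(d, method = linkage)
  list(order = c(rownames(keep)[hc$order], flagged), hclust = hc,
       flagged = flagged)
}

#' Tissue-max calls
#'
#' Assigns each gene to the sample group with maximal mean abundance
#' (replicate means). Ties go to the first tied group in metadata order and
#' are flagged; all-zero genes are flagged `no_signal` and excluded from
#' the summary counts.
#'
#' @param m wide tibble or matrix (genes x samples).
#' @param metadata tibble with `sample_id`, `group` covering every sample
#'   column; group order defines the tie-break order.
#' @return tibble of class `tissue_max_calls`: `gene_id`, `call`, `tied`,
#'   `no_signal`.
#' @seealso [tissue_max_summary()] for per-group counts and percentages.
#' @export
tissue_max_calls <- function(m, metadata) {
  mm <- as_id_matrix(m)
  metadata <- as_tibble(metadata)
  missing <- setdiff(colnames(mm), metadata$sample_id)
  if (length(missing)) {
    abort(paste0("samples missing from metadata: ",
                 paste(missing, collapse = ", ")))
  }
  groups <- unique(metadata$group)
  gm <- vapply(groups, function(g) {
    rowMeans(mm[, metadata$sample_id[metadata$group == g], drop = FALSE])
  }, numeric(nrow(mm)))
  no_signal <- rowSums(mm) == 0
  idx <- max.col(gm, ties.method = "first")
  n_at_max <- rowSums(gm >= gm[cbind(seq_len(nrow(gm)), idx)] - 1e-12)
  out <- tibble(
    gene_id = rownames(mm),
    call = unname(ifelse(no_signal, NA_character_, groups[idx])),
    tied = !no_signal & n_at_max > 1,
    no_signal = no_signal
  )
  class(out) <- c("tissue_max_calls", class(out))
  attr(out, "groups") <- groups
  out
}

#' Per-group tissue-max counts and percentages
#'
#' @param calls a [tissue_max_calls()] result.
#' @return tibble `group`, `n`, `pct` (integer percentage of non-flagged
#'   genes, rounded half away from zero).
#' @export
tissue_max_summary <- function(calls) {
  groups <- attr(calls, "groups") %||% sort(unique(stats::na.omit(calls$call)))
  called <- calls[!calls$no_signal, , drop = FALSE]
  n <- table(factor(called$call, levels = groups))
  tibble(group = groups, n = as.integer(n),
         pct = vapply(as.integer(n), pct_of, numeric(1), total = nrow(called)))
}

#' Induction calls from a paired treated/control design
#'
#' For every gene and timepoint, computes
#' `lfc = log2((treated_mean + 1) / (control_mean + 1))` on replicate means
#' (pseudocount 1) and calls `induced` / `repressed` / `unchanged` against
#' `+/- lfc_threshold`. A threshold-on-fold-change rule is used in place of
#' a formal test because the pipeline consumes normalised matrices without
#' count-level variance information.
#'
#' @param m wide tibble or matrix (genes x samples).
#' @param metadata tibble `sample_id`, `group`.
#' @param pairing tibble with columns `treated`, `control` naming matched
#'   sample groups (e.g. `48h` vs `48h-CK`); every treated group must have
#'   its control present.
#' @param lfc_threshold absolute log2 fold-change cutoff (default 1).
#' @return tibble: `gene_id`, `treated`, `control`, `lfc`, `call`.
#' @export
uv_response <- function(m, metadata, pairing, lfc_threshold = 1) {
  mm <- as_id_matrix(m)
  metadata <- as_tibble(metadata)
  pairing <- as_tibble(pairing)
  missing <- setdiff(c(pairing$treated, pairing$control),
                     unique(metadata$group))
  if (length(missing)) {
    abort(paste0("unpaired/missing sample group(s): ",
                 paste(missing, collapse = ", ")))
  }
  gmean <- function(g) {
    rowMeans(mm[, metadata$sample_id[metadata$group == g], drop = FALSE])
  }
  purrr::pmap_dfr(pairing, function(treated, control, ...) {
    lfc <- log2((gmean(treated) + 1) / (gmean(control) + 1))
    tibble(gene_id = rownames(mm), treated = treated, control = control,
           lfc = unname(lfc),
           call = dplyr::case_when(
             lfc >= lfc_threshold ~ "induced",
             lfc <= -lfc_threshold ~ "repressed",
             TRUE ~ "unchanged"))
  })
}
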