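# Transcript-metabolite correlation and candidate ranking, plus the
# glycoside ion-mass arithmetic used to confirm reaction products in
# negative-mode LC-MS.

#' Correlate stage-mean expression with metabolite profiles
#'
#' Pearson correlation of every gene x compound pair over shared stages,
#' two-sided p from the t distribution with n - 2 df, and
#' Benjamini-Hochberg q-values across all pairs. Pairs involving a
#' constant profile (r undefined) are skipped and flagged.
#'
#' @param expr_stages wide tibble or matrix of stage-mean expression
#'   (genes x stages); see [stage_means()].
#' @param metab wide tibble or matrix (compounds x stages).
#' @param stage_map optional tibble with columns `expr_stage`,
#'   `metab_stage` mapping expression stage names onto metabolite stage
#'   names; by default stages are matched by identical name.
#' @return tibble of class `correlation_results`: `gene_id`, `compound_id`,
#'   `r`, `p`, `q`; attribute `skipped` lists constant-profile pairs.
#' @export
correlate_profiles <- function(expr_stages, metab, stage_map = NULL) {
  em <- as_id_matrix(expr_stages)
  cm <- as_id_matrix(metab)
  if (!is.null(stage_map)) {
    stage_map <- as_tibble(stage_map)
    em <- em[, stage_map$expr_stage, drop = FALSE]
    colnames(em) <- stage_map$metab_stage
  }
  shared <- intersect(colnames(em), colnames(cm))
  if (length(shared) < 3) abort("need at least 3 shared stages")
  em <- em[, shared, drop = FALSE]
  cm <- cm[, shared, drop = FALSE]
  n <- length(shared)
  const_g <- apply(em, 1, stats::sd) == 0
  const_c <- apply(cm, 1, stats::sd) == 0
  r <- cor(t(em[!const_g, , drop = FALSE]), t(cm[!const_c, , drop = FALSE]))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  out <- tibble(
    gene_id = rep(rownames(r), times = ncol(r)),
    compound_id = rep(colnames(r), each = nrow(r)),
    r = as.vector(r),
    p = as.vector(p)
  )
  out$q <- p.adjust(out$p, method = "BH")
  skipped <- c(rownames(em)[const_g], rownames(cm)[const_c])
  if (length(skipped)) {
    warn(paste0("constant profile(s) skipped: ", paste(skipped, collapse = ", ")))
  }
  attr(out, "skipped") <- skipped
  attr(out, "n_stages") <- n
  class(out) <- c("correlation_results", class(out))
  out
}

#' Stage-mean expression matrix
#'
#' Collapses a genes x samples matrix to replicate means per sample group.
#'
#' @param m wide tibble or matrix (genes x samples).
#' @param metadata tibble `sample_id`, `group`.
#' @param stages optional subset/order of groups to keep.
#' @return wide tibble: `gene_id` plus one column per group.
#' @export
stage_means <- function(m, metadata, stages = NULL) {
  mm <- as_id_matrix(m)
  metadata <- as_tibble(metadata)
  groups <- stages %||% unique(metadata$group)
  out <- vapply(groups, function(g) {
    rowMeans(mm[, metadata$sample_id[metadata$group == g], drop = FALSE])
  }, numeric(nrow(mm)))
  matrix_to_tibble(out)
}

#' Select significant positive candidates for one compound
#'
#' Genes with `r > r_min` and `q <= q_max` against the named compound,
#' ranked by descending correlation.
#'
#' @param results a [correlate_profiles()] result.
#' @param compound compound id.
#' @param r_min minimum correlation (default 0, i.e. any positive r).
#' @param q_max BH q-value ceiling (default 0.05).
#' @return tibble of qualifying rows sorted by descending `r`.
#' @export
select_candidates <- function(results, compound, r_min = 0, q_max = 0.05) {
  if (!compound %in% results$compound_id) {
    abort(paste0("unknown compound: ", compound))
  }
  out <- results[results$compound_id == compound &
                   results$r > r_min & results$q <= q_max, , drop = FALSE]
  out[order(-out$r, out$gene_id), ]
}

#' Glycoside ion m/z
#'
#' Nominal-mass arithmetic for negative-mode glycoside ions: each hexose
#' unit adds 162 (glucose minus water), deprotonation subtracts 1, and the
#' formic-acid adduct adds a further 46. For 2-phenylethanol (aglycone 122)
#' this gives the mono-glucoside ions m/z 283 ([M-H]-) and 329 (formate
#' adduct). A monoisotopic mode (dehydrated hexose 162.0528, proton
#' 1.00728, formic acid 46.00548) is available for high-resolution work.
#'
#' @param aglycone_mass aglycone mass in Da (nominal by default).
#' @param n_hexose number of hexose units (>= 0, default 1).
#' @param adduct `"[M-H]-"` or `"[M+HCOO]-"` (formate).
#' @param monoisotopic use monoisotopic constants instead of nominal.
#' @return m/z value.
#' @export
#' @examples
#' glycoside_mz(122, 1)                  # 283
#' glycoside_mz(122, 1, "[M+HCOO]-")     # 329
glycoside_mz <- function(aglycone_mass, n_hexose = 1,
                         adduct = c("[M-H]-", "[M+HCOO]-"),
                         monoisotopic = FALSE) {
  adduct <- match.arg(adduct)
  if (aglycone_mass <= 0 || n_hexose < 0) {
    abort("masses must be positive and n_hexose >= 0")
  }
  hex <- if (monoisotopic) 162.0528 else 162
  prot <- if (monoisotopic) 1.00728 else 1
  formic <- if (monoisotopic) 46.00548 else 46
  mz <- aglycone_mass + hex * n_hexose - prot
  if (adduct == "[M+HCOO]-") mz <- mz + formic
  mz
}
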