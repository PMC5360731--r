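# Synthetic expression and metabolite matrices with planted truth.
#
# Noise model is lognormal on a TPM-like scale (the pipeline consumes
# normalised abundance matrices, not counts): observed = mean * exp(N(0, sd)).

#' Simulate an expression matrix with planted tissue-max genes
#'
#' Each gene is planted to peak in one sample group: its pre-noise mean
#' there is `baseline * effect_size`, while every other group draws a mean
#' uniformly in `[0.3, 1] * baseline`, so the planted group exceeds all
#' others by at least `effect_size`-fold before noise. Independent
#' lognormal noise is then applied per observation (each gene uses its own
#' seeded stream, so two genes planted identically still get independent
#' draws).
#'
#' @param gene_ids character vector of gene ids (e.g.
#'   `simulate_family()$truth_genes$gene_id`).
#' @param planted_max named character vector `gene_id -> sample group`;
#'   genes not named are assigned round-robin over `sample_groups`.
#' @param sample_groups tissue/stage groups; defaults mirror a perennial
#'   fruit design: leaf, flower, four developmental stages S1-S4 and two
#'   post-harvest ripening points.
#' @param n_replicates biological replicates per group (default 3).
#' @param effect_size fold-elevation of the planted group (must be > 1).
#' @param noise_sd sd of the lognormal noise on the log scale.
#' @param baseline baseline mean abundance (TPM-like units).
#' @param correlated_sets optional list of character vectors; the genes in
#'   each set share a lognormal latent profile over the sample groups
#'   (gene-specific scale, multiplicative jitter `profile_jitter_sd`), so
#'   their stage profiles are strongly mutually correlated -- the substrate
#'   for planting transcript-metabolite links. Genes in a set ignore
#'   `planted_max`; their planted group is the latent profile's argmax.
#' @param profile_jitter_sd log-scale jitter between members of a
#'   correlated set (default 0.05).
#' @param latent_sd log-scale spread of a correlated set's latent profile
#'   across sample groups (default 2, a strongly stage-regulated module).
#' @param seed integer seed.
#' @return list of class `expression_sim`: `matrix` (wide tibble, `gene_id`
#'   plus one column per sample), `metadata` (tibble `sample_id`, `group`,
#'   `replicate`), `truth` (tibble `gene_id`, `planted_group`).
#' @export
simulate_expression <- function(gene_ids,
                                planted_max = NULL,
                                sample_groups = c("leaf", "flower", "S1", "S2",
                                                  "S3", "S4", "S4+3d", "S4+6d"),
                                n_replicates = 3,
                                effect_size = 8,
                                noise_sd = 0.2,
                                baseline = 50,
                                correlated_sets = list(),
                                profile_jitter_sd = 0.05,
                                latent_sd = 2,
                                seed = 1) {
  if (effect_size <= 1) abort("effect_size must exceed 1")
  if (is.null(planted_max)) {
    planted_max <- setNames(rep(sample_groups, length.out = length(gene_ids)),
                            gene_ids)
  }
  unknown <- setdiff(unique(planted_max), sample_groups)
  if (length(unknown)) {
    abort(paste0("unknown sample group(s) in planted_max: ",
                 paste(unknown, collapse = ", ")))
  }
  extra <- setdiff(names(planted_max), gene_ids)
  if (length(extra)) {
    abort(paste0("planted_max names not in gene_ids: ",
                 paste(extra, collapse = ", ")))
  }
  # unplanted genes filled round-robin
  rest <- setdiff(gene_ids, names(planted_max))
  if (length(rest)) {
    planted_max <- c(planted_max,
                     setNames(rep(sample_groups, length.out = length(rest)), rest))
  }
  planted_max <- planted_max[gene_ids]

  metadata <- tidyr::expand_grid(group = sample_groups,
                                 replicate = seq_len(n_replicates)) |>
    dplyr::mutate(sample_id = sprintf("%s_r%d", .data$group, .data$replicate)) |>
    dplyr::select("sample_id", "group", "replicate")

  set_of <- setNames(rep(NA_integer_, length(gene_ids)), gene_ids)
  for (k in seq_along(correlated_sets)) set_of[correlated_sets[[k]]] <- k
  latents <- lapply(seq_along(correlated_sets), function(k) {
    with_seed(substream_seed(seed, paste0("latent_", k)), {
      setNames(baseline * exp(rnorm(length(sample_groups), 0, latent_sd)),
               sample_groups)
    })
  })

  n_g <- length(gene_ids)
  n_s <- nrow(metadata)
  m <- matrix(NA_real_, n_g, n_s, dimnames = list(gene_ids, metadata$sample_id))
  for (i in seq_len(n_g)) {
    with_seed(substream_seed(seed, paste0("expr_", gene_ids[i])), {
      if (!is.na(set_of[i])) {
        lat <- latents[[set_of[i]]]
        scale <- exp(rnorm(1, 0, 0.5))
        mu <- lat * scale * exp(rnorm(length(lat), 0, profile_jitter_sd))
        planted_max[i] <- names(lat)[which.max(lat)]
      } else {
        mu <- baseline * runif(length(sample_groups), 0.3, 1)
        names(mu) <- sample_groups
        mu[planted_max[i]] <- baseline * effect_size
      }
      means <- mu[metadata$group]
      m[i, ] <- means * exp(rnorm(n_s, 0, noise_sd))
    })
  }
  structure(list(
    matrix = matrix_to_tibble(m),
    metadata = metadata,
    truth = tibble(gene_id = gene_ids, planted_group = unname(planted_max))
  ), class = "expression_sim")
}

#' Simulate a paired treated/control design with planted induced genes
#'
#' Emulates a stress time-course (e.g. UV-B irradiation with matched
#' controls at each timepoint): induced genes get their treated mean raised
#' `effect_size`-fold over control at the stated timepoint; all other
#' treated/control pairs share a mean.
#'
#' @param gene_ids gene ids.
#' @param induced named list `timepoint -> character vector of induced
#'   genes` (e.g. `list("48h" = c("g001", ...))`).
#' @param timepoints treatment timepoints; each gets a `<tp>` treated and a
#'   `<tp>-CK` control group.
#' @param n_replicates,effect_size,noise_sd,baseline,seed as in
#'   [simulate_expression()].
#' @return list of class `expression_sim` (truth lists `gene_id`,
#'   `timepoint`, `induced`).
#' @export
simulate_uv_expression <- function(gene_ids, induced,
                                   timepoints = c("6h", "48h"),
                                   n_replicates = 3, effect_size = 8,
                                   noise_sd = 0.2, baseline = 50, seed = 1) {
  stopifnot(all(names(induced) %in% timepoints))
  groups <- as.vector(rbind(paste0(timepoints, "-CK"), timepoints))
  metadata <- tidyr::expand_grid(group = groups,
                                 replicate = seq_len(n_replicates)) |>
    dplyr::mutate(sample_id = sprintf("%s_r%d", .data$group, .data$replicate)) |>
    dplyr::select("sample_id", "group", "replicate")
  n_g <- length(gene_ids)
  m <- matrix(NA_real_, n_g, nrow(metadata),
              dimnames = list(gene_ids, metadata$sample_id))
  for (i in seq_len(n_g)) {
    with_seed(substream_seed(seed, paste0("uv_", gene_ids[i])), {
      mu <- setNames(baseline * runif(length(groups), 0.5, 1), groups)
      for (tp in timepoints) {
        mu[tp] <- mu[paste0(tp, "-CK")]
        if (gene_ids[i] %in% induced[[tp]]) {
          mu[tp] <- mu[paste0(tp, "-CK")] * effect_size
        }
      }
      means <- mu[metadata$group]
      m[i, ] <- means * exp(rnorm(nrow(metadata), 0, noise_sd))
    })
  }
  truth <- tidyr::expand_grid(gene_id = gene_ids, timepoint = timepoints) |>
    dplyr::mutate(induced = purrr::map2_lgl(
      .data$gene_id, .data$timepoint, ~ .x %in% induced[[.y]]))
  structure(list(matrix = matrix_to_tibble(m), metadata = metadata,
                 truth = truth),
            class = "expression_sim")
}

#' Simulate a metabolite matrix linked to chosen genes
#'
#' Each linked compound's stage profile is an affine transform of its
#' gene's stage-mean expression profile plus an orthogonalised noise
#' component calibrated so the sample Pearson correlation equals `r_target`
#' exactly (`r_target = 1` gives a noise-free linear copy). Unlinked
#' compounds are independent lognormal profiles.
#'
#' @param expr an `expression_sim` (or any list with `matrix` + `metadata`).
#' @param n_compounds total number of compounds emitted.
#' @param linked tibble with columns `gene_id`, `compound_id`, `r_target`
#'   (|r_target| <= 1); compounds not listed are unlinked.
#' @param stages stage groups used as the metabolite axis (default: the
#'   fruit stages of the expression design).
#' @param seed integer seed.
#' @return list of class `metabolite_sim`: `matrix` (wide tibble,
#'   `compound_id` plus one column per stage), `truth` (the `linked` table).
#' @export
simulate_metabolites <- function(expr, n_compounds, linked,
                                 stages = c("S1", "S2", "S3", "S4",
                                            "S4+3d", "S4+6d"),
                                 seed = 1) {
  linked <- as_tibble(linked)
  if (any(abs(linked$r_target) > 1)) abort("|r_target| must be <= 1")
  if (dplyr::n_distinct(linked$compound_id) > n_compounds) {
    abort("more linked compounds than n_compounds")
  }
  em <- as_id_matrix(expr$matrix)
  md <- expr$metadata
  missing_genes <- setdiff(linked$gene_id, rownames(em))
  if (length(missing_genes)) {
    abort(paste0("linked gene(s) absent from expression matrix: ",
                 paste(missing_genes, collapse = ", ")))
  }
  stages <- intersect(stages, unique(md$group))
  stage_means <- vapply(stages, function(s) {
    rowMeans(em[, md$sample_id[md$group == s], drop = FALSE])
  }, numeric(nrow(em)))

  compound_ids <- unique(c(linked$compound_id,
                           sprintf("cmp%03d", seq_len(n_compounds))))[seq_len(n_compounds)]
  n_st <- length(stages)
  out <- matrix(NA_real_, n_compounds, n_st,
                dimnames = list(compound_ids, stages))
  for (ci in seq_len(n_compounds)) {
    cid <- compound_ids[ci]
    row <- linked[linked$compound_id == cid, , drop = FALSE]
    with_seed(substream_seed(seed, paste0("metab_", cid)), {
      if (nrow(row) >= 1) {
        # calibrate against the mean profile of the compound's linked genes
        # (linked genes are expected to share a correlated stage profile;
        # see the correlated_sets argument of simulate_expression)
        x <- colMeans(stage_means[row$gene_id, , drop = FALSE])
        r <- row$r_target[1]
        xs <- (x - mean(x)) / stats::sd(x)
        e <- rnorm(n_st)
        e <- e - mean(e)
        e <- e - sum(e * xs) / sum(xs * xs) * xs   # orthogonal to x
        es <- if (stats::sd(e) > 0) (e - mean(e)) / stats::sd(e) else e
        y <- r * xs + sqrt(max(0, 1 - r^2)) * es
        prof <- 100 + 30 * y
      } else {
        prof <- 100 * exp(rnorm(n_st, 0, 0.5))
      }
      out[ci, ] <- prof - min(prof, 0) + 1  # keep abundances positive
    })
  }
  structure(list(matrix = matrix_to_tibble(out, id_col = "compound_id"),
                 truth = linked),
            class = "metabolite_sim")
}
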