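# End-to-end orchestration: simulate (optional) -> motif scan -> distances
# -> NJ -> group assignment -> introns -> projection -> events -> summary
# tables -> expression calls -> correlations. One root seed drives every
# stochastic stage through named substreams, so a fixed configuration
# reproduces the report byte for byte.

#' Pipeline configuration
#'
#' Either a simulation spec (synthetic mode) or a complete set of real-data
#' paths must be supplied.
#'
#' @param simulate a [family_sim_spec()] for synthetic mode, or `NULL`.
#' @param paths named list of input paths for real-data mode: `proteome`,
#'   `genome`, `gff3`, `msa`, `anchors` (TSV: anchor_id, group),
#'   `expression`, `metadata`, `metabolites`, optional `stage_map`.
#' @param motif consensus motif for the scan.
#' @param min_fraction motif score-fraction threshold.
#' @param window event-merge window in alignment columns.
#' @param lfc_threshold induction log2 fold-change cutoff.
#' @param r_min,q_max candidate-selection thresholds.
#' @param compound compound id for candidate ranking (default: first
#'   compound in the metabolite matrix).
#' @param seed root seed.
#' @param out_dir optional directory; when given, every stage table is
#'   written as TSV with a provenance header.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, paths = list(),
                            motif = PSPG_MOTIF, min_fraction = 0.4,
                            window = 0, lfc_threshold = 1,
                            r_min = 0, q_max = 0.05, compound = NULL,
                            seed = 1, out_dir = NULL) {
  if (is.null(simulate)) {
    needed <- c("proteome", "genome", "gff3", "msa", "anchors",
                "expression", "metadata", "metabolites")
    missing <- setdiff(needed, names(paths))
    if (length(missing)) {
      abort(paste0("real-data mode needs input path(s): ",
                   paste(missing, collapse = ", ")))
    }
    gone <- names(paths)[!vapply(paths, file.exists, logical(1))]
    if (length(gone)) {
      abort(paste0("input file(s) not found: ", paste(gone, collapse = ", ")))
    }
  } else {
    stopifnot(inherits(simulate, "family_sim_spec"))
  }
  structure(list(simulate = simulate, paths = paths, motif = motif,
                 min_fraction = min_fraction, window = window,
                 lfc_threshold = lfc_threshold, r_min = r_min, q_max = q_max,
                 compound = compound, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full family-analysis pipeline
#'
#' @param config a [pipeline_config()].
#' @return list of class `glycofam_report` collecting every stage output:
#'   `hits`, `tree`, `assignment`, `introns`, `events`, `event_summary`,
#'   `intron_table`, `chromosome_table`, `tissue_calls`, `tissue_summary`,
#'   `correlations`, `candidates`, and `summary` (headline percentages).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  synthetic <- !is.null(config$simulate)

  if (synthetic) {
    sim <- simulate_family(config$simulate, seed = seed)
    proteins <- tibble(protein_id = names(sim$proteins),
                       sequence = unname(sim$proteins))
    msa <- sim$msa
    models <- sim$models
    # anchors: the first member of each group, labelled from truth
    anch <- sim$truth_genes |>
      dplyr::group_by(.data$group) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
    anchors <- tibble(anchor_id = anch$gene_id, group = anch$group)
    linked_genes <- utils::head(sim$truth_genes$gene_id, 8)
    expr <- simulate_expression(sim$truth_genes$gene_id,
                                correlated_sets = list(linked_genes),
                                profile_jitter_sd = 0.01,
                                noise_sd = 0.05,
                                seed = seed)
    linked <- tibble(gene_id = linked_genes,
                     compound_id = "cmp001", r_target = 0.9995)
    metab <- simulate_metabolites(expr, n_compounds = 20, linked = linked,
                                  seed = seed)
    expr_matrix <- expr$matrix; metadata <- expr$metadata
    metab_matrix <- metab$matrix; stage_map <- NULL
  } else {
    p <- config$paths
    proteins <- read_protein_fasta(p$proteome)
    msa <- read_msa_fasta(p$msa)
    models <- parse_gene_models(p$gff3, p$genome)
    anchors <- readr::read_tsv(p$anchors, show_col_types = FALSE)
    expr_matrix <- readr::read_tsv(p$expression, show_col_types = FALSE)
    metadata <- readr::read_tsv(p$metadata, show_col_types = FALSE)
    metab_matrix <- readr::read_tsv(p$metabolites, show_col_types = FALSE)
    stage_map <- if (!is.null(p$stage_map)) {
      readr::read_tsv(p$stage_map, show_col_types = FALSE)
    } else NULL
  }

  hits <- scan_proteome(proteins, config$motif,
                        min_fraction = config$min_fraction)
  family_ids <- intersect(hits$protein_id, names(msa))

  dm <- pairwise_distance(msa[union(family_ids, intersect(anchors$anchor_id,
                                                          names(msa)))])
  tree <- neighbor_joining(dm)
  assignment <- assign_groups(tree, anchors)

  introns <- extract_introns(models)
  introns <- introns[introns$gene_id %in% names(msa), , drop = FALSE]
  introns <- project_introns(introns, msa)
  events <- detect_events(introns, window = config$window)
  n_carriers <- dplyr::n_distinct(introns$gene_id)
  ev_sum <- event_summary(events, n_carriers)

  fam_genes <- tibble(gene_id = family_ids)
  gene_counts <- count_gene_introns(introns, family_ids)
  asg <- rbind(
    tibble(gene_id = assignment$assignments$gene_id,
           group = assignment$assignments$group),
    tibble(gene_id = anchors$anchor_id, group = anchors$group))
  asg <- asg[asg$gene_id %in% family_ids, , drop = FALSE]
  intron_table <- intron_count_table(gene_counts, asg)
  gene_chrom <- dplyr::distinct(models[models$gene_id %in% family_ids,
                                       c("gene_id", "chromosome")])
  chromosome_table <- chromosome_summary(gene_chrom, asg)

  tissue_calls <- tissue_max_calls(expr_matrix, metadata)
  tissue_sum <- tissue_max_summary(tissue_calls)

  sm <- stage_means(expr_matrix, metadata)
  correlations <- correlate_profiles(sm, metab_matrix, stage_map = stage_map)
  compound <- config$compound %||% correlations$compound_id[1]
  candidates <- select_candidates(correlations, compound,
                                  r_min = config$r_min, q_max = config$q_max)

  summary_tbl <- tibble(
    quantity = c("family_members", "intron_bearing_genes", "events",
                 "intronless_pct", "candidates"),
    value = c(length(family_ids), n_carriers, nrow(events),
              intron_share(gene_counts, 0), nrow(candidates)))

  report <- structure(list(
    hits = hits, tree = tree, assignment = assignment, introns = introns,
    events = events, event_summary = ev_sum, intron_table = intron_table,
    chromosome_table = chromosome_table, tissue_calls = tissue_calls,
    tissue_summary = tissue_sum, correlations = correlations,
    candidates = candidates, summary = summary_tbl,
    config = config, seed = seed
  ), class = "glycofam_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.glycofam_report <- function(x, ...) {
  cat("<glycofam_report>\n")
  print(x$summary)
  invisible(x)
}

#' @export
glance.glycofam_report <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "quantity",
                     values_from = "value")
}

#' Write a pipeline report to disk
#'
#' Every stage table is written as TSV with a provenance header line
#' (package version, seed, configuration hash), so each number in the
#' report can be recomputed from the stage table it cites.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  cfg$out_dir <- NULL
  header <- sprintf("# glycofam %s; seed %s; config %s",
                    as.character(utils::packageVersion("glycofam")),
                    format(report$seed), rlang::hash(cfg))
  emit <- function(df, name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    writeLines(header, path)
    df <- as_tibble(df)
    df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  }
  emit(report$hits, "hits")
  emit(tidy(report$assignment), "assignments")
  emit(report$assignment$counts, "group_counts")
  emit(attr(report$events, "introns") %||% report$introns, "introns")
  emit(report$events, "events")
  emit(report$event_summary, "event_summary")
  emit(report$intron_table, "intron_table")
  emit(report$chromosome_table, "chromosome_table")
  emit(as_tibble(report$tissue_calls), "tissue_calls")
  emit(report$tissue_summary, "tissue_summary")
  emit(as_tibble(report$correlations), "correlations")
  emit(as_tibble(report$candidates), "candidates")
  emit(report$summary, "summary")
  ape::write.tree(report$tree, file.path(dir, "tree.nwk"))
  invisible(dir)
}
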