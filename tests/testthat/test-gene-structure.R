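# Intron extraction, the phase rule, alignment projection, event detection
# and the group-level summary tables.

two_exon_model <- function(l1, l2, strand = "+", gap = 100, chrom = "chr01") {
  if (strand == "+") {
    tibble::tibble(gene_id = "g", chromosome = chrom, strand = strand,
                   exon = 1:2, start = c(1, l1 + gap + 1),
                   end = c(l1, l1 + gap + l2))
  } else {
    total <- l1 + gap + l2
    tibble::tibble(gene_id = "g", chromosome = chrom, strand = strand,
                   exon = 1:2,
                   start = c(total - l1 + 1, 1),
                   end = c(total, l2))
  }
}

test_that("phases follow the cumulative-CDS-length rule", {
  expect_equal(extract_introns(two_exon_model(99, 300))$phase, 0)
  expect_equal(extract_introns(two_exon_model(99, 300))$cds_offset, 99)
  expect_equal(extract_introns(two_exon_model(100, 299))$phase, 1)
  expect_equal(extract_introns(two_exon_model(101, 298))$phase, 2)
  # host residue: phase 0 anchors to the following residue
  i0 <- extract_introns(two_exon_model(99, 300))
  expect_equal(i0$residue_index, 33)
  expect_equal(i0$anchor_residue, 34)
  i1 <- extract_introns(two_exon_model(100, 299))
  expect_equal(i1$residue_index, 34)
  expect_equal(i1$anchor_residue, 34)
})

test_that("phase equals L mod 3 for every prefix length 1..3000", {
  models <- purrr::map_dfr(1:3000, function(L) {
    tibble::tibble(gene_id = sprintf("gene%04d", L), chromosome = "chr01",
                   strand = "+", exon = 1:2,
                   start = c(1, L + 101), end = c(L, L + 100 + (3000 - L)))
  })
  # total CDS length is 3000 for every gene, so none is partial
  introns <- extract_introns(models)
  L <- introns$cds_offset
  expect_equal(introns$phase, L %% 3)
  expect_equal(introns$residue_index,
               L %/% 3 + ifelse(L %% 3 > 0, 1, 0))
})

test_that("minus-strand introns get identical offsets and phases", {
  for (l1 in c(99, 100, 101)) {
    plus <- extract_introns(two_exon_model(l1, 300 - (l1 - 99) - 1 + 1))
    minus <- extract_introns(two_exon_model(l1, 300 - (l1 - 99) - 1 + 1,
                                            strand = "-"))
    expect_equal(minus$cds_offset, plus$cds_offset)
    expect_equal(minus$phase, plus$phase)
    expect_equal(minus$length, plus$length)
  }
})

test_that("reversing a chromosome and flipping strands preserves (L, phase)", {
  sim <- small_family()
  chrlen <- nchar(sim$genome)
  flipped <- sim$models
  N <- chrlen[flipped$chromosome]
  new_start <- N - flipped$end + 1
  new_end <- N - flipped$start + 1
  flipped$start <- unname(new_start)
  flipped$end <- unname(new_end)
  flipped$strand <- ifelse(flipped$strand == "+", "-", "+")
  orig <- extract_introns(sim$models)
  flip <- extract_introns(flipped)
  ord <- function(x) x[order(x$gene_id, x$ordinal), ]
  o <- ord(orig); f <- ord(flip)
  expect_equal(f$cds_offset, o$cds_offset)
  expect_equal(f$phase, o$phase)
  expect_equal(f$residue_index, o$residue_index)
})

test_that("projection counts non-gap columns", {
  introns <- tibble::tibble(gene_id = "x", anchor_residue = 2)
  expect_equal(project_introns(introns, c(x = "M-KV"))$alignment_column, 3)
  expect_equal(project_introns(tibble::tibble(gene_id = "x",
                                              anchor_residue = 3),
                               c(x = "MKV"))$alignment_column, 3)
  expect_error(project_introns(tibble::tibble(gene_id = "x",
                                              anchor_residue = 4),
                               c(x = "M-KV")), "mismatch")
})

test_that("the merge window controls event splitting", {
  introns <- tibble::tibble(
    gene_id = c("a", "b", "c"), phase = c(1, 1, 1),
    alignment_column = c(50, 51, 80))
  ev0 <- detect_events(introns, window = 0, min_members = 1)
  expect_equal(nrow(ev0), 3)
  ev1 <- detect_events(introns, window = 1, min_members = 1)
  expect_equal(nrow(ev1), 2)
  expect_equal(ev1$event_id, c("I-1", "I-2"))
  expect_equal(ev1$n_genes, c(2, 1))
})

test_that("events recover the planted truth on a 10-event family", {
  spec <- family_sim_spec(n_family_genes = 96, n_decoy_proteins = 0,
                          intronless_fraction = 0)
  sim <- simulate_family(spec, seed = 1)
  introns <- project_introns(extract_introns(sim$models), sim$msa)
  events <- detect_events(introns, window = 0)
  expect_equal(nrow(events), 10)
  truth_members <- split(sim$truth_introns$gene_id,
                         sim$truth_introns$event_id)
  for (k in seq_len(nrow(events))) {
    expect_setequal(events$members[[k]],
                    truth_members[[events$event_id[k]]])
  }
  # conservation: per-event member counts sum to projected introns
  expect_equal(sum(events$n_introns), nrow(introns))
})

test_that("event membership and numbering ignore gene input order", {
  sim <- small_family()
  introns <- project_introns(extract_introns(sim$models), sim$msa)
  ev1 <- detect_events(introns)
  set.seed(2)
  ev2 <- detect_events(introns[sample(nrow(introns)), ])
  expect_equal(as.data.frame(ev1[, c("event_id", "column", "n_genes")]),
               as.data.frame(ev2[, c("event_id", "column", "n_genes")]))
  expect_equal(ev1$members, ev2$members)
})

test_that("intron-count table conserves family size and group totals", {
  sim <- small_family()
  genes <- sim$truth_genes[, c("gene_id", "n_introns")]
  asg <- sim$truth_genes[, c("gene_id", "group")]
  tab <- intron_count_table(genes, asg)
  tot_row <- tab[tab$group == "Total", ]
  expect_equal(tot_row$Total, nrow(genes))
  expect_equal(sum(tab$Total[tab$group != "Total"]), nrow(genes))
  # empty group keeps totals intact
  asg2 <- asg; asg2$group[asg2$group == "B"] <- "A"
  tab2 <- intron_count_table(genes, asg2)
  expect_equal(tab2$Total[tab2$group == "Total"], nrow(genes))
})

test_that("printed-table arithmetic: intronless and one-intron shares", {
  # the family-wide 72-of-168 intronless case and a 31-of-34 one-intron group
  genes <- tibble::tibble(
    gene_id = sprintf("u%03d", 1:168),
    n_introns = rep(c(0, 1, 2, 3, 5), c(72, 82, 9, 4, 1)))
  expect_equal(intron_share(genes, 0), 43)
  grpG <- tibble::tibble(gene_id = sprintf("G%02d", 1:34),
                         n_introns = rep(c(0, 1, 2, 3), c(1, 31, 1, 1)))
  asg <- tibble::tibble(gene_id = grpG$gene_id, group = "G")
  expect_equal(intron_share(grpG, 1, asg, group = "G"), 91)
})

test_that("chromosome summary buckets scaffolds as unplaced", {
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:10),
    chromosome = c(rep("chr01", 5), rep("chr02", 3), "scaffold_9", "scaffold_12"))
  cs <- chromosome_summary(genes)
  expect_equal(cs$n[cs$chromosome == "chr01"], 5)
  expect_equal(cs$n[cs$chromosome == "unplaced"], 2)
  expect_equal(sum(cs$n), 10)
  sim <- small_family()
  cs2 <- chromosome_summary(sim$truth_genes)
  truth_counts <- table(sim$truth_genes$chromosome)
  expect_equal(setNames(cs2$n, cs2$chromosome)[names(truth_counts)],
               setNames(as.integer(truth_counts), names(truth_counts)))
})

test_that("partial genes are flagged and excluded from phase analysis", {
  models <- dplyr::bind_rows(
    two_exon_model(99, 300),
    tibble::tibble(gene_id = "bad", chromosome = "chr02", strand = "+",
                   exon = 1:2, start = c(1, 201), end = c(100, 300)))
  attr(models, "partial") <- "bad"
  introns <- extract_introns(models)
  expect_false("bad" %in% introns$gene_id)
})
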