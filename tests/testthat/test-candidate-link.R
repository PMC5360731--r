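# Transcript-metabolite correlation, candidate selection and the glycoside
# ion-mass arithmetic.

stage_mat <- function(rows, ids) {
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  colnames(m) <- sprintf("S%d", seq_len(ncol(m)))
  m
}

test_that("perfectly (anti)correlated profiles give r = +/- 1", {
  x <- c(1, 3, 2, 5, 4, 6)
  expr <- stage_mat(list(x), "g1")
  metab <- stage_mat(list(2 * x + 7, -3 * x + 50), c("c_pos", "c_neg"))
  out <- correlate_profiles(expr, metab)
  expect_equal(out$r[out$compound_id == "c_pos"], 1)
  expect_equal(out$r[out$compound_id == "c_neg"], -1)
  expect_equal(out$p[out$compound_id == "c_pos"], 0)
})

test_that("r is invariant to positive affine transforms", {
  set.seed(21)
  x <- runif(6); y <- runif(6)
  base <- correlate_profiles(stage_mat(list(x), "g"),
                             stage_mat(list(y), "c"))$r
  trans <- correlate_profiles(stage_mat(list(3.2 * x + 11), "g"),
                              stage_mat(list(0.4 * y + 2), "c"))$r
  expect_equal(trans, base)
})

test_that("t-distribution p agrees with the exact permutation null", {
  x <- c(10, 20, 35, 55, 80, 120)
  y <- c(12, 25, 30, 60, 70, 135)
  out <- correlate_profiles(stage_mat(list(x), "g"), stage_mat(list(y), "c"))
  perms <- all_permutations(6)
  r_obs <- cor(x, y)
  r_null <- apply(perms, 1, function(p) cor(x, y[p]))
  p_exact <- mean(abs(r_null) >= abs(r_obs) - 1e-12)
  expect_lt(abs(out$p - p_exact), 0.03)
})

test_that("BH q-values are step-up monotone and within [0, 1]", {
  set.seed(22)
  expr <- stage_mat(lapply(1:30, function(i) rnorm(6)), sprintf("g%d", 1:30))
  metab <- stage_mat(lapply(1:5, function(i) rnorm(6)), sprintf("c%d", 1:5))
  out <- correlate_profiles(expr, metab)
  expect_true(all(out$q >= 0 & out$q <= 1))
  ord <- order(out$p)
  expect_true(all(diff(out$q[ord]) >= -1e-12))
  expect_equal(out$q, p.adjust(out$p, "BH"))
})

test_that("null calibration: ~5% of independent pairs reach p < 0.05", {
  set.seed(23)
  expr <- stage_mat(lapply(1:500, function(i) rnorm(6)),
                    sprintf("g%03d", 1:500))
  metab <- stage_mat(lapply(1:20, function(i) rnorm(6)),
                     sprintf("c%02d", 1:20))
  out <- correlate_profiles(expr, metab)   # 10,000 pairs
  frac <- mean(out$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))
})

test_that("unlinked compound profiles stay near-uncorrelated", {
  gid <- sprintf("g%02d", 1:30)
  es <- simulate_expression(gid, seed = 31)
  ms <- simulate_metabolites(es, n_compounds = 20,
                             linked = tibble::tibble(gene_id = character(0),
                                                     compound_id = character(0),
                                                     r_target = numeric(0)),
                             seed = 31)
  sm <- stage_means(es$matrix, es$metadata,
                    stages = c("S1", "S2", "S3", "S4", "S4+3d", "S4+6d"))
  out <- correlate_profiles(sm, ms$matrix)
  expect_lt(mean(abs(out$r)), 0.42)  # E|r| ~ 0.37 for n = 6 under the null
})

test_that("exact-calibration plants reach their target correlation", {
  gid <- sprintf("g%02d", 1:10)
  es <- simulate_expression(gid, seed = 41)
  ms <- simulate_metabolites(
    es, n_compounds = 3,
    linked = tibble::tibble(gene_id = "g01", compound_id = "cmpA",
                            r_target = c(1)),
    seed = 41)
  sm <- stage_means(es$matrix, es$metadata,
                    stages = c("S1", "S2", "S3", "S4", "S4+3d", "S4+6d"))
  out <- correlate_profiles(sm, ms$matrix)
  expect_equal(out$r[out$gene_id == "g01" & out$compound_id == "cmpA"], 1)
})

test_that("eight planted linked genes are selected in >= 95% of seeds", {
  gid <- sprintf("g%03d", 1:168)
  linked_genes <- gid[1:8]
  fruit <- c("S1", "S2", "S3", "S4", "S4+3d", "S4+6d")
  plant <- setNames(rep(c("leaf", "flower"), length.out = 160), gid[9:168])
  hits <- 0
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    es <- simulate_expression(gid, planted_max = plant,
                              correlated_sets = list(linked_genes),
                              profile_jitter_sd = 0.01, noise_sd = 0.05,
                              seed = 9000 + s)
    ms <- simulate_metabolites(
      es, n_compounds = 12,
      linked = tibble::tibble(gene_id = linked_genes, compound_id = "cmp001",
                              r_target = 0.9995),
      seed = 9000 + s)
    cr <- correlate_profiles(stage_means(es$matrix, es$metadata,
                                         stages = fruit), ms$matrix)
    cand <- select_candidates(cr, "cmp001")
    if (setequal(cand$gene_id, linked_genes)) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.95 - 2 * sqrt(0.05 * 0.95 / n_seeds))
})

test_that("selection is monotone in q_max and errors on unknown compounds", {
  set.seed(51)
  expr <- stage_mat(lapply(1:20, function(i) rnorm(6)), sprintf("g%d", 1:20))
  metab <- stage_mat(lapply(1:3, function(i) rnorm(6)), sprintf("c%d", 1:3))
  out <- correlate_profiles(expr, metab)
  loose <- select_candidates(out, "c1", q_max = 1)
  tight <- select_candidates(out, "c1", q_max = 0.2)
  expect_true(all(tight$gene_id %in% loose$gene_id))
  expect_equal(nrow(select_candidates(out, "c1", r_min = 1)), 0)
  expect_error(select_candidates(out, "nope"), "unknown compound")
})

test_that("constant profiles are skipped and flagged", {
  expr <- stage_mat(list(c(1, 1, 1, 1, 1, 1), c(1, 2, 3, 4, 5, 6)),
                    c("flat", "ok"))
  metab <- stage_mat(list(c(5, 4, 6, 2, 1, 3)), "c1")
  expect_warning(out <- correlate_profiles(expr, metab), "flat")
  expect_false("flat" %in% out$gene_id)
  expect_equal(attr(out, "skipped"), "flat")
})

test_that("glycoside ion masses reproduce the worked arithmetic", {
  expect_equal(glycoside_mz(122, 1, "[M-H]-"), 283)
  expect_equal(glycoside_mz(122, 1, "[M+HCOO]-"), 329)
  expect_equal(glycoside_mz(122, 0, "[M-H]-"), 121)
  expect_equal(glycoside_mz(154, 2, "[M-H]-"), 154 + 324 - 1)
  expect_equal(glycoside_mz(122, 1, "[M-H]-", monoisotopic = TRUE),
               122 + 162.0528 - 1.00728)
  expect_error(glycoside_mz(-5), "positive")
  expect_error(glycoside_mz(122, -1), "positive")
})
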