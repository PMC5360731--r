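# z-scores, clustering, tissue-max and induction calls, and the expression
# generator's contracts.

toy_matrix <- function(rows, ids = sprintf("g%d", seq_along(rows))) {
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  m
}

test_that("row z-scores use the population-sd convention", {
  z <- zscore_rows(toy_matrix(list(c(1, 2, 3))))
  expect_equal(unlist(z[1, -1], use.names = FALSE),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  suppressWarnings({
    z2 <- zscore_rows(toy_matrix(list(c(1, 2, 3), c(5, 5, 5))))
  })
  expect_equal(unlist(z2[2, -1], use.names = FALSE), c(0, 0, 0))
  expect_equal(attr(z2, "constant"), "g2")
  # any row: mean 0 within 1e-12
  set.seed(3)
  z3 <- zscore_rows(toy_matrix(list(runif(10), runif(10))))
  expect_lt(max(abs(rowMeans(as.matrix(z3[, -1])))), 1e-12)
})

test_that("identical rows merge first at height zero", {
  m <- toy_matrix(list(c(1, 2, 3, 4), c(2, 4, 6, 8), c(4, 3, 2, 1)))
  cl <- cluster_rows(m)
  # rows 1 and 2 are perfectly correlated -> first merge at height 0
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)
  expect_setequal(hclust_merge_sets(cl$hclust)[[1]], c(1, 2))
})

test_that("merge sequence equals the brute-force agglomeration oracle", {
  set.seed(9)
  for (k in 1:5) {
    n <- sample(4:6, 1)
    m <- toy_matrix(lapply(seq_len(n), function(i) rnorm(8)))
    d <- 1 - cor(t(m))
    oracle <- brute_force_average_linkage(as.dist(d))
    hc <- cluster_rows(m)$hclust
    expect_equal(hc$height, oracle$heights, tolerance = 1e-10)
    expect_equal(hclust_merge_sets(hc), oracle$merges)
  }
})

test_that("row order does not change the dendrogram", {
  set.seed(10)
  m <- toy_matrix(lapply(1:6, function(i) rnorm(8)))
  c1 <- cluster_rows(m)
  perm <- sample(6)
  c2 <- cluster_rows(m[perm, ])
  expect_equal(sort(c1$hclust$height), sort(c2$hclust$height),
               tolerance = 1e-10)
  sets1 <- lapply(hclust_merge_sets(c1$hclust),
                  function(s) sort(rownames(m)[s]))
  sets2 <- lapply(hclust_merge_sets(c2$hclust),
                  function(s) sort(rownames(m[perm, ])[s]))
  expect_equal(sets1, sets2)
})

test_that("tissue-max calls recover a strong planted design", {
  gid <- sprintf("g%03d", 1:168)
  fruit <- c("S1", "S2", "S3", "S4", "S4+3d", "S4+6d")
  plant <- setNames(c(rep("leaf", 45), rep("flower", 54),
                      rep(fruit, length.out = 69)), gid)
  es <- simulate_expression(gid, planted_max = plant, seed = 1)
  calls <- tissue_max_calls(es$matrix, es$metadata)
  expect_equal(calls$call, unname(plant[calls$gene_id]))
  smry <- tissue_max_summary(calls)
  expect_equal(smry$n[smry$group == "leaf"], 45)
  expect_equal(smry$pct[smry$group == "leaf"], 27)
  expect_equal(smry$pct[smry$group == "flower"], 32)
  expect_equal(sum(smry$n), 168)
})

test_that("noise-free argmax equals the planted group for every gene", {
  gid <- sprintf("g%02d", 1:40)
  es <- simulate_expression(gid, effect_size = 8, noise_sd = 0, seed = 2)
  calls <- tissue_max_calls(es$matrix, es$metadata)
  expect_equal(calls$call,
               es$truth$planted_group[match(calls$gene_id,
                                            es$truth$gene_id)])
})

test_that("gene streams are independent but reproducible", {
  gid <- c("a", "b")
  plant <- c(a = "leaf", b = "leaf")
  e1 <- simulate_expression(gid, planted_max = plant, seed = 4)
  e2 <- simulate_expression(gid, planted_max = plant, seed = 4)
  expect_identical(e1$matrix, e2$matrix)
  expect_false(isTRUE(all.equal(unlist(e1$matrix[1, -1]),
                                unlist(e1$matrix[2, -1]))))
})

test_that("ties go to the first metadata group and are flagged", {
  m <- toy_matrix(list(c(5, 5), c(0, 0)), ids = c("t", "z"))
  md <- tibble::tibble(sample_id = c("s1", "s2"), group = c("gB", "gA"))
  calls <- tissue_max_calls(m, md)
  expect_equal(calls$call[1], "gB")  # metadata order, not alphabetical
  expect_true(calls$tied[1])
  expect_true(calls$no_signal[2])
  smry <- tissue_max_summary(calls)
  expect_equal(sum(smry$n), 1)  # no-signal gene excluded
})

test_that("scaling a row never changes its tissue-max call", {
  set.seed(12)
  m <- toy_matrix(list(runif(6), runif(6)))
  md <- tibble::tibble(sample_id = colnames(m),
                       group = rep(c("x", "y", "z"), each = 2))
  c1 <- tissue_max_calls(m, md)
  c2 <- tissue_max_calls(m * 137.5, md)
  expect_equal(c1$call, c2$call)
})

test_that("induction calls follow the pseudocounted fold-change rule", {
  m <- toy_matrix(list(c(15, 15, 3, 3), c(7, 7, 7, 7)), ids = c("up", "flat"))
  md <- tibble::tibble(sample_id = colnames(m),
                       group = rep(c("48h", "48h-CK"), each = 2))
  pairing <- tibble::tibble(treated = "48h", control = "48h-CK")
  out <- uv_response(m, md, pairing, lfc_threshold = 1)
  expect_equal(out$lfc[out$gene_id == "up"], 2)  # log2(16/4)
  expect_equal(out$call[out$gene_id == "up"], "induced")
  expect_equal(out$lfc[out$gene_id == "flat"], 0)
  expect_equal(out$call[out$gene_id == "flat"], "unchanged")
  expect_error(uv_response(m, md, tibble::tibble(treated = "48h",
                                                 control = "6h-CK")),
               "6h-CK")
})

test_that("induction calls are antisymmetric under label swap", {
  gid <- sprintf("g%02d", 1:30)
  sim <- simulate_uv_expression(gid, induced = list("48h" = gid[1:10]),
                                seed = 6)
  fwd <- uv_response(sim$matrix, sim$metadata,
                     tibble::tibble(treated = "48h", control = "48h-CK"))
  rev <- uv_response(sim$matrix, sim$metadata,
                     tibble::tibble(treated = "48h-CK", control = "48h"))
  expect_equal(fwd$lfc, -rev$lfc)
  expect_equal(fwd$call == "induced", rev$call == "repressed")
})

test_that("planted induced genes are called exactly at strong effect", {
  gid <- sprintf("g%03d", 1:168)
  induced <- list("48h" = gid[1:65])
  sim <- simulate_uv_expression(gid, induced = induced, effect_size = 8,
                                noise_sd = 0.2, seed = 8)
  out <- uv_response(sim$matrix, sim$metadata,
                     tibble::tibble(treated = "48h", control = "48h-CK"))
  called <- out$gene_id[out$call == "induced"]
  expect_setequal(called, gid[1:65])
  expect_equal(round_half_up(100 * length(called) / 168), 39)
})
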