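# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the local aligner enumerates alignment paths,
# the clustering oracle re-averages original distances from scratch, and
# the NJ checks go through ape.

# Exhaustive local-alignment score by path enumeration (affine gaps: a gap
# of length k costs open + k * extend, matching the aligner's convention).
# Local alignments never start or end with a gap, and an insertion directly
# followed by a deletion (or vice versa) is never optimal under BLOSUM62
# (worst substitution -4 beats two gap openings), so those paths are pruned
# without affecting the maximum. Feasible for sequences up to ~7 residues.
brute_force_local <- function(a, b, mat, open = 10, extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- 0
  extend_path <- function(i, j, score, last) {
    # i, j: next unconsumed positions; alignment may stop after any match
    if (last == "M") best <<- max(best, score)
    if (i <= length(av) && j <= length(bv)) {
      extend_path(i + 1, j + 1, score + mat[av[i], bv[j]], "M")
    }
    if (i <= length(av) && last != "Y") {           # gap in b
      cost <- if (last == "X") extend else open + extend
      extend_path(i + 1, j, score - cost, "X")
    }
    if (j <= length(bv) && last != "X") {           # gap in a
      cost <- if (last == "Y") extend else open + extend
      extend_path(i, j + 1, score - cost, "Y")
    }
  }
  for (i in seq_along(av)) {
    for (j in seq_along(bv)) {
      extend_path(i + 1, j + 1, mat[av[i], bv[j]], "M")
    }
  }
  best
}

# Naive average-linkage agglomeration: cluster distances recomputed from the
# original dissimilarity matrix at every step (no Lance-Williams update).
brute_force_average_linkage <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    n <- length(clusters)
    bh <- Inf; bi <- NA; bj <- NA
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < bh - 1e-12) { bh <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, bh)
    merges <- c(merges, list(sort(c(clusters[[bi]], clusters[[bj]]))))
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# membership sets at each merge of an hclust tree, as sorted index vectors
hclust_merge_sets <- function(hc) {
  sets <- list()
  out <- list()
  for (k in seq_len(nrow(hc$merge))) {
    row <- hc$merge[k, ]
    grab <- function(x) if (x < 0) -x else sets[[x]]
    sets[[k]] <- sort(c(grab(row[1]), grab(row[2])))
    out[[k]] <- sets[[k]]
  }
  out
}

# random additive distance matrix from a random tree with positive lengths
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 2)
  d <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(d))
  list(tree = tr, d = d[ord, ord])
}

# all permutations of 1..n (n! rows), for exact permutation nulls
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow(sub), n - 1))
  }))
}

# small synthetic family reused by several files
small_family <- function(seed = 7) {
  spec <- family_sim_spec(n_family_genes = 24, n_decoy_proteins = 20,
                          group_labels = LETTERS[1:4], protein_length = 460,
                          intronless_fraction = 0.25)
  simulate_family(spec, seed = seed)
}
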