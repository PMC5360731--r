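# Distance-based phylogeny and anchor-based group assignment.
#
# Distances are p-distances with pairwise gap deletion (the simplest
# defensible model when none is specified; exposed as the only model).
# Neighbor joining follows Saitou-Nei with a fixed tie-break (lowest index
# pair) and negative branch lengths clamped to zero, so results are
# deterministic across platforms. Groups are named by labelled anchor
# leaves: each family leaf takes the label of its nearest anchor by path
# length, and per-label monophyly is audited rather than assumed.

#' Pairwise p-distances from a protein alignment
#'
#' p-distance = mismatches / compared columns, where columns with a gap in
#' either row are excluded (pairwise deletion). `X` is treated as a gap
#' (unknown residue, not comparable).
#'
#' @param msa named character vector of aligned rows, or a tibble with id
#'   and row columns.
#' @return symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
#' @examples
#' pairwise_distance(c(a = "AAAA", b = "AAAT"))["a", "b"]  # 0.25
pairwise_distance <- function(msa) {
  if (is.data.frame(msa)) msa <- setNames(msa[[2]], msa[[1]])
  n <- length(msa)
  if (n < 2) abort("need at least 2 sequences")
  if (anyDuplicated(names(msa))) abort("duplicate sequence ids")
  if (length(unique(nchar(msa))) != 1) abort("alignment rows differ in length")
  chars <- do.call(rbind, strsplit(toupper(msa), ""))
  ok <- chars != "-" & chars != "." & chars != "X"
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0) {
        abort(sprintf("no comparable columns between %s and %s",
                      names(msa)[i], names(msa)[j]))
      }
      d[i, j] <- d[j, i] <- sum(chars[i, comp] != chars[j, comp]) / nc
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining: at each step the pair minimising
#' Q(i, j) = (n - 2) d(i, j) - R_i - R_j is joined, with branch lengths from
#' the usual formulas. Exact Q ties are broken toward the lowest (i, j)
#' index pair. Negative branch lengths are clamped to zero and the total
#' clamped deficit recorded in the `"clamped_deficit"` attribute.
#'
#' @param d symmetric distance matrix with dimnames (see
#'   [pairwise_distance()]); at least 3 taxa (2 taxa form a trivial
#'   single-edge tree via [two_taxon_tree()]).
#' @return unrooted `phylo` object (binary; leaf set = dimnames of `d`).
#' @export
neighbor_joining <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  ids <- rownames(d)
  if (is.null(ids)) abort("distance matrix needs dimnames")
  if (nrow(d) < 3) abort("need at least 3 taxa (see two_taxon_tree for 2)")
  if (max(abs(d - t(d))) > 1e-12) abort("distance matrix must be symmetric")
  labs <- ids            # current node labels (newick fragments)
  D <- d
  deficit <- 0
  while (nrow(D) > 3) {
    n <- nrow(D)
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { deficit <- deficit - li; lj <- lj + li; li <- 0 }
    if (lj < 0) { deficit <- deficit - lj; li <- li + lj; lj <- 0 }
    new_lab <- sprintf("(%s:%.10g,%s:%.10g)", labs[i], li, labs[j], lj)
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    labs <- c(labs[keep], new_lab)
    rownames(D2) <- colnames(D2) <- labs
    D <- D2
  }
  # terminal 3-star via the three-point formulas
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  for (v in c("l1", "l2", "l3")) {
    val <- get(v)
    if (val < 0) { deficit <- deficit - val; assign(v, 0) }
  }
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    labs[1], l1, labs[2], l2, labs[3], l3)
  tree <- ape::read.tree(text = newick)
  if (deficit > 0) {
    inform(sprintf("clamped negative NJ branch lengths (total deficit %.4g)",
                   deficit))
  }
  attr(tree, "clamped_deficit") <- deficit
  tree
}

#' Trivial two-taxon tree
#'
#' @param d 2x2 distance matrix with dimnames.
#' @return `phylo` with a single edge of length `d[1, 2]` split evenly.
#' @export
two_taxon_tree <- function(d) {
  stopifnot(nrow(d) == 2)
  ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);", rownames(d)[1],
                                d[1, 2] / 2, rownames(d)[2], d[1, 2] / 2))
}

#' Assign family members to groups via anchor leaves
#'
#' Each non-anchor leaf receives the group label of its nearest anchor by
#' path length (sum of branch lengths along the tree). Exact ties go to the
#' lexicographically smallest label and are flagged. For every label the
#' monophyly of {anchors + assigned leaves} is audited (unrooted sense) and
#' violations reported, since nearest-anchor assignment formalises a
#' by-eye clade reading and disagreements should be visible, not hidden.
#'
#' @param tree unrooted `phylo` (e.g. from [neighbor_joining()]).
#' @param anchors tibble with columns `anchor_id`, `group`, or a named
#'   character vector `anchor_id -> group`. Every anchor must be a leaf.
#' @return object of class `group_assignment`: list with `assignments`
#'   (tibble `gene_id`, `group`, `nearest_anchor`, `tied`), `counts`
#'   (tibble `group`, `n` over non-anchor leaves), and `monophyletic`
#'   (named logical per label).
#' @export
assign_groups <- function(tree, anchors) {
  if (is.data.frame(anchors)) {
    anchors <- setNames(anchors$group, anchors$anchor_id)
  }
  missing <- setdiff(names(anchors), tree$tip.label)
  if (length(missing)) {
    abort(paste0("anchor(s) missing from tree: ", paste(missing, collapse = ", ")))
  }
  tips <- tree$tip.label
  members <- setdiff(tips, names(anchors))
  pd <- ape::cophenetic.phylo(tree)
  amat <- pd[members, names(anchors), drop = FALSE]
  labels_of <- unname(anchors)
  assigned <- character(length(members))
  nearest <- character(length(members))
  tied <- logical(length(members))
  for (k in seq_along(members)) {
    dmin <- min(amat[k, ])
    cand <- which(amat[k, ] <= dmin + 1e-12)
    cand_labels <- sort(unique(labels_of[cand]))
    assigned[k] <- cand_labels[1]
    tied[k] <- length(cand_labels) > 1
    hit <- cand[labels_of[cand] == assigned[k]][1]
    nearest[k] <- names(anchors)[hit]
  }
  assignments <- tibble(gene_id = members, group = assigned,
                        nearest_anchor = nearest, tied = tied)
  counts <- assignments |> dplyr::count(.data$group, name = "n")
  mono <- vapply(sort(unique(labels_of)), function(g) {
    set <- c(names(anchors)[labels_of == g],
             assignments$gene_id[assignments$group == g])
    if (length(set) <= 1 || length(set) >= length(tips) - 1) return(TRUE)
    ape::is.monophyletic(tree, tips = set, reroot = TRUE)
  }, logical(1))
  if (!all(mono)) {
    warn(paste0("non-monophyletic group(s): ",
                paste(names(mono)[!mono], collapse = ", ")))
  }
  structure(list(assignments = assignments, counts = counts,
                 monophyletic = mono),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("<group_assignment> %d leaves over %d groups (%d tie(s), %d monophyly violation(s))\n",
              nrow(x$assignments), nrow(x$counts), sum(x$assignments$tied),
              sum(!x$monophyletic)))
  print(x$counts)
  invisible(x)
}

#' @export
tidy.group_assignment <- function(x, ...) x$assignments

#' @export
glance.group_assignment <- function(x, ...) {
  tibble(n_leaves = nrow(x$assignments), n_groups = nrow(x$counts),
         n_tied = sum(x$assignments$tied),
         n_monophyly_violations = sum(!x$monophyletic))
}
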