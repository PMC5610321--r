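#' UPGMA clustering of a distance matrix into a rooted ultrametric tree
#'
#' Native implementation of unweighted pair group method with arithmetic mean:
#' the two clusters at minimal average distance `d` are merged into a node at
#' height `d/2`, and the distance from the merged cluster to every other
#' cluster is updated as the size-weighted arithmetic mean of its members'
#' distances. Ties on the minimal distance are broken by the lexicographically
#' smallest (row, column) pair in current cluster order, so the result is
#' deterministic.
#'
#' @param m A labelled symmetric distance matrix (a `mev_dist` from
#'   [mev_distance()]/[ffp_distance()], or any square numeric matrix with
#'   `rownames`), at least 2 taxa, finite non-negative entries, zero diagonal.
#' @return A rooted binary tree of class `phylo` (ape) with non-negative
#'   branch lengths; all leaves lie at the same depth (ultrametric). The
#'   merge trace is attached as attribute `"hclust"` so the dendrogram can be
#'   cut into flat clusters (see [clade_partition()]).
#' @examples
#' m <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' tr <- mev_upgma(m)
#' ape::write.tree(tr)
#' @export
mev_upgma <- function(m) {
  m <- as.matrix(m)
  validate_dist_matrix(m)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 taxa")
  labels <- rownames(m)

  d <- unclass(m)
  sizes <- rep(1L, n)
  code <- -seq_len(n)            # hclust convention: negatives are singletons
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    k <- nrow(d)
    ut <- upper.tri(d)
    mn <- min(d[ut])
    cand <- which(ut & d <= mn, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]

    merge[step, ] <- c(code[i], code[j])
    height[step] <- mn

    if (k > 2) {
      rest <- setdiff(seq_len(k), c(i, j))
      newd <- (sizes[i] * d[i, rest] + sizes[j] * d[j, rest]) / (sizes[i] + sizes[j])
      d[i, rest] <- newd
      d[rest, i] <- newd
    }
    sizes[i] <- sizes[i] + sizes[j]
    code[i] <- step
    d <- d[-j, -j, drop = FALSE]
    sizes <- sizes[-j]
    code <- code[-j]
  }

  hc <- structure(
    list(merge = merge, height = height, order = hclust_order(merge),
         labels = labels, method = "upgma", dist.method = "euclidean"),
    class = "hclust"
  )
  tree <- ape::as.phylo(hc)   # node heights = merge height / 2
  attr(tree, "hclust") <- hc
  tree
}

# leaf ordering consistent with the merge trace (no crossing branches)
hclust_order <- function(merge) {
  walk <- function(k) {
    if (k < 0) return(-k)
    c(walk(merge[k, 1]), walk(merge[k, 2]))
  }
  walk(nrow(merge))
}

#' Cut an UPGMA tree into k flat clusters
#'
#' Cuts the dendrogram underlying a [mev_upgma()] tree at the level that
#' leaves `k` clusters — the tree's induced partition of the taxa.
#'
#' @param tree A tree from [mev_upgma()].
#' @param k Number of clusters.
#' @return A tibble with columns `id` and `cluster` (integer group).
#' @export
clade_partition <- function(tree, k) {
  hc <- attr(tree, "hclust")
  if (is.null(hc)) stop("tree carries no merge trace; build it with mev_upgma()")
  grp <- stats::cutree(hc, k = k)
  tibble::tibble(id = names(grp), cluster = unname(grp))
}

#' Robinson-Foulds distance between two trees
#'
#' Counts the bipartitions (splits) of the leaf set present in exactly one of
#' the two trees, treating both as unrooted and ignoring trivial splits
#' (single leaf vs rest). Identical topologies give 0.
#'
#' @param t1,t2 Trees of class `phylo` on the same leaf set.
#' @return Non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) stop("trees have different leaf sets")
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# canonical keys of the non-trivial unrooted splits of a phylo tree
tree_splits <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  tr <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) below[[i]] <- tips[i]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  root <- n + 1L
  nodes <- setdiff(seq_len(n + tr$Nnode)[-seq_len(n)], root)
  keys <- vapply(nodes, function(v) split_key(below[[v]], tips), character(1))
  unique(keys[nzchar(keys)])
}

# one side of a split -> canonical key; "" if trivial
split_key <- function(side, tips) {
  other <- setdiff(tips, side)
  if (length(side) < 2 || length(other) < 2) return("")
  ref <- min(tips)
  part <- if (ref %in% side) other else side
  paste(sort(part), collapse = "\r")
}

#' Robinson-Foulds mismatch between two flat partitions
#'
#' Interprets each group of each partition as a leaf-set split (group vs the
#' rest) and counts the symmetric difference of the two split sets. Unlike
#' tree splits, singleton groups are meaningful for flat partitions and are
#' kept. 0 means the partitions agree exactly (up to group relabelling).
#'
#' @param p1,p2 Data frames with columns `id` and `cluster` (e.g. from
#'   [clade_partition()], or a truth table with `cluster = clade`).
#' @return Non-negative integer.
#' @export
partition_rf <- function(p1, p2) {
  p1 <- normalize_partition(p1)
  p2 <- normalize_partition(p2)
  if (!setequal(p1$id, p2$id)) stop("partitions cover different taxa")
  tips <- sort(p1$id)
  block_key <- function(side) {
    part <- if (tips[1] %in% side) setdiff(tips, side) else side
    paste(sort(part), collapse = "\r")
  }
  keys <- function(p) unique(vapply(split(p$id, p$cluster), block_key, character(1)))
  k1 <- keys(p1); k2 <- keys(p2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

normalize_partition <- function(p) {
  if (!is.data.frame(p) || !("id" %in% names(p))) {
    stop("expected a data frame with columns 'id' and 'cluster' (or 'clade')")
  }
  cl <- if ("cluster" %in% names(p)) p$cluster else p$clade
  if (is.null(cl)) stop("partition needs a 'cluster' or 'clade' column")
  tibble::tibble(id = as.character(p$id), cluster = as.character(cl))
}
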