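# Coalescent genealogies: rooted, binary, ultrametric trees with all tips
# contemporaneous at height 0. Node indices are 1-based: tips 1..n, internal
# nodes n+1..2n-1. Heights carry a `units` tag ("substitutions" for the
# skyline model, "generations" for the simulator).

#' Construct a genealogy tree
#'
#' @param parent Integer vector over all 2n-1 nodes; `NA` for the root.
#' @param left,right Integer children for internal nodes (`NA` for tips).
#' @param height Numeric node heights; tips at 0, parent strictly above
#'   children.
#' @param root Index of the root node.
#' @param n_tips Number of tips.
#' @param tip_labels Optional tip labels (default `t1..tn`).
#' @param units Height units: `"substitutions"` (per site) or
#'   `"generations"`.
#' @return Object of class `genealogy_tree`.
#' @export
genealogy_tree <- function(parent, left, right, height, root, n_tips,
                           tip_labels = NULL, units = "substitutions") {
  tot <- 2L * n_tips - 1L
  stopifnot(length(parent) == tot, length(height) == tot,
            length(left) == tot, length(right) == tot)
  if (any(height[seq_len(n_tips)] != 0))
    stop("tips must be at height 0 (contemporaneous sampling)")
  for (v in (n_tips + 1L):tot) {
    if (is.na(left[v]) || is.na(right[v]))
      stop("internal node without two children: tree must be binary")
    if (height[v] <= height[left[v]] || height[v] <= height[right[v]])
      stop("parent height must strictly exceed child heights")
  }
  if (is.null(tip_labels)) tip_labels <- paste0("t", seq_len(n_tips))
  structure(list(parent = as.integer(parent), left = as.integer(left),
                 right = as.integer(right), height = as.numeric(height),
                 root = as.integer(root), n_tips = as.integer(n_tips),
                 tip_labels = tip_labels, units = units),
            class = "genealogy_tree")
}

#' @export
print.genealogy_tree <- function(x, ...) {
  cat(sprintf("genealogy_tree: %d tips, TMRCA %.6g %s\n",
              x$n_tips, tmrca(x), x$units))
  invisible(x)
}

#' Root height (time to most recent common ancestor)
#' @param tree A `genealogy_tree`.
#' @return Numeric TMRCA in the tree's height units.
#' @export
tmrca <- function(tree) tree$height[tree$root]

#' Total branch length of a genealogy
#' @param tree A `genealogy_tree`.
#' @return Sum of all branch lengths in the tree's height units.
#' @export
total_branch_length <- function(tree) {
  tot <- 2L * tree$n_tips - 1L
  s <- 0
  for (v in seq_len(tot))
    if (!is.na(tree$parent[v]))
      s <- s + tree$height[tree$parent[v]] - tree$height[v]
  s
}

#' Tips descending from each node
#' @param tree A `genealogy_tree`.
#' @return List mapping node index to the integer vector of descendant tips.
#' @export
descendant_tips <- function(tree) {
  tot <- 2L * tree$n_tips - 1L
  out <- vector("list", tot)
  ord <- order(tree$height)
  for (v in ord) {
    if (v <= tree$n_tips) out[[v]] <- v
    else out[[v]] <- c(out[[tree$left[v]]], out[[tree$right[v]]])
  }
  out
}

#' Convert a genealogy to an ape "phylo" tree
#'
#' @param tree A `genealogy_tree`.
#' @return An [ape::as.phylo] compatible `phylo` object with branch lengths
#'   in the genealogy's height units.
#' @export
as_phylo <- function(tree) {
  n <- tree$n_tips
  tot <- 2L * n - 1L
  # ape convention: tips 1..n, root n+1, other internals follow
  internals <- setdiff((n + 1L):tot, tree$root)
  map <- integer(tot)
  map[seq_len(n)] <- seq_len(n)
  map[tree$root] <- n + 1L
  if (length(internals)) map[internals] <- n + 1L + seq_along(internals)
  edge <- matrix(0L, tot - 1L, 2L)
  elen <- numeric(tot - 1L)
  k <- 0L
  for (v in seq_len(tot)) {
    if (is.na(tree$parent[v])) next
    k <- k + 1L
    edge[k, ] <- c(map[tree$parent[v]], map[v])
    elen[k] <- tree$height[tree$parent[v]] - tree$height[v]
  }
  phy <- list(edge = edge, edge.length = elen, Nnode = n - 1L,
              tip.label = tree$tip_labels)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

# UPGMA-style starting tree from an alignment's per-site Hamming distances.
# Heights are half the average pairwise p-distance; a tiny ladder keeps
# internal heights strictly increasing when sequences coincide.
.upgma_start_tree <- function(aln, invariant_sites = 0) {
  n <- nrow(aln)
  if (n < 3L) stop("need at least 3 haplotypes")
  S <- ncol(aln) + invariant_sites
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- sum(aln[i, ] != aln[j, ]) / S
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  tot <- 2L * n - 1L
  parent <- rep(NA_integer_, tot)
  left <- rep(NA_integer_, tot)
  right <- rep(NA_integer_, tot)
  height <- numeric(tot)
  node_of <- function(code) if (code < 0L) -code else n + code
  eps <- 1e-9
  for (i in seq_len(n - 1L)) {
    v <- n + i
    a <- node_of(hc$merge[i, 1L])
    b <- node_of(hc$merge[i, 2L])
    left[v] <- a; right[v] <- b
    parent[a] <- v; parent[b] <- v
    h <- hc$height[i] / 2
    height[v] <- max(h, height[a] + eps, height[b] + eps,
                     if (i > 1L) height[v - 1L] + eps else eps)
  }
  genealogy_tree(parent, left, right, height, root = tot, n_tips = n,
                 tip_labels = rownames(aln), units = "substitutions")
}
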