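# Stage II: pairwise distances from MEA scores, weighted UPGMA guide tree,
# ClustalW-style sequence weights, and the node-count tree distance used by
# selective consistency.
#
# Tree representation: nodes 1..N are leaves (input order), node N+k is the
# k-th merge; `children` holds the two child node ids per internal node,
# `height` the ultrametric height, `size` the subtree node count.

#' Distance from an MEA alignment score
#'
#' `d = 1 - score / min(len_x, len_y)`, clamped to \[0, 1\]. A near-perfect
#' posterior (score close to the shorter length) gives a distance near 0.
#'
#' @param mea_score Non-negative MEA score.
#' @param len_x,len_y Sequence lengths (> 0).
#' @return Distance in \[0, 1\].
#' @export
score_to_distance <- function(mea_score, len_x, len_y) {
  if (any(len_x < 1) || any(len_y < 1)) stop("zero-length sequence", call. = FALSE)
  stopifnot(all(mea_score >= 0))
  pmin(1, pmax(0, 1 - mea_score / pmin(len_x, len_y)))
}

#' Distance matrix from an MEA score matrix
#' @param scores Symmetric matrix of pairwise MEA scores.
#' @param lengths Sequence lengths, in the same order.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
score_distance_matrix <- function(scores, lengths) {
  n <- length(lengths)
  D <- matrix(0, n, n, dimnames = dimnames(scores))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- score_to_distance(scores[i, j], lengths[i], lengths[j])
    }
  }
  D
}

#' Rank-normalize a distance matrix to \[0, 1\]
#'
#' Each unordered off-diagonal value is replaced by its rank among all
#' unordered pair values, scaled to \[0, 1\]; ties share the mean rank. The
#' output is order-isomorphic to the input.
#'
#' @param D Symmetric distance matrix.
#' @return Rank-normalized symmetric matrix (zero diagonal).
#' @export
rank_normalize <- function(D) {
  n <- nrow(D)
  stopifnot(n >= 2, isTRUE(all.equal(D, t(D))))
  ut <- upper.tri(D)
  v <- D[ut]
  r <- if (length(v) == 1) 0.5 else (rank(v, ties.method = "average") - 1) / (length(v) - 1)
  out <- matrix(0, n, n, dimnames = dimnames(D))
  out[ut] <- r
  out <- out + t(out)
  out
}

#' Weighted UPGMA (WPGMA) guide tree
#'
#' Agglomerative clustering merging the closest pair at each step; the
#' merged cluster's distance to any other is the plain mean of the two
#' members' distances (McQuitty / WPGMA update — the "weighted" UPGMA).
#' Node heights are half the merge distance, so the tree is ultrametric.
#' Ties break on the lowest (row, col) cluster-index pair.
#'
#' @param D Symmetric distance matrix (zero diagonal).
#' @param ids Leaf labels; default rownames of `D` or `s1..sN`.
#' @param method `"wpgma"` (default) or `"upgma"` (size-weighted average
#'   update) for comparison.
#' @return A `guide_tree` object.
#' @export
upgma <- function(D, ids = NULL, method = c("wpgma", "upgma")) {
  method <- match.arg(method)
  n <- nrow(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-12))) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (is.null(ids)) ids <- if (!is.null(rownames(D))) rownames(D) else paste0("s", seq_len(n))
  stopifnot(length(ids) == n, n >= 2)

  n_nodes <- 2L * n - 1L
  children <- matrix(0L, n_nodes, 2)
  height <- numeric(n_nodes)
  size <- integer(n_nodes)
  nleaf <- integer(n_nodes)
  size[1:n] <- 1L
  nleaf[1:n] <- 1L
  parent <- integer(n_nodes)

  active <- as.integer(1:n)      # node ids of live clusters, creation order
  d <- as.matrix(D)              # distances between live clusters
  for (step in seq_len(n - 1)) {
    k <- length(active)
    # first minimal (i, j), i < j, row-major over creation order
    best <- c(1L, 2L); bd <- Inf
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (d[i, j] < bd - 1e-15) { bd <- d[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    new_id <- n + step
    a <- active[i]; b <- active[j]
    children[new_id, ] <- c(a, b)
    parent[a] <- parent[b] <- new_id
    height[new_id] <- bd / 2
    size[new_id] <- size[a] + size[b] + 1L
    nleaf[new_id] <- nleaf[a] + nleaf[b]
    upd <- if (method == "wpgma") {
      (d[i, ] + d[j, ]) / 2
    } else {
      (nleaf[a] * d[i, ] + nleaf[b] * d[j, ]) / (nleaf[a] + nleaf[b])
    }
    keep <- setdiff(seq_len(k), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], upd[keep]),
               c(upd[keep], 0))
    active <- c(active[keep], new_id)
  }
  structure(list(n_leaves = n, labels = ids, children = children,
                 parent = parent, height = height, size = size,
                 n_below = nleaf),
            class = "guide_tree")
}

#' @export
print.guide_tree <- function(x, ...) {
  cat("guide_tree:", x$n_leaves, "leaves, root height",
      format(max(x$height), digits = 4), "\n")
  invisible(x)
}

# leaves under each node (list over all node ids)
leaves_below <- function(tree) {
  n_nodes <- length(tree$height)
  out <- vector("list", n_nodes)
  for (v in seq_len(tree$n_leaves)) out[[v]] <- v
  for (v in (tree$n_leaves + 1):n_nodes) {
    ch <- tree$children[v, ]
    out[[v]] <- c(out[[ch[1]]], out[[ch[2]]])
  }
  out
}

#' ClustalW-style sequence weights from a guide tree
#'
#' Each branch length is divided equally among the leaves below the branch
#' and summed per leaf; weights are normalized to sum 1. A tree with all
#' branch lengths zero yields uniform weights.
#'
#' @param tree A `guide_tree`.
#' @return Named numeric weights summing to 1.
#' @export
sequence_weights <- function(tree) {
  n <- tree$n_leaves
  w <- numeric(n)
  lb <- leaves_below(tree)
  for (v in seq_len(length(tree$height))) {
    p <- tree$parent[v]
    if (p == 0) next
    edge <- tree$height[p] - tree$height[v]
    under <- lb[[v]]
    w[under] <- w[under] + edge / length(under)
  }
  if (sum(w) <= 0) w <- rep(1, n)
  w <- w / sum(w)
  setNames(w, tree$labels)
}

#' Tree-guided distance between two leaves
#'
#' The number of nodes in the minimal subtree containing both leaves, i.e.
#' the subtree node count of their lowest common ancestor; `d(x, x) = 1`.
#'
#' @param tree A `guide_tree`.
#' @param x,y Leaf labels or indices.
#' @return Integer node count.
#' @export
tree_distance <- function(tree, x, y) {
  ix <- leaf_index(tree, x); iy <- leaf_index(tree, y)
  if (ix == iy) return(1L)
  tree$size[lca(tree, ix, iy)]
}

leaf_index <- function(tree, x) {
  if (is.character(x)) {
    i <- match(x, tree$labels)
    if (is.na(i)) stop("unknown leaf id: ", x, call. = FALSE)
    return(i)
  }
  i <- as.integer(x)
  if (i < 1 || i > tree$n_leaves) stop("unknown leaf index: ", x, call. = FALSE)
  i
}

lca <- function(tree, a, b) {
  anc <- a
  v <- a
  while (tree$parent[v] != 0) { v <- tree$parent[v]; anc <- c(anc, v) }
  v <- b
  while (!(v %in% anc)) v <- tree$parent[v]
  v
}

#' All pairwise tree-guided distances
#' @param tree A `guide_tree`.
#' @return Symmetric integer matrix with diagonal 1.
#' @export
tree_distance_matrix <- function(tree) {
  n <- tree$n_leaves
  lb <- leaves_below(tree)
  D <- matrix(1L, n, n, dimnames = list(tree$labels, tree$labels))
  # fill by walking nodes bottom-up: the LCA of a cross pair of a node's two
  # child subtrees is that node
  for (v in (n + 1):length(tree$height)) {
    ch <- tree$children[v, ]
    left <- lb[[ch[1]]]; right <- lb[[ch[2]]]
    D[left, right] <- tree$size[v]
    D[right, left] <- tree$size[v]
  }
  D
}

#' Newick string of a guide tree
#' @param tree A `guide_tree`.
#' @param digits Branch-length precision.
#' @return Newick string (rooted, with branch lengths).
#' @export
newick_string <- function(tree, digits = 10) {
  rec <- function(v) {
    p <- tree$parent[v]
    bl <- if (p == 0) 0 else tree$height[p] - tree$height[v]
    lab <- if (v <= tree$n_leaves) {
      tree$labels[v]
    } else {
      ch <- tree$children[v, ]
      paste0("(", rec(ch[1]), ",", rec(ch[2]), ")")
    }
    paste0(lab, ":", format(bl, digits = digits, scientific = FALSE))
  }
  root <- which(tree$parent == 0)
  ch <- tree$children[root, ]
  paste0("(", rec(ch[1]), ",", rec(ch[2]), ");")
}

#' Convert a guide tree to an ape "phylo" object
#' @param tree A `guide_tree`.
#' @return An [ape::read.tree()] phylo object.
#' @export
as_phylo <- function(tree) {
  ape::read.tree(text = newick_string(tree))
}

#' Write a guide tree to a Newick file
#' @param tree A `guide_tree`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  writeLines(newick_string(tree), path)
  invisible(path)
}
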