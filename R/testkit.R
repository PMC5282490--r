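# Synthetic protein-family generator: evolves an ancestor along a known
# tree with substitutions and indels, tracking the true multiple alignment
# in ancestral coordinates. Used by the test suite in place of downloaded
# benchmark families; every run is fully determined by the seed.

#' Specification of a synthetic protein family
#'
#' @param n Number of leaf sequences (>= 2); default 20.
#' @param length Ancestor length (>= 10); default 100.
#' @param sub_rate Per-site substitution probability per branch, in
#'   \[0, 1); default 0.05.
#' @param indel_rate Per-site probability that an indel event starts at a
#'   site, per branch, in \[0, 1); default 0.01.
#' @param indel_p Stopping parameter of the geometric indel-length
#'   distribution (length k with probability `(1-p)^(k-1) p`, mean `1/p`);
#'   default 0.5.
#' @param tree_shape `"random"` (default), `"balanced"`, or
#'   `"caterpillar"`.
#' @param seed RNG seed; default 1.
#' @return A `family_spec` list.
#' @export
family_spec <- function(n = 20, length = 100, sub_rate = 0.05,
                        indel_rate = 0.01, indel_p = 0.5,
                        tree_shape = c("random", "balanced", "caterpillar"),
                        seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  stopifnot(n >= 2, length >= 10,
            sub_rate >= 0, sub_rate < 1,
            indel_rate >= 0, indel_rate < 1,
            indel_p > 0, indel_p <= 1)
  structure(list(n = as.integer(n), length = as.integer(length),
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 indel_p = indel_p, tree_shape = tree_shape,
                 seed = as.integer(seed)),
            class = "family_spec")
}

# assemble a guide_tree from a merge table (node ids; children precede
# parents); unit-depth heights, enough for topology-driven uses
build_guide_tree <- function(merges, n, labels) {
  n_nodes <- 2L * n - 1L
  children <- matrix(0L, n_nodes, 2)
  parent <- integer(n_nodes)
  height <- numeric(n_nodes)
  size <- integer(n_nodes); size[1:n] <- 1L
  nleaf <- integer(n_nodes); nleaf[1:n] <- 1L
  for (k in seq_len(n - 1)) {
    v <- n + k
    a <- merges[k, 1]; b <- merges[k, 2]
    children[v, ] <- c(a, b)
    parent[a] <- parent[b] <- v
    height[v] <- max(height[a], height[b]) + 1
    size[v] <- size[a] + size[b] + 1L
    nleaf[v] <- nleaf[a] + nleaf[b]
  }
  structure(list(n_leaves = n, labels = labels, children = children,
                 parent = parent, height = height, size = size,
                 n_below = nleaf),
            class = "guide_tree")
}

random_topology <- function(n, shape) {
  merges <- matrix(0L, n - 1, 2)
  if (shape == "caterpillar") {
    merges[1, ] <- c(1L, 2L)
    if (n > 2) for (k in 2:(n - 1)) merges[k, ] <- c(n + k - 1L, k + 1L)
  } else if (shape == "balanced") {
    next_id <- n
    rec <- function(leaves) {
      if (length(leaves) == 1) return(leaves)
      half <- length(leaves) %/% 2
      a <- rec(leaves[seq_len(half)])
      b <- rec(leaves[-seq_len(half)])
      next_id <<- next_id + 1L
      merges[next_id - n, ] <<- c(a, b)
      next_id
    }
    rec(seq_len(n))
  } else {
    active <- seq_len(n)
    for (k in seq_len(n - 1)) {
      pick <- sample.int(length(active), 2)
      merges[k, ] <- active[pick]
      active <- c(active[-pick], n + k)
    }
  }
  merges
}

#' Generate a synthetic protein family with its true alignment
#'
#' Draws an ancestor from the background amino-acid frequencies and evolves
#' it down the tree: per branch, each site substitutes with probability
#' `sub_rate` (redrawn from the background) and starts an indel event with
#' probability `indel_rate` (insertion or deletion with equal probability,
#' geometric length). Insertions open new columns in the global (ancestral)
#' coordinate system, which yields the true multiple alignment of the
#' leaves. Identical seeds give bit-identical output.
#'
#' @param spec A [family_spec()].
#' @return List with `sequences` (a [seq_set()]), `alignment` (the true
#'   [msa()]), and `tree` (the generating `guide_tree`).
#' @export
generate_family <- function(spec = family_spec()) {
  stopifnot(is(spec, "family_spec"))
  with_seed(spec$seed, {
    f <- aa_background()
    aa <- names(f)
    labels <- sprintf("seq%02d", seq_len(spec$n))
    tree <- build_guide_tree(random_topology(spec$n, spec$tree_shape),
                             spec$n, labels)

    n_nodes <- 2L * spec$n - 1L
    root <- which(tree$parent == 0)
    # global alignment matrix over all tree nodes; grows as insertions land
    M <- matrix(GAP, n_nodes, spec$length)
    M[root, ] <- sample(aa, spec$length, replace = TRUE, prob = f)

    evolve_into <- function(child, parent_row) {
      row <- M[parent_row, ]
      res <- which(row != GAP)
      # substitutions
      mut <- res[runif(length(res)) < spec$sub_rate]
      if (length(mut)) {
        row[mut] <- sample(aa, length(mut), replace = TRUE, prob = f)
      }
      # indel events, processed right-to-left so column insertions do not
      # shift the coordinates of the remaining events
      ev <- sort(res[runif(length(res)) < spec$indel_rate], decreasing = TRUE)
      for (site in ev) {
        len <- stats::rgeom(1, spec$indel_p) + 1L
        if (runif(1) < 0.5) {
          res_now <- which(row != GAP)
          at <- match(site, res_now)
          if (is.na(at)) next
          kill <- res_now[seq(at, min(length(res_now), at + len - 1L))]
          row[kill] <- GAP
        } else {
          ins <- sample(aa, len, replace = TRUE, prob = f)
          L <- ncol(M)
          tail_cols <- if (site < L) M[, (site + 1L):L, drop = FALSE] else NULL
          M <<- cbind(M[, seq_len(site), drop = FALSE],
                      matrix(GAP, nrow(M), len), tail_cols)
          tail_row <- if (site < length(row)) row[(site + 1L):length(row)] else character(0)
          row <- c(row[seq_len(site)], ins, tail_row)
        }
      }
      if (!any(row != GAP)) {
        stop("indel rate too high: a sequence became empty", call. = FALSE)
      }
      M[child, ] <<- row
    }

    dfs <- function(v) {
      if (v <= spec$n) return(invisible())
      for (ch in tree$children[v, ]) {
        evolve_into(ch, v)
        dfs(ch)
      }
    }
    dfs(root)

    leaf_mat <- M[seq_len(spec$n), , drop = FALSE]
    rownames(leaf_mat) <- labels
    leaf_mat <- drop_allgap_cols(leaf_mat)
    truth <- msa(leaf_mat)
    list(sequences = degap(truth), alignment = truth, tree = tree)
  })
}
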