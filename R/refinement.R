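# Stage IV(b): iterative refinement. Each iteration splits the incumbent
# alignment into two profiles (column-oriented by default: rows with vs
# without a gap in a randomly chosen gapped column), strips gap-only
# columns, realigns the profiles, and keeps the candidate only if the
# acceptance rule allows it (non-increasing length by default).

#' Refinement configuration
#'
#' @param strategy Split strategy: `"column"` (default), `"random"`, or
#'   `"tree"`.
#' @param iterations Number of iterations, or `"auto"`: 30 when two
#'   consistency transformations ran, else 200.
#' @param acceptance `"length"` (non-increasing column count, default),
#'   `"trident"` (non-decreasing [trident_score()]), or `"always"`.
#' @param balance_bias `"none"` (default), `"balanced"`, or `"imbalanced"`:
#'   restrict the column draw to the `bias_pct` percent most (or least)
#'   balanced gapped columns.
#' @param bias_pct Percentage in (0, 100\] used with a biased draw; default
#'   50.
#' @param seed RNG seed for the split draws.
#' @return A `refinement_config` list.
#' @export
refinement_config <- function(strategy = c("column", "random", "tree"),
                              iterations = "auto",
                              acceptance = c("length", "trident", "always"),
                              balance_bias = c("none", "balanced", "imbalanced"),
                              bias_pct = 50, seed = 1L) {
  strategy <- match.arg(strategy)
  acceptance <- match.arg(acceptance)
  balance_bias <- match.arg(balance_bias)
  if (!identical(iterations, "auto")) {
    stopifnot(is.numeric(iterations), iterations >= 0)
  }
  stopifnot(bias_pct > 0, bias_pct <= 100)
  structure(list(strategy = strategy, iterations = iterations,
                 acceptance = acceptance, balance_bias = balance_bias,
                 bias_pct = bias_pct, seed = as.integer(seed)),
            class = "refinement_config")
}

#' Refinement iteration count from the consistency setting
#'
#' 30 iterations when two consistency transformations were applied, the
#' default 200 otherwise.
#'
#' @param transformations Number of consistency transformations that ran.
#' @return Integer iteration count.
#' @export
auto_refine_iterations <- function(transformations) {
  if (transformations == 2) 30L else 200L
}

#' Columns eligible for a column-oriented split
#'
#' Columns containing at least one gap and at least one residue.
#'
#' @param aln An [msa()].
#' @return Increasing 0-based column indices.
#' @export
candidate_columns <- function(aln) {
  mat <- unclass(aln)
  g <- colSums(mat == GAP)
  which(g >= 1 & g < nrow(mat)) - 1L
}

#' Randomly select a splitter column
#'
#' With no bias the draw is uniform over the candidates. With a bias the
#' candidates are sorted by `|g - N/2|` ascending (g = gap count; small
#' values give balanced splits) and the draw is restricted to the first
#' (`"balanced"`) or last (`"imbalanced"`) `pct` percent, at least one
#' column.
#'
#' @param candidates 0-based candidate columns, see [candidate_columns()].
#' @param aln The alignment (needed for gap counts under a bias).
#' @param bias `"none"`, `"balanced"`, or `"imbalanced"`.
#' @param pct Percentage in (0, 100\].
#' @return One 0-based column index (drawn from the current RNG stream).
#' @export
select_column <- function(candidates, aln, bias = "none", pct = 50) {
  if (length(candidates) == 0) stop("no candidate columns", call. = FALSE)
  pool <- candidates
  if (bias != "none") {
    mat <- unclass(aln)
    g <- colSums(mat == GAP)[candidates + 1L]
    ord <- order(abs(g - nrow(mat) / 2))   # stable: ties keep column order
    k <- max(1L, ceiling(length(candidates) * pct / 100))
    pool <- if (bias == "balanced") {
      candidates[ord][seq_len(k)]
    } else {
      candidates[ord][seq(length(candidates) - k + 1L, length(candidates))]
    }
  }
  pool[sample.int(length(pool), 1L)]
}

#' Split an alignment by gap presence in a column
#'
#' Rows with a gap in the splitter column form the first profile, rows with
#' a residue the second; both are non-empty for a candidate column.
#'
#' @param aln An [msa()].
#' @param col 0-based candidate column index.
#' @param index Global sequence indices of the rows (default `1:N`).
#' @param weights Row weights (default uniform).
#' @return List of two raw row groups: `list(gap = ..., res = ...)`, each a
#'   list with `mat`, `index`, `weights` (gap-only columns not yet
#'   stripped).
#' @export
split_by_column <- function(aln, col, index = NULL, weights = NULL) {
  mat <- unclass(aln)
  N <- nrow(mat)
  if (is.null(index)) index <- seq_len(N)
  if (is.null(weights)) weights <- rep(1 / N, N)
  is_gap <- mat[, col + 1L] == GAP
  if (!any(is_gap) || all(is_gap)) {
    stop("column ", col, " is not a candidate column (split would be empty)",
         call. = FALSE)
  }
  list(gap = list(mat = mat[is_gap, , drop = FALSE],
                  index = index[is_gap], weights = weights[is_gap]),
       res = list(mat = mat[!is_gap, , drop = FALSE],
                  index = index[!is_gap], weights = weights[!is_gap]))
}

#' Remove gap-only columns and build a profile
#'
#' @param group A row group from [split_by_column()] (or a list with `mat`,
#'   `index`, `weights`).
#' @return A [new_profile()] without all-gap columns.
#' @export
strip_gap_columns <- function(group) {
  mat <- drop_allgap_cols(group$mat)
  new_profile(msa(mat), group$index, group$weights)
}

#' Random horizontal split of an alignment
#'
#' Each row is assigned by a fair coin, redrawing until both sides are
#' non-empty.
#'
#' @inheritParams split_by_column
#' @param aln An [msa()] with at least 2 rows.
#' @return As [split_by_column()], with groups `a` and `b`.
#' @export
split_random <- function(aln, index = NULL, weights = NULL) {
  mat <- unclass(aln)
  N <- nrow(mat)
  stopifnot(N >= 2)
  if (is.null(index)) index <- seq_len(N)
  if (is.null(weights)) weights <- rep(1 / N, N)
  repeat {
    side <- runif(N) < 0.5
    if (any(side) && !all(side)) break
  }
  list(a = list(mat = mat[side, , drop = FALSE],
                index = index[side], weights = weights[side]),
       b = list(mat = mat[!side, , drop = FALSE],
                index = index[!side], weights = weights[!side]))
}

#' Guide-tree split of an alignment
#'
#' A uniformly random internal edge of the guide tree partitions the leaves
#' into the two profiles.
#'
#' @inheritParams split_random
#' @param tree A `guide_tree` over the same sequences; rows of `aln` are
#'   assumed to be the tree's leaves in input order.
#' @return As [split_random()].
#' @export
split_tree <- function(aln, tree, index = NULL, weights = NULL) {
  mat <- unclass(aln)
  N <- nrow(mat)
  stopifnot(N >= 2, tree$n_leaves == N)
  if (is.null(index)) index <- seq_len(N)
  if (is.null(weights)) weights <- rep(1 / N, N)
  # candidate edges: (node, parent) for every non-root node; breaking one
  # separates the leaves below the node from the rest
  nodes <- which(tree$parent != 0)
  v <- nodes[sample.int(length(nodes), 1L)]
  below <- leaves_below(tree)[[v]]
  side <- seq_len(N) %in% below
  list(a = list(mat = mat[side, , drop = FALSE],
                index = index[side], weights = weights[side]),
       b = list(mat = mat[!side, , drop = FALSE],
                index = index[!side], weights = weights[!side]))
}

# Stereochemical classes for the trident score (aliphatic, aromatic, polar,
# positive, negative, conformationally special); wildcards form their own
# class.
TRIDENT_CLASS <- c(A = 1, V = 1, L = 1, I = 1, M = 1, C = 1,
                   F = 2, W = 2, Y = 2, H = 2,
                   S = 3, T = 3, N = 3, Q = 3,
                   K = 4, R = 4,
                   D = 5, E = 5,
                   G = 6, P = 6,
                   B = 7, Z = 7, X = 7)

norm_entropy <- function(labels, K = 20) {
  n <- length(labels)
  if (n <= 1) return(0)
  p <- table(labels) / n
  H <- -sum(p * log(p))
  Hmax <- log(min(n, K))
  if (Hmax <= 0) 0 else min(1, H / Hmax)
}

#' Trident column-conservation score of an alignment
#'
#' Mean over columns of `(1 - t)^a * (1 - r)^b * (1 - g)^c`, where `t` is
#' the normalized Shannon entropy of the residue symbols, `r` the
#' normalized entropy over stereochemical classes, and `g` the gap
#' fraction. A fully conserved gapless alignment scores 1.
#'
#' @param aln An [msa()].
#' @param a,b,c Exponents of the three factors; default 1.
#' @return Score in \[0, 1\].
#' @export
trident_score <- function(aln, a = 1, b = 1, c = 1) {
  mat <- unclass(aln)
  N <- nrow(mat)
  col_score <- function(col) {
    res <- col[col != GAP]
    g <- 1 - length(res) / N
    if (length(res) == 0) return(0)
    t <- norm_entropy(res)
    r <- norm_entropy(TRIDENT_CLASS[res], K = max(TRIDENT_CLASS))
    (1 - t)^a * (1 - r)^b * (1 - g)^c
  }
  mean(apply(mat, 2, col_score))
}

#' Acceptance decision for a refined candidate
#'
#' @param candidate,incumbent Alignments over the same sequences.
#' @param rule `"always"`, `"length"` (accept iff the candidate has no more
#'   columns), or `"trident"` (accept iff the trident score did not
#'   decrease).
#' @return Logical.
#' @export
accept_alignment <- function(candidate, incumbent,
                             rule = c("length", "trident", "always")) {
  rule <- match.arg(rule)
  if (!setequal(rownames(candidate), rownames(incumbent))) {
    stop("candidate and incumbent align different sequences", call. = FALSE)
  }
  switch(rule,
         always = TRUE,
         length = ncol(candidate) <= ncol(incumbent),
         trident = trident_score(candidate) >= trident_score(incumbent))
}

#' Iterative refinement of an alignment
#'
#' For each iteration: split the incumbent per the configured strategy,
#' strip gap-only columns from both profiles, realign them with
#' [profile_align()] over the (transformed) posterior matrices, and accept
#' or reject by the configured rule. Iterations with no candidate column
#' (column strategy on a gapless alignment) are counted but skipped.
#'
#' @param aln The initial [msa()] (rows in input-sequence order).
#' @param ps The `posterior_set` used for realignment.
#' @param weights Sequence weights (input order).
#' @param tree Guide tree (required for the `"tree"` strategy).
#' @param config A [refinement_config()].
#' @return The refined [msa()].
#' @export
refine <- function(aln, ps, weights, tree = NULL,
                   config = refinement_config()) {
  iters <- config$iterations
  if (identical(iters, "auto")) iters <- 200L
  if (iters == 0) return(aln)
  if (config$strategy == "tree" && is.null(tree)) {
    stop("tree strategy needs a guide tree", call. = FALSE)
  }
  old_seed <- get_rng_state()
  on.exit(set_rng_state(old_seed))
  set.seed(config$seed)

  incumbent <- aln
  N <- nrow(aln)
  for (it in seq_len(iters)) {
    parts <- switch(config$strategy,
      column = {
        cand <- candidate_columns(incumbent)
        if (length(cand) == 0) next
        col <- select_column(cand, incumbent, config$balance_bias,
                             config$bias_pct)
        split_by_column(incumbent, col, weights = weights)
      },
      random = split_random(incumbent, weights = weights),
      tree = split_tree(incumbent, tree, weights = weights))
    P <- strip_gap_columns(parts[[1]])
    Q <- strip_gap_columns(parts[[2]])
    merged <- profile_align(P, Q, ps)
    ord <- order(merged$index)
    candidate <- msa(unclass(merged$aln)[ord, , drop = FALSE])
    if (accept_alignment(candidate, incumbent, config$acceptance)) {
      incumbent <- candidate
    }
  }
  incumbent
}
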