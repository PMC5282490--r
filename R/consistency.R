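# Stage III: selective consistency. Each pairwise posterior matrix S_xy is
# relaxed over third sequences z (S_xy <- weighted mix of S_xy and
# S_xz %*% S_zy), but only over the z accepted by a distance-based filter:
# either a deterministic threshold T on an aggregation alpha(d_xz, d_yz) of
# guide-tree distances, or a stochastic filter F on rank-normalized
# score distances. The surviving original signal is amplified per matrix by
# a coefficient h_xy that grows linearly with the number of relaxations.

#' Number of consistency transformations for a family of N sequences
#'
#' Two transformations for families of fewer than 50 sequences, one
#' otherwise.
#'
#' @param N Number of sequences (>= 2).
#' @return 2 if `N < 50`, else 1.
#' @export
num_transformations <- function(N) {
  stopifnot(N >= 2)
  if (N < 50) 2L else 1L
}

#' Consistency configuration
#'
#' @param mode `"deterministic-tree"` (default): threshold the aggregated
#'   node-count tree distance at `T`; `"stochastic-score"`: stochastic
#'   filter on rank-normalized score distances; `"full"`: relax over every
#'   third sequence.
#' @param alpha Aggregation of the two distances: `"max"` (default),
#'   `"min"`, or `"sum"`.
#' @param T Deterministic threshold; `NULL` (default) resolves to
#'   `ceiling(2 * sqrt(N))` on the node-count tree distance.
#' @param filter Stochastic filter preset: `"low"` (default), `"mid"`,
#'   `"high"` — see [triangle_filter()] — or a function mapping aggregated
#'   distance in \[0, 1\] to acceptance probability.
#' @param rate Expected acceptance rate of the triangle presets; default
#'   0.1.
#' @param h Amplification ceiling (>= 1); `NULL` resolves to 3 in the
#'   selective modes and 1 (off) in full mode.
#' @param cap Per-pair relaxation cap `R_max`; default 200.
#' @param iterations Number of transformations, or `"auto"` =
#'   [num_transformations()].
#' @param seed RNG seed for the stochastic filter.
#' @param invert Use the literal inequality `F(alpha0) <= p` instead of the
#'   acceptance-probability reading `p <= F(alpha0)`; default `FALSE`.
#' @return A `consistency_config` list.
#' @export
consistency_config <- function(mode = c("deterministic-tree",
                                        "stochastic-score", "full"),
                               alpha = c("max", "min", "sum"),
                               T = NULL, filter = "low", rate = 0.1,
                               h = NULL, cap = 200, iterations = "auto",
                               seed = 1L, invert = FALSE) {
  mode <- match.arg(mode)
  alpha <- match.arg(alpha)
  if (!is.null(T) && T < 0) stop("T must be >= 0", call. = FALSE)
  if (is.null(h)) h <- if (mode == "full") 1 else 3
  if (h < 1) stop("h must be >= 1", call. = FALSE)
  if (cap < 1) stop("cap must be >= 1", call. = FALSE)
  structure(list(mode = mode, alpha = alpha, T = T, filter = filter,
                 rate = rate, h = h, cap = cap, iterations = iterations,
                 seed = as.integer(seed), invert = invert),
            class = "consistency_config")
}

aggregate_dist <- function(d1, d2, alpha) {
  switch(alpha,
         max = pmax(d1, d2),
         min = pmin(d1, d2),
         sum = d1 + d2,
         stop("unknown aggregation function: ", alpha, call. = FALSE))
}

#' Deterministic acceptance of a relaxation
#'
#' Accept relaxation of S_xy over z iff `alpha(d_xz, d_yz) <= T`.
#'
#' @param d_xz,d_yz Non-negative distances.
#' @param alpha `"max"`, `"min"`, or `"sum"`.
#' @param T Threshold.
#' @return Logical.
#' @export
deterministic_accept <- function(d_xz, d_yz, alpha = "max", T) {
  stopifnot(all(d_xz >= 0), all(d_yz >= 0))
  aggregate_dist(d_xz, d_yz, alpha) <= T
}

#' Triangle stochastic filter presets
#'
#' Triangle-shaped acceptance-probability functions on \[0, 1\] whose
#' integral (the expected acceptance over uniformly distributed aggregated
#' distances) equals `rate`. `"low"` peaks at 0 (prefers closely related
#' third sequences), `"high"` at 1 (distant), `"mid"` at 0.5.
#'
#' @param type `"low"`, `"mid"`, or `"high"`.
#' @param rate Expected acceptance rate in (0, 0.5\]; default 0.1.
#' @return Vectorized function mapping \[0, 1\] to acceptance probability.
#' @export
triangle_filter <- function(type = c("low", "mid", "high"), rate = 0.1) {
  type <- match.arg(type)
  stopifnot(rate > 0, rate <= 0.5)
  switch(type,
         low = function(a) pmax(0, 1 - a / (2 * rate)),
         high = function(a) pmax(0, 1 - (1 - a) / (2 * rate)),
         mid = function(a) pmax(0, 1 - abs(a - 0.5) / rate))
}

#' Stochastic acceptance of relaxations
#'
#' For each aggregated distance, draws `p ~ U[0, 1]` from the current RNG
#' stream and accepts iff `p <= F(alpha0)`, making `F` an acceptance
#' probability. (`invert = TRUE` applies the opposite inequality
#' `F(alpha0) <= p`.)
#'
#' @param alpha0 Aggregated distance value(s) in \[0, 1\].
#' @param F Filter function, e.g. [triangle_filter()].
#' @param invert Flip the inequality; default `FALSE`.
#' @return Logical vector, one draw per element of `alpha0`.
#' @export
stochastic_accept <- function(alpha0, F, invert = FALSE) {
  prob <- F(alpha0)
  if (any(prob < 0 | prob > 1)) {
    stop("filter function must map into [0, 1]", call. = FALSE)
  }
  p <- runif(length(alpha0))
  if (invert) prob <= p else p <= prob
}

#' Amplification coefficient of the original posterior signal
#'
#' Varies linearly from 1 when no relaxations were performed to `h` when
#' the per-pair cap is reached: `h_xy = 1 + (h - 1) * min(n_xy, cap) / cap`.
#'
#' @param n_xy Number of relaxations performed for the pair.
#' @param cap Relaxation cap `R_max`; default 200.
#' @param h Ceiling value (>= 1); default 3.
#' @return The coefficient `h_xy` in \[1, h\].
#' @export
amplification_coeff <- function(n_xy, cap = 200, h = 3) {
  stopifnot(all(n_xy >= 0), h >= 1, cap >= 1)
  1 + (h - 1) * pmin(n_xy, cap) / cap
}

#' Build the relaxation plan for all pairs
#'
#' Decides, for every unordered sequence pair \{x, y\}, the set of third
#' sequences z over which S_xy will be relaxed, according to the configured
#' selectivity mode. Acceptance uses `alpha(d_xz, d_yz)`; in deterministic
#' mode candidates are additionally capped at `cap` closest-first by the
#' aggregated distance. Stochastic mode is seeded and reproducible.
#'
#' @param dist Distance matrix for the chosen mode: node-count tree
#'   distances ([tree_distance_matrix()]) for `"deterministic-tree"`,
#'   rank-normalized score distances ([rank_normalize()]) for
#'   `"stochastic-score"`; ignored for `"full"`.
#' @param config A [consistency_config()].
#' @return A `relaxation_plan`: list with `accepted` (list keyed `"i|j"` of
#'   accepted z indices) and `n` (symmetric matrix of counts `n_xy`).
#' @export
build_plan <- function(dist, config = consistency_config()) {
  N <- nrow(dist)
  stopifnot(N >= 2)
  T <- config$T
  if (is.null(T)) T <- ceiling(2 * sqrt(N))
  Ffun <- if (is.function(config$filter)) {
    config$filter
  } else {
    triangle_filter(config$filter, config$rate)
  }
  scale <- if (config$alpha == "sum") 2 else 1

  if (config$mode == "stochastic-score") {
    old_seed <- get_rng_state()
    on.exit(set_rng_state(old_seed))
    set.seed(config$seed)
  }

  accepted <- list()
  n_mat <- matrix(0L, N, N, dimnames = dimnames(dist))
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      zs <- setdiff(seq_len(N), c(i, j))
      a <- aggregate_dist(dist[i, zs], dist[j, zs], config$alpha)
      keep <- switch(config$mode,
        full = rep(TRUE, length(zs)),
        `deterministic-tree` = a <= T,
        `stochastic-score` = stochastic_accept(a / scale, Ffun,
                                               invert = config$invert))
      zs <- zs[keep]; a <- a[keep]
      if (length(zs) > config$cap) {
        ord <- order(a)       # closest-first, stable
        zs <- zs[ord][seq_len(config$cap)]
        zs <- sort(zs)
      }
      accepted[[pair_key(i, j)]] <- zs
      n_mat[i, j] <- n_mat[j, i] <- length(zs)
    }
  }
  structure(list(accepted = accepted, n = n_mat, T = T, mode = config$mode),
            class = "relaxation_plan")
}

#' Relax one posterior matrix over accepted third sequences
#'
#' `S'_xy = (h_xy (w_x + w_y) S_xy + sum_z w_z S_xz S_zy) /
#'          (h_xy (w_x + w_y) + sum_z w_z)`,
#' computed with sparse matrix products, then re-thresholded at `cutoff`.
#' With no accepted z and `h_xy = 1` the formula is the identity.
#'
#' @param S_xy Posterior matrix of the pair (sparse or dense).
#' @param accepted List of relaxation terms, each `list(w_z, S_xz, S_zy)`.
#' @param w_x,w_y Sequence weights of the pair.
#' @param h_xy Amplification coefficient, see [amplification_coeff()].
#' @param cutoff Sparsity cutoff applied to the result; default 0 (keep
#'   all nonzero cells).
#' @return The relaxed matrix as a `sparse_posterior`.
#' @export
relax_pair <- function(S_xy, accepted = list(), w_x, w_y, h_xy = 1,
                       cutoff = 0) {
  S_xy <- as_csparse(S_xy)
  num <- h_xy * (w_x + w_y) * S_xy
  den <- h_xy * (w_x + w_y)
  for (term in accepted) {
    S_xz <- as_csparse(term[[2]])
    S_zy <- as_csparse(term[[3]])
    if (nrow(S_xz) != nrow(S_xy) || ncol(S_zy) != ncol(S_xy) ||
        ncol(S_xz) != nrow(S_zy)) {
      stop("relaxation term dimensions do not match S_xy", call. = FALSE)
    }
    w_z <- term[[1]]
    num <- num + w_z * (S_xz %*% S_zy)
    den <- den + w_z
  }
  sparsify(num / den, cutoff)
}

#' Apply the consistency transformation to all posterior matrices
#'
#' One transformation relaxes every pair over its accepted third sequences
#' using the pre-transformation matrices (double-buffered, so the pass is
#' order-independent); repeated `iterations` times. `S'_yx` is the exact
#' transpose of `S'_xy` by construction (only the upper triangle is
#' stored).
#'
#' @param ps A `posterior_set` from [compute_posteriors()].
#' @param plan A `relaxation_plan` from [build_plan()], or `NULL` to build
#'   one from `dist` and `config`.
#' @param weights Sequence weights (see [sequence_weights()]); uniform if
#'   `NULL`.
#' @param config A [consistency_config()].
#' @param dist Distance matrix for plan building when `plan` is `NULL`.
#' @return The transformed `posterior_set`.
#' @export
consistency_transform <- function(ps, plan = NULL, weights = NULL,
                                  config = consistency_config(),
                                  dist = NULL) {
  N <- length(ps$ids)
  if (is.null(weights)) weights <- rep(1 / N, N)
  if (is.null(plan)) {
    if (is.null(dist)) stop("need a plan or a distance matrix", call. = FALSE)
    plan <- build_plan(dist, config)
  }
  iters <- config$iterations
  if (identical(iters, "auto")) iters <- num_transformations(N)
  for (pass in seq_len(iters)) {
    old <- ps$matrices
    new <- old
    for (i in seq_len(N - 1)) {
      for (j in (i + 1):N) {
        zs <- plan$accepted[[pair_key(i, j)]]
        terms <- lapply(zs, function(z) {
          list(weights[z], get_posterior(old, i, z), get_posterior(old, z, j))
        })
        h_xy <- amplification_coeff(plan$n[i, j], config$cap, config$h)
        new[[pair_key(i, j)]] <- relax_pair(old[[pair_key(i, j)]], terms,
                                            weights[i], weights[j], h_xy,
                                            cutoff = ps$cutoff)
      }
    }
    ps$matrices <- new
  }
  ps
}

# save/restore the global RNG stream so seeded internals do not disturb the
# caller's RNG
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

with_seed <- function(seed, code) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed)
  force(code)
}
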