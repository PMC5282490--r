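# Brute-force reference oracles. Exponential-time, deliberately independent
# re-implementations of the production algorithms, used by the test suite on
# tiny inputs. They share no helpers with the production code paths beyond
# the residue encoding of the alphabet.

ORACLE_MAX_LEN <- 7L

# enumerate every global pairwise alignment as a column sequence (path of
# M / X / Y operations); calls visit(ops) per alignment and returns the count
enumerate_paths <- function(nx, ny, visit = NULL) {
  count <- 0L
  rec <- function(i, j, ops) {
    if (i == nx && j == ny) {
      count <<- count + 1L
      if (!is.null(visit)) visit(ops)
      return(invisible())
    }
    if (i < nx && j < ny) rec(i + 1L, j + 1L, c(ops, "M"))
    if (i < nx) rec(i + 1L, j, c(ops, "X"))
    if (j < ny) rec(i, j + 1L, c(ops, "Y"))
  }
  rec(0L, 0L, character(0))
  count
}

#' Count all global pairwise alignments by explicit enumeration
#'
#' Enumerates every monotone column sequence for sequences of the given
#' lengths (2 vs 2 gives the Delannoy number 13).
#'
#' @param nx,ny Sequence lengths (or character strings).
#' @return Integer count of alignments visited.
#' @export
enumerate_pairwise_alignments <- function(nx, ny) {
  if (is.character(nx)) nx <- nchar(nx)
  if (is.character(ny)) ny <- nchar(ny)
  stopifnot(nx <= ORACLE_MAX_LEN, ny <= ORACLE_MAX_LEN)
  enumerate_paths(nx, ny)
}

#' Exhaustive pair-HMM posterior oracle
#'
#' Enumerates every alignment, weights it by its full pair-HMM path
#' probability (start distribution, transitions, emissions), and sums the
#' weights of alignments pairing residues (i, j), normalized by the total.
#'
#' @param x,y Short sequences (<= 7 residues).
#' @param params A [pair_hmm_params()].
#' @return Dense posterior matrix.
#' @export
oracle_hmm_posterior <- function(x, y, params) {
  xi <- encode_residues(as.character(x))
  yi <- encode_residues(as.character(y))
  nx <- length(xi); ny <- length(yi)
  stopifnot(nx <= ORACLE_MAX_LEN, ny <= ORACLE_MAX_LEN)
  match_p <- exp(params$log_match); ins_p <- exp(params$log_ins)
  delta <- params$delta; eps <- params$epsilon
  trans <- function(a, b) {
    if (a == "M") { if (b == "M") 1 - 2 * delta else delta }
    else if (b == a) eps
    else if (b == "M") 1 - eps
    else 0   # X <-> Y forbidden
  }
  start <- c(M = 1 - 2 * delta, X = delta, Y = delta)
  total <- 0
  mass <- matrix(0, nx, ny)
  enumerate_paths(nx, ny, function(ops) {
    w <- start[[ops[1]]]
    i <- 0L; j <- 0L
    cells <- NULL
    for (k in seq_along(ops)) {
      if (k > 1) w <- w * trans(ops[k - 1], ops[k])
      if (ops[k] == "M") {
        i <- i + 1L; j <- j + 1L
        w <- w * match_p[xi[i], yi[j]]
        cells <- rbind(cells, c(i, j))
      } else if (ops[k] == "X") {
        i <- i + 1L; w <- w * ins_p[xi[i]]
      } else {
        j <- j + 1L; w <- w * ins_p[yi[j]]
      }
    }
    total <<- total + w
    if (!is.null(cells)) {
      for (r in seq_len(nrow(cells))) {
        mass[cells[r, 1], cells[r, 2]] <<- mass[cells[r, 1], cells[r, 2]] + w
      }
    }
  })
  mass / total
}

#' Exhaustive partition-function posterior oracle
#'
#' Enumerates every affine-gap alignment with its Boltzmann weight
#' `exp((score - gap costs) / temperature)`; a gap run of length k costs
#' `gap_open + (k - 1) gap_extend`, and every change of gap direction opens
#' a new run.
#'
#' @param x,y Short sequences (<= 7 residues).
#' @param params A [partition_params()].
#' @return Dense posterior matrix.
#' @export
oracle_partition_posterior <- function(x, y, params) {
  xi <- encode_residues(as.character(x))
  yi <- encode_residues(as.character(y))
  nx <- length(xi); ny <- length(yi)
  stopifnot(nx <= ORACLE_MAX_LEN, ny <= ORACLE_MAX_LEN)
  beta <- 1 / params$temperature
  total <- 0
  mass <- matrix(0, nx, ny)
  enumerate_paths(nx, ny, function(ops) {
    sc <- 0
    i <- 0L; j <- 0L
    cells <- NULL
    for (k in seq_along(ops)) {
      if (ops[k] == "M") {
        i <- i + 1L; j <- j + 1L
        sc <- sc + params$score[xi[i], yi[j]]
        cells <- rbind(cells, c(i, j))
      } else {
        if (ops[k] == "X") i <- i + 1L else j <- j + 1L
        opened <- k == 1 || ops[k - 1] != ops[k]
        sc <- sc - if (opened) params$gap_open else params$gap_extend
      }
    }
    w <- exp(beta * sc)
    total <<- total + w
    if (!is.null(cells)) {
      for (r in seq_len(nrow(cells))) {
        mass[cells[r, 1], cells[r, 2]] <<- mass[cells[r, 1], cells[r, 2]] + w
      }
    }
  })
  mass / total
}

#' Brute-force maximum monotone matching score
#'
#' Maximum over all monotone column matchings of the summed cell values of
#' `C`, found by explicit enumeration — the oracle for both the MEA
#' alignment score and the profile-profile DP.
#'
#' @param C Score matrix (rows x columns; <= 7 each).
#' @return The optimal score.
#' @export
brute_column_match <- function(C) {
  nx <- nrow(C); ny <- ncol(C)
  stopifnot(nx <= ORACLE_MAX_LEN, ny <= ORACLE_MAX_LEN)
  best <- -Inf
  enumerate_paths(nx, ny, function(ops) {
    sc <- 0; i <- 0L; j <- 0L
    for (k in seq_along(ops)) {
      if (ops[k] == "M") {
        i <- i + 1L; j <- j + 1L
        sc <- sc + C[i, j]
      } else if (ops[k] == "X") i <- i + 1L else j <- j + 1L
    }
    if (sc > best) best <<- sc
  })
  best
}

#' Dense triple-loop consistency oracle
#'
#' Full (non-selective) consistency over dense matrices with explicit
#' elementwise loops: for every pair (x, y),
#' `S'_xy = (h (w_x + w_y) S_xy + sum_z w_z S_xz S_zy) /
#'          (h (w_x + w_y) + sum_z w_z)`.
#'
#' @param mats N x N list-of-lists of dense matrices (`mats[[x]][[y]]`,
#'   with `mats[[y]][[x]]` its transpose).
#' @param weights Sequence weights.
#' @param h Amplification coefficient applied to every pair.
#' @return List-of-lists of transformed dense matrices.
#' @export
dense_consistency <- function(mats, weights, h = 1) {
  N <- length(mats)
  out <- mats
  for (x in seq_len(N)) {
    for (y in seq_len(N)) {
      if (x == y) next
      S <- mats[[x]][[y]]
      num <- h * (weights[x] + weights[y]) * S
      den <- h * (weights[x] + weights[y])
      for (z in seq_len(N)) {
        if (z == x || z == y) next
        A <- mats[[x]][[z]]; B <- mats[[z]][[y]]
        P <- matrix(0, nrow(S), ncol(S))
        for (i in seq_len(nrow(S))) {
          for (j in seq_len(ncol(S))) {
            acc <- 0
            for (k in seq_len(ncol(A))) acc <- acc + A[i, k] * B[k, j]
            P[i, j] <- acc
          }
        }
        num <- num + weights[z] * P
        den <- den + weights[z]
      }
      out[[x]][[y]] <- num / den
    }
  }
  out
}

#' Brute-force WPGMA oracle
#'
#' Independent agglomerative implementation over leaf-set partitions.
#'
#' @param D Symmetric distance matrix.
#' @return List of merges, each `list(a, b, height)` with `a`, `b` the
#'   sorted leaf-index sets of the merged clusters.
#' @export
brute_upgma <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  d <- as.matrix(D)
  merges <- list()
  while (length(clusters) > 1) {
    k <- length(clusters)
    bi <- 1L; bj <- 2L; bd <- Inf
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (d[i, j] < bd - 1e-15) { bd <- d[i, j]; bi <- i; bj <- j }
      }
    }
    merges[[length(merges) + 1]] <-
      list(a = sort(clusters[[bi]]), b = sort(clusters[[bj]]), height = bd / 2)
    newd <- (d[bi, ] + d[bj, ]) / 2
    keep <- setdiff(seq_len(k), c(bi, bj))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    clusters <- c(clusters[keep], list(c(clusters[[bi]], clusters[[bj]])))
  }
  merges
}

#' Canonical merge list of a production guide tree
#'
#' Puts a [upgma()] tree into the form returned by [brute_upgma()] for
#' direct comparison.
#'
#' @param tree A `guide_tree`.
#' @return List of merges `list(a, b, height)` in merge order.
#' @export
canonical_merges <- function(tree) {
  lb <- leaves_below(tree)
  n <- tree$n_leaves
  lapply(seq_len(n - 1), function(k) {
    v <- n + k
    ch <- tree$children[v, ]
    list(a = sort(lb[[ch[1]]]), b = sort(lb[[ch[2]]]),
         height = tree$height[v])
  })
}
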