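# Stage IV(a): progressive profile-profile alignment in guide-tree order.
# A profile is an alignment block whose rows remember their global sequence
# index and weight; merging two profiles is a DP over column pairs scored by
# the weighted sum of transformed posteriors across all cross-sequence
# pairs.

#' Construct a profile
#'
#' @param aln An [msa()] (or named gapped strings).
#' @param index Integer vector: global sequence index of each row.
#' @param weights Numeric vector of per-row sequence weights (> 0).
#' @return A `profile` object.
#' @export
new_profile <- function(aln, index, weights) {
  aln <- if (is(aln, "msa")) aln else msa(aln)
  stopifnot(length(index) == nrow(aln), length(weights) == nrow(aln),
            all(weights > 0))
  structure(list(aln = aln, index = as.integer(index),
                 weights = as.numeric(weights)),
            class = "profile")
}

#' @export
print.profile <- function(x, ...) {
  cat("profile of", nrow(x$aln), "sequences x", ncol(x$aln), "columns\n")
  invisible(x)
}

# residue-index -> column map for one profile row
residue_columns <- function(mat, row) {
  which(mat[row, ] != GAP)
}

# weighted cross-pair posterior mass per (P column, Q column)
profile_score_matrix <- function(P, Q, ps, normalize = TRUE) {
  nP <- ncol(P$aln); nQ <- ncol(Q$aln)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  wsum <- 0
  for (a in seq_along(P$index)) {
    colP <- residue_columns(P$aln, a)
    for (b in seq_along(Q$index)) {
      colQ <- residue_columns(Q$aln, b)
      S <- get_posterior(ps, P$index[a], Q$index[b])
      w <- P$weights[a] * Q$weights[b]
      wsum <- wsum + w
      Tm <- as(S, "TsparseMatrix")
      if (length(Tm@x)) {
        ii <- c(ii, colP[Tm@i + 1L])
        jj <- c(jj, colQ[Tm@j + 1L])
        xx <- c(xx, w * Tm@x)
      }
    }
  }
  C <- matrix(0, nP, nQ)
  if (length(ii)) {
    C <- as.matrix(Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                        dims = c(nP, nQ)))
  }
  if (normalize && wsum > 0) C <- C / wsum
  C
}

#' Align two profiles
#'
#' Dynamic program over column pairs maximizing the summed (weighted)
#' posterior probability of the matched residue pairs; gap columns carry no
#' reward or penalty. Ties prefer a match, then a gap in `P`, then a gap in
#' `Q`.
#'
#' @param P,Q Profiles with disjoint sequence indices.
#' @param ps A `posterior_set` holding a matrix for every cross pair.
#' @param normalize Divide the column scores by the sum of cross-pair
#'   weight products (default `TRUE`); does not change the optimal path for
#'   a single merge.
#' @return The merged `profile` (rows of `P` first); its `score` attribute
#'   holds the optimal DP score.
#' @export
profile_align <- function(P, Q, ps, normalize = TRUE) {
  if (length(intersect(P$index, Q$index))) {
    stop("profiles share sequence indices", call. = FALSE)
  }
  C <- profile_score_matrix(P, Q, ps, normalize)
  r <- mea_dp_cpp(C)
  matP <- unclass(P$aln); matQ <- unclass(Q$aln)
  ncols <- length(r$ops)
  out <- matrix(GAP, nrow(matP) + nrow(matQ), ncols)
  i <- 0L; j <- 0L
  for (k in seq_len(ncols)) {
    op <- r$ops[k]
    if (op == 1L) {
      i <- i + 1L; j <- j + 1L
      out[seq_len(nrow(matP)), k] <- matP[, i]
      out[nrow(matP) + seq_len(nrow(matQ)), k] <- matQ[, j]
    } else if (op == 2L) {
      i <- i + 1L
      out[seq_len(nrow(matP)), k] <- matP[, i]
    } else {
      j <- j + 1L
      out[nrow(matP) + seq_len(nrow(matQ)), k] <- matQ[, j]
    }
  }
  rownames(out) <- c(rownames(matP), rownames(matQ))
  merged <- new_profile(msa(out), c(P$index, Q$index),
                        c(P$weights, Q$weights))
  attr(merged, "score") <- r$score
  merged
}

#' Progressive alignment along a guide tree
#'
#' Leaves start as single-row profiles; each internal node merges its
#' children with [profile_align()]. The root alignment is returned with
#' rows in input-sequence order.
#'
#' @param seqs The input [seq_set()].
#' @param tree A `guide_tree` over the same sequences.
#' @param ps A `posterior_set` (typically consistency-transformed).
#' @param weights Sequence weights; [sequence_weights()] of the tree by
#'   default.
#' @return The multiple alignment as an [msa()].
#' @export
progressive_align <- function(seqs, tree, ps, weights = NULL) {
  if (is.null(weights)) weights <- sequence_weights(tree)
  n <- tree$n_leaves
  stopifnot(length(seqs) == n)
  build <- function(v) {
    if (v <= n) {
      return(new_profile(setNames(seqs[[v]], names(seqs)[v]), v, weights[v]))
    }
    ch <- tree$children[v, ]
    profile_align(build(ch[1]), build(ch[2]), ps)
  }
  root <- which(tree$parent == 0)
  prof <- build(root)
  ord <- order(prof$index)
  msa(unclass(prof$aln)[ord, , drop = FALSE])
}
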