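# Supervised scoring of a test alignment against a reference: sum-of-pairs
# (SP, fraction of reference residue pairs recovered), total-column (TC,
# fraction of reference columns recovered), their geometric mean Q, and the
# relative alignment length.

# map: for each row, residue ordinal -> column index; and per column the
# residue ordinal per row (0 = gap)
residue_index_matrix <- function(aln) {
  mat <- unclass(aln)
  idx <- matrix(0L, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (r in seq_len(nrow(mat))) {
    res <- mat[r, ] != GAP
    idx[r, res] <- seq_len(sum(res))
  }
  idx
}

check_same_sequences <- function(test, ref) {
  if (!setequal(rownames(test), rownames(ref))) {
    stop("test and reference align different sequence sets", call. = FALSE)
  }
  dt <- degap(test); dr <- degap(ref)
  if (!identical(unclass(dt)[rownames(ref)], unclass(dr)[rownames(ref)])) {
    stop("test and reference rows degap to different sequences", call. = FALSE)
  }
}

# the set of aligned residue pairs of an alignment, encoded as integer keys
aligned_pair_keys <- function(aln) {
  idx <- residue_index_matrix(aln)
  n <- nrow(idx)
  ord <- order(rownames(idx))      # row-order invariance
  idx <- idx[ord, , drop = FALSE]
  maxres <- max(idx) + 1L
  keys <- numeric(0)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      both <- idx[a, ] > 0 & idx[b, ] > 0
      if (any(both)) {
        pair_id <- (a - 1) * n + b
        keys <- c(keys, (pair_id * maxres + idx[a, both]) * maxres + idx[b, both])
      }
    }
  }
  keys
}

#' Sum-of-pairs score against a reference alignment
#'
#' Fraction of residue pairs aligned in the same column of the reference
#' that are also aligned in the test alignment.
#'
#' @param test,ref Alignments ([msa()]) of the same sequences.
#' @return SP in \[0, 1\] (1 when the reference aligns no pairs).
#' @export
sp_score <- function(test, ref) {
  check_same_sequences(test, ref)
  ref_keys <- aligned_pair_keys(ref)
  if (length(ref_keys) == 0) return(1)
  test_keys <- aligned_pair_keys(test)
  sum(ref_keys %in% test_keys) / length(ref_keys)
}

#' Total-column score against a reference alignment
#'
#' Fraction of reference columns (with at least two residues) whose full
#' residue content is reproduced in a single column of the test alignment.
#'
#' @inheritParams sp_score
#' @return TC in \[0, 1\] (1 when the reference has no scorable column).
#' @export
tc_score <- function(test, ref) {
  check_same_sequences(test, ref)
  ids <- sort(rownames(ref))
  it <- residue_index_matrix(test)[ids, , drop = FALSE]
  ir <- residue_index_matrix(ref)[ids, , drop = FALSE]
  # column of test holding residue k of row r
  pos <- lapply(seq_along(ids), function(r) {
    cols <- which(it[r, ] > 0)
    setNames(cols, it[r, cols])
  })
  scorable <- which(colSums(ir > 0) >= 2)
  if (length(scorable) == 0) return(1)
  hit <- 0L
  for (cc in scorable) {
    rows <- which(ir[, cc] > 0)
    tcols <- vapply(rows, function(r) pos[[r]][[as.character(ir[r, cc])]],
                    numeric(1))
    if (length(unique(tcols)) == 1) hit <- hit + 1L
  }
  hit / length(scorable)
}

#' Geometric-mean quality score
#' @param SP,TC Scores in \[0, 1\].
#' @return `sqrt(SP * TC)`.
#' @export
combined_q <- function(SP, TC) {
  stopifnot(SP >= 0, SP <= 1, TC >= 0, TC <= 1)
  sqrt(SP * TC)
}

#' Relative alignment length
#' @param test,ref Alignments.
#' @return `ncol(test) / ncol(ref)`.
#' @export
relative_length <- function(test, ref) {
  ncol(test) / ncol(ref)
}

#' Full score report for a test alignment
#'
#' @inheritParams sp_score
#' @return A one-row data frame with columns `SP`, `TC`, `Q`,
#'   `relative_length`.
#' @export
score_alignment <- function(test, ref) {
  SP <- sp_score(test, ref)
  TC <- tc_score(test, ref)
  data.frame(SP = SP, TC = TC, Q = combined_q(SP, TC),
             relative_length = relative_length(test, ref))
}
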