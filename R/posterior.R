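# Stage I: pairwise posterior probability matrices (pair HMM + partition
# function), their combination and sparsification, and maximum expected
# accuracy (MEA) pairwise alignment.

#' Pair-HMM posterior matrix
#'
#' Cell (i, j) is the posterior probability that residue i of `x` aligns to
#' residue j of `y`, marginalized over all global alignments by
#' forward-backward on the 3-state pair HMM.
#'
#' @param x,y Sequences (single character strings or elements of a
#'   [seq_set()]).
#' @param params A [pair_hmm_params()] object.
#' @return Dense numeric matrix `nchar(x)` x `nchar(y)` with values in
#'   \[0, 1\]; row and column sums do not exceed 1.
#' @export
hmm_posterior <- function(x, y, params = pair_hmm_params()) {
  stopifnot(is(params, "pair_hmm_params"))
  xi <- encode_residues(as.character(x))
  yi <- encode_residues(as.character(y))
  if (length(xi) < 1 || length(yi) < 1) stop("empty sequence", call. = FALSE)
  pairhmm_posterior_cpp(xi, yi, params$log_match, params$log_ins,
                        params$delta, params$epsilon)
}

#' Partition-function posterior matrix
#'
#' Cell (i, j) is the Boltzmann-weighted probability of pairing residues
#' (i, j) over the affine-gap alignment ensemble at the configured
#' temperature.
#'
#' @inheritParams hmm_posterior
#' @param params A [partition_params()] object.
#' @return Dense numeric matrix with values in \[0, 1\].
#' @export
partition_posterior <- function(x, y, params = partition_params()) {
  stopifnot(is(params, "partition_params"))
  xi <- encode_residues(as.character(x))
  yi <- encode_residues(as.character(y))
  if (length(xi) < 1 || length(yi) < 1) stop("empty sequence", call. = FALSE)
  partition_posterior_cpp(xi, yi, params$score, params$gap_open,
                          params$gap_extend, 1 / params$temperature)
}

#' Combine two posterior matrices cellwise
#'
#' @param a,b Dense matrices of identical dimension.
#' @param method `"mean"` (arithmetic mean, default) or `"rms"` (root mean
#'   square).
#' @return Combined dense matrix.
#' @export
combine_posteriors <- function(a, b, method = c("mean", "rms")) {
  method <- match.arg(method)
  if (!identical(dim(a), dim(b))) {
    stop("posterior matrices have different dimensions", call. = FALSE)
  }
  switch(method,
         mean = (a + b) / 2,
         rms = sqrt((a * a + b * b) / 2))
}

#' Sparsify a dense posterior matrix
#'
#' Retains exactly the cells with probability at or above `cutoff` and
#' records the sparsity coefficient beta (stored cells / total cells).
#'
#' @param dense Dense numeric matrix.
#' @param cutoff Probability cutoff in \[0, 1); default 0.01.
#' @return A `sparse_posterior`: a `dgCMatrix` with attributes `cutoff` and
#'   `beta`.
#' @export
sparsify <- function(dense, cutoff = 0.01) {
  stopifnot(cutoff >= 0, cutoff < 1)
  m <- as_csparse(dense)
  if (cutoff > 0) {
    m@x[m@x < cutoff] <- 0
  }
  m <- Matrix::drop0(m)
  structure(m, cutoff = cutoff,
            beta = Matrix::nnzero(m) / prod(dim(m)))
}

#' Densify a sparse posterior
#' @param S A `sparse_posterior` (or any Matrix).
#' @return Base dense matrix.
#' @export
densify <- function(S) {
  as.matrix(S)
}

#' Sparsity coefficient of a sparse posterior
#' @param S A `sparse_posterior`.
#' @return beta, the stored-cell fraction.
#' @export
beta_coeff <- function(S) {
  b <- attr(S, "beta")
  if (is.null(b)) Matrix::nnzero(S) / prod(dim(S)) else b
}

#' Maximum expected accuracy pairwise alignment
#'
#' Dynamic program maximizing the sum of posterior probabilities over
#' matched cells along a monotone alignment path; unmatched residues are
#' free.
#'
#' @param S Posterior matrix for the pair (dense or sparse), rows indexed by
#'   `x` residues.
#' @param x,y The sequences (character strings); lengths must match
#'   `dim(S)`.
#' @return List with `alignment` (a 2-row [msa()]) and `score` (the optimal
#'   posterior sum).
#' @export
mea_align <- function(S, x, y) {
  Sd <- as.matrix(S)
  x <- as.character(x); y <- as.character(y)
  if (nrow(Sd) != nchar(x) || ncol(Sd) != nchar(y)) {
    stop("posterior matrix dimensions do not match the sequences", call. = FALSE)
  }
  r <- mea_dp_cpp(Sd)
  xs <- strsplit(x, "")[[1]]
  ys <- strsplit(y, "")[[1]]
  rowx <- character(length(r$ops)); rowy <- character(length(r$ops))
  i <- 0L; j <- 0L
  for (k in seq_along(r$ops)) {
    op <- r$ops[k]
    if (op == 1L) {
      i <- i + 1L; j <- j + 1L
      rowx[k] <- xs[i]; rowy[k] <- ys[j]
    } else if (op == 2L) {
      i <- i + 1L
      rowx[k] <- xs[i]; rowy[k] <- GAP
    } else {
      j <- j + 1L
      rowx[k] <- GAP; rowy[k] <- ys[j]
    }
  }
  ids <- c(if (!is.null(names(x))) names(x) else "x",
           if (!is.null(names(y))) names(y) else "y")
  aln <- msa(setNames(c(paste(rowx, collapse = ""),
                        paste(rowy, collapse = "")), ids))
  list(alignment = aln, score = r$score)
}

#' Compute all pairwise posterior matrices for a sequence set
#'
#' Stage I driver: for every pair, the pair-HMM and partition-function
#' posteriors are computed, combined, and sparsified; the MEA score feeds
#' the stage II distances.
#'
#' @param seqs A [seq_set()] with at least 2 members.
#' @param hmm [pair_hmm_params()].
#' @param part [partition_params()], or `NULL` to use the HMM posterior
#'   alone.
#' @param combine Combination rule, see [combine_posteriors()].
#' @param cutoff Sparsity cutoff, see [sparsify()].
#' @return A `posterior_set`: list with `matrices` (upper-triangle pair list
#'   keyed `"i|j"`), `scores` (symmetric MEA-score matrix), `ids`, `cutoff`.
#' @export
compute_posteriors <- function(seqs, hmm = pair_hmm_params(),
                               part = partition_params(),
                               combine = "mean", cutoff = 0.01) {
  seqs <- if (is(seqs, "seq_set")) seqs else seq_set(seqs)
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  ids <- names(seqs)
  mats <- list()
  scores <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      P <- hmm_posterior(seqs[[i]], seqs[[j]], hmm)
      if (!is.null(part)) {
        P <- combine_posteriors(P, partition_posterior(seqs[[i]], seqs[[j]], part),
                                method = combine)
      }
      mats[[pair_key(i, j)]] <- sparsify(P, cutoff)
      scores[i, j] <- scores[j, i] <- mea_dp_cpp(P)$score
    }
  }
  structure(list(matrices = mats, scores = scores, ids = ids,
                 cutoff = cutoff, lengths = nchar(seqs)),
            class = "posterior_set")
}

pair_key <- function(i, j) paste0(min(i, j), "|", max(i, j))

# coerce dense or Matrix input to column-compressed sparse form
as_csparse <- function(m) {
  if (is(m, "CsparseMatrix")) return(m)
  as(as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
}

#' Fetch the posterior matrix of a pair, oriented rows = first argument
#' @param ps A `posterior_set` (or a bare list keyed `"i|j"`).
#' @param i,j Sequence indices.
#' @return Sparse matrix with rows indexed by residues of sequence `i`.
#' @export
get_posterior <- function(ps, i, j) {
  mats <- if (is.list(ps) && !is.null(ps$matrices)) ps$matrices else ps
  m <- mats[[pair_key(i, j)]]
  if (is.null(m)) stop("no posterior matrix for pair (", i, ", ", j, ")",
                       call. = FALSE)
  if (i < j) m else Matrix::t(m)
}
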