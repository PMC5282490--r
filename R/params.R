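# Model parameters for stage I: substitution matrices, pair-HMM emission /
# transition parameters, and partition-function settings.

# Robinson & Robinson amino-acid background frequencies (canonical order),
# renormalized to sum exactly 1.
aa_background <- function() {
  f <- c(A = 0.078, C = 0.019, D = 0.054, E = 0.063, F = 0.039, G = 0.074,
         H = 0.022, I = 0.051, K = 0.057, L = 0.090, M = 0.022, N = 0.045,
         P = 0.052, Q = 0.043, R = 0.051, S = 0.071, T = 0.058, V = 0.064,
         W = 0.013, Y = 0.032)
  f <- f[AA_CANONICAL]
  f / sum(f)
}

#' Load a substitution matrix from a plain-text file
#'
#' Reads the conventional whitespace-separated square format (NCBI-style):
#' optional `#` comment lines, a header row of residue labels, then one
#' labelled row per residue.
#'
#' @param path Path to the matrix file.
#' @return Numeric matrix with residue row/column names.
#' @export
read_submatrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- strsplit(trimws(lines[-1]), "\\s+")
  lab <- vapply(body, `[`, character(1), 1)
  vals <- t(vapply(body, function(r) as.numeric(r[-1]), numeric(length(header))))
  dimnames(vals) <- list(lab, header)
  if (!isTRUE(all.equal(rownames(vals), colnames(vals)))) {
    stop("substitution matrix rows and columns are labelled differently",
         call. = FALSE)
  }
  vals
}

#' Fetch a named substitution matrix
#'
#' `"BLOSUM62"` (default), `"BLOSUM45"`, `"BLOSUM80"`, `"PAM250"`, `"PAM30"`,
#' `"PAM70"` resolve through Biostrings; any other value is treated as a file
#' path for [read_submatrix()].
#'
#' @param name Matrix identifier or file path.
#' @return Numeric substitution matrix.
#' @export
get_submatrix <- function(name = "BLOSUM62") {
  shipped <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
               "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  if (name %in% shipped) {
    env <- new.env()
    utils::data(list = name, package = "Biostrings", envir = env)
    return(get(name, envir = env))
  }
  read_submatrix(name)
}

# 21x21 score matrix in internal coding (20 canonical + wildcard), taken
# from a labelled substitution matrix; the wildcard uses the matrix's own X
# column when present, else the background-expected score.
internal_score_matrix <- function(sub) {
  f <- aa_background()
  sc <- matrix(0, 21, 21)
  sc[1:20, 1:20] <- sub[AA_CANONICAL, AA_CANONICAL]
  if ("X" %in% rownames(sub)) {
    sc[21, 1:20] <- sub["X", AA_CANONICAL]
    sc[1:20, 21] <- sub[AA_CANONICAL, "X"]
    sc[21, 21] <- sub["X", "X"]
  } else {
    ex <- as.vector(f %*% sub[AA_CANONICAL, AA_CANONICAL])
    sc[21, 1:20] <- ex
    sc[1:20, 21] <- ex
    sc[21, 21] <- sum(f * ex)
  }
  sc
}

# Solve for lambda such that sum_ab f_a f_b exp(lambda * s_ab) = 1, giving a
# normalized joint emission distribution q_ab implied by a log-odds matrix.
lambda_for_matrix <- function(sub, f = aa_background()) {
  s <- sub[AA_CANONICAL, AA_CANONICAL]
  ff <- outer(f, f)
  g <- function(l) sum(ff * exp(l * s)) - 1
  stats::uniroot(g, c(1e-4, 2), tol = 1e-14)$root
}

#' Pair hidden Markov model parameters
#'
#' Three-state pair HMM (match plus one insert state per sequence). Match
#' emissions are the joint distribution `q(a,b) = f_a f_b exp(lambda s_ab)`
#' implied by the substitution matrix (lambda solved so q sums to 1); insert
#' emissions are the background frequencies. Ambiguity codes emit as a
#' background-expected wildcard.
#'
#' @param delta Gap-open transition probability (match to either insert
#'   state); default 0.0199.
#' @param epsilon Gap-extension probability (insert self-transition);
#'   default 0.7943.
#' @param submatrix Substitution matrix identifier or path (see
#'   [get_submatrix()]); default `"BLOSUM62"`.
#' @return A `pair_hmm_params` object.
#' @export
pair_hmm_params <- function(delta = 0.0199, epsilon = 0.7943,
                            submatrix = "BLOSUM62") {
  stopifnot(is.numeric(delta), is.numeric(epsilon))
  if (delta <= 0 || delta >= 0.5) stop("delta must be in (0, 0.5)", call. = FALSE)
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must be in (0, 1)", call. = FALSE)
  sub <- get_submatrix(submatrix)
  f <- aa_background()
  lambda <- lambda_for_matrix(sub, f)
  q <- outer(f, f) * exp(lambda * sub[AA_CANONICAL, AA_CANONICAL])
  stopifnot(abs(sum(q) - 1) < 1e-9)
  # wildcard row/column: expectation over the alphabet
  qq <- matrix(0, 21, 21)
  qq[1:20, 1:20] <- q
  qq[21, 1:20] <- as.vector(f %*% q)
  qq[1:20, 21] <- as.vector(q %*% f)
  qq[21, 21] <- as.vector(f %*% q %*% f)
  ins <- c(f, sum(f * f))
  structure(list(delta = delta, epsilon = epsilon,
                 log_match = log(qq), log_ins = log(ins),
                 submatrix = if (is.character(submatrix)) submatrix else "custom",
                 lambda = lambda),
            class = "pair_hmm_params")
}

#' Partition-function parameters
#'
#' Affine-gap Boltzmann ensemble over global alignments: an alignment with
#' total substitution score `s` and gap runs of lengths `k_1, k_2, ...`
#' has weight `exp((s - sum_i (gap_open + (k_i - 1) gap_extend)) / temperature)`.
#'
#' @param submatrix Substitution matrix identifier or path; default
#'   `"BLOSUM62"`.
#' @param gap_open Positive gap-opening cost (charged for the first gap
#'   position); default 22.
#' @param gap_extend Positive per-position extension cost; default 1.
#' @param temperature Boltzmann temperature, > 0; default 5.
#' @return A `partition_params` object.
#' @export
partition_params <- function(submatrix = "BLOSUM62", gap_open = 22,
                             gap_extend = 1, temperature = 5) {
  if (!is.finite(gap_open) || !is.finite(gap_extend)) {
    stop("gap penalties must be finite", call. = FALSE)
  }
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  sub <- get_submatrix(submatrix)
  structure(list(score = internal_score_matrix(sub),
                 gap_open = gap_open, gap_extend = gap_extend,
                 temperature = temperature,
                 submatrix = if (is.character(submatrix)) submatrix else "custom"),
            class = "partition_params")
}

#' Read a key = value configuration file
#'
#' Plain-text configuration: one `key = value` pair per line, `#` comments.
#' Values are parsed as numbers where possible, otherwise kept as strings.
#'
#' @param path Path to the config file.
#' @return Named list of settings.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & grepl("=", lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
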