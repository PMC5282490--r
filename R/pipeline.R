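# End-to-end pipeline: stage I posteriors -> stage II guide tree -> stage
# III selective consistency -> stage IV progressive alignment + refinement,
# plus the RAM-capped sparsity adjustment and bulk mode.

#' Pipeline configuration
#'
#' Materializes every tunable of the four stages; the resolved list is
#' echoed in the result for reproducibility.
#'
#' @param submatrix Substitution matrix identifier or path; default
#'   `"BLOSUM62"`.
#' @param delta,epsilon Pair-HMM gap open/extend probabilities.
#' @param gap_open,gap_extend,temperature Partition-function parameters.
#' @param combine Posterior combination rule (`"mean"` or `"rms"`).
#' @param cutoff Sparsity cutoff; default 0.01.
#' @param memory_budget Optional posterior-storage budget in bytes; the
#'   cutoff is raised on a fixed grid until the estimate fits (see
#'   [fit_sparsity()]).
#' @param consistency A [consistency_config()]; seeded from `seed` when
#'   left default.
#' @param refine A [refinement_config()]; seeded from `seed` when left
#'   default.
#' @param seed Global seed; default 1.
#' @param verbose Print one structured line per stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(submatrix = "BLOSUM62",
                            delta = 0.0199, epsilon = 0.7943,
                            gap_open = 22, gap_extend = 1, temperature = 5,
                            combine = "mean", cutoff = 0.01,
                            memory_budget = NULL,
                            consistency = NULL, refine = NULL,
                            seed = 1L, verbose = FALSE) {
  seed <- as.integer(seed)
  if (is.null(consistency)) consistency <- consistency_config(seed = seed)
  if (is.null(refine)) refine <- refinement_config(seed = seed)
  structure(list(submatrix = submatrix, delta = delta, epsilon = epsilon,
                 gap_open = gap_open, gap_extend = gap_extend,
                 temperature = temperature, combine = combine,
                 cutoff = cutoff, memory_budget = memory_budget,
                 consistency = consistency, refine = refine,
                 seed = seed, verbose = verbose),
            class = "pipeline_config")
}

#' Raise the sparsity cutoff to fit a memory budget
#'
#' Estimates sparse posterior storage over all N(N-1)/2 matrices and raises
#' the cutoff minimally along a fixed grid until the estimate fits the
#' budget. Without exact counts the estimate uses the row-sum bound (at
#' cutoff c a length-L row stores at most min(L, 1/c) cells). Cutoffs above
#' the documented floor of 0.5 are refused rather than degrading silently.
#'
#' @param memory_budget Budget in bytes (> 0).
#' @param N Number of sequences.
#' @param lengths Sequence lengths.
#' @param cutoff Current cutoff (the grid never goes below it).
#' @param cell_counts Optional function `f(cutoff)` returning the exact
#'   total retained cells (used when matrices are already available).
#' @param bytes_per_cell Storage cost per sparse cell; default 16.
#' @param grid Candidate cutoffs; default
#'   `c(0.01, 0.02, 0.05, 0.1, 0.15, 0.2, 0.3, 0.5)`.
#' @return The selected cutoff (>= `cutoff`).
#' @export
fit_sparsity <- function(memory_budget, N = NULL, lengths = NULL,
                         cutoff = 0.01, cell_counts = NULL,
                         bytes_per_cell = 16,
                         grid = c(0.01, 0.02, 0.05, 0.1, 0.15, 0.2, 0.3, 0.5)) {
  stopifnot(memory_budget > 0)
  grid <- sort(unique(c(cutoff, grid[grid >= cutoff])))
  estimate <- function(cut) {
    if (!is.null(cell_counts)) return(cell_counts(cut) * bytes_per_cell)
    stopifnot(!is.null(N), !is.null(lengths))
    cells <- 0
    for (i in seq_len(N - 1)) {
      for (j in (i + 1):N) {
        lmin <- min(lengths[i], lengths[j])
        lmax <- max(lengths[i], lengths[j])
        cells <- cells + lmax * min(lmin, ceiling(1 / cut))
      }
    }
    cells * bytes_per_cell
  }
  for (cut in grid) {
    if (estimate(cut) <= memory_budget) return(cut)
  }
  stop("memory budget infeasible even at the floor cutoff (0.5); ",
       "needs at least ", estimate(grid[length(grid)]), " bytes",
       call. = FALSE)
}

resparsify_set <- function(ps, cutoff) {
  ps$matrices <- lapply(ps$matrices, function(m) sparsify(m, cutoff))
  ps$cutoff <- cutoff
  ps
}

#' Align a protein family end to end
#'
#' Runs the four stages with the automatic rules: the number of consistency
#' transformations follows [num_transformations()] and the refinement
#' iteration count follows [auto_refine_iterations()] (both overridable
#' through the configs).
#'
#' @param input A FASTA path or a [seq_set()] (>= 2 sequences).
#' @param config A [pipeline_config()].
#' @param output Optional path for the aligned FASTA.
#' @param tree_out Optional path for a Newick dump of the guide tree.
#' @return An `msa_result`: list with `alignment`, `tree`, `weights`,
#'   `posteriors`, `config` (resolved), and `stats` (per-stage log).
#' @export
align_msa <- function(input, config = pipeline_config(), output = NULL,
                      tree_out = NULL) {
  seqs <- if (is(input, "seq_set")) {
    input
  } else if (is.character(input) && length(input) == 1 && is.null(names(input))) {
    read_fasta(input)
  } else {
    seq_set(input)
  }
  N <- length(seqs)
  if (N < 2) stop("stage input: need at least 2 sequences", call. = FALSE)
  stats <- list(N = N, mean_length = mean(nchar(seqs)))
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))

  # stage I: posterior matrices -------------------------------------------
  t0 <- proc.time()[3]
  hmm <- pair_hmm_params(config$delta, config$epsilon, config$submatrix)
  part <- partition_params(config$submatrix, config$gap_open,
                           config$gap_extend, config$temperature)
  ps <- compute_posteriors(seqs, hmm, part, config$combine, config$cutoff)
  if (!is.null(config$memory_budget)) {
    counter <- function(cut) {
      sum(vapply(ps$matrices, function(m) sum(m@x >= cut), numeric(1)))
    }
    cut <- fit_sparsity(config$memory_budget, N, nchar(seqs),
                        cutoff = config$cutoff, cell_counts = counter)
    if (cut > config$cutoff) ps <- resparsify_set(ps, cut)
  }
  stats$cutoff <- ps$cutoff
  stats$beta_mean <- mean(vapply(ps$matrices, beta_coeff, numeric(1)))
  stats$t_posterior <- proc.time()[3] - t0
  say("stage I: %d pairs, mean beta %.3f (%.1fs)", length(ps$matrices),
      stats$beta_mean, stats$t_posterior)

  # stage II: guide tree --------------------------------------------------
  t0 <- proc.time()[3]
  D <- score_distance_matrix(ps$scores, nchar(seqs))
  tree <- upgma(D, names(seqs))
  weights <- sequence_weights(tree)
  stats$t_tree <- proc.time()[3] - t0
  say("stage II: guide tree built (%.1fs)", stats$t_tree)

  # stage III: selective consistency --------------------------------------
  t0 <- proc.time()[3]
  ccfg <- config$consistency
  dist <- switch(ccfg$mode,
                 `deterministic-tree` = tree_distance_matrix(tree),
                 `stochastic-score` = rank_normalize(D),
                 full = D)
  plan <- build_plan(dist, ccfg)
  iters <- if (identical(ccfg$iterations, "auto")) num_transformations(N) else ccfg$iterations
  ccfg$iterations <- iters
  ps <- consistency_transform(ps, plan, weights, ccfg)
  stats$transformations <- iters
  stats$mean_relaxations <- mean(plan$n[upper.tri(plan$n)])
  stats$t_consistency <- proc.time()[3] - t0
  say("stage III: %d transformation(s), mean relaxations %.1f (%.1fs)",
      iters, stats$mean_relaxations, stats$t_consistency)

  # stage IV: progressive alignment + refinement --------------------------
  t0 <- proc.time()[3]
  aln <- progressive_align(seqs, tree, ps, weights)
  rcfg <- config$refine
  if (identical(rcfg$iterations, "auto")) {
    rcfg$iterations <- auto_refine_iterations(iters)
  }
  aln <- refine(aln, ps, weights, tree, rcfg)
  stats$refine_iterations <- rcfg$iterations
  stats$columns <- ncol(aln)
  stats$t_align <- proc.time()[3] - t0
  say("stage IV: %d columns after %d refinement iterations (%.1fs)",
      ncol(aln), rcfg$iterations, stats$t_align)

  if (!is.null(output)) write_alignment(aln, output)
  if (!is.null(tree_out)) write_newick(tree, tree_out)
  config$consistency <- ccfg
  config$refine <- rcfg
  structure(list(alignment = aln, tree = tree, weights = weights,
                 posteriors = ps, config = config, stats = stats),
            class = "msa_result")
}

#' @export
print.msa_result <- function(x, ...) {
  cat("msa_result:", x$stats$N, "sequences,", x$stats$columns, "columns",
      sprintf("(%d consistency transformation(s), %d refinement iterations)\n",
              x$stats$transformations, x$stats$refine_iterations))
  invisible(x)
}

#' Align many families in one run
#'
#' Independent [align_msa()] runs over a list of FASTA files sharing one
#' resolved configuration; one family failing does not abort the others.
#'
#' @param inputs Character vector of FASTA paths (>= 1).
#' @param config A [pipeline_config()] shared by all runs.
#' @param out_dir Output directory; each family is written as
#'   `<name>.aln.fasta`. `NULL` skips writing.
#' @return A `bulk_result`: list with `summary` (one data-frame row per
#'   family: name, N, mean length, columns, status, elapsed seconds) and
#'   `results` (per-family `msa_result` or the error message). The
#'   `partial_failure` attribute flags any failed family.
#' @export
align_bulk <- function(inputs, config = pipeline_config(), out_dir = NULL) {
  stopifnot(length(inputs) >= 1)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  rows <- list(); results <- list()
  names_all <- make.unique(
    sub("\\.(fa|fasta|faa)$", "", basename(inputs), ignore.case = TRUE))
  for (k in seq_along(inputs)) {
    path <- inputs[k]
    name <- names_all[k]
    t0 <- proc.time()[3]
    res <- tryCatch({
      out <- if (is.null(out_dir)) NULL else file.path(out_dir, paste0(name, ".aln.fasta"))
      align_msa(path, config, output = out)
    }, error = function(e) e)
    elapsed <- proc.time()[3] - t0
    if (inherits(res, "error")) {
      rows[[name]] <- data.frame(family = name, N = NA, mean_length = NA,
                                 columns = NA, status = conditionMessage(res),
                                 elapsed = elapsed)
      results[[name]] <- conditionMessage(res)
    } else {
      rows[[name]] <- data.frame(family = name, N = res$stats$N,
                                 mean_length = res$stats$mean_length,
                                 columns = res$stats$columns,
                                 status = "ok", elapsed = elapsed)
      results[[name]] <- res
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(summary = summary, results = results),
            class = "bulk_result",
            partial_failure = any(summary$status != "ok"))
}
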