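test_that("pair-HMM posterior matches the exhaustive path oracle", {
  set.seed(41)
  hp <- pair_hmm_params()
  for (k in 1:12) {
    x <- rand_tiny_seq(sample(1:5, 1))
    y <- rand_tiny_seq(sample(1:5, 1))
    got <- hmm_posterior(x, y, hp)
    want <- oracle_hmm_posterior(x, y, hp)
    expect_lt(max(abs(got - want)), 1e-10)
    # model symmetry: transposing the pair transposes the posterior
    expect_lt(max(abs(got - t(hmm_posterior(y, x, hp)))), 1e-12)
    expect_true(all(got >= 0 & got <= 1))
    expect_true(all(rowSums(got) <= 1 + 1e-9))
    expect_true(all(colSums(got) <= 1 + 1e-9))
  }
  # single-cell case
  p11 <- hmm_posterior("A", "A", hp)
  expect_equal(dim(p11), c(1, 1))
  expect_true(p11[1, 1] > 0 && p11[1, 1] <= 1)
})

test_that("partition posterior matches the Boltzmann enumeration oracle", {
  set.seed(42)
  pp <- partition_params()
  for (k in 1:12) {
    x <- rand_tiny_seq(sample(1:5, 1))
    y <- rand_tiny_seq(sample(1:5, 1))
    got <- partition_posterior(x, y, pp)
    want <- oracle_partition_posterior(x, y, pp)
    expect_lt(max(abs(got - want)), 1e-10)
    expect_lt(max(abs(got - t(partition_posterior(y, x, pp)))), 1e-12)
  }
})

test_that("low temperature concentrates the partition posterior on the optimum", {
  pp <- partition_params(temperature = 0.05)
  P <- partition_posterior("ACDEF", "ACDEF", pp)
  expect_true(all(diag(P) > 0.99))
  expect_error(partition_params(temperature = 0), "temperature")
  expect_error(partition_params(gap_open = Inf), "finite")
})

test_that("posterior combination is the configured cellwise mean", {
  M <- rand_posterior_matrix(3, 4)
  expect_equal(combine_posteriors(M, M), M)
  expect_equal(combine_posteriors(matrix(0, 3, 4), M), M / 2)
  expect_equal(combine_posteriors(matrix(0.2), matrix(0.6)), matrix(0.4))
  expect_equal(combine_posteriors(matrix(0.2), matrix(0.6), method = "rms"),
               matrix(sqrt((0.04 + 0.36) / 2)))
  expect_error(combine_posteriors(M, matrix(0, 4, 3)), "dimension")
})

test_that("sparsification retains exactly the above-cutoff cells", {
  M <- matrix(c(0.5, 0.02, 0.005, 0.9), 2, 2, byrow = TRUE)
  # M = [[0.5, 0.02], [0.005, 0.9]] row-major
  S <- sparsify(M, 0.01)
  expect_equal(Matrix::nnzero(S), 3)
  expect_equal(attr(S, "beta"), 0.75)
  expect_equal(densify(sparsify(M, 0)), M)
  # monotonicity: beta never increases with the cutoff
  set.seed(7)
  for (k in 1:10) {
    R <- rand_posterior_matrix(6, 5)
    cuts <- sort(runif(4))
    betas <- vapply(cuts, function(ct) beta_coeff(sparsify(R, ct)), numeric(1))
    expect_true(all(diff(betas) <= 0))
  }
})

test_that("MEA alignment maximizes the posterior sum", {
  S <- diag(4)
  r <- mea_align(S, "ACDE", "ACDE")
  expect_equal(r$score, 4)
  expect_equal(unname(msa_strings(r$alignment)), c("ACDE", "ACDE"))
  expect_equal(mea_align(matrix(0, 2, 3), "AC", "ACD")$score, 0)
  # brute-force oracle on random sparse instances, exact score ties
  set.seed(8)
  for (k in 1:40) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    S <- rand_posterior_matrix(n, m) * (matrix(runif(n * m), n, m) < 0.6)
    x <- rand_tiny_seq(n); y <- rand_tiny_seq(m)
    got <- mea_align(S, x, y)
    expect_equal(got$score, brute_column_match(S), tolerance = 1e-12)
    # score invariant under transposing S and swapping the sequences
    expect_equal(got$score, mea_align(t(S), y, x)$score, tolerance = 1e-12)
    # the returned alignment realizes the returned score
    expect_identical(unclass(degap(got$alignment))[[1]], x)
  }
})

test_that("compute_posteriors assembles a coherent posterior set", {
  set.seed(5)
  seqs <- rand_seq_set(4, 15)
  ps <- compute_posteriors(seqs, cutoff = 0.01)
  expect_length(ps$matrices, 6)
  expect_true(all(ps$scores[upper.tri(ps$scores)] > 0))
  S12 <- get_posterior(ps, 1, 2)
  S21 <- get_posterior(ps, 2, 1)
  expect_identical(as.matrix(S21), t(as.matrix(S12)))
  expect_true(all(as.matrix(S12) >= 0 & as.matrix(S12) <= 1))
  expect_error(compute_posteriors(seqs[1]), "at least 2")
})
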