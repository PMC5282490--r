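test_that("transformation count and amplification follow the published rules", {
  expect_equal(num_transformations(30), 2L)
  expect_equal(num_transformations(49), 2L)
  expect_equal(num_transformations(50), 1L)
  expect_equal(num_transformations(1000), 1L)

  expect_equal(amplification_coeff(0), 1)
  expect_equal(amplification_coeff(200, 200, 3), 3)
  expect_equal(amplification_coeff(100, 200, 3), 2)
  expect_equal(amplification_coeff(500, 200, 3), 3)  # capped
})

test_that("deterministic acceptance thresholds the aggregated distance", {
  expect_true(deterministic_accept(3, 5, "max", 6))
  expect_false(deterministic_accept(3, 5, "max", 4.9))
  expect_false(deterministic_accept(1, 1, "max", 0))   # T = 0: selectivity off
  expect_true(deterministic_accept(100, 3, "max", Inf)) # T = Inf: full
  expect_true(deterministic_accept(3, 5, "sum", 8))
  expect_true(deterministic_accept(3, 5, "min", 3))
  expect_error(deterministic_accept(3, 5, "median", 1), "unknown")
})

test_that("stochastic filter draws behave as acceptance probabilities", {
  set.seed(10)
  expect_true(all(stochastic_accept(runif(100), function(a) rep(1, length(a)))))
  expect_false(any(stochastic_accept(runif(100), function(a) rep(0, length(a)))))
  # invert flag applies the literal published inequality
  set.seed(10)
  a <- runif(1000)
  F <- triangle_filter("low", 0.1)
  set.seed(99); acc <- stochastic_accept(a, F)
  set.seed(99); inv <- stochastic_accept(a, F, invert = TRUE)
  expect_equal(acc, !inv)
  expect_error(stochastic_accept(0.5, function(a) 2), "\\[0, 1\\]")
})

test_that("triangle presets integrate to the configured acceptance rate", {
  grid <- seq(0, 1, length.out = 2e5 + 1)
  for (type in c("low", "mid", "high")) {
    F <- triangle_filter(type, 0.1)
    expect_equal(mean(F(grid)), 0.1, tolerance = 1e-3)
    expect_true(all(F(grid) >= 0 & F(grid) <= 1))
  }
  expect_equal(mean(triangle_filter("low", 0.25)(grid)), 0.25, tolerance = 1e-3)
})

test_that("relaxation plans match a brute-force triple scan", {
  fam <- generate_family(family_spec(n = 7, length = 20, seed = 21))
  Dt <- tree_distance_matrix(fam$tree)
  cfg <- consistency_config(mode = "deterministic-tree", T = 5)
  plan <- build_plan(Dt, cfg)
  for (i in 1:6) {
    for (j in (i + 1):7) {
      want <- Filter(function(z) {
        deterministic_accept(Dt[i, z], Dt[j, z], "max", 5)
      }, setdiff(1:7, c(i, j)))
      expect_equal(plan$accepted[[paste0(i, "|", j)]], want)
      expect_equal(plan$n[i, j], length(want))
    }
  }
  # full mode accepts everything
  pf <- build_plan(Dt, consistency_config(mode = "full"))
  expect_true(all(pf$n[upper.tri(pf$n)] == 5))
  # stochastic plans are reproducible for a fixed seed
  set.seed(5)
  M0 <- matrix(runif(49), 7, 7)
  Dr <- rank_normalize((M0 + t(M0)) * (1 - diag(7)))
  cfg_s <- consistency_config(mode = "stochastic-score", alpha = "sum",
                              filter = "low", seed = 77)
  p1 <- build_plan(Dr, cfg_s)
  p2 <- build_plan(Dr, cfg_s)
  expect_identical(p1$accepted, p2$accepted)
})

test_that("relax_pair implements the weighted relaxation formula", {
  # empty accepted set with h_xy = 1 is the exact identity
  S <- sparsify(rand_posterior_matrix(3, 4), 0)
  out <- relax_pair(S, list(), w_x = 0.3, w_y = 0.2, h_xy = 1)
  expect_equal(as.matrix(out), as.matrix(S))

  # dense 2x2 hand oracle, one accepted z, uniform weights
  S_xy <- matrix(c(0.6, 0.1, 0.2, 0.5), 2)
  S_xz <- matrix(c(0.7, 0.2, 0.1, 0.6), 2)
  S_zy <- matrix(c(0.5, 0.3, 0.4, 0.4), 2)
  w <- 1 / 3
  got <- relax_pair(S_xy, list(list(w, S_xz, S_zy)), w, w, h_xy = 1)
  want <- (1 * (w + w) * S_xy + w * (S_xz %*% S_zy)) / (1 * (w + w) + w)
  expect_equal(as.matrix(got), want, tolerance = 1e-14)
  expect_error(relax_pair(S_xy, list(list(w, S_xz, matrix(0, 3, 2))),
                          w, w, 1), "dimensions")
})

test_that("the transform equals the dense triple-loop oracle in full mode", {
  set.seed(31)
  seqs <- rand_seq_set(4, 8)
  ps <- compute_posteriors(seqs, cutoff = 0)
  w <- rep(0.25, 4)
  h_xy <- amplification_coeff(2, 200, 3)   # n_xy = N - 2 = 2 for all pairs

  cfg <- consistency_config(mode = "deterministic-tree", T = Inf, h = 3,
                            iterations = 1)
  Dt <- matrix(3, 4, 4); diag(Dt) <- 1
  got <- consistency_transform(ps, weights = w, config = cfg, dist = Dt)
  want <- dense_consistency(dense_mats_from_ps(ps), w, h = h_xy)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_lt(max(abs(as.matrix(get_posterior(got, i, j)) - want[[i]][[j]])),
                1e-9)
      # exact transpose symmetry
      expect_identical(as.matrix(get_posterior(got, j, i)),
                       t(as.matrix(get_posterior(got, i, j))))
      # cells stay in [0, 1]
      expect_true(all(as.matrix(get_posterior(got, i, j)) >= 0 &
                        as.matrix(get_posterior(got, i, j)) <= 1))
    }
  }

  # T = 0 with h = 1 is the identity
  cfg0 <- consistency_config(mode = "deterministic-tree", T = 0, h = 1,
                             iterations = 1)
  same <- consistency_transform(ps, weights = w, config = cfg0, dist = Dt)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(as.matrix(get_posterior(same, i, j)),
                   as.matrix(get_posterior(ps, i, j)))
    }
  }

  # two iterations compose the single transformation with itself
  cfg2 <- cfg; cfg2$iterations <- 2
  twice <- consistency_transform(ps, weights = w, config = cfg2, dist = Dt)
  once_once <- consistency_transform(got, weights = w, config = cfg, dist = Dt)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(as.matrix(get_posterior(twice, i, j)),
                   as.matrix(get_posterior(once_once, i, j)), tolerance = 1e-12)
    }
  }

  # deterministic selectivity converges to full consistency as T grows
  cfg_full <- consistency_config(mode = "full", h = 3, iterations = 1)
  full <- consistency_transform(ps, weights = w, config = cfg_full, dist = Dt)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(as.matrix(get_posterior(got, i, j)),
                   as.matrix(get_posterior(full, i, j)), tolerance = 1e-12)
    }
  }
})

test_that("sparse relaxation equals the dense path at cutoff zero", {
  set.seed(33)
  for (k in 1:5) {
    S_xy <- rand_posterior_matrix(3, 4)
    S_xz <- rand_posterior_matrix(3, 3)
    S_zy <- rand_posterior_matrix(3, 4)
    w <- runif(3); w <- w / sum(w)
    got <- relax_pair(sparsify(S_xy, 0),
                      list(list(w[3], sparsify(S_xz, 0), sparsify(S_zy, 0))),
                      w[1], w[2], h_xy = 1.5)
    want <- (1.5 * (w[1] + w[2]) * S_xy + w[3] * (S_xz %*% S_zy)) /
      (1.5 * (w[1] + w[2]) + w[3])
    expect_lt(max(abs(as.matrix(got) - want)), 1e-12)
  }
})
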