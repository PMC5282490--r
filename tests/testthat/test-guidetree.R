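test_that("score-based distances follow the documented formula", {
  expect_equal(score_to_distance(3, 4, 6), 0.25)
  expect_equal(score_to_distance(0, 5, 9), 1)
  expect_lt(score_to_distance(4.999, 5, 5), 0.001)
  expect_equal(score_to_distance(12, 5, 5), 0)  # clamped
  expect_error(score_to_distance(1, 0, 5), "zero-length")
})

test_that("rank normalization is an order-isomorphic map onto [0, 1]", {
  D <- matrix(0, 3, 3)
  D[1, 2] <- D[2, 1] <- 0.3
  D[1, 3] <- D[3, 1] <- 0.9
  D[2, 3] <- D[3, 2] <- 0.5
  R <- rank_normalize(D)
  expect_equal(sort(R[upper.tri(R)]), c(0, 0.5, 1))
  expect_equal(R[1, 2], 0)
  expect_equal(R[1, 3], 1)

  Deq <- matrix(0.4, 4, 4); diag(Deq) <- 0
  Req <- rank_normalize(Deq)
  expect_true(all(Req[upper.tri(Req)] == 0.5))

  set.seed(2)
  for (k in 1:5) {
    M <- matrix(0, 5, 5)
    v <- runif(10)
    M[upper.tri(M)] <- v
    M <- M + t(M)
    R <- rank_normalize(M)
    expect_equal(cor(M[upper.tri(M)], R[upper.tri(R)], method = "spearman"), 1)
    expect_true(all(R >= 0 & R <= 1))
  }
})

test_that("WPGMA merges closest clusters with mean-update distances", {
  # N = 2: a single root, each branch d/2
  D2 <- matrix(c(0, 3, 3, 0), 2)
  t2 <- upgma(D2, c("a", "b"))
  expect_equal(max(t2$height), 1.5)
  expect_equal(sequence_weights(t2), c(a = 0.5, b = 0.5))

  # hand-run 3x3: merge (a,b) at height 1, then c joins at height 4
  D3 <- matrix(c(0, 2, 8,
                 2, 0, 8,
                 8, 8, 0), 3, byrow = TRUE)
  t3 <- upgma(D3, c("a", "b", "c"))
  expect_equal(sort(t3$height), c(0, 0, 0, 1, 4))
  expect_equal(sort(t3$children[4, ]), c(1, 2))

  # random matrices against the independent brute-force oracle
  set.seed(3)
  for (k in 1:5) {
    M <- matrix(0, 6, 6)
    M[upper.tri(M)] <- runif(15, 1, 10)
    M <- M + t(M)
    tree <- upgma(M)
    want <- brute_upgma(M)
    got <- canonical_merges(tree)
    for (s in seq_along(want)) {
      expect_equal(got[[s]]$height, want[[s]]$height, tolerance = 1e-12)
      expect_setequal(list(got[[s]]$a, got[[s]]$b),
                      list(want[[s]]$a, want[[s]]$b))
    }
    # ultrametric: heights increase along every merge path
    for (v in 7:11) {
      expect_true(all(tree$height[tree$children[v, ]] <= tree$height[v] + 1e-9))
    }
  }
})

test_that("WPGMA heights agree with the phangorn reference implementation", {
  skip_if_not_installed("phangorn")
  set.seed(9)
  M <- matrix(0, 7, 7, dimnames = list(paste0("s", 1:7), paste0("s", 1:7)))
  M[upper.tri(M)] <- runif(21, 1, 10)
  M <- M + t(M)
  ours <- ape::cophenetic.phylo(as_phylo(upgma(M)))
  ref <- ape::cophenetic.phylo(phangorn::upgma(as.dist(M), method = "mcquitty"))
  expect_lt(max(abs(ours[rownames(ref), colnames(ref)] - ref)), 1e-8)
})

test_that("sequence weights follow the branch-sharing rule", {
  # caterpillar ((a,b),c): heights 1 and 2 -> raw weights a=b=1.5, c=2
  D3 <- matrix(c(0, 2, 4,
                 2, 0, 4,
                 4, 4, 0), 3, byrow = TRUE)
  t3 <- upgma(D3, c("a", "b", "c"))
  w <- sequence_weights(t3)
  expect_equal(w, c(a = 1.5, b = 1.5, c = 2) / 5)

  # balanced tree with equal branch lengths -> uniform
  D4 <- matrix(2, 4, 4); diag(D4) <- 0
  w4 <- sequence_weights(upgma(D4, letters[1:4]))
  expect_equal(unname(w4), rep(0.25, 4))

  # permutation invariance
  set.seed(4)
  M <- matrix(0, 5, 5)
  M[upper.tri(M)] <- runif(10, 1, 5)
  M <- M + t(M)
  rownames(M) <- colnames(M) <- paste0("s", 1:5)
  w1 <- sequence_weights(upgma(M))
  perm <- c(3, 1, 5, 2, 4)
  w2 <- sequence_weights(upgma(M[perm, perm]))
  expect_equal(w2[names(w1)], w1, tolerance = 1e-12)
})

test_that("tree distance counts the minimal subtree's nodes", {
  fam <- generate_family(family_spec(n = 8, seed = 13, length = 20))
  tree <- fam$tree
  # siblings span 3 nodes; root-separated leaves span the whole tree
  root <- which(tree$parent == 0)
  for (v in (tree$n_leaves + 1):length(tree$height)) {
    ch <- tree$children[v, ]
    if (all(ch <= tree$n_leaves)) {
      expect_equal(tree_distance(tree, ch[1], ch[2]), 3)
    }
  }
  expect_equal(tree_distance(tree, tree$labels[1], tree$labels[1]), 1)
  expect_error(tree_distance(tree, "nope", tree$labels[1]), "unknown")

  # brute-force minimal-subtree oracle over all pairs
  Dt <- tree_distance_matrix(tree)
  expect_true(isSymmetric(Dt))
  for (x in 1:7) {
    for (y in (x + 1):8) {
      expect_equal(Dt[x, y], brute_min_subtree(tree, x, y))
    }
  }
  expect_equal(max(Dt), 2 * 8 - 1)  # some pair spans the root

  # 5-leaf caterpillar: leaves 1 and 3 meet in the 5-node subtree
  cat5 <- generate_family(family_spec(n = 5, seed = 1, length = 20,
                                      tree_shape = "caterpillar"))$tree
  expect_equal(tree_distance(cat5, 1, 3), brute_min_subtree(cat5, 1, 3))
  expect_equal(tree_distance(cat5, 1, 3), 5)
})

test_that("newick export is parseable and preserves leaves", {
  D3 <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, byrow = TRUE)
  tree <- upgma(D3, c("a", "b", "c"))
  ph <- as_phylo(tree)
  expect_setequal(ph$tip.label, c("a", "b", "c"))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, f)
  expect_equal(ape::read.tree(f)$Nnode, 2)
})
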