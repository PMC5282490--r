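test_that("candidate columns are the gapped, non-empty ones", {
  expect_equal(candidate_columns(msa(c(a = "ACDE", b = "ACDE"))), integer(0))
  expect_equal(candidate_columns(msa(c(a = "AC-D", b = "ACCD"))), 2L)
  toy <- msa(c(a = "A-C-E", b = "ABCDE", c = "ABC-E"))
  expect_equal(candidate_columns(toy), c(1L, 3L))
})

test_that("column selection respects bias and is uniform without it", {
  toy <- msa(c(a = "A-C-E", b = "ABCDE", c = "ABC-E"))
  expect_equal(select_column(1L, toy), 1L)   # single candidate, any bias
  expect_error(select_column(integer(0), toy), "no candidate")

  # uniform draw over 4 candidates
  aln <- msa(c(a = "-AC-GG", b = "AACCGG", c = "A-CC-G"))
  cand <- candidate_columns(aln)
  expect_length(cand, 4)
  set.seed(60)
  draws <- replicate(10000, select_column(cand, aln))
  freq <- table(draws) / 10000
  expect_true(all(abs(freq - 0.25) < 0.02))

  # balanced bias restricts to the most balanced half: build a 10-row
  # alignment whose candidate columns have gap counts 1, 2, 5, 9
  rows <- sapply(1:10, function(r) {
    paste0(ifelse(r <= 1, "-", "A"), ifelse(r <= 2, "-", "C"),
           ifelse(r <= 5, "-", "D"), ifelse(r <= 9, "-", "E"), "G")
  })
  names(rows) <- paste0("r", 1:10)
  big <- msa(rows)
  cand <- candidate_columns(big)
  expect_equal(cand, 0:3)
  # |g - N/2| = (4, 3, 0, 4): balanced-50% keeps columns with g = 5, 2
  set.seed(61)
  picks <- unique(replicate(300, select_column(cand, big, "balanced", 50)))
  expect_setequal(picks, c(2L, 1L))
  # imbalanced-50% keeps the two largest |g - N/2| (g = 1 and 9)
  set.seed(62)
  picks <- unique(replicate(300, select_column(cand, big, "imbalanced", 50)))
  expect_setequal(picks, c(0L, 3L))
})

test_that("column split groups rows by gap presence", {
  aln <- msa(c(a = "A-C", b = "ABC", c = "A-C"))
  parts <- split_by_column(aln, 1L)
  expect_equal(rownames(parts$gap$mat), c("a", "c"))
  expect_equal(rownames(parts$res$mat), "b")
  expect_error(split_by_column(aln, 0L), "not a candidate")

  five <- msa(c(a = "-ACD", b = "AACD", c = "AACD", d = "AACD", e = "AACD"))
  parts <- split_by_column(five, 0L)
  expect_equal(nrow(parts$gap$mat), 1)
  expect_equal(nrow(parts$res$mat), 4)
})

test_that("gap-only columns are stripped after splitting", {
  mat2 <- rbind(a = strsplit("AC-D", "")[[1]], b = strsplit("AC-D", "")[[1]])
  grp <- list(mat = mat2, index = 1:2, weights = c(0.5, 0.5))
  # rows a, b share a gap column that is gap-only within the group
  prof <- strip_gap_columns(grp)
  expect_equal(ncol(prof$aln), 3)
  single <- strip_gap_columns(list(mat = matrix(c("A", "-", "-", "C"), 1,
                                                dimnames = list("a", NULL)),
                                   index = 1, weights = 1))
  expect_equal(unname(msa_strings(single$aln)), "AC")
  # splitting on a candidate column always shortens the gap side
  aln <- msa(c(a = "A-CD", b = "ABCD", c = "AB-D"))
  parts <- split_by_column(aln, 1L)
  expect_lt(ncol(strip_gap_columns(parts$gap)$aln), ncol(aln))
})

test_that("random and tree splits produce valid bipartitions", {
  aln <- msa(c(a = "ACD", b = "ACD"))
  set.seed(63)
  parts <- split_random(aln)
  expect_equal(sort(c(nrow(parts$a$mat), nrow(parts$b$mat))), c(1, 1))

  # all 7 bipartitions of 4 rows appear under repeated draws
  aln4 <- msa(c(a = "ACD", b = "ACD", c = "ACD", d = "ACD"))
  set.seed(64)
  seen <- character(0)
  for (k in 1:2000) {
    p <- split_random(aln4)
    key <- paste(sort(rownames(p$a$mat)), collapse = "")
    key2 <- paste(sort(rownames(p$b$mat)), collapse = "")
    seen <- union(seen, min(key, key2))
  }
  expect_length(seen, 7)

  # tree split always cuts out a clade
  fam <- generate_family(family_spec(n = 6, length = 20, seed = 65))
  truth_aln <- fam$alignment
  set.seed(66)
  for (k in 1:20) {
    p <- split_tree(truth_aln, fam$tree)
    expect_gt(nrow(p$a$mat), 0)
    expect_gt(nrow(p$b$mat), 0)
    side <- sort(match(rownames(p$a$mat), fam$tree$labels))
    clades <- lapply(probmsa:::leaves_below(fam$tree), sort)
    expect_true(any(vapply(clades, identical, logical(1), y = side)))
  }
})

test_that("trident score matches hand arithmetic", {
  expect_equal(trident_score(msa(c(a = "AAA", b = "AAA", c = "AAA"))), 1)

  # 2-column toy: a/b/c residues (A, A, C) and (K, -, K)
  toy <- msa(c(a = "AK", b = "A-", c = "CK"))
  # column 1: symbols (A, A, C): t = entropy(2/3, 1/3)/log(3), classes
  # (1, 1, 1): r = 0, g = 0
  t1 <- -(2 / 3 * log(2 / 3) + 1 / 3 * log(1 / 3)) / log(3)
  s1 <- (1 - t1)
  # column 2: symbols (K, K): t = 0, r = 0, g = 1/3
  s2 <- 1 - 1 / 3
  expect_equal(trident_score(toy), mean(c(s1, s2)), tolerance = 1e-12)

  # maximal diversity drives the column score toward zero
  div <- msa(c(a = "A", b = "K", c = "D", d = "F", e = "S"))
  expect_lt(trident_score(div), 0.05)
})

test_that("acceptance rules compare candidate and incumbent", {
  a10 <- msa(c(a = "ACDEFGHIKL", b = "ACDEFGHIKL"))
  a12 <- msa(c(a = "ACDEFGHIK--L", b = "ACD--EFGHIKL"))
  expect_true(accept_alignment(a10, a12, "length"))
  expect_false(accept_alignment(a12, a10, "length"))
  expect_true(accept_alignment(a10, a10, "length"))  # equality accepted
  expect_true(accept_alignment(a12, a10, "always"))
  expect_true(accept_alignment(a10, a12, "trident"))
  expect_error(accept_alignment(a10, msa(c(x = "AC", y = "AC")), "length"),
               "different sequences")
})

test_that("refinement preserves invariants and obeys the length rule", {
  fam <- generate_family(family_spec(n = 8, length = 60, seed = 70))
  ps <- compute_posteriors(fam$sequences)
  D <- score_distance_matrix(ps$scores, nchar(fam$sequences))
  tree <- upgma(D, names(fam$sequences))
  w <- sequence_weights(tree)
  ps <- consistency_transform(ps, weights = w,
                              config = consistency_config(),
                              dist = tree_distance_matrix(tree))
  aln0 <- progressive_align(fam$sequences, tree, ps, w)

  expect_identical(refine(aln0, ps, w, tree,
                          refinement_config(iterations = 0)), aln0)

  for (strat in c("column", "random", "tree")) {
    cfg <- refinement_config(strategy = strat, iterations = 15,
                             acceptance = "length", seed = 71)
    out <- refine(aln0, ps, w, tree, cfg)
    expect_lte(ncol(out), ncol(aln0))
    expect_identical(unclass(degap(out)), unclass(fam$sequences))
    expect_s3_class(out, "msa")   # constructor re-validated: no all-gap cols
  }

  # seeded determinism
  cfg <- refinement_config(iterations = 10, seed = 72)
  expect_identical(msa_strings(refine(aln0, ps, w, tree, cfg)),
                   msa_strings(refine(aln0, ps, w, tree, cfg)))
})
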