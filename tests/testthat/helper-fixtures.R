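# Shared fixture builders. Everything is generated in code under fixed
# seeds; no files are read.

# random sequence over a reduced 4-letter alphabet (keeps the enumeration
# oracles cheap)
rand_tiny_seq <- function(len, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# random posterior-like matrix with row and column sums <= 1
rand_posterior_matrix <- function(n, m) {
  M <- matrix(runif(n * m), n, m)
  M / max(c(rowSums(M), colSums(M), 1))
}

# small sequence set of full-alphabet proteins
rand_seq_set <- function(n, len) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seq_set(setNames(
    vapply(seq_len(n), function(i) paste(sample(aa, len, replace = TRUE),
                                         collapse = ""), character(1)),
    paste0("s", seq_len(n))))
}

# dense NxN list-of-lists view of a posterior_set, for the dense oracle
dense_mats_from_ps <- function(ps) {
  N <- length(ps$ids)
  out <- lapply(seq_len(N), function(i) vector("list", N))
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i != j) out[[i]][[j]] <- as.matrix(get_posterior(ps, i, j))
    }
  }
  out
}

# independent minimal-subtree node count (test-side oracle for
# tree_distance): enumerate every node, check that both leaves are below it
# by walking parent pointers, take the smallest subtree size
brute_min_subtree <- function(tree, x, y) {
  is_below <- function(leaf, v) {
    w <- leaf
    repeat {
      if (w == v) return(TRUE)
      w <- tree$parent[w]
      if (w == 0) return(FALSE)
    }
  }
  sizes <- vapply(seq_along(tree$height), function(v) {
    if (is_below(x, v) && is_below(y, v)) tree$size[v] else NA_integer_
  }, integer(1))
  min(sizes, na.rm = TRUE)
}
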