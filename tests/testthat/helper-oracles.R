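# Independent oracles used by the tests; these stay separate from the
# implementation paths they check.

# Brute-force Gotoh affine-gap global alignment score under a
# match/mismatch scoring function; gap of length L costs open + extend * L.
oracle_affine_score <- function(a, b, score_fun, open = 10, extend = 0.5) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in b (a consumed)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in a (b consumed)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + extend * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(open + extend * (j - 1))
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- score_fun(av[i], bv[j])
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      # opposite-gap adjacency is allowed (each gap opens separately)
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                             X[i, j + 1] - extend,
                             Y[i, j + 1] - open - extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                             Y[i + 1, j] - extend,
                             X[i + 1, j] - open - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

ednafull_score <- function(x, y) if (x == y) 5 else -4

# Pearson chi-square by explicit expected counts.
oracle_chi2 <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - e)^2 / e)
}

# Brute-force intra/inter pair tally for cross_domain_pct.
oracle_cross_domain <- function(dense, bins1, bins2) {
  intra <- 0; inter <- 0
  n <- nrow(dense)
  for (i in seq_len(n)) for (j in i:n) {
    v <- dense[i, j]
    in1 <- c(i %in% bins1, j %in% bins1)
    in2 <- c(i %in% bins2, j %in% bins2)
    if (all(in1) || all(in2)) intra <- intra + v
    else if (any(in1) && any(in2)) inter <- inter + v
  }
  inter * 100 / (intra + inter)
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = "")
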