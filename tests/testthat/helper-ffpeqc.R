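# shared fixture builders; all randomness is seeded at the call site

rand_expr <- function(p, n, seed = 1, mean = 8, sd = 1) {
  set.seed(seed)
  expr_matrix(matrix(rnorm(p * n, mean, sd), p, n,
    dimnames = list(sprintf("f%04d", seq_len(p)), sprintf("s%03d", seq_len(n)))
  ))
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# independent leave-one-out oracle: naive O(p * n^2) loop
brute_force_loo_dfarray <- function(m) {
  p <- nrow(m)
  n <- ncol(m)
  out <- matrix(NA_real_, p, n, dimnames = dimnames(m))
  for (i in seq_len(p)) {
    for (j in seq_len(n)) {
      rest <- m[i, -j]
      mu <- mean(rest)
      s <- sd(rest)
      out[i, j] <- if (s == 0) {
        if (m[i, j] - mu == 0) 0 else NA_real_
      } else {
        (m[i, j] - mu) / s
      }
    }
  }
  out
}

# independent distance oracle for the standardized-profile outlier metric
brute_force_lumi <- function(m, dissimilarity = "euclidean") {
  mu <- apply(m, 1, mean)
  s <- apply(m, 1, sd)
  z <- (m[s > 0, , drop = FALSE] - mu[s > 0]) / s[s > 0]
  target <- apply(z, 1, median)
  vapply(seq_len(ncol(z)), function(j) {
    if (dissimilarity == "euclidean") {
      sqrt(sum((z[, j] - target)^2))
    } else {
      1 - cor(z[, j], target)
    }
  }, numeric(1))
}
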