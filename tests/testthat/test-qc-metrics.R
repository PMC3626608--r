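test_that("stress summarizes mean-centered absolute shifts on the fold-change scale", {
  S <- cbind(
    zero = rep(0, 5),
    const = rep(3.7, 5), # constant shifts carry no stress
    mixed = c(0, 0, 1, 2, 2) # mean 1, |S - 1| = (1,1,0,1,1), median 1
  )
  st <- compute_stress(S)
  expect_equal(st$stress, c(1, 1, 2))
  expect_true(all(st$stress >= 1))
})

test_that("stress is invariant to a constant added to one array's raw values", {
  Y <- rand_expr(400, 6, seed = 13)
  s1 <- compute_stress(quantile_normalize(Y))
  Y2 <- unclass(Y)
  Y2[, 2] <- Y2[, 2] + 4
  s2 <- compute_stress(quantile_normalize(expr_matrix(Y2)))
  expect_lt(max(abs(log2(s2$stress) - log2(s1$stress))), 1e-9)
})

test_that("exact leave-one-out dfArray matches the naive brute force", {
  Y <- rand_expr(10, 6, seed = 2)
  res <- compute_dfarray(Y, mode = "exact_loo")
  oracle <- brute_force_loo_dfarray(unclass(Y))
  expect_equal(res$grid, oracle, tolerance = 1e-10)

  # and again on a second instance with different moments
  Y2 <- rand_expr(10, 6, seed = 99, mean = 12, sd = 3)
  expect_equal(compute_dfarray(Y2, mode = "exact_loo")$grid,
    brute_force_loo_dfarray(unclass(Y2)),
    tolerance = 1e-10
  )
})

test_that("robust and exact dfArray agree on Gaussian data and rank an outlier first", {
  set.seed(31)
  p <- 2000
  n <- 20
  # Gaussian arrays with heterogeneous noise scales, so the per-sample
  # summaries genuinely vary and rank correlation is informative
  sds <- seq(0.5, 1.5, length.out = n)
  m <- vapply(sds, function(s) rnorm(p, 8, s), numeric(p))
  dimnames(m) <- list(sprintf("f%04d", 1:p), sprintf("s%02d", 1:n))
  # inject one array deviating strongly on a third of the features
  hit <- sample(p, p / 3)
  m[hit, 7] <- m[hit, 7] + 4
  Y <- expr_matrix(m)
  rob <- compute_dfarray(Y, mode = "robust")
  loo <- compute_dfarray(Y, mode = "exact_loo")
  expect_gte(cor(rob$summary$dfarray, loo$summary$dfarray, method = "spearman"), 0.9)
  expect_identical(which.max(rob$summary$dfarray), 7L)
  expect_identical(which.max(loo$summary$dfarray), 7L)
  # symmetric-noise agreement of the per-sample summaries
  expect_lt(max(abs(rob$summary$dfarray / loo$summary$dfarray - 1)), 0.15)
})

test_that("dfArray zero-spread guard yields 0 for constant features and excludes otherwise", {
  m <- rbind(
    const = rep(5, 5),
    spread = c(1, 2, 3, 4, 5),
    dead = c(0, 0, 0, 0, 3)
  )
  colnames(m) <- paste0("s", 1:5)
  Y <- expr_matrix(m)
  rob <- compute_dfarray(Y, mode = "robust")
  expect_equal(unname(rob$grid["const", ]), rep(0, 5))
  expect_equal(unname(rob$grid["dead", 1:4]), rep(0, 4)) # numerator 0 too
  expect_true(is.na(rob$grid["dead", 5])) # 3 vs zero MAD -> excluded
  expect_equal(rob$summary$n_excluded, c(0, 0, 0, 0, 1))

  loo <- compute_dfarray(Y, mode = "exact_loo")
  expect_true(is.na(loo$grid["dead", 5])) # mean 0, sd 0 after exclusion
  expect_error(compute_dfarray(Y[, 1:2]), "at least 3")
})

test_that("RLE is zero for identical columns and localizes a shifted column", {
  base <- sort(rnorm(50))
  m <- matrix(rep(base, 4), 50, 4, dimnames = list(sprintf("f%02d", 1:50), paste0("s", 1:4)))
  expect_true(all(compute_rle(expr_matrix(m))$grid == 0))

  m[, 2] <- m[, 2] + 1
  rle <- compute_rle(expr_matrix(m))
  expect_equal(rle$summary$rle_median, c(0, 1, 0, 0))
  # row medians of the grid are 0 by construction
  expect_lt(max(abs(apply(rle$grid, 1, median))), 1e-12)

  # permutation equivariance
  perm <- c(3, 1, 4, 2)
  rle_p <- compute_rle(expr_matrix(m[, perm]))
  expect_equal(rle_p$summary$rle_median, rle$summary$rle_median[perm])
})

test_that("NUSE scales standard errors by the feature median and is scale-free", {
  p <- 30
  se_common <- runif(p, 0.1, 1)
  m <- matrix(rep(se_common, 4), p, 4,
    dimnames = list(sprintf("f%02d", 1:p), paste0("s", 1:4))
  )
  nuse <- compute_nuse(se_matrix(m))
  expect_true(all(abs(nuse$grid - 1) < 1e-12))
  expect_equal(nuse$summary$nuse_median, rep(1, 4))

  # one array at 1.5x everyone else's SE
  m2 <- m
  m2[, 3] <- 1.5 * m2[, 3]
  nuse2 <- compute_nuse(se_matrix(m2))
  expect_equal(nuse2$summary$nuse_median[3], 1.5)

  # global rescaling leaves the metric unchanged
  nuse3 <- compute_nuse(se_matrix(m2 * 7))
  expect_equal(nuse3$summary$nuse_median, nuse2$summary$nuse_median)

  # zero-median features are dropped and counted; all-zero SE is an error
  m4 <- rbind(m2, dead = 0)
  nuse4 <- compute_nuse(se_matrix(m4))
  expect_equal(nuse4$n_dropped, 1L)
  expect_error(compute_nuse(se_matrix(matrix(0, 3, 3))), "all zeros")
})

test_that("lumi outlier distances match the brute-force oracle and flag a noisy array", {
  set.seed(17)
  p <- 100
  n <- 8
  profile <- rnorm(p, 8, 2)
  m <- profile + matrix(rnorm(p * n, 0, 0.3), p, n)
  m[, 5] <- profile + rnorm(p, 0, 3) # 10x noise scale
  dimnames(m) <- list(sprintf("f%03d", 1:p), sprintf("s%02d", 1:n))
  Y <- expr_matrix(m)

  for (diss in c("euclidean", "one_minus_correlation")) {
    res <- compute_lumi_outlier(Y, dissimilarity = diss, th = 2)
    expect_equal(res$lumi_distance, unname(brute_force_lumi(m, diss)), tolerance = 1e-10)
    expect_identical(which.max(res$lumi_distance), 5L)
    expect_true(res$lumi_flag[5])
    expect_false(any(res$lumi_flag[-5]))
  }
})

test_that("lumi flags are invariant to feature duplication and sample permutation", {
  set.seed(23)
  p <- 60
  n <- 6
  m <- matrix(rnorm(p * n, 8), p, n,
    dimnames = list(sprintf("f%03d", 1:p), paste0("s", 1:n))
  )
  m[, 2] <- m[, 2] + rnorm(p, 0, 4)
  Y <- expr_matrix(m)
  res <- compute_lumi_outlier(Y)

  dup <- expr_matrix(rbind(m, m), feature_ids = sprintf("g%03d", 1:(2 * p)))
  res_dup <- compute_lumi_outlier(dup)
  expect_equal(res_dup$lumi_distance, sqrt(2) * res$lumi_distance, tolerance = 1e-9)
  expect_identical(res_dup$lumi_flag, res$lumi_flag)

  perm <- sample(n)
  res_perm <- compute_lumi_outlier(Y[, perm])
  expect_equal(res_perm$lumi_distance, res$lumi_distance[perm], tolerance = 1e-12)

  # degenerate input: no feature spread
  flat <- expr_matrix(matrix(rep(c(1, 2, 3), 3), 3, 3,
    dimnames = list(paste0("f", 1:3), paste0("s", 1:3))
  ))
  expect_error(compute_lumi_outlier(flat), "positive spread")
})

test_that("quadrant classification follows the IQR/skew cutoffs", {
  sym <- seq(-3, 3, length.out = 101) # symmetric: skew exactly 0.5
  lowskew <- c(rep(0, 70), seq(5, 35, length.out = 31)) # Q1 = Q2 = 0, Q3 > 2 -> skew 0
  flat <- rep(1, 101)
  m <- cbind(sym = sym, lowskew = lowskew, flat = flat)
  rownames(m) <- sprintf("f%03d", seq_len(nrow(m)))
  expect_warning(q <- classify_quadrants(expr_matrix(m)), "zero IQR")
  expect_equal(q$skew[1], 0.5)
  expect_equal(q$iqr[1], 3)
  expect_identical(q$quadrant[1], "R1")
  # hand computation under the type-7 rule for the dead-probe-floor column
  qs <- unname(quantile(lowskew, c(.25, .5, .75), type = 7))
  expect_equal(q$iqr[2], qs[3] - qs[1])
  expect_equal(q$skew[2], 0)
  expect_identical(q$quadrant[2], "R2")
  # zero-IQR sentinel
  expect_true(is.na(q$skew[3]))
  expect_identical(q$quadrant[3], "R4")
})

test_that("assembled QC table aligns metrics and applies inclusive thresholds", {
  set.seed(41)
  sim <- simulate_ffpe(sim_config(p = 300, n = 8, seed = 41))
  Y <- sim$matrix
  norm <- quantile_normalize(Y)
  qc <- assemble_array_qc(
    stress = compute_stress(norm),
    dfarray = compute_dfarray(norm),
    rle = compute_rle(norm),
    lumi = compute_lumi_outlier(Y),
    quadrants = classify_quadrants(Y),
    n_floored = attr(Y, "n_floored")
  )
  expect_s3_class(qc, "array_qc")
  expect_identical(nrow(qc), 8L)
  expect_identical(
    names(qc),
    c(
      "sample_id", "stress", "dfarray75", "rle_median", "rle_iqr",
      "nuse_median", "lumi_distance", "lumi_flag", "iqr", "skew", "quadrant",
      "n_floored", "flag_stress", "flag_dfarray", "flag_lumi", "flag_nuse"
    )
  )
  expect_true(all(is.na(qc$nuse_median))) # no SE supplied
  expect_false(any(qc$flag_nuse))

  # boundary behavior: thresholds are inclusive (>=)
  ids <- qc$sample_id
  stress_b <- tibble::tibble(sample_id = ids, stress = c(1.49, 1.5, rep(1, 6)))
  df_b <- compute_dfarray(norm)
  df_b$summary$dfarray <- c(1, 1, 2.0, rep(0.5, 5))
  qc_b <- assemble_array_qc(
    stress = stress_b, dfarray = df_b, rle = compute_rle(norm),
    lumi = compute_lumi_outlier(Y), quadrants = classify_quadrants(Y)
  )
  expect_identical(qc_b$flag_stress[1:3], c(FALSE, TRUE, FALSE))
  expect_identical(qc_b$flag_dfarray[1:3], c(FALSE, FALSE, TRUE))

  # misaligned sample ids are rejected
  st <- compute_stress(norm)
  st$sample_id[1] <- "nope"
  expect_error(
    assemble_array_qc(
      stress = st, dfarray = compute_dfarray(norm), rle = compute_rle(norm),
      lumi = compute_lumi_outlier(Y), quadrants = classify_quadrants(Y)
    ),
    "not aligned"
  )
})
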