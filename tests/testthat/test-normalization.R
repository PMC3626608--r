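test_that("quantile normalization reproduces the order-statistic-mean target", {
  Y <- expr_matrix(matrix(c(1, 2, 3, 3, 4, 5), 3, 2,
    dimnames = list(paste0("f", 1:3), c("a", "b"))
  ))
  res <- quantile_normalize(Y)
  # target is the per-rank mean of (1,2,3) and (3,4,5): (2,3,4)
  expect_equal(unclass(res$normalized), cbind(c(2, 3, 4), c(2, 3, 4)),
    ignore_attr = TRUE
  )
  expect_equal(res$shifts, cbind(c(-1, -1, -1), c(1, 1, 1)), ignore_attr = TRUE)
})

test_that("quantile normalization postconditions hold on random data", {
  Y <- rand_expr(500, 8, seed = 3)
  res <- quantile_normalize(Y)
  srt <- apply(unclass(res$normalized), 2, sort)
  expect_lt(max(abs(srt - srt[, 1])), 1e-12) # identical sorted columns
  expect_lt(max(abs(unclass(Y) - (unclass(res$normalized) + res$shifts))), 1e-12)

  # already-identical columns are a fixed point
  Yc <- expr_matrix(matrix(rep(sort(rnorm(50)), 4), 50, 4,
    dimnames = list(sprintf("f%02d", 1:50), paste0("s", 1:4))
  ))
  resc <- quantile_normalize(Yc)
  expect_lt(max(abs(resc$shifts)), 1e-12)

  # idempotence: renormalizing the output shifts nothing
  res2 <- quantile_normalize(res$normalized)
  expect_lt(max(abs(res2$shifts)), 1e-12)
})

test_that("quantile normalization handles ties deterministically and order-invariantly", {
  set.seed(11)
  vals <- sample(rep(rnorm(30), each = 2)) # heavy ties
  Y <- expr_matrix(matrix(c(vals, rnorm(60)), 60, 2,
    dimnames = list(sprintf("f%02d", 1:60), c("a", "b"))
  ))
  r1 <- quantile_normalize(Y)
  # tied cells receive identical normalized values
  tied_groups <- split(seq_along(vals), vals)
  for (g in tied_groups[lengths(tied_groups) > 1]) {
    expect_lt(diff(range(unclass(r1$normalized)[g, 1])), 1e-12)
  }
  # permuting samples permutes the result identically
  perm <- c(2, 1)
  r2 <- quantile_normalize(Y[, perm])
  expect_equal(unclass(r2$normalized), unclass(r1$normalized)[, perm], ignore_attr = TRUE)
})

test_that("quantile normalization matches limma on tie-free data", {
  skip_if_not_installed("limma")
  Y <- rand_expr(200, 6, seed = 5)
  ours <- unclass(quantile_normalize(Y)$normalized)
  theirs <- limma::normalizeQuantiles(unclass(Y))
  expect_equal(ours, theirs, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("adding a constant to one column changes that column's shifts uniformly", {
  Y <- rand_expr(300, 5, seed = 9)
  Y2 <- unclass(Y)
  Y2[, 3] <- Y2[, 3] + 2.5
  r1 <- quantile_normalize(Y)
  r2 <- quantile_normalize(expr_matrix(Y2))
  delta <- r2$shifts[, 3] - r1$shifts[, 3]
  # tie-free, so ranks are unchanged: the change is a constant across cells
  # (the constant itself is c minus its c/n leak into the shared target)
  expect_lt(diff(range(delta)), 1e-9)
  expect_equal(mean(delta), 2.5 - 2.5 / 5, tolerance = 1e-9)
})

test_that("feature-target normalization is a no-op on target-identical arrays", {
  p <- 200
  target <- sort(rnorm(p, 8, 2))
  Y <- expr_matrix(matrix(rep(target, 4), p, 4,
    dimnames = list(sprintf("f%03d", 1:p), paste0("s", 1:4))
  ))
  res <- feature_target_normalize(Y)
  expect_lt(max(abs(res$shifts)), 1e-12)
  expect_identical(res$method, "feature_target")
})

test_that("feature-target normalization removes a constant per-array offset", {
  set.seed(21)
  p <- 400
  target <- rnorm(p, 8, 2)
  Y <- expr_matrix(
    cbind(a = target, b = target, c = target + 1.5, d = target - 0.5),
    feature_ids = sprintf("f%03d", 1:p)
  )
  res <- feature_target_normalize(Y)
  expect_lt(max(abs(unclass(res$normalized)[, "c"] - target)), 1e-6)
  expect_lt(max(abs(res$shifts[, "c"] - 1.5)), 1e-6)
  # reconstruction
  expect_lt(max(abs(unclass(Y) - (unclass(res$normalized) + res$shifts))), 1e-12)
})

test_that("feature-target normalization drives RLE medians to zero on monotone distortions", {
  Y <- generate_monotone_distortion_set(p = 500, n = 6, seed = 4)
  res <- feature_target_normalize(Y)
  rle <- compute_rle(res)
  expect_lt(max(abs(rle$summary$rle_median)), 0.05)
})

test_that("span validation rejects unusable windows", {
  Y <- rand_expr(100, 4)
  expect_error(feature_target_normalize(Y, span = 0))
  expect_error(feature_target_normalize(Y, span = 1.5))
  expect_error(feature_target_normalize(Y[, 1:2]), "at least 3 arrays")
})
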