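#' Simulation configuration for FFPE-like expression data
#'
#' Describes a synthetic experiment whose arrays follow the additive
#' log2 model: a per-feature true abundance, a small per-array offset, and
#' mean-zero noise with feature-specific standard deviation. Feature
#' abundances are a two-component mixture — a fraction `frac_expressed` of
#' features around `baseline_mean`, the remainder pinned at
#' `background_level` (the "dead probe" floor). Defaults are chosen so a
#' clean run lands in quadrant R1 (IQR above 2, skew above 0.2) and mimic an
#' archival-tissue cohort where roughly 15% of arrays show degraded
#' distributions.
#'
#' @param p Feature count (>= 10).
#' @param n Sample count (>= 4).
#' @param seed Integer seed; every generator call is deterministic given the
#'   config.
#' @param frac_expressed Fraction of features in the expressed component.
#' @param baseline_mean,baseline_sd Mean/sd of expressed-feature abundances
#'   (log2 units).
#' @param background_level Floor abundance of unexpressed features (log2).
#' @param noise_sd Typical measurement noise sd; the per-feature sd is
#'   `noise_sd * exp(N(0, 0.25))`, giving feature-specific variances.
#' @param offset_sd Sd of the per-array constant offset (log2).
#' @param outlier_specs List of [outlier_spec()] entries describing injected
#'   degradation.
#' @return A `sim_config` list.
#' @export
sim_config <- function(p = 5000, n = 96, seed = 1, frac_expressed = 0.7,
                       baseline_mean = 10, baseline_sd = 2.5,
                       background_level = 5, noise_sd = 0.3,
                       offset_sd = 0.05, outlier_specs = list()) {
  stopifnot(
    p >= 10, n >= 4, frac_expressed >= 0, frac_expressed <= 1,
    noise_sd > 0, offset_sd >= 0, baseline_sd > 0
  )
  n_out <- sum(vapply(outlier_specs, `[[`, numeric(1), "n_arrays"))
  if (n_out >= n) stop("more outlier arrays than samples", call. = FALSE)
  structure(
    list(
      p = as.integer(p), n = as.integer(n), seed = as.integer(seed),
      frac_expressed = frac_expressed, baseline_mean = baseline_mean,
      baseline_sd = baseline_sd, background_level = background_level,
      noise_sd = noise_sd, offset_sd = offset_sd,
      outlier_specs = outlier_specs
    ),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @param kind One of `"dead_collapse"` (a fraction of expressed features
#'   collapses to background — the failed-hybridization mode),
#'   `"range_compression"` (the whole distribution contracts about its
#'   median), `"skewed_degradation"` (the lower half of the distribution is
#'   squeezed toward background, driving the skew statistic down),
#'   `"profile_discordant"` (a fraction of features swap true abundances:
#'   marginal distribution preserved, feature profile broken — invisible to
#'   marginal metrics, visible to dfArray), or `"constant_shift"` (a uniform
#'   additive offset; a brightness artifact that no quality metric should
#'   flag).
#' @param n_arrays How many arrays receive this degradation.
#' @param severity Fraction in (0, 1] controlling the strength of the effect.
#' @export
outlier_spec <- function(kind = c(
                           "dead_collapse", "range_compression",
                           "skewed_degradation", "profile_discordant",
                           "constant_shift"
                         ),
                         n_arrays = 1, severity = 0.5) {
  kind <- match.arg(kind)
  stopifnot(n_arrays >= 1, severity > 0, severity <= 1)
  list(kind = kind, n_arrays = as.integer(n_arrays), severity = severity)
}

#' Generate a synthetic FFPE-like expression matrix with ground truth
#'
#' Draws true feature abundances from the two-component mixture in the
#' config, builds each array as abundance + array offset + feature-specific
#' noise, then applies the configured degradation operators to randomly
#' chosen arrays. Deterministic under the config seed: the same config yields
#' bitwise-identical output.
#'
#' @param config A [sim_config()].
#' @return A list with elements `matrix` (an [expr_matrix()]) and `truth`
#'   (a tibble: `sample_id`, `label` — `"good"` or the degradation kind —
#'   and `severity`), plus `mu` (the true abundance vector).
#' @export
simulate_ffpe <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- config$p
  n <- config$n

  n_expr <- round(config$frac_expressed * p)
  expressed <- sample.int(p) <= n_expr
  mu <- rep(config$background_level, p)
  mu[expressed] <- stats::rnorm(n_expr, config$baseline_mean, config$baseline_sd)
  sigma <- config$noise_sd * exp(stats::rnorm(p, 0, 0.25))

  offsets <- stats::rnorm(n, 0, config$offset_sd)
  # sigma recycles down rows: noise sd is feature-specific
  Y <- mu + matrix(stats::rnorm(p * n, 0, sigma), p, n)
  Y <- sweep(Y, 2, offsets, `+`)

  label <- rep("good", n)
  severity <- rep(NA_real_, n)
  n_out <- sum(vapply(config$outlier_specs, `[[`, integer(1), "n_arrays"))
  out_idx <- if (n_out > 0) sample.int(n, n_out) else integer(0)
  pos <- 1L
  for (spec in config$outlier_specs) {
    for (k in seq_len(spec$n_arrays)) {
      j <- out_idx[pos]
      pos <- pos + 1L
      label[j] <- spec$kind
      severity[j] <- spec$severity
      Y[, j] <- degrade_column(
        Y[, j], spec$kind, spec$severity,
        mu = mu, sigma = sigma, expressed = expressed,
        background = config$background_level, offset = offsets[j]
      )
    }
  }

  sample_ids <- sprintf("S%03d", seq_len(n))
  feature_ids <- sprintf("F%05d", seq_len(p))
  mat <- expr_matrix(Y, feature_ids = feature_ids, sample_ids = sample_ids)
  truth <- tibble::tibble(
    sample_id = sample_ids, label = label, severity = severity
  )
  list(matrix = mat, truth = truth, mu = mu)
}

degrade_column <- function(y, kind, severity, mu, sigma, expressed, background,
                           offset) {
  p <- length(y)
  switch(kind,
    dead_collapse = {
      expr_idx <- which(expressed)
      kill <- sample(expr_idx, round(severity * length(expr_idx)))
      y[kill] <- background + offset + stats::rnorm(length(kill), 0, sigma[kill])
      y
    },
    range_compression = {
      med <- stats::median(y)
      med + (1 - severity) * (y - med)
    },
    skewed_degradation = {
      med <- stats::median(y)
      low <- y < med
      floor_ <- background + offset
      y[low] <- floor_ + (1 - severity) * (y[low] - floor_)
      y
    },
    profile_discordant = {
      swap <- sample.int(p, round(severity * p))
      mu_perm <- mu[swap][sample.int(length(swap))]
      y[swap] <- mu_perm + offset + stats::rnorm(length(swap), 0, sigma[swap])
      y
    },
    constant_shift = y + 2 * severity,
    stop("unknown degradation kind: ", kind, call. = FALSE)
  )
}

#' Noiseless monotone distortions of one target profile
#'
#' Fixture generator for feature-specific normalization: one latent target
#' vector, each column a strictly increasing smooth (cubic) function of it,
#' with no noise. Every column is rank-identical to the target, and a
#' feature-target normalization should push every array's median RLE to
#' essentially zero.
#'
#' The distortion for array j is `g_j(t) = a_j + b_j * t + c_j * (t - m)^3`
#' with `b_j > 0` and `c_j >= 0`, which is strictly increasing everywhere.
#'
#' @param p Feature count (>= 100).
#' @param n Sample count (>= 3).
#' @param seed Integer seed.
#' @return An [expr_matrix()].
#' @export
generate_monotone_distortion_set <- function(p = 1000, n = 10, seed = 1) {
  stopifnot(p >= 100, n >= 3)
  set.seed(seed)
  target <- stats::rnorm(p, 8, 2)
  m <- mean(target)
  Y <- vapply(seq_len(n), function(j) {
    a <- stats::runif(1, -1, 1)
    b <- stats::runif(1, 0.7, 1.3)
    cc <- stats::runif(1, 0, 0.02)
    a + b * target + cc * (target - m)^3
  }, numeric(p))
  expr_matrix(Y,
    feature_ids = sprintf("F%05d", seq_len(p)),
    sample_ids = sprintf("S%03d", seq_len(n))
  )
}
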