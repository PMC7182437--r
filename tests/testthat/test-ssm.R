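# small synthetic shape populations (rows = samples, columns = 3P)
linear_family <- function(M = 10, P = 20, seed = 5) {
  set.seed(seed)
  base <- rnorm(3 * P)
  dir <- rnorm(3 * P)
  t(vapply(seq_len(M), function(i) base + (i - (M + 1) / 2) * dir,
           numeric(3 * P)))
}

test_that("identical shapes give a zero-mode model without failure", {
  S <- matrix(rep(rnorm(30), each = 5), nrow = 5)
  m <- fit_ssm(S)
  expect_length(m$sd, 0)
  expect_equal(m$mean, S[1, ])
})

test_that("a one-parameter linear family yields exactly one mode matching the dense oracle", {
  S <- linear_family()
  m <- fit_ssm(S)
  big <- m$sd > 1e-8 * m$sd[1]
  expect_equal(sum(big), 1)
  # dense-covariance eigendecomposition oracle
  eg <- eigen(cov(S), symmetric = TRUE)
  expect_equal(m$sd[1]^2, eg$values[1], tolerance = 1e-8)
  expect_gt(abs(sum(m$modes[, 1] * eg$vectors[, 1])), 1 - 1e-8)
})

test_that("Gram-trick PCA equals the dense eigendecomposition on random data", {
  set.seed(6)
  S <- matrix(rnorm(10 * 60), 10, 60)
  m <- fit_ssm(S)
  eg <- eigen(cov(S), symmetric = TRUE)
  k <- length(m$sd)
  expect_equal(k, 9)  # at most M - 1 nonzero modes
  expect_equal(m$sd^2, eg$values[1:k], tolerance = 1e-8)
  dots <- abs(colSums(m$modes * eg$vectors[, 1:k]))
  expect_true(all(dots > 1 - 1e-8))
  expect_lt(max(abs(crossprod(m$modes) - diag(k))), 1e-8)
  expect_equal(sum(m$ev), 1, tolerance = 1e-10)
})

test_that("explained variance follows the squared-sd formula", {
  expect_equal(explained_variance(1), 1)
  expect_equal(explained_variance(c(2, 1, 1)), c(2 / 3, 1 / 6, 1 / 6))
  set.seed(7)
  s <- abs(rnorm(8))
  expect_equal(explained_variance(s), s^2 / sum(s^2), tolerance = 1e-12)
  expect_error(explained_variance(c(1, -1)), "nonnegative")
  expect_error(explained_variance(c(0, 0)), "zero")
})

test_that("mode retention count honours the cumulative threshold", {
  ev <- c(0.6, 0.3, 0.1)
  expect_equal(n_modes_for(ev, 0.95), 3)
  expect_equal(n_modes_for(ev, 0.90), 2)
  expect_equal(n_modes_for(ev, 1), 3)
  expect_equal(n_modes_for(ev, 0.5), 1)
  expect_error(n_modes_for(ev, 0), "threshold")
})

test_that("morphing and projection are exact inverses on the retained modes", {
  set.seed(8)
  S <- matrix(rnorm(12 * 30), 12, 30)
  m <- fit_ssm(S)
  expect_equal(morph(m, numeric(0)), m$mean)
  expect_equal(morph(m, rep(0, 3)), m$mean)
  expect_equal(morph(m, c(2, rep(0, length(m$sd) - 1))),
               m$mean + 2 * m$sd[1] * m$modes[, 1])
  expect_equal(project(m, m$mean), rep(0, length(m$sd)))
  expect_equal(project(m, m$mean + 2 * m$sd[1] * m$modes[, 1]),
               c(2, rep(0, length(m$sd) - 1)), tolerance = 1e-8)
  lam <- rnorm(length(m$sd))
  expect_equal(project(m, morph(m, lam)), lam, tolerance = 1e-8)
  # training-weight centring identity: mean projected weight is zero
  W <- t(apply(S, 1, function(s) project(m, s)))
  expect_lt(max(abs(colMeans(W))), 1e-8)
  expect_error(morph(m, rep(0, length(m$sd) + 1)), "more weights")
})

test_that("reconstruction error is zero with all modes and monotone in retention", {
  set.seed(9)
  S <- matrix(rnorm(8 * 45), 8, 45)
  m <- fit_ssm(S)
  K <- length(m$sd)
  full <- reconstruction_errors(m, S, K)
  expect_lt(max(full$per_sample$hausdorff), 1e-6)
  # k = 0 equals the distance to the mean shape
  zero <- reconstruction_errors(m, S, 0)
  expect_equal(zero$per_sample$rms,
               vapply(seq_len(8), function(i) {
                 di <- matrix(S[i, ] - m$mean, ncol = 3, byrow = TRUE)
                 sqrt(mean(rowSums(di^2)))
               }, numeric(1)), tolerance = 1e-12)
  rms <- vapply(0:K, function(k)
    reconstruction_errors(m, S, k)$summary[["rms_mean"]], numeric(1))
  expect_true(all(diff(rms) <= 1e-12))
})

test_that("an SSM archive round-trips through JSON", {
  set.seed(10)
  S <- matrix(rnorm(6 * 30), 6, 30)
  rownames(S) <- paste0("s", 1:6)
  m <- fit_ssm(S)
  f <- withr::local_tempfile(fileext = ".json")
  write_ssm(m, f)
  m2 <- read_ssm(f)
  expect_equal(m2$mean, m$mean)
  expect_equal(m2$modes, m$modes)
  expect_equal(m2$sd, m$sd)
  expect_equal(m2$ev, m$ev)
  expect_identical(m2$ids, m$ids)
})

test_that("latent-parameter recovery: G independent parameters span G modes", {
  # noise-free cohort driven by 4 latent parameters through the generator
  tpl <- cached_template()
  co <- sample_cohort(cohort_spec(12, seed = 21, noise_sd = 0,
                                  fraction_left = 0,
                                  params = list(
    global_scale = c(1, 0), femur_shaft_len = c(30, 0),
    tibia_shaft_len = c(25, 0), femur_shaft_diam = c(28, 0),
    tibia_shaft_diam = c(24, 0), femur_bend_frontal = c(0, 0),
    tibia_bend_frontal = c(0, 0), condyle_ap = c(60, 0),
    condyle_ml = c(76, 0), plateau_ap = c(50, 0), plateau_ml = c(74, 0),
    rel_frontal_rot = c(0, 8), rel_axial_rot = c(0, 4),
    plateau_slope = c(7, 4), femoral_jointline_tilt = c(-6, 0),
    tibial_jointline_tilt = c(0, 4))), tpl)
  # identical topology and no registration: stack vertex coordinates directly
  S <- t(vapply(co, function(s) c(t(s$femur$vertices), t(s$tibia$vertices)),
                numeric(3 * (nrow(tpl$femur$vertices) + nrow(tpl$tibia$vertices)))))
  m <- fit_ssm(S)
  expect_gte(sum(cumsum(m$ev) < 0.99), 0)
  expect_lte(n_modes_for(m$ev, 0.99), 4)
})
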