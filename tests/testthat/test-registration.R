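test_that("rigid alignment recovers a known rotation and translation", {
  tpl <- cached_template()
  s <- apply_params(tpl, generative_params(rel_frontal_rot = 4))
  R10 <- kneessm:::rot_z(10)
  tr <- c(5, 0, 0)
  moved <- s
  tf <- function(m) triangle_mesh(kneessm:::apply_rigid(m$vertices, R10, tr),
                                  m$faces)
  moved$femur <- tf(s$femur)
  moved$tibia <- tf(s$tibia)
  moved$landmarks <- kneessm:::apply_rigid(s$landmarks, R10, tr)
  al <- rigid_align_pair(moved, s)
  expect_lt(max(abs(al$rotation %*% R10 - diag(3))), 1e-6)
  expect_lt(max(abs(as.numeric(al$rotation %*% tr) + al$translation)), 1e-6)
  expect_lt(al$residual, 1e-6)
  expect_equal(det(al$rotation), 1, tolerance = 1e-10)
})

test_that("aligning a sample to itself is the identity", {
  tpl <- cached_template()
  al <- rigid_align_pair(tpl, tpl)
  expect_lt(max(abs(al$rotation - diag(3))), 1e-8)
  expect_lt(max(abs(al$translation)), 1e-8)
  expect_lt(al$residual, 1e-9)
})

test_that("rigid alignment never fits scale and preserves intra-sample geometry", {
  tpl <- cached_template()
  scaled <- tpl
  scaled$femur <- triangle_mesh(tpl$femur$vertices * 1.1, tpl$femur$faces)
  scaled$tibia <- triangle_mesh(tpl$tibia$vertices * 1.1, tpl$tibia$faces)
  scaled$landmarks <- tpl$landmarks * 1.1
  al <- rigid_align_pair(scaled, tpl)
  # a pure rotation cannot absorb the 10% scale: residual stays nonzero
  expect_gt(al$residual, 0.1)
  expect_equal(abs(det(al$rotation)), 1, tolerance = 1e-10)
  # femur-tibia relative pose untouched: all landmark pair distances kept
  d0 <- dist(scaled$landmarks)
  d1 <- dist(al$sample$landmarks)
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("CPD leaves an already-matching source in place", {
  tpl <- cached_template()
  Y <- tpl$femur$vertices
  reg <- cpd_register(Y, Y, cpd_config(max_iter = 60))
  expect_lt(max(abs(reg$points - Y)), 1e-6)
})

test_that("CPD recovers a smooth synthetic bend to below 0.1 mm", {
  tpl <- cached_template()
  Y <- tpl$femur$vertices
  # smooth 5-degree bend over the bone length, not a global rotation
  th <- (5 * pi / 180) * (Y[, 3] - min(Y[, 3])) / diff(range(Y[, 3]))
  X <- Y
  X[, 1] <- Y[, 1] * cos(th) + Y[, 3] * sin(th) * 0.25
  reg <- cpd_register(Y, X, cpd_config())
  resid <- closest_on_surface(reg$points,
                              triangle_mesh(X, tpl$femur$faces))$dist
  expect_lt(mean(resid), 0.1)
})

test_that("the CPD penalised log-likelihood trace is monotone non-decreasing", {
  tpl <- cached_template()
  Y <- tpl$tibia$vertices
  X <- Y %*% t(kneessm:::rot_y(4))
  reg <- cpd_register(Y, X, cpd_config())
  ll <- reg$loglik
  expect_true(all(diff(ll) >= -1e-8 * pmax(abs(ll[-length(ll)]), 1)))
})

test_that("CPD tolerates uniform outliers in the target", {
  tpl <- cached_template()
  Y <- tpl$femur$vertices
  X <- Y %*% t(kneessm:::rot_y(3))
  set.seed(4)
  Xo <- rbind(X, matrix(runif(3 * round(0.1 * nrow(X)), -60, 60), ncol = 3))
  clean <- mean(closest_on_surface(cpd_register(Y, X, cpd_config())$points,
                                   triangle_mesh(X, tpl$femur$faces))$dist)
  noisy <- mean(closest_on_surface(cpd_register(Y, Xo, cpd_config(w = 0.1))$points,
                                   triangle_mesh(X, tpl$femur$faces))$dist)
  expect_lt(noisy, 2 * max(clean, 1e-3))
})

test_that("CPD rejects degenerate inputs", {
  expect_error(cpd_register(matrix(0, 5, 3), matrix(0, 20, 3)), "at least 10")
  expect_error(cpd_config(w = 1), "w must be")
  expect_error(cpd_config(beta = 0), "positive")
})

test_that("correspondences are reference-indexed and exact for the reference itself", {
  tpl <- cached_template()
  out <- correspond(tpl$femur, tpl$femur, cpd_config(max_iter = 60))
  expect_equal(nrow(out), nrow(tpl$femur$vertices))
  expect_lt(max(abs(out - tpl$femur$vertices)), 1e-6)
  expect_false(any(attr(out, "outlier")))
})

test_that("correspondence points land on the sample surface", {
  tpl <- cached_template()
  s <- apply_params(tpl, generative_params(condyle_ml = 80,
                                           femur_bend_frontal = 3))
  out <- correspond(tpl$femur, s$femur, cpd_config())
  d <- closest_on_surface(out, s$femur)$dist
  expect_lt(max(d[!attr(out, "outlier")]), 1e-8)
  expect_equal(nrow(out), nrow(tpl$femur$vertices))
})

test_that("the cohort correspondence set is reference-ordered and deterministic", {
  tpl <- cached_template()
  co <- sample_cohort(cohort_spec(4, seed = 3, noise_sd = 0,
                                  fraction_left = 0), tpl)
  cfg <- cpd_config(max_iter = 60)
  corr <- build_correspondences(co, tpl, cfg)
  P <- corr$p_femur + corr$p_tibia
  expect_equal(dim(corr$shapes), c(4L, 3L * P))
  expect_identical(rownames(corr$shapes), vapply(co, `[[`, "", "id"))
  # permuting the cohort permutes rows only
  corr2 <- build_correspondences(co[c(3, 1, 4, 2)], tpl, cfg)
  expect_equal(corr2$shapes[rownames(corr$shapes), ], corr$shapes,
               tolerance = 1e-12)
  # cohort = [reference] gives the reference's own vertices
  corr3 <- build_correspondences(list(tpl), tpl, cfg)
  ref_vec <- c(t(tpl$femur$vertices), t(tpl$tibia$vertices))
  expect_lt(max(abs(corr3$shapes[1, ] - ref_vec)), 1e-6)
})
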