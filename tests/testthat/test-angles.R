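test_that("a fully neutral landmark set yields all-zero angles", {
  ang <- compute_angles(neutral_landmarks())
  expect_equal(unname(ang), rep(0, 5), tolerance = 1e-10)
})

test_that("beta + gamma = alpha whenever the joint lines are parallel", {
  set.seed(14)
  for (i in 1:10) {
    lm <- neutral_landmarks()
    tilt <- runif(1, -10, 10)           # shared world-frame joint-line tilt
    femrot <- runif(1, -12, 12)         # frontal rotation of the femoral axis
    Rt <- kneessm:::rot_y(-tilt)
    for (nm in c("med_distal_condyle", "lat_distal_condyle",
                 "med_plateau", "lat_plateau"))
      lm[nm, ] <- as.numeric(Rt %*% lm[nm, ])
    # rotate only the femoral mechanical axis: the joint lines stay parallel
    Rf <- kneessm:::rot_y(femrot)
    for (nm in c("hip_center", "knee_center_femur"))
      lm[nm, ] <- as.numeric(Rf %*% lm[nm, ])
    ang <- compute_angles(lm)
    expect_equal(ang[["FVV"]] + ang[["TVV"]], ang[["HKA"]],
                 tolerance = 1e-9)
  }
})

test_that("rotating the tibial landmarks in the frontal plane shifts HKA accordingly", {
  lm <- neutral_landmarks()
  base <- compute_angles(lm)
  R <- kneessm:::rot_y(5)
  tib <- c("knee_center_tibia", "med_plateau", "lat_plateau",
           "ant_plateau", "post_plateau", "ankle_center")
  lm[tib, ] <- lm[tib, ] %*% t(R)
  ang <- compute_angles(lm)
  expect_equal(abs(ang[["HKA"]] - base[["HKA"]]), 5, tolerance = 1e-9)
})

test_that("angles are invariant under global rigid motion of all landmarks", {
  tpl <- cached_template()
  p <- generative_params(rel_frontal_rot = 7, rel_axial_rot = 4,
                         plateau_slope = 10, tibial_jointline_tilt = 3)
  lm <- apply_params(tpl, p)$landmarks
  base <- compute_angles(lm)
  set.seed(8)
  for (i in 1:10) {
    R <- random_rotation()
    tr <- rnorm(3, 0, 50)
    lm2 <- sweep(lm %*% t(R), 2, tr, "+")
    expect_equal(compute_angles(lm2), base, tolerance = 1e-9)
  }
})

test_that("degenerate landmark pairs are rejected by name", {
  lm <- neutral_landmarks()
  lm["lat_plateau", ] <- lm["med_plateau", ]
  expect_error(compute_angles(lm), "plateau ML")
  lm <- neutral_landmarks()[-1, ]
  expect_error(compute_angles(lm), "hip_center")
})

test_that("stability labels honour the printed thresholds with closed boundaries", {
  mk <- function(...) {
    a <- c(HKA = 0, FVV = -6, IER = 0, TVV = 0, TS = 7)
    a[names(c(...))] <- c(...)
    a
  }
  expect_false(label_stability(mk(HKA = 2))[["HKA"]])
  expect_true(label_stability(mk(HKA = 4))[["HKA"]])
  expect_false(label_stability(mk(HKA = 3))[["HKA"]])   # boundary is stable
  expect_false(label_stability(mk(FVV = -6))[["FVV"]])
  expect_true(label_stability(mk(FVV = -1))[["FVV"]])
  expect_false(label_stability(mk(TS = 11))[["TS"]])    # boundary
  expect_true(label_stability(mk(TS = 11.5))[["TS"]])
  expect_true(label_stability(mk(IER = -5.01))[["IER"]])
  expect_false(label_stability(mk(TVV = 5))[["TVV"]])
  expect_error(label_stability(c(HKA = 1)), "missing angle")
})

test_that("corrected deviation is the absolute distance from the centre", {
  expect_equal(corrected_deviation(10, 7), 3)
  expect_equal(corrected_deviation(4, 7), 3)
  expect_equal(corrected_deviation(7, 7), 0)
  expect_equal(corrected_deviation(c(-9, -3), -6), c(3, 3))
})

test_that("computed angles equal the generative angles across a noise-free cohort", {
  tpl <- cached_template()
  co <- sample_cohort(cohort_spec(8, seed = 12, noise_sd = 0), tpl)
  tab <- angle_table(co)
  for (i in seq_along(co)) {
    truth <- co[[i]]$angles
    for (v in names(truth))
      expect_equal(tab[[v]][i], truth[[v]], tolerance = 1e-6)
  }
})
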