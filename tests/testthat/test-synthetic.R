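test_that("the neutral template sits at the physiological centres", {
  tpl <- cached_template()
  ang <- compute_angles(tpl$landmarks)
  expect_equal(ang[["HKA"]], 0, tolerance = 1e-8)
  expect_equal(ang[["TS"]], 7, tolerance = 1e-8)
  expect_equal(ang[["FVV"]], -6, tolerance = 1e-8)
  expect_equal(ang[["TVV"]], 0, tolerance = 1e-8)
  expect_equal(ang[["IER"]], 0, tolerance = 1e-8)
  # hip, knee centres and ankle proxies are collinear on the z axis
  expect_lt(max(abs(tpl$landmarks[c("hip_center", "knee_center_femur",
                                    "knee_center_tibia", "ankle_center"),
                                  1:2])), 1e-9)
  # meshes are watertight and positively oriented
  expect_gt(mesh_volume(tpl$femur), 0)
  expect_gt(mesh_volume(tpl$tibia), 0)
})

test_that("identity parameters reproduce the template exactly", {
  tpl <- cached_template()
  s <- apply_params(tpl, generative_params())
  expect_equal(s$femur$vertices, tpl$femur$vertices, tolerance = 1e-9)
  expect_equal(s$tibia$vertices, tpl$tibia$vertices, tolerance = 1e-9)
  expect_equal(s$landmarks, tpl$landmarks, tolerance = 1e-9)
})

test_that("single-angle deformities close exactly through compute_angles", {
  tpl <- cached_template()
  s <- apply_params(tpl, generative_params(rel_frontal_rot = 5))
  expect_equal(compute_angles(s$landmarks)[["HKA"]], 5, tolerance = 1e-6)
  s <- apply_params(tpl, generative_params(rel_axial_rot = 8))
  expect_equal(compute_angles(s$landmarks)[["IER"]], 8, tolerance = 1e-6)
})

test_that("combined deformities round-trip all five generative angles", {
  tpl <- cached_template()
  set.seed(33)
  for (i in 1:5) {
    p <- generative_params(
      rel_frontal_rot = runif(1, -15, 15),
      rel_axial_rot = runif(1, -10, 10),
      plateau_slope = runif(1, 0, 14),
      femoral_jointline_tilt = runif(1, -11, -1),
      tibial_jointline_tilt = runif(1, -8, 8),
      femur_bend_frontal = runif(1, -5, 5),
      tibia_bend_frontal = runif(1, -4, 4),
      global_scale = runif(1, 0.85, 1.15),
      femur_shaft_len = runif(1, 21, 39),
      tibia_shaft_len = runif(1, 21, 29),
      condyle_ml = runif(1, 68, 84),
      plateau_ap = runif(1, 44, 56))
    s <- apply_params(tpl, p)
    ang <- compute_angles(s$landmarks)
    expect_equal(ang[["HKA"]], p$rel_frontal_rot, tolerance = 1e-6)
    expect_equal(ang[["FVV"]], p$femoral_jointline_tilt, tolerance = 1e-6)
    expect_equal(ang[["TVV"]], p$tibial_jointline_tilt, tolerance = 1e-6)
    expect_equal(ang[["IER"]], p$rel_axial_rot, tolerance = 1e-6)
    expect_equal(ang[["TS"]], p$plateau_slope, tolerance = 1e-6)
    expect_equal(unname(s$angles), unname(ang), tolerance = 1e-9)
  }
})

test_that("a left sample is the exact mirror of its right twin", {
  tpl <- cached_template()
  pr <- generative_params(rel_frontal_rot = 6, rel_axial_rot = -3,
                          side = "right")
  pl <- pr; pl$side <- "left"
  class(pl) <- "generative_params"
  sr <- apply_params(tpl, pr)
  sl <- apply_params(tpl, pl)
  expect_lt(max(abs(mirror_ml(sl$femur)$vertices - sr$femur$vertices)), 1e-9)
  expect_lt(max(abs(mirror_ml(sl$tibia)$vertices - sr$tibia$vertices)), 1e-9)
})

test_that("parameter validation rejects invalid values", {
  expect_error(generative_params(noise_sd = -1), "noise_sd")
  expect_error(generative_params(global_scale = 0), "positive")
  expect_error(generative_params(femur_shaft_len = 50), "crop range")
  expect_error(generative_params(tibia_shaft_len = 19), "crop range")
  expect_error(generative_params(rel_frontal_rot = NaN), "finite")
  expect_error(generative_params(side = "up"), "side")
})

test_that("cohort sampling is seeded, sized and validated", {
  spec <- cohort_spec(10, seed = 4, noise_sd = 0)
  tpl <- cached_template()
  co1 <- sample_cohort(spec, tpl)
  co2 <- sample_cohort(spec, tpl)
  expect_length(co1, 10)
  expect_identical(lapply(co1, function(s) s$femur$vertices),
                   lapply(co2, function(s) s$femur$vertices))
  expect_identical(vapply(co1, `[[`, "", "id"),
                   sprintf("knee_%03d", 1:10))
  expect_error(cohort_spec(2), "at least 3")
  expect_error(cohort_spec(5, fraction_left = 1.2), "fraction_left")
  expect_error(cohort_spec(5, params = list(bogus = c(0, 1))), "unknown")
  expect_error(cohort_spec(5, params = list(rel_frontal_rot = c(0, -1))),
               "nonnegative")
})

test_that("unstable-by-HKA fraction matches the truncated-normal tail mass", {
  # alpha* ~ N(0, 6) truncated at +/-15; analytic tail mass outside +/-3
  s <- 6; lo <- -15; hi <- 15; thr <- 3
  Z <- pnorm(hi / s) - pnorm(lo / s)
  tail_mass <- 1 - (pnorm(thr / s) - pnorm(-thr / s)) / Z
  tpl <- cached_template()
  co <- sample_cohort(cohort_spec(200, seed = 99, noise_sd = 0,
                                  params = list(rel_frontal_rot = c(0, 6, -15, 15))),
                      tpl)
  hka <- vapply(co, function(x) x$angles[["HKA"]], numeric(1))
  frac <- mean(abs(hka) > thr)
  expect_lt(abs(frac - tail_mass), 0.07)
})

test_that("cohort statistics converge to the specified distributions", {
  tpl <- cached_template()
  co <- sample_cohort(cohort_spec(500, seed = 5, noise_sd = 0), tpl)
  spec <- cohort_spec(500, seed = 5, noise_sd = 0)
  for (nm in c("rel_frontal_rot", "plateau_slope", "global_scale")) {
    v <- spec$dists[[nm]]
    draws <- vapply(co, function(s) s$params[[nm]], numeric(1))
    # truncation at +/-3 SD barely changes mean/SD; allow 3 standard errors
    expect_lt(abs(mean(draws) - v[1]), 3 * v[2] / sqrt(500) + 0.02 * v[2])
    expect_lt(abs(sd(draws) - v[2]), 0.15 * v[2])
  }
})

test_that("cohort directories round-trip through write_cohort/read_cohort", {
  tpl <- cached_template()
  co <- sample_cohort(cohort_spec(3, seed = 2, noise_sd = 0), tpl)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_length(list.files(dir, pattern = "\\.ply$"), 6)
  expect_true(all(file.exists(file.path(dir, c("cohort.csv", "landmarks.csv")))))
  back <- read_cohort(dir)
  expect_equal(back[[2]]$femur$vertices, co[[2]]$femur$vertices,
               tolerance = 1e-5)
  expect_equal(back[[2]]$landmarks, co[[2]]$landmarks, tolerance = 1e-9)
  expect_equal(back[[2]]$angles, co[[2]]$angles, tolerance = 1e-9)
  expect_identical(back[[3]]$side, co[[3]]$side)
})
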