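#' @name alignment-angles
#' @title Clinical knee-alignment angles
#'
#' @description
#' The five angular variables describing tibio-femoral alignment:
#'
#' * `HKA` (hip-knee-ankle, alpha): frontal-plane angle between the femoral
#'   mechanical axis (hip centre to femoral knee centre) and the tibial
#'   mechanical axis (tibial knee centre to ankle centre); varus positive.
#' * `FVV` (femoral varus-valgus, beta): frontal-plane angle of the femoral
#'   mechanical axis to the normal of the femoral joint line (medial to
#'   lateral distal condyle); valgus negative.
#' * `TVV` (tibial varus-valgus, gamma): the analogous tibial angle using
#'   the medial-lateral plateau line. With parallel joint lines
#'   beta + gamma = alpha.
#' * `IER` (internal-external rotation, theta): axial-plane angle between
#'   the femoral epicondylar axis and the tibial medial-lateral plateau
#'   axis; external positive.
#' * `TS` (tibial slope, omega): sagittal-plane angle of the
#'   anterior-posterior plateau line to the normal of the tibial mechanical
#'   axis; posterior slope positive.
#'
#' All angles are computed in a canonical anatomical frame re-derived from
#' the landmarks themselves (z along the tibial mechanical axis, x along
#' the tibial plateau medial-lateral line orthogonalised against z), which
#' makes the measurements invariant to any global rigid motion of the
#' landmark set.
NULL

#' Required landmark names
#'
#' @return character vector of the landmark names a complete landmark set
#'   must contain.
#' @export
landmark_names <- function() {
  c("hip_center", "knee_center_femur", "knee_center_tibia",
    "med_distal_condyle", "lat_distal_condyle",
    "med_epicondyle", "lat_epicondyle",
    "med_plateau", "lat_plateau", "ant_plateau", "post_plateau",
    "ankle_center")
}

check_landmarks <- function(lm) {
  lm <- as.matrix(lm)
  if (ncol(lm) != 3) stop("landmarks must be an n x 3 matrix")
  missing <- setdiff(landmark_names(), rownames(lm))
  if (length(missing) > 0)
    stop("missing landmarks: ", paste(missing, collapse = ", "))
  if (!all(is.finite(lm))) stop("landmark coordinates must be finite")
  lm
}

# signed plane angles in degrees
deg_atan2 <- function(y, x) atan2(y, x) * 180 / pi

#' Compute the five clinical alignment angles from landmarks
#'
#' @param lm named landmark matrix (rows named as in [landmark_names()],
#'   columns x/y/z in mm), in the right-side convention (left-side samples
#'   must be mirrored first).
#' @return named numeric vector with elements `HKA`, `FVV`, `TVV`, `IER`,
#'   `TS` in signed degrees. See [alignment-angles] for definitions and
#'   sign conventions.
#' @export
compute_angles <- function(lm) {
  lm <- check_landmarks(lm)
  p <- function(name) lm[name, ]

  dup <- function(a, b, what) {
    if (sqrt(sum((a - b)^2)) < 1e-9)
      stop("degenerate landmark pair: ", what)
  }
  dup(p("hip_center"), p("knee_center_femur"), "hip_center/knee_center_femur")
  dup(p("knee_center_tibia"), p("ankle_center"), "knee_center_tibia/ankle_center")
  dup(p("med_distal_condyle"), p("lat_distal_condyle"), "distal condyles")
  dup(p("med_epicondyle"), p("lat_epicondyle"), "epicondyles")
  dup(p("med_plateau"), p("lat_plateau"), "plateau ML")
  dup(p("ant_plateau"), p("post_plateau"), "plateau AP")

  # canonical anatomical frame from the landmarks: z up the tibial
  # mechanical axis, x medio-lateral from the tibial plateau line
  ez <- p("knee_center_tibia") - p("ankle_center")
  ez <- ez / sqrt(sum(ez^2))
  ml <- p("lat_plateau") - p("med_plateau")
  ey <- c(ez[2] * ml[3] - ez[3] * ml[2],
          ez[3] * ml[1] - ez[1] * ml[3],
          ez[1] * ml[2] - ez[2] * ml[1])
  ney <- sqrt(sum(ey^2))
  if (ney < 1e-9) stop("degenerate landmark pair: plateau ML parallel to tibial axis")
  ey <- ey / ney
  ex <- c(ey[2] * ez[3] - ey[3] * ez[2],
          ey[3] * ez[1] - ey[1] * ez[3],
          ey[1] * ez[2] - ey[2] * ez[1])
  B <- rbind(ex, ey, ez)
  q <- function(name) as.numeric(B %*% lm[name, ])

  # frontal-plane direction angle: 0 = straight down (-z), + toward lateral
  phi_frontal <- function(v) deg_atan2(v[1], -v[3])
  # frontal-plane angle of the downward normal of an ML joint line
  psi_jointline <- function(j) deg_atan2(j[3], j[1])
  ang_axial <- function(v) deg_atan2(v[2], v[1])

  fem_axis <- q("knee_center_femur") - q("hip_center")
  tib_axis <- q("ankle_center") - q("knee_center_tibia")
  phi_f <- phi_frontal(fem_axis)
  phi_t <- phi_frontal(tib_axis)

  jf <- q("lat_distal_condyle") - q("med_distal_condyle")
  jt <- q("lat_plateau") - q("med_plateau")
  epi <- q("lat_epicondyle") - q("med_epicondyle")
  ap <- q("ant_plateau") - q("post_plateau")

  hka <- phi_f - phi_t
  fvv <- phi_f - psi_jointline(jf)
  tvv <- psi_jointline(jt) - phi_t
  ier <- ang_axial(epi) - ang_axial(jt)
  # sagittal: anterior normal of the tibial axis as reference
  ts <- deg_atan2(ap[3], ap[2]) - deg_atan2(tib_axis[2], -tib_axis[3])

  wrap <- function(a) ((a + 180) %% 360) - 180
  out <- wrap(c(HKA = hka, FVV = fvv, TVV = tvv, IER = ier, TS = ts))
  if (any(abs(out) >= 90))
    stop("computed angle outside (-90, 90); landmark set implausible")
  out
}

#' Physiological normality thresholds for the five alignment angles
#'
#' Per-angle centre and half-width of the physiological range: HKA 0 +/- 3,
#' FVV -6 +/- 2 (physiological valgum), IER 0 +/- 5, TVV 0 +/- 5,
#' TS 7 +/- 4 degrees.
#'
#' @return data frame with columns `angle`, `center`, `half_width`.
#' @export
default_thresholds <- function() {
  data.frame(angle = c("HKA", "FVV", "IER", "TVV", "TS"),
             center = c(0, -6, 0, 0, 7),
             half_width = c(3, 2, 5, 5, 4),
             stringsAsFactors = FALSE)
}

check_thresholds <- function(thr) {
  stopifnot(is.data.frame(thr),
            all(c("angle", "center", "half_width") %in% names(thr)))
  if (any(!is.finite(thr$center)) || any(!is.finite(thr$half_width)) ||
      any(thr$half_width <= 0))
    stop("invalid thresholds: half_width must be positive and finite")
  thr
}

#' Label per-angle knee stability
#'
#' An angle is labelled stable when it lies inside the closed physiological
#' interval `center +/- half_width`, unstable otherwise. Boundary values
#' count as stable. The five labels are independent: a knee may be stable
#' for one angle and unstable for another.
#'
#' @param angles named numeric vector (names as in `thr$angle`), degrees.
#' @param thr thresholds data frame, see [default_thresholds()].
#' @return named logical vector, `TRUE` = unstable.
#' @export
label_stability <- function(angles, thr = default_thresholds()) {
  thr <- check_thresholds(thr)
  missing <- setdiff(thr$angle, names(angles))
  if (length(missing) > 0)
    stop("missing angle values: ", paste(missing, collapse = ", "))
  out <- abs(angles[thr$angle] - thr$center) > thr$half_width
  names(out) <- thr$angle
  out
}

#' Corrected deviation of a clinical angle
#'
#' Absolute deviation from the physiological centre,
#' `X_hat = |x - center|`, used when correlating mode weights with
#' instability grade: both increases and decreases away from the
#' physiological value indicate instability.
#'
#' @param x angle value(s), degrees.
#' @param center physiological mean of that angle, degrees.
#' @return nonnegative deviation(s), degrees.
#' @export
corrected_deviation <- function(x, center) {
  stopifnot(all(is.finite(x)), is.finite(center))
  abs(x - center)
}

#' Angle and stability table for a cohort
#'
#' @param samples list of `knee_sample` objects (or a named list with
#'   `landmarks`).
#' @param thr thresholds data frame.
#' @param use_true if `TRUE` and samples carry generative ground-truth
#'   angles, use those; otherwise compute from landmarks (right-side
#'   convention; left samples are mirrored internally).
#' @return data frame: id, side, the five angles, and five logical
#'   `unstable_*` columns.
#' @export
angle_table <- function(samples, thr = default_thresholds(),
                        use_true = FALSE) {
  rows <- lapply(samples, function(s) {
    ang <- if (use_true && !is.null(s$angles)) s$angles
           else compute_angles(sample_landmarks_right(s))
    lab <- label_stability(ang, thr)
    data.frame(id = s$id, side = s$side,
               HKA = ang[["HKA"]], FVV = ang[["FVV"]], IER = ang[["IER"]],
               TVV = ang[["TVV"]], TS = ang[["TS"]],
               unstable_HKA = lab[["HKA"]], unstable_FVV = lab[["FVV"]],
               unstable_IER = lab[["IER"]], unstable_TVV = lab[["TVV"]],
               unstable_TS = lab[["TS"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# landmarks of a sample in the right-side convention
sample_landmarks_right <- function(s) {
  lm <- s$landmarks
  if (identical(s$side, "left")) lm[, 1] <- -lm[, 1]
  lm
}
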