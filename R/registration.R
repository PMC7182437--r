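#' @name registration
#' @title Rigid and deformable registration
#'
#' @description
#' Each femur+tibia pair is first registered rigidly (rotation +
#' translation, never scale) as one combined point cloud to the reference
#' pair, which preserves the sample's internal femoro-tibial pose and
#' joint space. Dense correspondences are then extracted per bone: the
#' reference bone's vertices are deformed toward the sample surface by
#' coherent point drift (CPD), a Gaussian-mixture registration with a
#' smooth Gaussian-kernel motion field, and each deformed reference vertex
#' is projected onto its closest point on the sample surface. The result
#' is reference-indexed: every sample is described by the same number of
#' points in the same order, which is what the shape model requires.
NULL

#' CPD configuration
#'
#' @param beta Gaussian kernel width of the motion field (larger = more
#'   globally coherent deformation), in units of the point coordinates.
#' @param lam regularisation weight of the motion field (larger = stiffer).
#' @param w expected outlier fraction in `[0, 1)`.
#' @param max_iter maximum EM iterations.
#' @param tol relative penalised log-likelihood change for convergence.
#' @param rank size of the truncated eigendecomposition of the Gaussian
#'   kernel used to accelerate the M-step (the kernel is very smooth, so a
#'   small rank is essentially exact); `0` uses the full dense solve.
#' @return list of class `cpd_config`.
#' @export
cpd_config <- function(beta = 3, lam = 10, w = 0.1, max_iter = 150,
                       tol = 1e-5, rank = 60) {
  if (beta <= 0 || lam <= 0) stop("beta and lam must be positive")
  if (w < 0 || w >= 1) stop("w must be in [0, 1)")
  if (tol <= 0) stop("tol must be positive")
  if (rank < 0) stop("rank must be nonnegative")
  structure(list(beta = beta, lam = lam, w = w,
                 max_iter = as.integer(max_iter), tol = tol,
                 rank = as.integer(rank)),
            class = "cpd_config")
}

# Kabsch rotation+translation (no scaling) mapping P onto Q, least squares
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = cq - as.numeric(R %*% cp))
}

#' Rigidly align a knee pair to a reference pair
#'
#' One rotation + translation (no scaling) is fitted for the concatenated
#' femur+tibia cloud by iterative closest point with a Procrustes inner
#' step, minimising point-to-surface residuals to the reference pair.
#' When both samples carry landmarks the transform is initialised by
#' landmark Procrustes, otherwise by centroid + principal axes. The
#' femur-tibia relative pose within the sample is untouched.
#'
#' @param sample,reference `knee_sample` objects (right-side convention).
#' @param max_iter ICP iterations.
#' @param tol convergence threshold on the relative residual change.
#' @return list with `rotation`, `translation`, `sample` (the transformed
#'   `knee_sample`), `residual` (mean point-to-surface distance, mm) and
#'   `converged`.
#' @export
rigid_align_pair <- function(sample, reference, max_iter = 50, tol = 1e-5) {
  stopifnot(inherits(sample, "knee_sample"),
            inherits(reference, "knee_sample"))
  P <- rbind(sample$femur$vertices, sample$tibia$vertices)
  refmesh <- triangle_mesh(
    rbind(reference$femur$vertices, reference$tibia$vertices),
    rbind(reference$femur$faces,
          reference$tibia$faces + nrow(reference$femur$vertices)))
  if (!is.null(sample$landmarks) && !is.null(reference$landmarks) &&
      all(landmark_names() %in% rownames(sample$landmarks)) &&
      all(landmark_names() %in% rownames(reference$landmarks))) {
    init <- kabsch(sample$landmarks[landmark_names(), ],
                   reference$landmarks[landmark_names(), ])
  } else {
    # centroid + principal axes, sign-fixed toward a proper rotation
    pr_s <- svd(cov(P))$u
    pr_r <- svd(cov(refmesh$vertices))$u
    R0 <- pr_r %*% t(pr_s)
    if (det(R0) < 0) {
      pr_s[, 3] <- -pr_s[, 3]
      R0 <- pr_r %*% t(pr_s)
    }
    init <- list(R = R0,
                 t = colMeans(refmesh$vertices) - as.numeric(R0 %*% colMeans(P)))
  }
  R <- init$R; tr <- init$t
  prev <- Inf; resid <- Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    Pt <- apply_rigid(P, R, tr)
    cl <- cpp_closest_on_mesh(Pt, refmesh$vertices, refmesh$faces)
    resid <- mean(cl$dist)
    if (is.finite(prev) && abs(prev - resid) <= max(tol * prev, 1e-10)) {
      converged <- TRUE
      break
    }
    prev <- resid
    step <- kabsch(Pt, cl$points)
    R <- step$R %*% R
    tr <- as.numeric(step$R %*% tr) + step$t
  }
  if (!converged)
    warning("rigid alignment did not converge; returning best transform")
  out <- sample
  tf <- function(m) triangle_mesh(apply_rigid(m$vertices, R, tr), m$faces)
  out$femur <- tf(sample$femur)
  out$tibia <- tf(sample$tibia)
  if (!is.null(sample$landmarks))
    out$landmarks <- apply_rigid(sample$landmarks, R, tr)
  list(rotation = R, translation = tr, sample = out, residual = resid,
       converged = converged)
}

#' Non-rigid coherent point drift registration
#'
#' Deforms the `source` point set toward `target` with a Gaussian-kernel
#' motion field estimated by EM on a Gaussian mixture with a uniform
#' outlier component. The penalised log-likelihood trace is monotone
#' non-decreasing (a generalised-EM property) and is returned for
#' inspection.
#'
#' @param source M x 3 points to deform (the reference bone's vertices).
#' @param target N x 3 points to register onto.
#' @param cfg a [cpd_config()].
#' @return list with `points` (deformed source), `loglik` (trace),
#'   `sigma2`, `iterations`, `converged`.
#' @export
cpd_register <- function(source, target, cfg = cpd_config()) {
  Y <- matrix(as.numeric(source), ncol = 3)
  X <- matrix(as.numeric(target), ncol = 3)
  M <- nrow(Y); N <- nrow(X)
  if (M < 10 || N < 10) stop("point sets must have at least 10 points")
  stopifnot(inherits(cfg, "cpd_config"))
  # kernel width and regularisation are in normalised units: centre on the
  # joint centroid and scale to unit RMS radius, as is conventional for CPD
  ctr <- colMeans(rbind(X, Y))
  X <- sweep(X, 2, ctr); Y <- sweep(Y, 2, ctr)
  scl <- sqrt(mean(rowSums(rbind(X, Y)^2)))
  if (scl <= 0) scl <- 1
  X <- X / scl; Y <- Y / scl
  G <- exp(-as.matrix(stats::dist(Y))^2 / (2 * cfg$beta^2))
  # optional low-rank kernel: the Gaussian kernel at these widths is very
  # smooth, so a truncated eigenbasis is essentially exact and turns the
  # O(M^3) M-step solve into O(M K^2) (Woodbury identity)
  lowrank <- cfg$rank > 0 && cfg$rank < M
  if (lowrank) {
    # motion field parameterised in the scaled kernel eigenbasis,
    # T = Y + Q B with Q = U Lam^(1/2): the prior penalty becomes a plain
    # ridge on B and the M-step a well-conditioned K x K SPD solve
    eg <- eigen(G, symmetric = TRUE)
    K <- min(cfg$rank, sum(eg$values > eg$values[1] * 1e-8))
    Q <- eg$vectors[, seq_len(K), drop = FALSE] *
      rep(sqrt(eg$values[seq_len(K)]), each = M)
  }
  # isotropic variance init: mean squared distance between the sets / 3
  sigma2 <- (M * sum(X^2) + N * sum(Y^2) -
               2 * sum(colSums(X) * colSums(Y))) / (3 * M * N)
  W <- matrix(0, M, 3)           # full-rank field coefficients
  B <- if (lowrank) matrix(0, ncol(Q), 3)   # eigenbasis coefficients
  TY <- Y
  trace <- numeric(0)
  converged <- FALSE
  it <- 0
  while (it < cfg$max_iter) {
    it <- it + 1
    e <- cpd_estep(X, TY, sigma2, cfg$w)
    if (!is.finite(e$loglik))
      stop("CPD variance collapsed to a non-finite value; aborting")
    pen <- if (lowrank) sum(B^2) else sum(W * (G %*% W))
    ll_pen <- e$loglik - cfg$lam / 2 * pen
    trace <- c(trace, ll_pen)
    if (it > 1) {
      rel <- abs(ll_pen - trace[it - 1]) / max(abs(trace[it - 1]), 1e-12)
      if (rel < cfg$tol) {
        converged <- TRUE
        break
      }
    }
    cc <- cfg$lam * sigma2
    if (lowrank) {
      A <- crossprod(Q, Q * e$P1) + diag(cc, ncol(Q))
      B <- solve(A, crossprod(Q, e$PX - e$P1 * Y))
      TY <- Y + Q %*% B
    } else {
      # symmetrised M-step system (divide by P1): (G + c/P1) W = rhs
      d <- pmax(e$P1, 1e-12)
      ch <- chol(G + diag(cc / d))
      W <- backsolve(ch, backsolve(ch, e$PX / d - Y, transpose = TRUE))
      TY <- Y + G %*% W
    }
    xPx <- sum(e$Pt1 * rowSums(X^2))
    tPt <- sum(e$P1 * rowSums(TY^2))
    sigma2 <- (xPx - 2 * sum(e$PX * TY) + tPt) / (3 * e$Np)
    if (!is.finite(sigma2))
      stop("CPD variance collapsed to a non-finite value; aborting")
    if (sigma2 < 1e-10) {
      sigma2 <- 1e-10
      converged <- TRUE
      break
    }
  }
  list(points = sweep(TY * scl, 2, ctr, "+"), loglik = trace,
       sigma2 = sigma2 * scl^2, iterations = it, converged = converged)
}

#' Reference-indexed dense correspondence for one bone
#'
#' CPD-deforms the reference bone's vertices toward the sample bone, then
#' projects each deformed vertex to its closest point on the sample
#' surface. The output always has exactly as many points as the reference
#' bone has vertices, in reference order. Projections farther than `gate`
#' are treated as outliers and kept at the deformed (unprojected)
#' position.
#'
#' @param reference_bone,sample_bone `triangle_mesh` objects in the common
#'   (rigidly aligned) frame.
#' @param cfg a [cpd_config()].
#' @param gate projection gate in mm (default 5).
#' @return P x 3 matrix with attribute `outlier` (logical vector).
#' @export
correspond <- function(reference_bone, sample_bone, cfg = cpd_config(),
                       gate = 5) {
  stopifnot(is_triangle_mesh(reference_bone), is_triangle_mesh(sample_bone))
  reg <- cpd_register(reference_bone$vertices, sample_bone$vertices, cfg)
  pr <- closest_on_surface(reg$points, sample_bone)
  out <- pr$points
  bad <- pr$dist > gate
  if (any(bad)) out[bad, ] <- reg$points[bad, , drop = FALSE]
  attr(out, "outlier") <- bad
  out
}

#' Build the cohort correspondence set
#'
#' Rigidly aligns every sample pair to the reference pair and extracts
#' per-bone reference-indexed correspondences, stacked as one flat shape
#' vector per sample (femur block then tibia block, x/y/z interleaved per
#' point). Deterministic given inputs and configuration. Samples whose
#' registration fails are reported and skipped.
#'
#' @param cohort list of `knee_sample` objects (right-side convention;
#'   mirror left sides upstream).
#' @param reference the reference `knee_sample` (typically preprocessed
#'   and remeshed).
#' @param cfg a [cpd_config()].
#' @param gate projection gate in mm.
#' @return object of class `correspondence_set`: list with `shapes`
#'   (M x 3P matrix, rownames = sample ids), `p_femur`, `p_tibia`,
#'   `reference`, `transforms`, `failed`.
#' @export
build_correspondences <- function(cohort, reference, cfg = cpd_config(),
                                  gate = 5) {
  stopifnot(inherits(reference, "knee_sample"))
  p_f <- nrow(reference$femur$vertices)
  p_t <- nrow(reference$tibia$vertices)
  rows <- list(); transforms <- list(); failed <- character(0)
  for (s in cohort) {
    res <- tryCatch({
      al <- rigid_align_pair(s, reference)
      cf <- correspond(reference$femur, al$sample$femur, cfg, gate)
      ct <- correspond(reference$tibia, al$sample$tibia, cfg, gate)
      list(vec = c(t(cf), t(ct)),
           tf = list(rotation = al$rotation, translation = al$translation,
                     residual = al$residual))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("correspondence failed for sample '", s$id, "': ",
              conditionMessage(res))
      failed <- c(failed, s$id)
    } else {
      rows[[s$id]] <- res$vec
      transforms[[s$id]] <- res$tf
    }
  }
  shapes <- do.call(rbind, rows)
  structure(list(shapes = shapes, p_femur = p_f, p_tibia = p_t,
                 reference = reference, transforms = transforms,
                 failed = failed),
            class = "correspondence_set")
}

#' Select the reference sample of a cohort
#'
#' Deterministic analogue of picking a low-deformity reference: the sample
#' minimising the summed absolute deviation of its five clinical angles
#' from the physiological centres. Ties break on cohort order.
#'
#' @param cohort list of `knee_sample` objects with angles available
#'   (ground truth or computable from landmarks).
#' @param thr thresholds table supplying the physiological centres.
#' @return index of the reference sample in `cohort`.
#' @export
select_reference <- function(cohort, thr = default_thresholds()) {
  dev <- vapply(cohort, function(s) {
    ang <- if (!is.null(s$angles)) s$angles
           else compute_angles(sample_landmarks_right(s))
    sum(abs(ang[thr$angle] - thr$center))
  }, numeric(1))
  which.min(dev)
}

#' Serialize / read a correspondence set
#'
#' The shape matrix is written as headerless CSV (rows = samples, columns
#' = 3P flattened coordinates) next to a JSON sidecar with sample ids,
#' per-bone point counts and per-sample rigid transforms.
#'
#' @param corr a `correspondence_set`.
#' @param path basename; writes `<path>.csv` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_correspondences <- function(corr, path) {
  stopifnot(inherits(corr, "correspondence_set"))
  write.table(corr$shapes, paste0(path, ".csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  side <- list(ids = rownames(corr$shapes),
               p_femur = corr$p_femur, p_tibia = corr$p_tibia,
               failed = corr$failed,
               transforms = lapply(corr$transforms, function(tf)
                 list(rotation = as.numeric(tf$rotation),
                      translation = tf$translation,
                      residual = tf$residual)))
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_correspondences
#' @export
read_correspondences <- function(path) {
  shapes <- unname(as.matrix(read.csv(paste0(path, ".csv"), header = FALSE)))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rownames(shapes) <- side$ids
  structure(list(shapes = shapes,
                 p_femur = side$p_femur, p_tibia = side$p_tibia,
                 reference = NULL,
                 transforms = side$transforms, failed = side$failed),
            class = "correspondence_set")
}
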