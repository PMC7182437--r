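#' Fit the joint tibio-femoral statistical shape model
#'
#' PCA over the correspondence set: the mean shape vector and the
#' eigenvectors/eigenvalues of the sample covariance of the centred shape
#' vectors, computed through the M x M Gram matrix (with M samples and 3P
#' coordinates, at most M - 1 modes carry variance). Mode standard
#' deviations are stored in mm (descending); mode signs are fixed by
#' making each mode's largest-magnitude component positive so results are
#' deterministic.
#'
#' @param corr a `correspondence_set` (or a bare M x 3P matrix).
#' @return object of class `ssm_model`: `mean` (3P), `modes` (3P x k,
#'   orthonormal columns), `sd` (k, mm), `ev` (explained-variance
#'   proportions), `n_samples`, `p_femur`, `p_tibia`, `ids`.
#' @export
fit_ssm <- function(corr) {
  if (inherits(corr, "correspondence_set")) {
    S <- corr$shapes
    p_f <- corr$p_femur; p_t <- corr$p_tibia
  } else {
    S <- as.matrix(corr)
    p_f <- ncol(S) / 3; p_t <- 0
  }
  M <- nrow(S)
  if (M < 3) stop("at least 3 samples are required")
  m_bar <- colMeans(S)
  C <- sweep(S, 2, m_bar)
  # Gram trick: eigendecompose C C' / (M-1), map back to 3P space
  G <- tcrossprod(C) / (M - 1)
  eg <- eigen(G, symmetric = TRUE)
  tol <- max(eg$values) * 1e-10
  keep <- which(eg$values > pmax(tol, 0))
  if (max(eg$values) <= 0) keep <- integer(0)
  if (length(keep) > 0) {
    lam <- eg$values[keep]
    V <- crossprod(C, eg$vectors[, keep, drop = FALSE])
    V <- sweep(V, 2, sqrt((M - 1) * lam), "/")
    # deterministic sign: largest |component| positive
    for (j in seq_len(ncol(V))) {
      i <- which.max(abs(V[, j]))
      if (V[i, j] < 0) V[, j] <- -V[, j]
    }
    sds <- sqrt(lam)
  } else {
    V <- matrix(0, ncol(S), 0)
    sds <- numeric(0)
  }
  structure(list(mean = m_bar, modes = V, sd = sds,
                 ev = if (length(sds)) explained_variance(sds) else numeric(0),
                 n_samples = M, p_femur = p_f, p_tibia = p_t,
                 ids = rownames(S)),
            class = "ssm_model")
}

#' @exportS3Method base::print
print.ssm_model <- function(x, ...) {
  cat(sprintf("ssm_model: %d samples, %d points (%d femur + %d tibia), %d modes\n",
              x$n_samples, length(x$mean) / 3, x$p_femur, x$p_tibia,
              length(x$sd)))
  if (length(x$ev)) {
    k95 <- n_modes_for(x$ev, 0.95)
    cat(sprintf("  modes for 95%% EV: %d; first EVs: %s\n", k95,
                paste(sprintf("%.3f", utils::head(x$ev, 5)), collapse = " ")))
  }
  invisible(x)
}

#' Explained variance per mode
#'
#' `EV_j = sigma_j^2 / sum_i sigma_i^2`, the fraction of total shape
#' variance carried by each mode; sums to one.
#'
#' @param sds vector of mode standard deviations (nonnegative, not all 0).
#' @return vector of explained-variance proportions.
#' @export
explained_variance <- function(sds) {
  if (any(sds < 0)) stop("mode SDs must be nonnegative")
  tot <- sum(sds^2)
  if (tot == 0) stop("all mode SDs are zero")
  sds^2 / tot
}

#' Number of modes needed for a cumulative explained-variance threshold
#'
#' @param ev explained-variance proportions (descending).
#' @param threshold in `(0, 1]` (default 0.95).
#' @return smallest k with `cumsum(ev)[k] >= threshold`.
#' @export
n_modes_for <- function(ev, threshold = 0.95) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  cs <- cumsum(ev)
  k <- which(cs >= threshold - 1e-12)
  if (length(k) == 0) length(ev) else k[1]
}

#' Morph a shape from mode weights
#'
#' Reconstructs a shape vector from the mean plus weighted modes:
#' `S = mean + sum_i lambda_i * sigma_i * v_i`. Weights are in SD units;
#' all-zero weights give the mean shape.
#'
#' @param model an `ssm_model`.
#' @param lambda numeric weight vector (length <= number of modes).
#' @return shape vector of length 3P.
#' @export
morph <- function(model, lambda) {
  stopifnot(inherits(model, "ssm_model"))
  k <- length(lambda)
  if (k > length(model$sd)) stop("more weights than modes")
  if (!all(is.finite(lambda))) stop("weights must be finite")
  if (k == 0) return(model$mean)
  model$mean + as.numeric(model$modes[, seq_len(k), drop = FALSE] %*%
                            (lambda * model$sd[seq_len(k)]))
}

#' Project a shape onto the model
#'
#' Mode weights by scalar product: `lambda_i = v_i . (s - mean) / sigma_i`
#' for the first `k` modes; a zero-variance mode gets weight 0.
#'
#' @param model an `ssm_model`.
#' @param s shape vector of length 3P.
#' @param k number of modes (default all).
#' @return numeric weight vector (SD units).
#' @export
project <- function(model, s, k = length(model$sd)) {
  stopifnot(inherits(model, "ssm_model"))
  if (length(s) != length(model$mean))
    stop("shape vector length does not match the model")
  if (k > length(model$sd)) stop("more modes requested than available")
  if (k == 0) return(numeric(0))
  idx <- seq_len(k)
  lam <- as.numeric(crossprod(model$modes[, idx, drop = FALSE],
                              s - model$mean))
  ifelse(model$sd[idx] > 0, lam / model$sd[idx], 0)
}

# shape vector -> point matrix / meshes on the reference topology
shape_to_points <- function(v) matrix(v, ncol = 3, byrow = TRUE)

#' Rebuild femur and tibia meshes from a shape vector
#'
#' @param model an `ssm_model` fitted from a `correspondence_set` whose
#'   reference is available.
#' @param s shape vector.
#' @param reference the reference `knee_sample` supplying the topology.
#' @return list with `femur` and `tibia` `triangle_mesh` objects.
#' @export
shape_to_meshes <- function(model, s, reference) {
  P <- shape_to_points(s)
  pf <- model$p_femur
  list(femur = triangle_mesh(P[seq_len(pf), , drop = FALSE],
                             reference$femur$faces),
       tibia = triangle_mesh(P[pf + seq_len(model$p_tibia), , drop = FALSE],
                             reference$tibia$faces))
}

#' Reconstruction errors under truncated mode retention
#'
#' Each sample's shape vector is projected onto the first `k_modes` modes
#' and morphed back; the reconstruction is compared to the sample's
#' correspondence points. Three per-sample metrics are reported: the RMS
#' point error (the quantity guaranteed non-increasing in `k` under
#' nested orthogonal projections), the mean point distance, and the
#' maximum point distance (a vertex-sampled Hausdorff distance, since
#' reconstruction and sample share the reference indexing).
#'
#' @param model an `ssm_model`.
#' @param corr the `correspondence_set` the model was fitted on (or any
#'   compatible one).
#' @param k_modes number of retained modes.
#' @return list with `per_sample` (data frame: id, rms, mean, hausdorff,
#'   mm) and `summary` (mean and SD of each metric across the cohort).
#' @export
reconstruction_errors <- function(model, corr, k_modes) {
  S <- if (inherits(corr, "correspondence_set")) corr$shapes else as.matrix(corr)
  if (k_modes > length(model$sd)) stop("k_modes exceeds available modes")
  res <- lapply(seq_len(nrow(S)), function(i) {
    s <- S[i, ]
    rec <- morph(model, project(model, s, k_modes))
    d <- sqrt(rowSums((shape_to_points(s) - shape_to_points(rec))^2))
    c(rms = sqrt(mean(d^2)), mean = mean(d), hausdorff = max(d))
  })
  per <- data.frame(id = rownames(S) %||% as.character(seq_len(nrow(S))),
                    do.call(rbind, res), stringsAsFactors = FALSE)
  summ <- c(rms_mean = mean(per$rms), rms_sd = sd(per$rms),
            mean_mean = mean(per$mean), mean_sd = sd(per$mean),
            hausdorff_mean = mean(per$hausdorff), hausdorff_sd = sd(per$hausdorff))
  list(per_sample = per, summary = summ)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize / read an SSM model archive
#'
#' Writes mean, modes, SDs, explained variance and bookkeeping as one
#' JSON archive (text, lossless numeric precision).
#'
#' @param model an `ssm_model`.
#' @param path output path (`.json`).
#' @return `path` invisibly, or the restored `ssm_model`.
#' @export
write_ssm <- function(model, path) {
  stopifnot(inherits(model, "ssm_model"))
  obj <- list(mean = model$mean, modes = as.numeric(model$modes),
              n_modes = ncol(model$modes), sd = model$sd, ev = model$ev,
              n_samples = model$n_samples, p_femur = model$p_femur,
              p_tibia = model$p_tibia, ids = model$ids)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ssm
#' @export
read_ssm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = obj$mean,
                 modes = matrix(obj$modes, ncol = obj$n_modes),
                 sd = obj$sd, ev = obj$ev, n_samples = obj$n_samples,
                 p_femur = obj$p_femur, p_tibia = obj$p_tibia,
                 ids = obj$ids),
            class = "ssm_model")
}
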