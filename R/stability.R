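#' @name stability-analysis
#' @title Classifying knee instability from shape-mode weights
#'
#' @description
#' The statistical layer relating mode-of-variation weights to the
#' per-angle stability labels: linear and quadratic Gaussian discriminant
#' analysis (with covariance shrinkage towards the diagonal, needed when
#' the feature count approaches the size of the smaller class), logistic
#' regression with Wald tests, leave-one-out (LOO) cross-validated
#' accuracy / sensitivity / specificity, greedy low-dimensional mode
#' subset selection, unpaired rank-sum tests between stable and unstable
#' groups, and Spearman correlation of each mode weight with the corrected
#' deviation of each clinical angle. The positive class is "unstable"
#' throughout.
NULL

#' Classifier specification
#'
#' @param kind `"lda"`, `"qda"` or `"logreg"`.
#' @param features integer mode indices, or `"all"`.
#' @param shrinkage covariance shrinkage rho in `[0, 1]` for lda/qda:
#'   `Sigma <- (1 - rho) Sigma + rho diag(Sigma)`.
#' @param ridge ridge penalty for logistic regression (used automatically
#'   on separation).
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("lda", "qda", "logreg"),
                            features = "all", shrinkage = 0.1,
                            ridge = 1e-4) {
  kind <- match.arg(kind)
  if (!(identical(features, "all") ||
        (is.numeric(features) && all(features >= 1))))
    stop("features must be 'all' or positive indices")
  if (shrinkage < 0 || shrinkage > 1) stop("shrinkage must be in [0, 1]")
  if (ridge < 0) stop("ridge must be nonnegative")
  structure(list(kind = kind, features = features, shrinkage = shrinkage,
                 ridge = ridge), class = "classifier_spec")
}

# Gaussian discriminant fit (shared by lda/qda); labels logical (TRUE =
# unstable, the positive class)
fit_gda <- function(X, y, kind, shrinkage) {
  X <- as.matrix(X)
  cls <- list(`FALSE` = X[!y, , drop = FALSE], `TRUE` = X[y, , drop = FALSE])
  if (any(vapply(cls, nrow, 1L) < 2))
    stop("each class needs at least 2 samples")
  mus <- lapply(cls, colMeans)
  shrink <- function(S) {
    S <- (1 - shrinkage) * S + shrinkage * diag(diag(S), ncol(X))
    S + diag(1e-10 * max(diag(S), 1), ncol(X))
  }
  if (kind == "lda") {
    Sp <- Reduce(`+`, lapply(cls, function(Z)
      crossprod(sweep(Z, 2, colMeans(Z))))) / (nrow(X) - 2)
    covs <- list(`FALSE` = shrink(Sp), `TRUE` = shrink(Sp))
  } else {
    covs <- lapply(cls, function(Z) shrink(cov(Z)))
  }
  priors <- vapply(cls, nrow, 1L) / nrow(X)
  list(mus = mus, covs = covs, priors = priors)
}

predict_gda <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  scores <- vapply(c("FALSE", "TRUE"), function(k) {
    mu <- fit$mus[[k]]; S <- fit$covs[[k]]
    ch <- chol(S)
    z <- backsolve(ch, t(sweep(Xnew, 2, mu)), transpose = TRUE)
    -0.5 * colSums(z^2) - sum(log(diag(ch))) + log(fit$priors[[k]])
  }, numeric(nrow(Xnew)))
  if (nrow(Xnew) == 1) scores <- matrix(scores, nrow = 1,
                                        dimnames = list(NULL, c("FALSE", "TRUE")))
  scores[, "TRUE"] > scores[, "FALSE"]
}

# logistic prediction for LOO (ridge fallback on separation)
fit_predict_logreg <- function(X, y, Xnew, ridge) {
  X <- as.matrix(X)
  Xnew <- matrix(as.numeric(Xnew), ncol = ncol(X))
  tr <- as.data.frame(X)
  names(tr) <- paste0("f", seq_len(ncol(X)))
  nw <- as.data.frame(Xnew)
  names(nw) <- names(tr)
  df <- cbind(y = y, tr)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  sep <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE) ||
    anyNA(stats::coef(fit))
  if (sep) {
    co <- ridge_logreg(cbind(1, X), y, ridge)$coef
    eta <- as.numeric(cbind(1, Xnew) %*% co)
  } else {
    eta <- stats::predict(fit, newdata = nw, type = "link")
  }
  as.logical(eta > 0)
}

# penalised IRLS (ridge on all but the intercept)
ridge_logreg <- function(Xd, y, ridge, tol = 1e-8, max_iter = 100) {
  p <- ncol(Xd)
  pen <- diag(c(0, rep(ridge, p - 1)), p)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    Wd <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xd, Xd * Wd) + pen
    g <- crossprod(Xd, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  list(coef = beta, hessian = H, iterations = it)
}

#' Confusion-matrix metrics
#'
#' Accuracy `(TP+TN)/n`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`; an undefined ratio (empty class) is reported as `NaN`
#' with a warning.
#'
#' @param TP,FN,TN,FP nonnegative integer counts, positive class =
#'   unstable.
#' @return named vector `c(AC, SE, SP)`.
#' @export
confusion_metrics <- function(TP, FN, TN, FP) {
  counts <- c(TP, FN, TN, FP)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  n <- sum(counts)
  if (n == 0) stop("empty confusion matrix")
  ac <- (TP + TN) / n
  se <- if (TP + FN > 0) TP / (TP + FN) else {
    warning("sensitivity undefined: no positive cases"); NaN
  }
  sp <- if (TN + FP > 0) TN / (TN + FP) else {
    warning("specificity undefined: no negative cases"); NaN
  }
  c(AC = ac, SE = se, SP = sp)
}

#' Leave-one-out classification of stability labels
#'
#' Each sample is predicted by a classifier trained on the remaining
#' n - 1; folds in which the training set loses an entire class are
#' flagged and excluded from the counts.
#'
#' @param weights matrix of per-sample mode weights (rows = samples).
#' @param labels logical vector, `TRUE` = unstable.
#' @param spec a [classifier_spec()].
#' @return list with `confusion` (TP/FN/TN/FP), `metrics` (AC/SE/SP),
#'   `predictions`, `skipped` (fold indices without both classes).
#' @export
loo_evaluate <- function(weights, labels, spec = classifier_spec("lda")) {
  X <- as.matrix(weights)
  y <- as.logical(labels)
  stopifnot(nrow(X) == length(y), inherits(spec, "classifier_spec"))
  if (sum(y) < 2 || sum(!y) < 2)
    stop("each class needs at least 2 samples")
  if (!identical(spec$features, "all")) {
    if (max(spec$features) > ncol(X)) stop("feature index out of range")
    X <- X[, spec$features, drop = FALSE]
  }
  n <- nrow(X)
  pred <- rep(NA, n)
  skipped <- integer(0)
  min_per_class <- if (spec$kind == "logreg") 1L else 2L
  for (i in seq_len(n)) {
    ytr <- y[-i]
    # a fold whose training set loses a class (or, for the Gaussian
    # discriminants, cannot estimate a class covariance) is excluded
    if (sum(ytr) < min_per_class || sum(!ytr) < min_per_class) {
      skipped <- c(skipped, i)
      next
    }
    pred[i] <- switch(spec$kind,
      lda = ,
      qda = predict_gda(fit_gda(X[-i, , drop = FALSE], ytr, spec$kind,
                                spec$shrinkage),
                        X[i, , drop = FALSE]),
      logreg = fit_predict_logreg(X[-i, , drop = FALSE], ytr,
                                  X[i, , drop = FALSE], spec$ridge))
  }
  ok <- !is.na(pred)
  TP <- sum(pred[ok] & y[ok]); FN <- sum(!pred[ok] & y[ok])
  TN <- sum(!pred[ok] & !y[ok]); FP <- sum(pred[ok] & !y[ok])
  list(confusion = c(TP = TP, FN = FN, TN = TN, FP = FP),
       metrics = confusion_metrics(TP, FN, TN, FP),
       predictions = pred, skipped = skipped)
}

#' Logistic regression of a stability label on mode weights
#'
#' Maximum-likelihood binomial fit (IRLS) with per-coefficient Wald z
#' tests. Complete separation or non-convergence triggers an automatic
#' ridge fallback (flagged in the result).
#'
#' @param weights matrix of mode weights.
#' @param labels logical vector, `TRUE` = unstable.
#' @param ridge fallback ridge penalty.
#' @return data frame (term, estimate, se, z, p) with attributes
#'   `separation` and `collinear`.
#' @export
fit_logreg <- function(weights, labels, ridge = 1e-4) {
  X <- as.matrix(weights)
  y <- as.logical(labels)
  if (sum(y) < 2 || sum(!y) < 2) stop("each class needs at least 2 samples")
  if (is.null(colnames(X))) colnames(X) <- paste0("mov", seq_len(ncol(X)))
  qr_rank <- qr(cbind(1, X))$rank
  collinear <- qr_rank < ncol(X) + 1
  df <- data.frame(y = y, X)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                     family = stats::binomial(),
                                     control = list(epsilon = 1e-8,
                                                    maxit = 100)))
  co <- stats::coef(fit)
  separation <- !fit$converged || anyNA(co) || any(abs(co[-1]) > 15) ||
    collinear
  if (separation) {
    rf <- ridge_logreg(cbind(1, X), y, ridge)
    est <- rf$coef
    se <- sqrt(diag(solve(rf$hessian)))
  } else {
    sm <- summary(fit)$coefficients
    est <- sm[, "Estimate"]
    se <- sm[, "Std. Error"]
  }
  z <- est / se
  out <- data.frame(term = c("(Intercept)", colnames(X)),
                    estimate = as.numeric(est), se = as.numeric(se),
                    z = as.numeric(z),
                    p = 2 * pnorm(-abs(as.numeric(z))),
                    stringsAsFactors = FALSE)
  attr(out, "separation") <- separation
  attr(out, "collinear") <- collinear
  out
}

#' Greedy forward selection of discriminative modes
#'
#' Adds, one at a time, the mode that maximises LOO accuracy of the given
#' classifier; ties break towards the lower mode index, so the result is
#' deterministic.
#'
#' @param weights matrix of mode weights.
#' @param labels logical vector, `TRUE` = unstable.
#' @param spec a [classifier_spec()] (its `features` field is ignored).
#' @param k subset size (>= 1).
#' @param candidates candidate mode indices (default all columns).
#' @return integer vector of selected mode indices (length `k`), with
#'   attribute `accuracy` (LOO accuracy at each step).
#' @export
select_modes <- function(weights, labels, spec = classifier_spec("qda"),
                         k = 3, candidates = seq_len(ncol(as.matrix(weights)))) {
  if (k < 1) stop("k must be at least 1")
  X <- as.matrix(weights)
  chosen <- integer(0)
  accs <- numeric(0)
  for (step in seq_len(k)) {
    rest <- setdiff(candidates, chosen)
    if (length(rest) == 0) break
    acc <- vapply(rest, function(j) {
      sp <- spec; sp$features <- "all"
      # only the accuracy matters here; degenerate-class SE/SP warnings
      # from individual candidate evaluations are not informative
      suppressWarnings(
        loo_evaluate(X[, c(chosen, j), drop = FALSE], labels,
                     sp)$metrics[["AC"]])
    }, numeric(1))
    best <- rest[which.max(acc)]   # which.max takes the first = lowest index
    chosen <- c(chosen, best)
    accs <- c(accs, max(acc))
  }
  attr(chosen, "accuracy") <- accs
  chosen
}

#' Two-sided rank-sum test for two unpaired groups
#'
#' Mann-Whitney/Wilcoxon rank-sum statistic; the p-value is computed by
#' exact enumeration of all rank splits when `nA + nB <= exact_max`
#' (handling ties by enumerating over the observed pooled values) and by
#' the tie-corrected normal approximation otherwise.
#'
#' @param a,b numeric vectors (each >= 3 values).
#' @param exact_max largest pooled size for exact enumeration (default 12).
#' @return list with `statistic` (rank sum of `a`), `p`, `method`.
#' @export
ranksum_test <- function(a, b, exact_max = 12) {
  if (length(a) < 3 || length(b) < 3) stop("both groups need >= 3 values")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  w <- sum(r[seq_len(na)])
  if (n <= exact_max) {
    splits <- utils::combn(n, na)
    ws <- apply(splits, 2, function(idx) sum(r[idx]))
    p_lo <- mean(ws <= w + 1e-12)
    p_hi <- mean(ws >= w - 1e-12)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact enumeration"
  } else {
    mu <- na * (n + 1) / 2
    ties <- table(pooled)
    tiecorr <- sum(ties^3 - ties) / (n * (n - 1))
    s2 <- na * nb / 12 * ((n + 1) - tiecorr)
    if (s2 <= 0) return(list(statistic = w, p = 1,
                             method = "normal approximation"))
    # continuity-corrected two-sided normal approximation
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(s2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = w, p = p, method = method)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties, Pearson correlation of the ranks, and a
#' two-sided p from `t = c * sqrt((n-2)/(1-c^2))` on n - 2 degrees of
#' freedom.
#'
#' @param x,y numeric vectors (>= 4 pairs).
#' @return list with `c` (coefficient) and `p`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("at least 4 pairs are required")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(list(c = NA_real_, p = NA_real_))
  cc <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (abs(cc) >= 1) return(list(c = sign(cc), p = 0))
  tstat <- cc * sqrt((n - 2) / (1 - cc^2))
  list(c = cc, p = 2 * pt(-abs(tstat), df = n - 2))
}

#' Full instability analysis battery
#'
#' For every clinical angle: LOO-validated LDA, QDA and logistic
#' classification on all retained mode weights; greedy QDA subsets of
#' size 3 and 4; logistic-regression Wald p per mode; unpaired rank-sum
#' tests between stable and unstable groups for modes flagged significant
#' by the logistic fit; and Spearman correlation of every retained mode
#' against the corrected deviation of every angle.
#'
#' @param weights M x k matrix of retained mode weights (rownames = ids).
#' @param angles data frame from [angle_table()] (id + five angles +
#'   `unstable_*` flags).
#' @param thr thresholds table (supplies the physiological centres).
#' @param shrinkage discriminant covariance shrinkage.
#' @param p_threshold significance level for flagging modes (default
#'   0.05).
#' @param adjust p-value adjustment for the per-mode logistic tests
#'   (`"none"` default, `"BH"` available).
#' @return object of class `analysis_report` (nested list; see
#'   [report_tables()] for flat CSV-able views).
#' @export
run_analysis <- function(weights, angles, thr = default_thresholds(),
                         shrinkage = 0.1, p_threshold = 0.05,
                         adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  W <- as.matrix(weights)
  need <- c("id", thr$angle, paste0("unstable_", thr$angle))
  missing <- setdiff(need, names(angles))
  if (length(missing) > 0)
    stop("angle table lacks columns: ", paste(missing, collapse = ", "))
  if (!is.null(rownames(W))) {
    if (!setequal(rownames(W), angles$id))
      stop("ids of weights and angle table do not match")
    W <- W[angles$id, , drop = FALSE]
  } else if (nrow(W) != nrow(angles)) {
    stop("weights and angle table have different sizes")
  }
  colnames(W) <- paste0("mov", seq_len(ncol(W)))
  out <- list()
  for (v in thr$angle) {
    y <- angles[[paste0("unstable_", v)]]
    entry <- list(variable = v,
                  n_unstable = sum(y), n_stable = sum(!y))
    if (sum(y) < 2 || sum(!y) < 2) {
      warning("variable ", v, ": fewer than 2 samples in one class; ",
              "classification skipped")
      entry$skipped <- TRUE
      out[[v]] <- entry
      next
    }
    entry$skipped <- FALSE
    for (kind in c("lda", "qda", "logreg")) {
      sp <- classifier_spec(kind, shrinkage = shrinkage)
      ev <- loo_evaluate(W, y, sp)
      entry[[kind]] <- list(confusion = ev$confusion, metrics = ev$metrics)
    }
    for (k in c(3, 4)) {
      if (ncol(W) >= k) {
        sel <- select_modes(W, y, classifier_spec("qda", shrinkage = shrinkage),
                            k = k)
        ev <- loo_evaluate(W[, sel, drop = FALSE], y,
                           classifier_spec("qda", shrinkage = shrinkage))
        entry[[paste0("qda_top", k)]] <- list(modes = as.integer(sel),
                                              metrics = ev$metrics)
      }
    }
    lr <- fit_logreg(W, y)
    pv <- lr$p[-1]
    if (adjust == "BH") pv <- stats::p.adjust(pv, "BH")
    sig <- which(pv < p_threshold)
    entry$logreg_coefficients <- lr
    entry$significant_modes <- as.integer(sig)
    entry$ranksum <- lapply(sig, function(j) {
      rs <- ranksum_test(W[!y, j], W[y, j])
      list(mode = j, statistic = rs$statistic, p = rs$p, method = rs$method)
    })
    out[[v]] <- entry
  }
  # Spearman of every mode against every corrected angle deviation
  centers <- setNames(thr$center, thr$angle)
  corr <- do.call(rbind, lapply(thr$angle, function(v) {
    xv <- corrected_deviation(angles[[v]], centers[[v]])
    do.call(rbind, lapply(seq_len(ncol(W)), function(j) {
      sc <- spearman_cor(W[, j], xv)
      data.frame(variable = v, mode = j, c = sc$c, p = sc$p,
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(variables = out, spearman = corr,
                 n = nrow(W), n_modes = ncol(W)),
            class = "analysis_report")
}

#' Flat tables from an analysis report
#'
#' @param report an `analysis_report`.
#' @return list of data frames: `classification` (one row per variable x
#'   classifier), `subsets`, `logreg`, `ranksum`, `spearman`.
#' @export
report_tables <- function(report) {
  stopifnot(inherits(report, "analysis_report"))
  rows <- list(); subs <- list(); lr <- list(); rs <- list()
  for (v in names(report$variables)) {
    e <- report$variables[[v]]
    if (isTRUE(e$skipped)) next
    for (kind in c("lda", "qda", "logreg")) {
      m <- e[[kind]]$metrics
      rows[[paste(v, kind)]] <- data.frame(
        variable = v, classifier = toupper(kind),
        AC = m[["AC"]], SE = m[["SE"]], SP = m[["SP"]],
        stringsAsFactors = FALSE)
    }
    for (k in c("qda_top3", "qda_top4")) {
      if (!is.null(e[[k]])) {
        m <- e[[k]]$metrics
        subs[[paste(v, k)]] <- data.frame(
          variable = v, subset = k,
          modes = paste(e[[k]]$modes, collapse = ","),
          AC = m[["AC"]], SE = m[["SE"]], SP = m[["SP"]],
          stringsAsFactors = FALSE)
      }
    }
    co <- e$logreg_coefficients
    co <- co[co$term != "(Intercept)", ]
    lr[[v]] <- data.frame(variable = v, co, stringsAsFactors = FALSE)
    if (length(e$ranksum))
      rs[[v]] <- do.call(rbind, lapply(e$ranksum, function(r)
        data.frame(variable = v, mode = r$mode, statistic = r$statistic,
                   p = r$p, method = r$method, stringsAsFactors = FALSE)))
  }
  list(classification = do.call(rbind, unname(rows)),
       subsets = do.call(rbind, unname(subs)),
       logreg = do.call(rbind, unname(lr)),
       ranksum = do.call(rbind, unname(rs)),
       spearman = report$spearman)
}

#' Serialize / read an analysis report (lossless JSON round trip)
#'
#' @param report an `analysis_report`.
#' @param path output path (`.json`).
#' @return `path` invisibly, or the restored `analysis_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  # named atomic vectors (metrics, confusion) are written as JSON objects
  # so their names survive the round trip
  to_json_form <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
    if (is.list(x)) return(lapply(x, to_json_form))
    x
  }
  jsonlite::write_json(to_json_form(unclass(report)), path, digits = NA,
                       auto_unbox = TRUE, dataframe = "columns",
                       na = "string")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$spearman <- as.data.frame(obj$spearman, stringsAsFactors = FALSE)
  obj$variables <- lapply(obj$variables, function(e) {
    for (nm in intersect(c("lda", "qda", "logreg"), names(e))) {
      e[[nm]]$metrics <- unlist(e[[nm]]$metrics)
      e[[nm]]$confusion <- unlist(e[[nm]]$confusion)
    }
    for (nm in intersect(c("qda_top3", "qda_top4"), names(e)))
      e[[nm]]$metrics <- unlist(e[[nm]]$metrics)
    if (!is.null(e$logreg_coefficients))
      e$logreg_coefficients <- as.data.frame(e$logreg_coefficients,
                                             stringsAsFactors = FALSE)
    e
  })
  structure(obj, class = "analysis_report")
}
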