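test_that("LOO classification is perfect on separated classes", {
  set.seed(31)
  X <- matrix(c(rnorm(10, -10), rnorm(10, 10)), ncol = 1)
  y <- rep(c(FALSE, TRUE), each = 10)
  for (kind in c("lda", "qda", "logreg")) {
    ev <- loo_evaluate(X, y, classifier_spec(kind))
    expect_equal(unname(ev$metrics), c(1, 1, 1))
    expect_equal(sum(ev$confusion), 20)
  }
})

test_that("LOO accuracy on uninformative features stays near chance", {
  set.seed(32)
  X <- matrix(rnorm(200 * 3), ncol = 3)
  y <- rep(c(TRUE, FALSE), 100)
  ev <- loo_evaluate(X, y, classifier_spec("lda"))
  expect_gte(ev$metrics[["AC"]], 0.4 - 1e-12)
  expect_lte(ev$metrics[["AC"]], 0.6 + 1e-12)
  expect_equal(sum(!is.na(ev$predictions)), 200)
})

test_that("in-package LDA agrees with the reference implementation without shrinkage", {
  skip_if_not_installed("MASS")
  set.seed(33)
  X <- matrix(rnorm(60 * 2), ncol = 2)
  y <- X[, 1] + 0.5 * X[, 2] + rnorm(60, 0, 0.8) > 0
  fit <- kneessm:::fit_gda(X, y, "lda", shrinkage = 0)
  ours <- kneessm:::predict_gda(fit, X)
  ref <- MASS::lda(X, grouping = y)
  theirs <- as.logical(stats::predict(ref, X)$class)
  expect_equal(ours, theirs)
})

test_that("confusion metrics handle degenerate classes explicitly", {
  expect_equal(unname(confusion_metrics(9, 1, 8, 2)), c(0.85, 0.9, 0.8))
  expect_warning(m <- confusion_metrics(0, 0, 10, 0), "sensitivity")
  expect_true(is.nan(m[["SE"]]))
  expect_equal(m[["AC"]], 1)
  expect_warning(m2 <- confusion_metrics(10, 0, 0, 0), "specificity")
  expect_equal(m2[["AC"]], 1)
  expect_equal(m2[["SE"]], 1)
  expect_true(is.nan(m2[["SP"]]))
  expect_error(confusion_metrics(-1, 0, 1, 0), "nonnegative")
})

test_that("logistic regression flags significance correctly on simulated data", {
  set.seed(34)
  # a feature unrelated to the labels is rarely significant
  hits <- vapply(1:10, function(i) {
    x <- matrix(rnorm(300), ncol = 1)
    y <- rep(c(TRUE, FALSE), 150)
    fit_logreg(x, y)$p[2] < 0.05
  }, logical(1))
  expect_lte(sum(hits), 2)
  # logit(p) = 2x is recovered
  set.seed(35)
  x <- rnorm(2000)
  y <- runif(2000) < plogis(2 * x)
  co <- fit_logreg(matrix(x, ncol = 1), y)
  expect_gt(co$estimate[2], 1.6)
  expect_lt(co$estimate[2], 2.4)
})

test_that("separation and collinearity fall back to ridge without crashing", {
  x <- c(rnorm(10, -5), rnorm(10, 5))
  y <- x > 0
  out <- fit_logreg(cbind(x, x), y)   # duplicated + separable
  expect_true(attr(out, "separation"))
  expect_true(attr(out, "collinear"))
  expect_true(all(is.finite(out$estimate)))
})

test_that("greedy mode selection finds separating features and matches exhaustive search", {
  set.seed(36)
  n <- 40
  y <- rep(c(TRUE, FALSE), n / 2)
  X <- matrix(rnorm(n * 5), ncol = 5)
  X[, 3] <- ifelse(y, 8, -8) + rnorm(n, 0, 0.1)  # perfectly separating
  sel <- select_modes(X, y, classifier_spec("lda"), k = 1)
  expect_equal(sel[1], 3L)
  # k = 2 greedy equals exhaustive search over all 10 pairs
  spec <- classifier_spec("qda")
  sel2 <- select_modes(X, y, spec, k = 2)
  acc_pair <- function(pair)
    loo_evaluate(X[, pair, drop = FALSE], y, spec)$metrics[["AC"]]
  pairs <- utils::combn(5, 2)
  best_exh <- max(apply(pairs, 2, acc_pair))
  expect_equal(acc_pair(sel2), best_exh, tolerance = 1e-12)
  # determinism
  expect_identical(as.integer(sel2),
                   as.integer(select_modes(X, y, spec, k = 2)))
})

test_that("rank-sum p-values match exhaustive enumeration and the approximation", {
  rs <- ranksum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$p, 0.1)
  expect_match(rs$method, "exact")
  expect_equal(ranksum_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  set.seed(37)
  for (i in 1:5) {
    a <- rnorm(5); b <- rnorm(6, 0.5)
    expect_equal(ranksum_test(a, b)$p, oracle_ranksum_p(a, b),
                 tolerance = 1e-12)
  }
  # exact vs normal approximation at nA = nB = 10
  a <- rnorm(10); b <- rnorm(10, 1)
  exact <- oracle_ranksum_p(a, b)
  approx <- ranksum_test(a, b)$p   # pooled n = 20 > exact_max
  expect_match(ranksum_test(a, b)$method, "approx")
  expect_lt(abs(exact - approx), 0.02)
  expect_error(ranksum_test(1:2, 1:5), "3 values")
})

test_that("Spearman correlation matches the rank-formula oracle and cor.test", {
  expect_equal(spearman_cor(1:8, 2 * (1:8))$c, 1)
  expect_equal(spearman_cor(1:8, -(1:8)^3)$c, -1)
  expect_equal(spearman_cor(1:8, -(1:8)^3)$p, 0)
  set.seed(38)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(6)
    got <- spearman_cor(x, y)
    expect_equal(got$c, oracle_spearman_c(x, y), tolerance = 1e-12)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(got$c, unname(ref$estimate), tolerance = 1e-12)
  }
  # ties: average ranks
  x <- c(1, 1, 2, 3, 3, 4)
  y <- c(2, 1, 2, 5, 4, 6)
  expect_equal(spearman_cor(x, y)$c, oracle_spearman_c(x, y), tolerance = 1e-12)
  expect_error(spearman_cor(1:3, 1:3), "4 pairs")
})

test_that("the analysis battery assembles a coherent, serialisable report", {
  set.seed(39)
  n <- 40
  hka <- c(rnorm(n / 2, 0, 1.2), rnorm(n / 2, 6, 1.5))
  W <- cbind(mov1 = as.numeric(scale(hka)) + rnorm(n, 0, 0.6),
             mov2 = rnorm(n), mov3 = rnorm(n), mov4 = rnorm(n))
  rownames(W) <- sprintf("s%02d", 1:n)
  angles <- data.frame(id = rownames(W), side = "right",
                       HKA = hka, FVV = rnorm(n, -6, 3), IER = rnorm(n, 0, 4),
                       TVV = rnorm(n, 0, 4), TS = rnorm(n, 7, 3.5))
  thr <- default_thresholds()
  for (v in thr$angle) {
    i <- match(v, thr$angle)
    angles[[paste0("unstable_", v)]] <-
      abs(angles[[v]] - thr$center[i]) > thr$half_width[i]
  }
  rep <- suppressWarnings(run_analysis(W, angles))
  # the informative mode drives HKA classification well above chance and
  # is flagged by the logistic fit
  expect_gt(rep$variables$HKA$qda$metrics[["AC"]], 0.7)
  expect_true(1 %in% rep$variables$HKA$significant_modes)
  expect_true(1 %in% rep$variables$HKA$qda_top3$modes)
  # Spearman table covers every mode x variable pair
  expect_equal(nrow(rep$spearman), 4 * 5)
  # mov1 correlates with corrected HKA deviation
  sc <- rep$spearman[rep$spearman$variable == "HKA" & rep$spearman$mode == 1, ]
  expect_lt(sc$p, 0.01)
  # lossless JSON round trip of the flat tables
  f <- withr::local_tempfile(fileext = ".json")
  write_report(rep, f)
  rep2 <- read_report(f)
  expect_equal(rep2$spearman$c, rep$spearman$c, tolerance = 1e-12)
  expect_equal(rep2$variables$HKA$qda$metrics, rep$variables$HKA$qda$metrics,
               tolerance = 1e-12)
  tabs <- report_tables(rep)
  expect_equal(nrow(tabs$classification), 15)
  expect_true(all(tabs$classification$AC >= 0 & tabs$classification$AC <= 1))
})

test_that("widened thresholds make everything stable and skip classification", {
  set.seed(40)
  W <- matrix(rnorm(30), ncol = 3)
  rownames(W) <- sprintf("s%d", 1:10)
  thr <- default_thresholds()
  thr$half_width <- rep(1e6, 5)
  angles <- data.frame(id = rownames(W), side = "right",
                       HKA = rnorm(10), FVV = rnorm(10, -6), IER = rnorm(10),
                       TVV = rnorm(10), TS = rnorm(10, 7))
  for (v in thr$angle) angles[[paste0("unstable_", v)]] <- FALSE
  expect_warning(rep <- run_analysis(W, angles, thr), "skipped")
  expect_true(all(vapply(rep$variables, `[[`, TRUE, "skipped")))
})

test_that("mismatched ids and missing columns are named errors", {
  W <- matrix(rnorm(20), ncol = 2)
  rownames(W) <- sprintf("a%d", 1:10)
  angles <- data.frame(id = sprintf("b%d", 1:10), HKA = rnorm(10))
  expect_error(run_analysis(W, angles), "lacks columns")
})
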