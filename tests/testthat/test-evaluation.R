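test_that("confusion counts and sensitivity/specificity", {
  cm <- confusion_from_counts(22, 199, 377, 6)
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 604)
  ss <- sens_spec(cm)
  expect_equal(ss[["sensitivity"]], 22 / 28)
  expect_equal(ss[["specificity"]], 377 / 576)
  expect_error(confusion_from_counts(0, 0, 0, 0), "empty")
  expect_error(confusion_from_counts(-1, 0, 1, 0), "non-negative")
  expect_equal(sens_spec(confusion_from_counts(5, 0, 5, 0)),
               c(sensitivity = 1, specificity = 1))
  expect_error(sens_spec(confusion_from_counts(0, 3, 2, 0)), "sensitivity")
})

test_that("a dichotomous rule's AUROC is (sens+spec)/2", {
  expect_equal(binary_rule_auroc(22 / 28, 377 / 576), 0.7201, tolerance = 5e-5)
  expect_equal(binary_rule_auroc(1, 1), 1)
  expect_equal(binary_rule_auroc(0.5, 0.5), 0.5)
  expect_error(binary_rule_auroc(1.2, 0.5), "\\[0, 1\\]")
  # identity against the U-statistic on 0/1 scores
  set.seed(17)
  for (i in 1:50) {
    y <- rbinom(40, 1, 0.4); s <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    cm <- confusion_from_predictions(s == 1, y == 1)
    if (cm$tp + cm$fn == 0 || cm$tn + cm$fp == 0) next
    ss <- sens_spec(cm)
    expect_equal(auroc_mann_whitney(s, y),
                 binary_rule_auroc(ss[["sensitivity"]], ss[["specificity"]]))
  }
})

test_that("Mann-Whitney AUROC: ties, separation, pair enumeration", {
  expect_equal(auroc_mann_whitney(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auroc_mann_whitney(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  # {pos: 3, 2; neg: 1, 2}: pairs (3>1)=1, (3>2)=1, (2>1)=1, (2==2)=0.5
  expect_equal(auroc_mann_whitney(c(3, 2, 1, 2), c(1, 1, 0, 0)), 3.5 / 4)
  expect_error(auroc_mann_whitney(1:4, rep(1, 4)), "both")
})

test_that("U-statistic equals the trapezoidal ROC area on random data", {
  trap <- function(scores, labels) {
    r <- roc_curve(scores, labels)
    o <- order(r$fpr, r$tpr)
    sum(diff(r$fpr[o]) * (head(r$tpr[o], -1) + tail(r$tpr[o], -1)) / 2)
  }
  set.seed(23)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- sample(1:8, n, replace = TRUE) + rnorm(n, 0, ifelse(i %% 2, 0, 0.3))
    expect_equal(auroc_mann_whitney(s, y), trap(s, y), tolerance = 1e-12)
  }
})

test_that("DeLong variance equals brute-force placement arithmetic", {
  s <- c(0.9, 0.7, 0.3, 0.8, 0.2, 0.7)
  y <- c(1, 1, 1, 0, 0, 0)
  res <- delong_ci(s, y)
  # brute-force placement values via explicit double loops
  pos <- s[y == 1]; neg <- s[y == 0]
  v10 <- sapply(pos, function(x) mean(ifelse(x > neg, 1, ifelse(x == neg, 0.5, 0))))
  v01 <- sapply(neg, function(x) mean(ifelse(pos > x, 1, ifelse(pos == x, 0.5, 0))))
  expect_equal(res$auroc, mean(v10), tolerance = 1e-12)
  expect_equal(res$var, var(v10) / 3 + var(v01) / 3, tolerance = 1e-12)
  expect_true(res$ci[["lo"]] <= res$auroc && res$auroc <= res$ci[["hi"]])

  # agreement with pROC's DeLong machinery on a larger instance
  set.seed(5)
  s2 <- rnorm(60); y2 <- rbinom(60, 1, 0.4)
  ours <- delong_ci(s2, y2)
  ref <- pROC::roc(y2, s2, direction = "<", quiet = TRUE)
  expect_equal(ours$auroc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(unname(ours$ci),
               as.numeric(pROC::ci.auc(ref, method = "delong"))[c(1, 3)],
               tolerance = 1e-9)
})

test_that("DeLong CI degenerate and level-0 behaviour", {
  s <- c(4, 3, 2, 1); y <- c(1, 1, 0, 0)
  res <- delong_ci(s, y)
  expect_equal(res$var, 0)
  expect_equal(unname(res$ci), c(1, 1))
  res0 <- delong_ci(c(0.9, 0.2, 0.7, 0.4, 0.6, 0.1), c(1, 0, 1, 0, 1, 0),
                    level = 0)
  expect_equal(unname(res0$ci), rep(res0$auroc, 2))
  expect_error(delong_ci(c(1, 2, 3), c(1, 0, 0)), "at least 2")
})

test_that("paired DeLong comparison: self, antisymmetry, brute force, pROC", {
  set.seed(29)
  y <- c(1, 1, 1, 0, 0, 0, 0, 1)
  a <- c(0.9, 0.6, 0.8, 0.4, 0.3, 0.6, 0.2, 0.7)
  b <- c(0.7, 0.5, 0.9, 0.6, 0.2, 0.4, 0.3, 0.5)

  self <- delong_compare(a, a, y)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)

  ab <- delong_compare(a, b, y); ba <- delong_compare(b, a, y)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)

  # brute-force covariance of placement vectors
  pl <- function(s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    list(v10 = sapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg))),
         v01 = sapply(neg, function(x) mean((pos > x) + 0.5 * (pos == x))))
  }
  pa <- pl(a); pb <- pl(b)
  vd <- (var(pa$v10) + var(pb$v10) - 2 * cov(pa$v10, pb$v10)) / 4 +
    (var(pa$v01) + var(pb$v01) - 2 * cov(pa$v01, pb$v01)) / 4
  z_exp <- (mean(pa$v10) - mean(pb$v10)) / sqrt(vd)
  expect_equal(ab$z, z_exp, tolerance = 1e-12)

  # cross-check with pROC's paired DeLong test
  s1 <- rnorm(80); s2 <- s1 + rnorm(80); yy <- rbinom(80, 1, 0.5)
  ours <- delong_compare(s1, s2, yy)
  ref <- pROC::roc.test(pROC::roc(yy, s1, direction = "<", quiet = TRUE),
                        pROC::roc(yy, s2, direction = "<", quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(abs(ours$z), abs(as.numeric(ref$statistic)), tolerance = 1e-9)
  expect_equal(ours$p, as.numeric(ref$p.value), tolerance = 1e-9)

  expect_error(delong_compare(a, b[-1], y), "equal-length")
})

test_that("Brier score arithmetic and bounds", {
  expect_equal(brier(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier(rep(0.5, 10), rbinom(10, 1, 0.5)), 0.25)
  expect_equal(brier(c(0.8, 0.2), c(1, 0)), 0.04)
  expect_error(brier(c(1.1, 0.5), c(1, 0)), "\\[0, 1\\]")
})

test_that("prevalence-calibrated score beats the constant forecast on Brier", {
  set.seed(41)
  score <- rnorm(400, 0, 2)
  y <- rbinom(400, 1, plogis(-2 + score))
  ic <- calibrate_intercept(score, mean(y))
  expect_lte(brier(plogis(ic + score), y), brier(rep(mean(y), 400), y))
})

test_that("bootstrap validation is seeded, reproducible, and sane", {
  set.seed(59)
  dat <- data.frame(x = rnorm(150))
  dat$alf <- rbinom(150, 1, plogis(-1 + 1.5 * dat$x)) == 1
  fixed_model <- function(train) function(newdata) plogis(newdata$x)

  r1 <- bootstrap_validate(dat, "alf", fixed_model, B = 30, seed = 7)
  r2 <- bootstrap_validate(dat, "alf", fixed_model, B = 30, seed = 7)
  expect_identical(r1, r2)
  r3 <- bootstrap_validate(dat, "alf", fixed_model, B = 30, seed = 8)
  expect_false(identical(r1$auroc$mean, r3$auroc$mean))

  expect_no_error(bootstrap_validate(dat, "alf", fixed_model, B = 1, seed = 1))
  expect_error(bootstrap_validate(dat, "alf", fixed_model, B = 30), "seed")

  # bootstrap mean AUROC of a fixed rule tracks the apparent AUROC
  expect_lt(abs(r1$auroc$mean - r1$apparent[["auroc"]]), 0.05)
  expect_true(r1$auroc$ci[["lo"]] <= r1$auroc$ci[["hi"]])
})

test_that("single-class resamples are redrawn, not dropped", {
  dat <- data.frame(x = c(rnorm(28), rnorm(2) + 3))
  dat$alf <- c(rep(FALSE, 28), rep(TRUE, 2))
  fixed_model <- function(train) function(newdata) plogis(newdata$x)
  r <- bootstrap_validate(dat, "alf", fixed_model, B = 50, seed = 3)
  expect_gt(r$redraws, 0)   # 2/30 events: single-class draws are common
  expect_length(r$auroc$mean, 1)
})
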