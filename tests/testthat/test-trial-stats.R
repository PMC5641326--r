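test_that("Tukey letters separate clearly different groups and only those", {
  set.seed(61)
  d <- data.frame(g = rep(c("a1", "a2", "b"), each = 10),
                  y = c(rnorm(10, 0, 0.1), rnorm(10, 0, 0.1), rnorm(10, 5, 0.1)))
  out <- anova_tukey(d, "y", "g")
  expect_equal(out$means$letters, c("a", "a", "b"))
  expect_lt(out$anova$p, 1e-10)
  # identical samples share one letter via the zero-variance fast path
  d2 <- data.frame(g = rep(c("x", "y", "z"), each = 3), y = rep(1, 9))
  out2 <- anova_tukey(d2, "y", "g")
  expect_equal(unique(out2$means$letters), "a")
  # two levels degenerate to a single pairwise comparison
  d3 <- data.frame(g = rep(c("u", "v"), each = 8), y = c(rnorm(8), rnorm(8, 4)))
  out3 <- anova_tukey(d3, "y", "g")
  expect_equal(out3$means$letters, c("a", "b"))
})

test_that("letter sharing matches the pairwise Tukey decisions on random fixtures", {
  set.seed(62)
  for (rep in 1:25) {
    k <- sample(3:6, 1)
    d <- data.frame(g = rep(paste0("L", seq_len(k)), each = 8),
                    y = rnorm(8 * k, mean = rep(runif(k, 0, 3), each = 8)))
    out <- anova_tukey(d, "y", "g")
    lv <- out$means$level
    shares <- function(a, b) {
      la <- strsplit(out$means$letters[out$means$level == a], "")[[1]]
      lb <- strsplit(out$means$letters[out$means$level == b], "")[[1]]
      length(intersect(la, lb)) > 0
    }
    for (i in seq_along(lv)) for (j in seq_along(lv)) {
      if (j <= i) next
      expect_equal(shares(lv[i], lv[j]), out$tukey[lv[i], lv[j]] >= 0.05,
                   info = sprintf("rep %d pair %s-%s", rep, lv[i], lv[j]))
    }
  }
})

test_that("levels with too few observations are excluded with a warning", {
  d <- data.frame(g = c(rep("a", 5), rep("b", 5), "c"), y = rnorm(11))
  expect_warning(out <- anova_tukey(d, "y", "g"), "excluding")
  expect_equal(out$means$level, c("a", "b"))
})

test_that("PCA on standardized traits has the documented structure", {
  set.seed(63)
  x <- rnorm(100)
  d <- data.frame(t1 = x, t2 = 2 * x + 3)  # perfectly collinear
  p <- pca_traits(d, c("t1", "t2"))
  expect_equal(p$explained[1], 1, tolerance = 1e-12)
  # isotropic data: shares approximately equal
  d2 <- as.data.frame(matrix(rnorm(10000 * 4), ncol = 4))
  p2 <- pca_traits(d2, names(d2))
  expect_true(all(abs(p2$explained - 0.25) < 0.02))
  # orthonormal loadings
  ltl <- t(p2$loadings) %*% p2$loadings
  expect_lt(max(abs(ltl - diag(4))), 1e-10)
  # sign convention: largest-magnitude loading positive
  expect_true(all(apply(p2$loadings, 2, function(v) v[which.max(abs(v))] > 0)))
  d3 <- data.frame(a = rnorm(20), b = rnorm(20), c = 1)
  expect_warning(p3 <- pca_traits(d3, c("a", "b", "c")), "constant")
  expect_equal(p3$traits, c("a", "b"))
})

test_that("correlation networks keep exactly the thresholded edges", {
  set.seed(64)
  n <- 90
  x <- rnorm(n)
  d <- data.frame(a = x, b = x + rnorm(n, 0, 0.3), c = rnorm(n), dup = x)
  net <- correlation_network(d)
  # duplicated column: edge with r = 1
  e <- net$edges
  expect_true(any(e$from == "a" & e$to == "dup" & abs(e$r - 1) < 1e-12))
  # brute-force double loop with cor.test as oracle
  traits <- names(d)
  want <- character(0)
  for (i in seq_along(traits)) for (j in seq_along(traits)) {
    if (j <= i) next
    ct <- suppressWarnings(cor.test(d[[traits[i]]], d[[traits[j]]]))
    if (!is.na(ct$estimate) && abs(ct$estimate) > 0.6 && ct$p.value < 0.001)
      want <- c(want, paste(traits[i], traits[j]))
  }
  expect_setequal(paste(e$from, e$to), want)
  # edge p-values agree with cor.test
  for (k in seq_len(nrow(e))) {
    ct <- cor.test(d[[e$from[k]]], d[[e$to[k]]])
    expect_equal(e$p[k], ct$p.value, tolerance = 1e-9)
  }
})

test_that("independent traits produce empty networks at the default thresholds", {
  set.seed(65)
  hits <- 0
  for (rep in 1:100) {
    d <- as.data.frame(matrix(rnorm(90 * 5), ncol = 5))
    hits <- hits + nrow(correlation_network(d)$edges)
  }
  expect_equal(hits, 0)
})

test_that("stepwise selection recovers a strong linear signal", {
  set.seed(66)
  n <- 50
  d <- data.frame(x1 = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                  n3 = rnorm(n), n4 = rnorm(n))
  d$y <- 3 + 2 * d$x1 + rnorm(n, 0, 0.01)
  fit <- stepwise_select(d, "y", c("x1", "n1", "n2", "n3", "n4"))
  expect_true("x1" %in% fit$predictors)
  expect_equal(unname(fit$coefficients["x1"]), 2, tolerance = 0.01)
  expect_equal(fit$intercept, 3, tolerance = 0.01)
  # zero-signal candidates with the strict p criterion: intercept-only model
  d$y0 <- rnorm(n)
  fit0 <- stepwise_select(d, "y0", c("n1", "n2", "n3", "n4"),
                          direction = "forward", criterion = "p",
                          p_enter = 0.001)
  expect_equal(length(fit0$predictors), 0)
  # perfectly collinear candidate is skipped with a warning
  d$x1b <- 2 * d$x1
  expect_warning(fitc <- stepwise_select(d, "y", c("x1", "x1b", "n1")),
                 "collinear")
  expect_false("x1b" %in% fitc$predictors)
})

test_that("LMG shares sum to R2 and match the brute-force oracle", {
  set.seed(67)
  n <- 60
  z <- rnorm(n)
  d <- data.frame(p1 = z + rnorm(n, 0, 0.5), p2 = z + rnorm(n, 0, 0.8),
                  p3 = rnorm(n))
  d$y <- d$p1 + 0.5 * d$p2 + 0.3 * d$p3 + rnorm(n, 0, 0.5)
  fit <- .fit <- lm(y ~ p1 + p2 + p3, data = d)
  mf <- model_fit_from_lm(fit, d, "y")
  expect_equal(sum(mf$variance_shares), mf$r2, tolerance = 1e-9)
  want <- oracle_lmg(d, "y", c("p1", "p2", "p3"))
  expect_equal(mf$variance_shares[names(want)], want, tolerance = 1e-12)
  expect_true(all(mf$variance_shares >= 0))
  # single predictor: share equals the model R2
  mf1 <- model_fit_from_lm(lm(y ~ p1, data = d), d, "y")
  expect_equal(unname(mf1$variance_shares), mf1$r2, tolerance = 1e-12)
})

test_that("orthogonal predictors get their marginal R2 as LMG share", {
  n <- 40
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, 1), each = n / 2)  # exactly orthogonal to x1
  set.seed(68)
  d <- data.frame(x1 = x1, x2 = x2)
  d$y <- x1 + 2 * x2 + rnorm(n, 0, 0.3)
  mf <- model_fit_from_lm(lm(y ~ x1 + x2, data = d), d, "y")
  r2_1 <- summary(lm(y ~ x1, data = d))$r.squared
  r2_2 <- summary(lm(y ~ x2, data = d))$r.squared
  expect_equal(unname(mf$variance_shares["x1"]), r2_1, tolerance = 1e-10)
  expect_equal(unname(mf$variance_shares["x2"]), r2_2, tolerance = 1e-10)
})

test_that("SEP is the residual standard error", {
  d <- data.frame(x = 1:10)
  d$y <- 2 * d$x + 1
  # suppress lm's "essentially perfect fit" note on the exact-fit fixture
  mf <- suppressWarnings(model_fit_from_lm(lm(y ~ x, data = d), d, "y"))
  expect_equal(mf$sep, 0, tolerance = 1e-10)       # perfect fit
  set.seed(69)
  d$y2 <- rnorm(10)
  mf0 <- model_fit_from_lm(lm(y2 ~ 1, data = d), d, "y2")
  expect_equal(mf0$sep, sd(d$y2), tolerance = 1e-12) # intercept-only: sample sd
  # arbitrary fixture: matches hand-computed residual SS
  d$y3 <- 1.5 * d$x + rnorm(10)
  lmfit <- lm(y3 ~ x, data = d)
  mf3 <- model_fit_from_lm(lmfit, d, "y3")
  expect_equal(mf3$sep, sqrt(sum(resid(lmfit)^2) / (10 - 2)), tolerance = 1e-12)
})

test_that("published model fixtures predict as printed", {
  fx <- yield_model_fixtures()
  ground <- fx$ground
  expect_equal(apply_model(unlist(ground$coefficients), ground$intercept,
                           data.frame(GGA_gr = 0)), 1.41)
  aerial <- fx$aerial
  expect_equal(apply_model(unlist(aerial$coefficients), aerial$intercept,
                           data.frame(WBI = 0, SAVI = 0)), -19.02)
  # affine property: prediction at the mean row = mean of predictions
  rows <- data.frame(WBI = c(0.9, 1.0, 1.1), SAVI = c(1.2, 1.4, 1.3))
  preds <- apply_model(unlist(aerial$coefficients), aerial$intercept, rows)
  mid <- apply_model(unlist(aerial$coefficients), aerial$intercept,
                     as.data.frame(t(colMeans(rows))))
  expect_equal(mean(preds), mid, tolerance = 1e-12)
  expect_error(apply_model(unlist(aerial$coefficients), aerial$intercept,
                           data.frame(WBI = 1)), "SAVI")
  # combined-model shares as printed sum to the printed r2 (within rounding)
  expect_equal(sum(unlist(fx$all$variance_shares)), fx$all$r2, tolerance = 0.001)
})

test_that("interaction ANOVA reports all three terms", {
  trial <- generate_trial(synthetic_config(seed = 9), rasters = FALSE)
  at <- anova_interaction(trial$design, "gy")
  expect_true(all(c("genotype", "treatment", "genotype:treatment") %in%
                  rownames(at)))
})
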