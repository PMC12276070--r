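test_that("standardization round-trips and is affine-invariant", {
  x <- cbind(a = c(2, 4, 6), b = c(1, 5, 9))
  s <- standardize(x)
  expect_equal(colMeans(s$z), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(s$z, 2, sd), c(a = 1, b = 1), tolerance = 1e-12)
  expect_equal(invert_standardizer(s, s$z), x, tolerance = 1e-12,
               ignore_attr = TRUE)
  # affine re-expression of the raw units leaves z-scores unchanged
  s2 <- standardize(cbind(a = 100 + 7 * x[, "a"], b = x[, "b"]))
  expect_equal(unname(s2$z), unname(s$z), tolerance = 1e-12)
  expect_error(standardize(cbind(a = rep(3, 5))), "a")
})

test_that("PMM leaves complete data untouched and stays on observed support", {
  cfg <- synthetic_config(n_control = 30, n_disease = 30, missing_rate = 0,
                          outlier_rate = 0, seed = 71)
  co <- generate_cohort(cfg)
  stack <- impute_pmm(co, m = 3, iterations = 2, seed = 1)
  for (d in stack$datasets)
    expect_equal(d$nfl, co$nfl, tolerance = 1e-12)

  cfg2 <- synthetic_config(n_control = 40, n_disease = 40,
                           missing_rate = 0.15, outlier_rate = 0, seed = 72)
  co2 <- generate_cohort(cfg2)
  stack2 <- impute_pmm(co2, m = 4, iterations = 5, seed = 2)
  for (m in stack2$markers) {
    obs <- co2[[m]][!is.na(co2[[m]])]
    for (d in stack2$datasets) {
      expect_false(anyNA(d[[m]]))
      expect_true(all(d[[m]][is.na(co2[[m]])] %in% obs))
    }
  }
  # deterministic given seed
  stack2b <- impute_pmm(co2, m = 4, iterations = 5, seed = 2)
  expect_identical(stack2$datasets, stack2b$datasets)
})

test_that("pooled means after MCAR masking recover pre-mask truth", {
  cfg <- synthetic_config(n_control = 150, n_disease = 150,
                          missing_rate = 0, outlier_rate = 0, seed = 73)
  full <- generate_cohort(cfg)
  masked <- full
  set.seed(5)
  pm <- plasma_markers(cfg$panel)
  for (m in pm) masked[[m]][runif(nrow(full)) < 0.15] <- NA
  stack <- impute_pmm(masked, m = 5, iterations = 5, seed = 3)
  for (m in pm) {
    pooled_mean <- mean(sapply(stack$datasets, function(d) mean(d[[m]])))
    se <- sd(full[[m]]) / sqrt(nrow(full))
    expect_lt(abs(pooled_mean - mean(full[[m]])), 3 * se)
  }
})

test_that("rank-1 data put all variance on PC1 with equal loadings", {
  set.seed(74)
  a <- rnorm(50)
  co <- make_cohort(cbind(x = a, y = 2 * a + 3), group = rep("YA", 50))
  stack <- structure(list(m = 1L, datasets = list(co),
                          markers = c("x", "y"), seed = 1L),
                     class = "imputed_stack")
  p <- pca_pooled(stack, n_components = 2, log_transform = "no")
  expect_equal(p$explained_variance_fraction[1], 1, tolerance = 1e-9)
  expect_equal(abs(unname(p$loadings[, 1])), rep(1 / sqrt(2), 2),
               tolerance = 1e-9)
})

test_that("pooling identical datasets equals a single-dataset PCA", {
  co <- generate_cohort(synthetic_config(n_control = 40, n_disease = 40,
                                         missing_rate = 0, outlier_rate = 0,
                                         seed = 75))
  stack <- impute_pmm(co, m = 4, iterations = 2, seed = 1)
  pooled <- pca_pooled(stack, n_components = 2, log_transform = "no")
  single <- prcomp(standardize(as.matrix(co[, stack$markers]))$z)
  ref <- single$rotation[, 1:2]
  for (cmp in 1:2) {
    v <- pooled$loadings[, cmp]
    r <- ref[, cmp]
    if (sum(v * r) < 0) r <- -r
    expect_equal(unname(v), unname(r), tolerance = 1e-8)
  }
  ev <- single$sdev^2 / sum(single$sdev^2)
  expect_equal(pooled$explained_variance_fraction, ev[1:2],
               tolerance = 1e-8)
})

test_that("a planted two-factor panel reproduces the loading structure", {
  set.seed(76)
  n <- 300
  neuro <- rnorm(n)         # shared neurodegeneration/tauopathy factor
  amyloid <- rnorm(n)       # independent amyloid factor
  pm <- c("abeta42_40", "ptau181", "ptau231", "nfl", "gfap")
  vals <- cbind(abeta42_40 = exp(0.9 * amyloid + 0.3 * rnorm(n)),
                ptau181 = exp(0.8 * neuro + 0.3 * rnorm(n)),
                ptau231 = exp(0.8 * neuro + 0.3 * rnorm(n)),
                nfl = exp(0.8 * neuro + 0.3 * rnorm(n)),
                gfap = exp(0.8 * neuro + 0.3 * rnorm(n)))
  panel <- do.call(rbind, lapply(pm, function(m)
    marker_def(m, "plasma", if (m == "abeta42_40") "decrease" else "increase")))
  co <- make_cohort(vals, group = rep(c("YA", "OA"), n / 2), panel = panel)
  stack <- impute_pmm(co, m = 2, iterations = 1, seed = 1)
  p <- pca_pooled(stack, n_components = 2)  # auto log applies
  L <- abs(p$loadings)
  expect_true(all(L[c("ptau181", "ptau231", "nfl", "gfap"), 1] >
                    L["abeta42_40", 1]))
  expect_true(all(L["abeta42_40", 2] >
                    L[c("ptau181", "ptau231", "nfl", "gfap"), 2]))
})

test_that("GAM reproduces a noiseless line and locates a logistic inflection", {
  age <- seq(20, 60, length.out = 80)
  y <- 2 + 0.5 * age
  fit <- fit_gam(age, y)
  expect_lt(max(abs(fit$fitted - (2 + 0.5 * fit$age_grid))), 1e-6)
  expect_equal(mean(fit$derivative), 0.5, tolerance = 1e-3)
  expect_true(all(fit$ci_lower <= fit$fitted & fit$fitted <= fit$ci_upper))

  set.seed(77)
  age2 <- runif(300, 20, 60)
  y2 <- trajectory_value(age2, 45, 4, "increase") + rnorm(300, 0, 0.05)
  fit2 <- fit_gam(age2, y2)
  expect_lt(abs(fit2$age_grid[which.max(fit2$derivative)] - 45), 2)
})

test_that("GAM confidence bands tighten with sample size", {
  gen <- function(n, seed) {
    set.seed(seed)
    age <- runif(n, 20, 60)
    fit_gam(age, sin(age / 8) + rnorm(n, 0, 0.3),
            age_grid = seq(25, 55, length.out = 50))
  }
  w50 <- mean(gen(50, 78)$ci_upper - gen(50, 78)$ci_lower)
  w500 <- mean(gen(500, 79)$ci_upper - gen(500, 79)$ci_lower)
  expect_lt(w500, w50)
})

test_that("LOESS at span 1 matches OLS on linear data and agrees with GAM", {
  set.seed(80)
  age <- runif(60, 20, 60)
  y <- 1 + 0.3 * age + rnorm(60, 0, 1e-8)
  fit <- fit_loess(age, y, span = 1)
  ols <- lm(y ~ age)
  pred <- predict(ols, data.frame(age = fit$age_grid))
  expect_lt(max(abs(fit$fitted - pred)), 1e-4)

  set.seed(81)
  age2 <- runif(600, 20, 60)
  y2 <- trajectory_value(age2, 45, 4, "increase") + rnorm(600, 0, 0.05)
  g <- fit_gam(age2, y2)
  l <- fit_loess(age2, y2, span = 0.5)
  expect_lt(abs(g$age_grid[which.max(g$derivative)] -
                  l$age_grid[which.max(l$derivative)]), 2)
  expect_error(fit_loess(age2[1:12], y2[1:12], span = 0.1), "span")
})

test_that("LOESS bands cover the true curve at honest rates", {
  set.seed(82)
  hits <- replicate(200, {
    age <- runif(120, 20, 60)
    truth <- trajectory_value(age, 42, 6, "increase")
    fit <- fit_loess(age, truth + rnorm(120, 0, 0.5), span = 0.5,
                     age_grid = seq(25, 55, length.out = 40))
    tr <- trajectory_value(fit$age_grid, 42, 6, "increase")
    mean(tr >= fit$ci_lower & tr <= fit$ci_upper)
  })
  expect_gt(mean(hits), 0.9)
})

test_that("Rubin pooling collapses to the single fit for identical inputs", {
  set.seed(83)
  age <- runif(60, 20, 60)
  y <- 0.1 * age + rnorm(60)
  f <- fit_gam(age, y)
  pooled <- pool_smooths(list(f, f, f))
  expect_equal(pooled$fitted, f$fitted, tolerance = 1e-12)
  expect_equal(pooled$se, f$se, tolerance = 1e-12)
})

test_that("composite z-score honours the amyloid inversion and missingness", {
  panel <- default_panel()
  pm <- plasma_markers(panel)
  set.seed(84)
  vals <- matrix(rnorm(40 * 9), 40, 9,
                 dimnames = list(NULL, panel$name))
  co <- make_cohort(vals, group = rep(c("YA", "OA"), 20), panel = panel)
  comp <- composite_z(co)
  z <- standardize(vals[, pm])$z
  manual <- rowSums(cbind(-z[, "abeta42_40"], z[, setdiff(pm, "abeta42_40")]))
  expect_equal(as.numeric(comp), manual, tolerance = 1e-10)
  # marker order irrelevant
  comp2 <- composite_z(co, plasma_markers = rev(pm))
  expect_equal(as.numeric(comp2), as.numeric(comp), tolerance = 1e-12)
  # all-missing participant flagged
  co2 <- co
  co2[3, pm] <- NA
  comp3 <- composite_z(co2)
  expect_true(is.na(comp3[3]))
  expect_equal(attr(comp3, "n_flagged"), 1L)
})

test_that("null cohorts give a near-zero mean composite", {
  co <- generate_cohort(synthetic_config(effect_size = 0, missing_rate = 0,
                                         outlier_rate = 0, id_effect = 0,
                                         n_control = 250, n_disease = 250,
                                         seed = 85))
  comp <- composite_z(co)
  expect_lt(abs(mean(comp)), 3 * sd(comp) / sqrt(length(comp)))
})

test_that("change-window detection brackets a logistic midpoint", {
  set.seed(86)
  age <- runif(400, 20, 60)
  y <- trajectory_value(age, 45, 4, "increase") + rnorm(400, 0, 0.05)
  w <- max_change_window(fit_loess(age, y))
  expect_gte(w$peak_age, 43)
  expect_lte(w$peak_age, 47)
  expect_true(w$start_age <= 45 && 45 <= w$end_age)
})

test_that("a linear trend yields a full-grid window and shifts equivariantly", {
  set.seed(87)
  age <- runif(200, 20, 60)
  y <- 0.2 * age + rnorm(200, 0, 1e-6)
  f <- fit_loess(age, y, span = 1)
  w <- max_change_window(f)
  expect_equal(w$start_age, min(f$age_grid))
  expect_equal(w$end_age, max(f$age_grid))

  set.seed(88)
  age2 <- runif(300, 20, 60)
  y2 <- trajectory_value(age2, 40, 4, "increase") + rnorm(300, 0, 0.05)
  grid <- seq(22, 58, length.out = 80)
  w1 <- max_change_window(fit_loess(age2, y2, age_grid = grid))
  w2 <- max_change_window(fit_loess(age2 + 5, y2, age_grid = grid + 5))
  expect_equal(w2$peak_age - w1$peak_age, 5, tolerance = 1)
  expect_equal(w2$start_age - w1$start_age, 5, tolerance = 1)

  set.seed(89)
  age3 <- runif(100, 20, 60)
  fdec <- fit_loess(age3, -0.2 * age3 + rnorm(100, 0, 1e-8), span = 1)
  expect_warning(wflat <- max_change_window(fdec), "not positive")
  expect_true(is.na(wflat$peak_age))
})
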