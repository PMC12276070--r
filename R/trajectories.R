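# Age-trajectory arm: PMM multiple imputation, Rubin-pooled PCA, GAM/LOESS
# smooths with confidence bands, composite z-score, maximal-change window.

#' Column-wise standardization with stored parameters
#'
#' Centers and scales each column to mean 0, SD 1 on its observed cells, and
#' keeps the transform parameters so the identical transform can be reused
#' (e.g. across imputed datasets) and inverted.
#'
#' @param x Numeric matrix or data frame of marker columns (missing allowed).
#' @return Object of class `"standardizer"`: `z` (standardized matrix),
#'   `center`, `scale`.
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  if (any(colSums(!is.na(x)) < 2L))
    stop("standardize: every column needs >= 2 non-missing values")
  ctr <- colMeans(x, na.rm = TRUE)
  scl <- apply(x, 2, sd, na.rm = TRUE)
  zero <- scl < 1e-12
  if (any(zero))
    stop("standardize: zero variance in column(s): ",
         paste(colnames(x)[zero], collapse = ", "))
  structure(list(z = sweep(sweep(x, 2, ctr), 2, scl, "/"),
                 center = ctr, scale = scl),
            class = "standardizer")
}

#' @rdname standardize
#' @param obj A `"standardizer"`.
#' @param newdata Matrix/data frame with the same columns, to transform with
#'   the stored parameters.
#' @export
apply_standardizer <- function(obj, newdata) {
  stopifnot(inherits(obj, "standardizer"))
  x <- as.matrix(newdata)[, names(obj$center), drop = FALSE]
  sweep(sweep(x, 2, obj$center), 2, obj$scale, "/")
}

#' @rdname standardize
#' @param z Standardized matrix to map back to the original scale.
#' @export
invert_standardizer <- function(obj, z) {
  stopifnot(inherits(obj, "standardizer"))
  sweep(sweep(as.matrix(z), 2, obj$scale, "*"), 2, obj$center, "+")
}

#' Multiple imputation by chained-equations predictive mean matching
#'
#' Fills missing marker cells by PMM: each incomplete marker is regressed (on
#' its complete cases) on all other markers plus age, group and ID level;
#' every missing cell then receives the observed value of one of the
#' `donors` complete cases whose prediction is nearest its own, chosen at
#' random. Markers are visited cyclically for `iterations` sweeps, and the
#' whole procedure is repeated independently `m` times. Imputed values are
#' always members of the observed support of their column.
#'
#' @param cohort A cohort data frame.
#' @param m Number of imputed datasets (>= 2 for pooling).
#' @param iterations Chained-equation sweeps per dataset.
#' @param donors Donor-pool size for matching.
#' @param markers Markers to impute/use as predictors; defaults to the
#'   panel's plasma markers (the PCA arm's inputs).
#' @param seed Integer seed; deterministic given the seed.
#' @return Object of class `"imputed_stack"`: `m`, `datasets` (list of
#'   complete cohort copies), `markers`, `seed`.
#' @export
impute_pmm <- function(cohort, m = 10L, iterations = 10L, donors = 5L,
                       markers = NULL, seed = 1L) {
  panel <- cohort_panel(cohort)
  if (is.null(markers)) markers <- plasma_markers(panel)
  stopifnot(m >= 1L, iterations >= 1L, donors >= 1L)
  vals <- marker_matrix(cohort, markers)
  miss <- is.na(vals)
  incomplete <- colnames(vals)[colSums(miss) > 0]
  for (v in incomplete) {
    if (sum(!miss[, v]) < donors)
      stop("impute_pmm: marker '", v, "' has fewer complete cases (",
           sum(!miss[, v]), ") than donors (", donors, ")")
  }
  covars <- cbind(age = cohort$age,
                  oa = as.numeric(cohort$group == "OA"),
                  moderate = as.numeric(cohort$id_level == "moderate"))
  set.seed(seed)
  datasets <- vector("list", m)
  for (d in seq_len(m)) {
    cur <- vals
    # initialize missing cells from random observed values of the column
    for (v in incomplete) {
      obs <- cur[!miss[, v], v]
      cur[miss[, v], v] <- sample(obs, sum(miss[, v]), replace = TRUE)
    }
    if (length(incomplete)) {
      for (it in seq_len(iterations)) {
        for (v in incomplete) {
          X <- cbind(1, covars, cur[, setdiff(colnames(cur), v), drop = FALSE])
          yobs <- !miss[, v]
          beta <- qr.coef(qr(X[yobs, , drop = FALSE]), vals[yobs, v])
          beta[is.na(beta)] <- 0
          pred <- drop(X %*% beta)
          pobs <- pred[yobs]
          vobs <- vals[yobs, v]
          for (i in which(miss[, v])) {
            nn <- order(abs(pobs - pred[i]))[seq_len(donors)]
            cur[i, v] <- vobs[nn[sample.int(donors, 1L)]]
          }
        }
      }
    }
    dat <- cohort
    for (v in colnames(cur)) dat[[v]] <- cur[, v]
    datasets[[d]] <- dat
  }
  structure(list(m = m, datasets = datasets, markers = markers, seed = seed),
            class = "imputed_stack")
}

# Per-dataset marker matrix after optional log transform and the z-scoring
# the PCA arm requires. log_transform: "auto" logs only if all observed raw
# values are positive.
prepare_pca_matrix <- function(dat, markers, log_transform) {
  x <- marker_matrix(dat, markers)
  do_log <- switch(log_transform,
                   yes = TRUE, no = FALSE,
                   auto = all(x > 0, na.rm = TRUE))
  if (do_log && any(x <= 0, na.rm = TRUE))
    stop("pca_pooled: log transform requested but non-positive values in ",
         paste(markers[colSums(x <= 0, na.rm = TRUE) > 0], collapse = ", "))
  if (do_log) x <- log(x)
  standardize(x)$z
}

#' PCA pooled across imputed datasets
#'
#' Within each imputed dataset the plasma markers are (optionally)
#' log-transformed, standardized to zero mean and unit variance, and
#' decomposed by PCA. Because eigenvectors are defined only up to sign, each
#' dataset's components are flipped to align with the first dataset's before
#' loadings and explained-variance fractions are averaged; pooled loading
#' columns are renormalized to unit Euclidean norm.
#'
#' @param stack An [impute_pmm()] stack (a single complete cohort also
#'   works: pass a stack of `m = 1`).
#' @param markers Markers to decompose; defaults to the stack's markers.
#' @param n_components Components to retain (default 2).
#' @param log_transform `"auto"` (default: log when all observed values are
#'   positive), `"yes"`, or `"no"`.
#' @return Object of class `"pca_pooled"`: `loadings` (markers x components,
#'   pooled, unit-norm columns), `explained_variance_fraction`,
#'   `n_components`, `log_applied`, `per_dataset` (list of per-dataset
#'   loadings).
#' @export
pca_pooled <- function(stack, markers = NULL, n_components = 2L,
                       log_transform = c("auto", "yes", "no")) {
  log_transform <- match.arg(log_transform)
  stopifnot(inherits(stack, "imputed_stack"))
  if (is.null(markers)) markers <- stack$markers
  if (n_components > length(markers))
    stop("pca_pooled: n_components exceeds number of markers")
  if (log_transform == "auto") {
    allpos <- all(vapply(stack$datasets, function(dat)
      all(marker_matrix(dat, markers) > 0, na.rm = TRUE), logical(1)))
    log_transform <- if (allpos) "yes" else "no"
  }
  per <- lapply(stack$datasets, function(dat) {
    z <- prepare_pca_matrix(dat, markers, log_transform)
    p <- prcomp(z, center = FALSE, scale. = FALSE)
    list(loadings = p$rotation[, seq_len(n_components), drop = FALSE],
         expl = (p$sdev^2 / sum(p$sdev^2))[seq_len(n_components)])
  })
  ref <- per[[1]]$loadings
  aligned <- lapply(per, function(pd) {
    L <- pd$loadings
    for (cmp in seq_len(n_components)) {
      dp <- sum(L[, cmp] * ref[, cmp])
      if (abs(dp) < 1e-8)
        warning("pca_pooled: component ", cmp,
                " nearly orthogonal across imputations; sign alignment ",
                "unreliable")
      if (dp < 0) L[, cmp] <- -L[, cmp]
    }
    L
  })
  pooled <- Reduce(`+`, aligned) / length(aligned)
  pooled <- sweep(pooled, 2, sqrt(colSums(pooled^2)), "/")
  expl <- Reduce(`+`, lapply(per, `[[`, "expl")) / length(per)
  dimnames(pooled) <- list(markers, paste0("PC", seq_len(n_components)))
  structure(list(loadings = pooled,
                 explained_variance_fraction = unname(expl),
                 n_components = n_components,
                 log_applied = log_transform == "yes",
                 per_dataset = aligned),
            class = "pca_pooled")
}

#' Per-dataset principal-component scores
#'
#' Projects each imputed dataset's standardized (and, matching the pooled
#' fit, optionally log-transformed) marker matrix onto the pooled loadings.
#'
#' @param stack An [impute_pmm()] stack.
#' @param pca A [pca_pooled()] fit.
#' @param markers Markers; default the loadings' rownames.
#' @return List of score matrices (participants x components), one per
#'   imputed dataset.
#' @export
pc_scores <- function(stack, pca, markers = rownames(pca$loadings)) {
  log_transform <- if (pca$log_applied) "yes" else "no"
  lapply(stack$datasets, function(dat)
    prepare_pca_matrix(dat, markers, log_transform) %*% pca$loadings)
}

new_smooth_fit <- function(age_grid, fitted, se, method, span_or_df,
                           level = 0.95) {
  zc <- qnorm(1 - (1 - level) / 2)
  d <- c(diff(fitted) / diff(age_grid), NA)
  d[length(d)] <- d[length(d) - 1L]
  structure(list(age_grid = age_grid, fitted = fitted,
                 ci_lower = fitted - zc * se, ci_upper = fitted + zc * se,
                 se = se, derivative = d, method = method,
                 span_or_df = span_or_df, level = level),
            class = "smooth_fit")
}

default_grid <- function(age, n_grid) seq(min(age), max(age),
                                          length.out = n_grid)

#' Penalized-spline GAM smooth of a response on age
#'
#' Fits `y ~ s(age)` with a cubic regression spline basis and a
#' second-derivative penalty, smoothing parameter chosen by generalized
#' cross-validation ([mgcv::gam()]). Returns the fitted curve on an age
#' grid with a pointwise confidence band from the smoother's covariance and
#' a finite-difference derivative (per-year rate of change).
#'
#' @param age Ages (years); at least 10 points spanning >= 10 years.
#' @param y Response values.
#' @param age_grid Evaluation grid; default `n_grid` equispaced points over
#'   the observed age range.
#' @param n_grid Grid size (default 100).
#' @param k Spline basis dimension (default 8).
#' @param level Confidence level for the band (default 0.95).
#' @return A `"smooth_fit"`: `age_grid`, `fitted`, `ci_lower`, `ci_upper`,
#'   `se`, `derivative`, `method`, `span_or_df` (effective df).
#' @export
fit_gam <- function(age, y, age_grid = NULL, n_grid = 100L, k = 8L,
                    level = 0.95) {
  ok <- !is.na(age) & !is.na(y)
  age <- age[ok]; y <- y[ok]
  if (length(y) < 10L) stop("fit_gam: need >= 10 points")
  if (diff(range(age)) < 10) stop("fit_gam: ages must span >= 10 years")
  if (is.null(age_grid)) age_grid <- default_grid(age, n_grid)
  fit <- mgcv::gam(y ~ s(age, k = k, bs = "cr"), method = "GCV.Cp")
  pr <- predict(fit, newdata = data.frame(age = age_grid), se.fit = TRUE)
  new_smooth_fit(age_grid, as.numeric(pr$fit), as.numeric(pr$se.fit),
                 "gam", sum(fit$edf), level)
}

#' LOESS smooth of z-scored values on age
#'
#' Local linear regression with tricube weights ([stats::loess()],
#' `degree = 1`). The confidence band is `fitted +/- z * SE`, with the
#' standard error derived from the residual variance and the local weight
#' vector; the derivative is by finite differences on the grid.
#'
#' @param age Ages (years); at least 10 points.
#' @param z Response (typically a z-scored marker or composite).
#' @param span LOESS span in (0, 1]; default 0.75.
#' @inheritParams fit_gam
#' @return A `"smooth_fit"` with `method = "loess"` and
#'   `span_or_df = span`.
#' @export
fit_loess <- function(age, z, span = 0.75, age_grid = NULL, n_grid = 100L,
                      level = 0.95) {
  ok <- !is.na(age) & !is.na(z)
  age <- age[ok]; z <- z[ok]
  if (length(z) < 10L) stop("fit_loess: need >= 10 points")
  if (span <= 0 || span > 1) stop("fit_loess: span must be in (0, 1]")
  if (floor(span * length(z)) < 4L)
    stop("fit_loess: span too small for local neighborhoods at n = ",
         length(z))
  if (is.null(age_grid)) age_grid <- default_grid(age, n_grid)
  fit <- loess(z ~ age, span = span, degree = 1, family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  pr <- predict(fit, newdata = data.frame(age = age_grid), se = TRUE)
  new_smooth_fit(age_grid, as.numeric(pr$fit), as.numeric(pr$se.fit),
                 "loess", span, level)
}

#' Pool smooth fits across imputed datasets by Rubin's rules
#'
#' Combines per-dataset curves evaluated on a common age grid: the pooled
#' curve is the mean of the per-dataset fits, and its variance at each grid
#' point is the within-imputation variance plus `(1 + 1/m)` times the
#' between-imputation variance.
#'
#' @param fits List of `"smooth_fit"` objects on identical grids.
#' @return A pooled `"smooth_fit"`.
#' @export
pool_smooths <- function(fits) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "smooth_fit")))
  g <- fits[[1]]$age_grid
  for (f in fits) stopifnot(isTRUE(all.equal(f$age_grid, g)))
  m <- length(fits)
  Q <- vapply(fits, `[[`, numeric(length(g)), "fitted")
  U <- vapply(fits, function(f) f$se^2, numeric(length(g)))
  if (m == 1L) {
    qbar <- drop(Q); tvar <- drop(U)
  } else {
    qbar <- rowMeans(Q)
    B <- apply(Q, 1, var)
    tvar <- rowMeans(U) + (1 + 1 / m) * B
  }
  new_smooth_fit(g, qbar, sqrt(tvar), fits[[1]]$method,
                 mean(vapply(fits, `[[`, numeric(1), "span_or_df")),
                 fits[[1]]$level)
}

#' Pathology-aligned composite z-score
#'
#' Standardizes each plasma marker over the cohort and sums the z-scores,
#' with markers listed in `invert` (by default the amyloid-beta 42/40 ratio,
#' which falls with pathology) multiplied by -1 so all markers point in the
#' direction of disease. Missing cells are handled by rescaling the mean of
#' the available z-scores to the full marker count (`na_action = "scale"`)
#' or by returning `NA` for incomplete participants (`"exclude"`).
#'
#' @param cohort A cohort data frame.
#' @param plasma_markers Markers to combine; default the panel's plasma
#'   markers.
#' @param invert Markers whose z-score is sign-flipped.
#' @param na_action `"scale"` (default) or `"exclude"`.
#' @return Numeric vector (one composite per participant, `NA` where no
#'   contributing marker is observed) with attribute `"n_flagged"` counting
#'   participants with no plasma values.
#' @export
composite_z <- function(cohort, plasma_markers = NULL,
                        invert = "abeta42_40",
                        na_action = c("scale", "exclude")) {
  na_action <- match.arg(na_action)
  panel <- cohort_panel(cohort)
  if (is.null(plasma_markers)) plasma_markers <- plasma_markers(panel)
  stopifnot(all(invert %in% plasma_markers))
  z <- standardize(marker_matrix(cohort, plasma_markers))$z
  z[, invert] <- -z[, invert]
  K <- ncol(z)
  n_obs <- rowSums(!is.na(z))
  comp <- switch(na_action,
                 scale = rowMeans(z, na.rm = TRUE) * K,
                 exclude = rowSums(z))
  comp[n_obs == 0] <- NA_real_
  if (na_action == "exclude") comp[n_obs < K] <- NA_real_
  structure(comp, n_flagged = sum(n_obs == 0))
}

#' Window of maximal rate of change of a smooth
#'
#' Locates the age at which the smooth's derivative peaks and the maximal
#' contiguous grid interval containing that peak over which the derivative
#' stays at or above `criterion` times the peak rate. This identifies the
#' age range in which a biomarker (or composite) changes fastest.
#'
#' @param fit A `"smooth_fit"`.
#' @param criterion Fraction of the peak rate defining the window (default
#'   0.5).
#' @return Object of class `"change_window"`: `start_age`, `peak_age`,
#'   `end_age`, `peak_rate`, `criterion`. All-`NA` (with a warning) when the
#'   peak derivative is not positive.
#' @export
max_change_window <- function(fit, criterion = 0.5) {
  stopifnot(inherits(fit, "smooth_fit"), criterion > 0, criterion <= 1)
  d <- fit$derivative
  ipk <- which.max(d)
  if (!is.finite(d[ipk]) || d[ipk] <= 0) {
    warning("max_change_window: peak derivative is not positive; ",
            "empty window returned")
    return(structure(list(start_age = NA_real_, peak_age = NA_real_,
                          end_age = NA_real_, peak_rate = d[ipk],
                          criterion = criterion), class = "change_window"))
  }
  above <- d >= criterion * d[ipk]
  lo <- ipk
  while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- ipk
  while (hi < length(d) && above[hi + 1L]) hi <- hi + 1L
  structure(list(start_age = fit$age_grid[lo],
                 peak_age = fit$age_grid[ipk],
                 end_age = fit$age_grid[hi],
                 peak_rate = d[ipk], criterion = criterion),
            class = "change_window")
}

#' @export
print.change_window <- function(x, ...) {
  cat(sprintf(
    "change window: ages %.1f-%.1f (peak %.1f, rate %.3g/yr, >= %d%% of peak)\n",
    x$start_age, x$end_age, x$peak_age, x$peak_rate,
    round(100 * x$criterion)))
  invisible(x)
}
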