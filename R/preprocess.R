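#' Flag gross outliers by the 1.5 x IQR rule
#'
#' Flags values lying below `Q1 - k * IQR` or above `Q3 + k * IQR`. Quartiles
#' use linear interpolation between order statistics
#' (`stats::quantile(type = 7)`) by default; the convention is configurable
#' because flagged counts can shift for values at the fence. Missing values
#' are never flagged.
#'
#' @param values Numeric vector (missing allowed); at least 4 non-missing
#'   values are required.
#' @param k Fence multiplier (default 1.5).
#' @param type Quantile type passed to [stats::quantile()].
#' @return Logical vector the length of `values`; `TRUE` marks an outlier.
#' @export
iqr_outlier_mask <- function(values, k = 1.5, type = 7) {
  obs <- values[!is.na(values)]
  if (length(obs) < 4L)
    stop("iqr_outlier_mask needs at least 4 non-missing values (got ",
         length(obs), "); quartiles would be meaningless")
  q <- quantile(obs, c(0.25, 0.75), type = type, names = FALSE)
  iqr <- q[2] - q[1]
  !is.na(values) & (values < q[1] - k * iqr | values > q[2] + k * iqr)
}

#' Cell-wise IQR outlier exclusion
#'
#' Applies [iqr_outlier_mask()] to each requested marker column and sets the
#' flagged cells to missing. Exclusion is cell-wise, not participant-wise:
#' per-marker sample sizes shrink but participants are retained, and the
#' event-based model marginalizes over the resulting missing cells.
#'
#' @param cohort A cohort data frame.
#' @param markers Markers to screen; defaults to the panel's plasma markers
#'   (gross assay outliers are a plasma phenomenon here).
#' @param k,type Passed to [iqr_outlier_mask()].
#' @return List with `cohort` (flagged cells set to `NA`) and `counts`
#'   (named integer vector of excluded cells per marker).
#' @export
apply_iqr_exclusion <- function(cohort, markers = NULL, k = 1.5, type = 7) {
  panel <- cohort_panel(cohort)
  if (is.null(markers)) markers <- plasma_markers(panel)
  counts <- setNames(integer(length(markers)), markers)
  for (m in markers) {
    mask <- iqr_outlier_mask(cohort[[m]], k = k, type = type)
    counts[m] <- sum(mask)
    cohort[[m]][mask] <- NA_real_
  }
  list(cohort = cohort, counts = counts)
}

#' Fit a control-anchored ID-level residualizer
#'
#' Regresses a marker on the intellectual-disability level indicator
#' (mild = 0, moderate = 1) using younger-adult (YA) rows only, so that the
#' adjustment captures baseline-ability differences uncontaminated by
#' disease. The fitted coefficients are then applied to all rows:
#' `residual = value - intercept - slope * moderate`. Older-adult residuals
#' therefore retain any disease-related shift.
#'
#' @param cohort A cohort data frame.
#' @param marker Marker name.
#' @return An object of class `"id_residualizer"` with fields `marker`,
#'   `intercept`, `slope`.
#' @export
fit_id_residualizer <- function(cohort, marker) {
  validate_cohort(cohort)
  ya <- cohort$group == "YA" & !is.na(cohort[[marker]])
  y <- cohort[[marker]][ya]
  mod <- as.numeric(cohort$id_level[ya] == "moderate")
  if (length(y) < 3L)
    stop("fit_id_residualizer('", marker,
         "'): need >= 3 non-missing YA values, got ", length(y))
  if (length(unique(mod)) < 2L) {
    warning("fit_id_residualizer('", marker,
            "'): only one ID level in YA; intercept-only model")
    fit <- list(intercept = mean(y), slope = 0)
  } else {
    co <- coef(lm(y ~ mod))
    fit <- list(intercept = unname(co[1]), slope = unname(co[2]))
  }
  structure(c(list(marker = marker), fit), class = "id_residualizer")
}

#' Apply an ID-level residualizer
#'
#' @param model An `"id_residualizer"` from [fit_id_residualizer()].
#' @param cohort A cohort data frame (any rows, YA or OA).
#' @return Numeric vector of residuals (missing where the marker is missing).
#' @export
id_residuals <- function(model, cohort) {
  stopifnot(inherits(model, "id_residualizer"))
  mod <- as.numeric(cohort$id_level == "moderate")
  cohort[[model$marker]] - model$intercept - model$slope * mod
}

#' Residualize all markers of a cohort for ID level
#'
#' @param cohort A cohort data frame.
#' @param markers Marker names; defaults to the full panel.
#' @return The cohort with marker columns replaced by YA-anchored ID-level
#'   residuals; the fitted residualizers are attached as attribute
#'   `"residualizers"`.
#' @export
residualize_cohort <- function(cohort, markers = NULL) {
  panel <- cohort_panel(cohort)
  if (is.null(markers)) markers <- panel$name
  models <- lapply(markers, function(m) fit_id_residualizer(cohort, m))
  names(models) <- markers
  for (m in markers) cohort[[m]] <- id_residuals(models[[m]], cohort)
  attr(cohort, "residualizers") <- models
  cohort
}

#' Kruskal-Wallis screen of group differences, controlling for ID level
#'
#' For each marker, computes the Kruskal-Wallis rank statistic (tie-corrected,
#' chi-square reference with 1 df for two groups) comparing YA vs OA, by
#' default on YA-anchored ID-level residuals so that baseline-ability
#' differences do not masquerade as disease signal. Markers with `p < alpha`
#' are selected as event-based-model inputs.
#'
#' @param cohort A cohort data frame.
#' @param alpha Significance level (default 0.05, no multiplicity
#'   adjustment).
#' @param markers Marker names; defaults to the full panel.
#' @param residualize If `TRUE` (default) test ID-residualized values; if
#'   `FALSE`, raw values.
#' @return A data frame of class `"screen_result"` with columns `marker`,
#'   `H`, `p_value`, `n`, `selected`.
#' @export
kruskal_wallis_screen <- function(cohort, alpha = 0.05, markers = NULL,
                                  residualize = TRUE) {
  panel <- cohort_panel(cohort)
  if (is.null(markers)) markers <- panel$name
  dat <- if (residualize) residualize_cohort(cohort, markers) else cohort
  rows <- lapply(markers, function(m) {
    x <- dat[[m]]
    ok <- !is.na(x)
    if (sum(ok & dat$group == "YA") < 2L || sum(ok & dat$group == "OA") < 2L) {
      warning("kruskal_wallis_screen: marker '", m,
              "' skipped (a group has < 2 non-missing values)")
      return(NULL)
    }
    kt <- kruskal.test(x[ok], factor(dat$group[ok]))
    data.frame(marker = m, H = unname(kt$statistic),
               p_value = unname(kt$p.value), n = sum(ok),
               selected = unname(kt$p.value) < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Exclude participants with excessive cognitive missingness
#'
#' Mirrors a cohort-assembly rule in which participants missing at least a
#' given fraction of their cognitive battery are excluded before analysis.
#'
#' @param cohort A cohort data frame.
#' @param max_missing_frac Exclusion threshold: participants with a missing
#'   fraction `>=` this value (default 0.75) are dropped.
#' @param markers Markers over which missingness is computed; defaults to the
#'   panel's cognitive markers.
#' @return List with `cohort` (retained rows), `n_in`, `n_excluded`, `n_out`.
#' @export
filter_participants <- function(cohort, max_missing_frac = 0.75,
                                markers = NULL) {
  panel <- cohort_panel(cohort)
  if (is.null(markers)) markers <- cognitive_markers(panel)
  mm <- marker_matrix(cohort, markers)
  frac <- rowMeans(is.na(mm))
  keep <- frac < max_missing_frac
  list(cohort = cohort[keep, , drop = FALSE],
       n_in = nrow(cohort), n_excluded = sum(!keep), n_out = sum(keep))
}
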