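#' Fit a constrained normal/abnormal Gaussian mixture to one marker
#'
#' The event-based model needs, for every marker, a density for measurements
#' in the normal (pre-event) state and one for the abnormal (post-event)
#' state. These are estimated as a two-component Gaussian mixture on the
#' pooled sample under three constraints that make the fit identifiable at
#' cohort-scale n:
#'
#' * the normal component is anchored to the control-group (YA) moments --
#'   controls pin the normal density reliably, whereas a freely re-estimated
#'   normal component lets the mixture collapse onto the bulk of the data;
#' * the abnormal mean must lie on the pathological side of the normal mean
#'   (per the marker's `direction`) and at least `min_separation` control
#'   SDs away from it -- mirroring the convention of calling a measurement
#'   abnormal when it deviates by 1.5 SD or more, and preventing the
#'   weakly-identified low-prevalence (late-event) fits from collapsing into
#'   a second copy of the normal component;
#' * the abnormal SD equals the normal SD by default
#'   (`equal_variances = TRUE`); with `equal_variances = FALSE` it is free
#'   up to the normal SD.
#'
#' The abnormal displacement and mixing weight are then estimated by
#' maximum likelihood (multi-start Nelder-Mead; deterministic). If the
#' optimum is degenerate -- the abnormal weight collapsing to 0 or 1, as
#' happens in the zero-separation limit where the groups are
#' indistinguishable -- the fit falls back to the group-label
#' plug-in estimates (YA moments for normal, OA moments for abnormal) and is
#' flagged, which with indistinguishable groups leaves the two components
#' nearly coincident and the event likelihood uninformative.
#'
#' @param values Numeric marker values (missing allowed, dropped).
#' @param group_labels Character vector (`"YA"`/`"OA"`), same length.
#' @param direction Direction of pathological change.
#' @param marker Marker name, used in error messages.
#' @param min_separation Minimum abnormal-mean displacement, in control-SD
#'   units (default 1.5).
#' @param equal_variances If `TRUE` (default) the abnormal SD is tied to the
#'   normal SD.
#' @param max_iter Optimizer iteration cap per start.
#' @return Object of class `"mixture_fit"`: `marker`, `normal_mean`,
#'   `normal_sd`, `abnormal_mean`, `abnormal_sd`, `mixing_weight` (fraction
#'   abnormal), `direction`, `fallback`, `loglik`.
#' @export
fit_mixture <- function(values, group_labels,
                        direction = c("increase", "decrease"),
                        marker = "", min_separation = 1.5,
                        equal_variances = TRUE, max_iter = 2000L) {
  direction <- match.arg(direction)
  ok <- !is.na(values)
  x <- values[ok]
  g <- group_labels[ok]
  if (sum(g == "YA") < 5L || sum(g == "OA") < 5L)
    stop("fit_mixture('", marker,
         "'): need >= 5 non-missing values per group")
  if (var(x) < 1e-12)
    stop("fit_mixture('", marker, "'): degenerate variance")
  sd_floor <- max(1e-6 * sd(x), 1e-12)
  sgn <- if (direction == "increase") 1 else -1

  mu1 <- mean(x[g == "YA"])
  s1 <- max(sd(x[g == "YA"]), sd_floor)
  mu_oa <- mean(x[g == "OA"])
  s_oa <- max(sd(x[g == "OA"]), sd_floor)
  w_oa <- mean(g == "OA")
  logit <- function(p) log(p / (1 - p))
  inv_logit <- function(q) 1 / (1 + exp(-q))

  # p = (log excess displacement [, log abnormal sd], logit weight);
  # abnormal mean = mu1 + sgn * s1 * (min_separation + exp(p[1]))
  nll <- function(p) {
    d <- s1 * (min_separation + exp(p[1]))
    s2 <- if (equal_variances) s1 else exp(p[2])
    w <- inv_logit(p[length(p)])
    if (!is.finite(d) || s2 > s1 * (1 + 1e-9) || s2 < sd_floor) return(1e10)
    -sum(log(pmax((1 - w) * dnorm(x, mu1, s1) +
                    w * dnorm(x, mu1 + sgn * d, s2), 1e-300)))
  }
  d0 <- log(max(sgn * (mu_oa - mu1) / s1 - min_separation, 0.25))
  starts <- if (equal_variances) {
    list(c(d0, logit(min(max(w_oa, 0.05), 0.95))),
         c(log(0.25), logit(0.15)), c(log(1), logit(0.5)))
  } else {
    list(c(d0, log(s1), logit(min(max(w_oa, 0.05), 0.95))),
         c(log(0.25), log(0.7 * s1), logit(0.15)),
         c(log(1), log(0.9 * s1), logit(0.5)))
  }
  best <- NULL
  for (st in starts) {
    o <- stats::optim(st, nll, method = "Nelder-Mead",
                      control = list(maxit = max_iter))
    if (is.null(best) || o$value < best$value) best <- o
  }
  excess <- exp(best$par[1])
  d <- s1 * (min_separation + excess)
  s2 <- if (equal_variances) s1 else exp(best$par[2])
  w <- inv_logit(best$par[length(best$par)])

  # A displacement pinned at the separation floor is a legitimate
  # (conservative) constrained estimate for a weak component; only weight
  # collapse -- no abnormal mass at all, the zero-separation limit -- is
  # degenerate.
  fallback <- w < 0.02 || w > 1 - 0.02
  if (fallback) {
    fit <- list(normal_mean = mu1, normal_sd = s1,
                abnormal_mean = mu_oa, abnormal_sd = s_oa,
                mixing_weight = w_oa, loglik = NA_real_)
  } else {
    fit <- list(normal_mean = mu1, normal_sd = s1,
                abnormal_mean = mu1 + sgn * d, abnormal_sd = s2,
                mixing_weight = w, loglik = -best$value)
  }
  if (min(fit$normal_sd, fit$abnormal_sd)^2 < 1e-12)
    stop("fit_mixture('", marker, "'): degenerate component variance")
  structure(c(list(marker = marker), fit,
              list(direction = direction, fallback = fallback)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "mixture_fit '%s' (%s%s): normal N(%.4g, %.4g), abnormal N(%.4g, %.4g), w_abn = %.3f\n",
    x$marker, x$direction, if (x$fallback) ", plug-in fallback" else "",
    x$normal_mean, x$normal_sd, x$abnormal_mean, x$abnormal_sd,
    x$mixing_weight))
  invisible(x)
}

#' Fit mixtures for every marker of a cohort
#'
#' @param cohort A cohort data frame (normally ID-residualized).
#' @param markers Marker names; defaults to the full panel.
#' @param ... Passed to [fit_mixture()].
#' @return Named list of `"mixture_fit"` objects.
#' @export
fit_cohort_mixtures <- function(cohort, markers = NULL, ...) {
  panel <- cohort_panel(cohort)
  if (is.null(markers)) markers <- panel$name
  fits <- lapply(markers, function(m)
    fit_mixture(cohort[[m]], cohort$group,
                direction = marker_direction(panel, m), marker = m, ...))
  names(fits) <- markers
  fits
}

# Component log-densities with a floor keeping downstream logs finite.
mixture_logdens <- function(fit, x) {
  list(normal = log(pmax(dnorm(x, fit$normal_mean, fit$normal_sd), 1e-300)),
       abnormal = log(pmax(dnorm(x, fit$abnormal_mean, fit$abnormal_sd),
                           1e-300)))
}
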