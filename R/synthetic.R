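#' Configuration for the synthetic cohort generator
#'
#' Builds a validated configuration describing a cross-sectional cohort of
#' adults with Down syndrome: a younger-adult (YA, control) group and an
#' older-adult (OA, at-risk) group, a planted ordering of marker abnormality
#' events with strictly increasing onset ages, per-marker effect sizes (in
#' residual-SD units), baseline means and noise SDs, an additive
#' intellectual-disability (ID) level effect, and rates of missingness and
#' gross plasma outliers.
#'
#' Baseline means and noise SDs default to values on the scale reported for
#' pre-decline adults with Down syndrome (e.g. an amyloid-beta 42/40 ratio
#' near 0.06, NfL near 9 pg/mL, a first-trial memory score near 11). Onset
#' ages default to an even stagger across 36-54 years, the window in which
#' Alzheimer's pathology emerges in this population.
#'
#' @param panel Marker panel (see [default_panel()]).
#' @param n_control,n_disease Group sizes (YA / OA), each >= 2.
#' @param age_range_control,age_range_disease Age ranges in years.
#' @param ordering Planted event ordering: a permutation of the panel's marker
#'   names, earliest event first.
#' @param onset_ages Age (years) at which each event in `ordering` occurs;
#'   strictly increasing along `ordering`.
#' @param effect_size Named vector: separation between normal and abnormal
#'   means per marker, in units of that marker's `noise_sd`.
#' @param base_mean,noise_sd Named vectors of baseline (normal) means and
#'   residual SDs per marker.
#' @param id_effect Named vector: additive shift for moderate (vs mild) ID.
#' @param p_moderate_id Probability a participant has moderate ID.
#' @param stage_jitter_sd SD (years) of the per-participant jitter applied to
#'   age before thresholding against `onset_ages`, so that latent stage is
#'   monotone in age without being a deterministic function of it.
#' @param missing_rate Probability each marker cell is missing (completely at
#'   random).
#' @param outlier_rate Probability each observed plasma cell is corrupted by a
#'   gross multiplicative outlier.
#' @param outlier_factor Multiplicative factor for injected outliers.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(panel = default_panel(),
                             n_control = 60L,
                             n_disease = 60L,
                             age_range_control = c(20, 35),
                             age_range_disease = c(36, 59),
                             ordering = c("abeta42_40", "pal", "nfl",
                                          "ptau231", "ptau181", "tol",
                                          "ied", "nepsy", "gfap"),
                             onset_ages = NULL,
                             effect_size = NULL,
                             base_mean = NULL,
                             noise_sd = NULL,
                             id_effect = NULL,
                             p_moderate_id = 0.53,
                             stage_jitter_sd = 2,
                             missing_rate = 0.05,
                             outlier_rate = 0.04,
                             outlier_factor = 5,
                             seed = 1L) {
  validate_panel(panel)
  markers <- panel$name
  default_base <- c(abeta42_40 = 0.06, ptau181 = 4.01, ptau231 = 5.41,
                    nfl = 8.79, gfap = 66.74, pal = 11.17, tol = 7.44,
                    nepsy = 18.86, ied = 7.15)
  default_sd <- c(abeta42_40 = 0.01, ptau181 = 1.94, ptau231 = 1.38,
                  nfl = 4.79, gfap = 26.09, pal = 4.67, tol = 2.82,
                  nepsy = 8.31, ied = 1.83)
  fill <- function(x, defaults, fallback) {
    out <- setNames(rep(fallback, length(markers)), markers)
    hit <- intersect(markers, names(defaults))
    out[hit] <- defaults[hit]
    if (!is.null(x)) {
      if (is.null(names(x)) && length(x) == 1L) {
        out[] <- x
      } else {
        bad <- setdiff(names(x), markers)
        if (length(bad)) stop("unknown marker in config: ", bad[1L])
        out[names(x)] <- x
      }
    }
    out
  }
  base_mean <- fill(base_mean, default_base, 0)
  noise_sd <- fill(noise_sd, default_sd, 1)
  effect_size <- fill(effect_size, setNames(rep(2, length(markers)), markers), 2)
  cg <- cognitive_markers(panel)
  default_id <- setNames(rep(0, length(markers)), markers)
  default_id[cg] <- -0.5 * noise_sd[cg]  # moderate ID scores lower on cognition
  id_effect <- fill(id_effect, default_id, 0)

  if (is.null(onset_ages))
    onset_ages <- seq(36, 54, length.out = length(ordering))

  cfg <- structure(list(
    panel = panel, n_control = as.integer(n_control),
    n_disease = as.integer(n_disease),
    age_range_control = age_range_control,
    age_range_disease = age_range_disease,
    ordering = ordering, onset_ages = onset_ages,
    effect_size = effect_size, base_mean = base_mean, noise_sd = noise_sd,
    id_effect = id_effect, p_moderate_id = p_moderate_id,
    stage_jitter_sd = stage_jitter_sd, missing_rate = missing_rate,
    outlier_rate = outlier_rate, outlier_factor = outlier_factor,
    seed = as.integer(seed)), class = "synthetic_config")
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  chk <- function(cond, field, msg)
    if (!cond) stop("invalid synthetic_config field '", field, "': ", msg,
                    call. = FALSE)
  markers <- cfg$panel$name
  chk(cfg$n_control >= 2L, "n_control", "must be >= 2")
  chk(cfg$n_disease >= 2L, "n_disease", "must be >= 2")
  chk(length(cfg$age_range_control) == 2L &&
        diff(cfg$age_range_control) > 0, "age_range_control",
      "must be an increasing pair of ages")
  chk(length(cfg$age_range_disease) == 2L &&
        diff(cfg$age_range_disease) > 0, "age_range_disease",
      "must be an increasing pair of ages")
  chk(setequal(cfg$ordering, markers) &&
        length(cfg$ordering) == length(markers), "ordering",
      "must be a permutation of the panel's marker names")
  chk(length(cfg$onset_ages) == length(cfg$ordering), "onset_ages",
      "must have one onset age per event in `ordering`")
  chk(all(diff(cfg$onset_ages) > 0), "onset_ages",
      "must be strictly increasing along `ordering`")
  for (f in c("p_moderate_id", "missing_rate", "outlier_rate")) {
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1L &&
          cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must be a probability in [0,1]")
  }
  chk(all(cfg$noise_sd > 0), "noise_sd", "must be positive")
  chk(cfg$stage_jitter_sd >= 0, "stage_jitter_sd", "must be >= 0")
  chk(cfg$outlier_factor > 1, "outlier_factor", "must exceed 1")
  invisible(cfg)
}

#' Latent sigmoid event trajectory
#'
#' Logistic curve used to synthesize gradually-transitioning marker values: a
#' marker sits at `base` long before its event, crosses its midpoint
#' (`base` plus half the full excursion, signed by `direction`) at
#' `onset_age`, and saturates at `base + delta` (direction `"increase"`) or
#' `base - delta` (`"decrease"`).
#'
#' @param age Age(s) in years (vectorized).
#' @param onset_age Midpoint age of the transition.
#' @param width Transition width in years (> 0); the logistic scale.
#' @param direction `"increase"` or `"decrease"`.
#' @param base Pre-event asymptote.
#' @param delta Magnitude of the full excursion (>= 0).
#' @return Numeric vector of trajectory values.
#' @export
trajectory_value <- function(age, onset_age, width,
                             direction = c("increase", "decrease"),
                             base = 0, delta = 1) {
  direction <- match.arg(direction)
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("width must be a positive number of years")
  s <- if (direction == "increase") 1 else -1
  base + s * delta / (1 + exp(-(age - onset_age) / width))
}

#' Generate a synthetic cohort with a planted event ordering
#'
#' Draws ages uniformly within each group's range, assigns a latent disease
#' stage by thresholding a jittered age against the onset schedule, and
#' generates each marker as its baseline mean, shifted by
#' `effect_size * noise_sd` in the marker's pathological direction once its
#' event has occurred, plus the ID-level effect for moderate-ID participants
#' and Gaussian noise. Missing cells are then masked completely at random and
#' gross multiplicative outliers are injected into observed plasma cells. The
#' latent stage is recorded (before corruption) in `truth_stage`.
#'
#' @param config A [synthetic_config()].
#' @return A `data.frame` of class `c("cohort", "data.frame")` with columns
#'   `participant_id`, `age`, `group` (`"YA"`/`"OA"`), `id_level`
#'   (`"mild"`/`"moderate"`), one column per marker, and `truth_stage`. The
#'   marker panel and planted truth (ordering, onset ages) are attached as
#'   attributes `"panel"` and `"truth"`.
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  n <- config$n_control + config$n_disease
  grp <- rep(c("YA", "OA"), c(config$n_control, config$n_disease))
  age <- c(runif(config$n_control, config$age_range_control[1],
                 config$age_range_control[2]),
           runif(config$n_disease, config$age_range_disease[1],
                 config$age_range_disease[2]))
  id_level <- ifelse(runif(n) < config$p_moderate_id, "moderate", "mild")
  jitter <- rnorm(n, 0, config$stage_jitter_sd)
  stage <- vapply(age + jitter,
                  function(a) sum(config$onset_ages <= a), integer(1))

  markers <- config$panel$name
  vals <- matrix(NA_real_, n, length(markers),
                 dimnames = list(NULL, markers))
  pos_of <- match(markers, config$ordering)  # event position of each marker
  dirsgn <- ifelse(config$panel$direction == "increase", 1, -1)
  moderate <- id_level == "moderate"
  for (j in seq_along(markers)) {
    m <- markers[j]
    occurred <- stage >= pos_of[j]
    vals[, j] <- config$base_mean[m] +
      occurred * dirsgn[j] * config$effect_size[m] * config$noise_sd[m] +
      moderate * config$id_effect[m] +
      rnorm(n, 0, config$noise_sd[m])
  }
  if (config$missing_rate > 0) {
    miss <- matrix(runif(n * length(markers)) < config$missing_rate,
                   n, length(markers))
    vals[miss] <- NA_real_
  }
  if (config$outlier_rate > 0) {
    pl <- markers %in% plasma_markers(config$panel)
    out <- matrix(runif(n * length(markers)) < config$outlier_rate,
                  n, length(markers))
    out[, !pl] <- FALSE
    out[is.na(vals)] <- FALSE
    vals[out] <- vals[out] * config$outlier_factor
  }

  cohort <- data.frame(participant_id = sprintf("P%04d", seq_len(n)),
                       age = age, group = grp, id_level = id_level,
                       stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(vals))
  cohort$truth_stage <- stage
  structure(cohort,
            panel = config$panel,
            truth = list(ordering = config$ordering,
                         onset_ages = config$onset_ages),
            class = c("cohort", "data.frame"))
}

cohort_panel <- function(cohort, panel = NULL) {
  if (!is.null(panel)) return(validate_panel(panel))
  p <- attr(cohort, "panel")
  if (is.null(p)) stop("cohort has no attached marker panel; pass `panel`")
  validate_panel(p)
}

validate_cohort <- function(cohort, panel = NULL) {
  panel <- cohort_panel(cohort, panel)
  need <- c("participant_id", "age", "group", "id_level", panel$name)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(cohort$group %in% c("YA", "OA")))
    stop("cohort: group must be 'YA' or 'OA'")
  if (!all(cohort$id_level %in% c("mild", "moderate")))
    stop("cohort: id_level must be 'mild' or 'moderate'")
  invisible(cohort)
}

marker_matrix <- function(cohort, markers) {
  as.matrix(cohort[, markers, drop = FALSE])
}
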