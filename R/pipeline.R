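# End-to-end pipeline: simulate -> preprocess -> EBM -> trajectories, with a
# serializable configuration and a run manifest recording flow counts.

#' Pipeline run configuration
#'
#' Collects every stage parameter with documented defaults into one
#' serializable object. `write_run_config()` / `read_run_config()` round-trip
#' it as YAML (or JSON when the path ends in `.json`).
#'
#' @param seed Master seed for every source of randomness.
#' @param simulate If `TRUE`, generate a synthetic cohort; otherwise read
#'   `input` as a cohort CSV.
#' @param input Input cohort CSV (ignored when `simulate = TRUE`).
#' @param out_dir Output directory for all artifacts.
#' @param synthetic Named list of [synthetic_config()] overrides.
#' @param alpha Screening significance level.
#' @param screen_residualize Screen on ID-residualized values (default) or
#'   raw.
#' @param include_markers Optional explicit EBM marker include-list
#'   overriding the screen's selection.
#' @param max_cognitive_missing Participant-exclusion threshold on the
#'   fraction of missing cognitive scores (`NULL` to skip filtering).
#' @param mcmc_iter,mcmc_burnin,greedy_starts Event-sequence sampler
#'   settings.
#' @param m,imp_iterations,donors Multiple-imputation settings.
#' @param span LOESS span.
#' @param criterion Change-window fraction-of-peak criterion.
#' @param n_components Principal components retained.
#' @param composite_markers Markers summed into the composite z-score.
#' @param run_trajectories,run_ebm Stage toggles.
#' @return Object of class `"run_config"` (a named list).
#' @export
run_config <- function(seed = 1L,
                       simulate = TRUE,
                       input = NULL,
                       out_dir = "dsebm-results",
                       synthetic = list(),
                       alpha = 0.05,
                       screen_residualize = TRUE,
                       include_markers = NULL,
                       max_cognitive_missing = 0.75,
                       mcmc_iter = 100000L,
                       mcmc_burnin = 50000L,
                       greedy_starts = 10L,
                       m = 10L,
                       imp_iterations = 10L,
                       donors = 5L,
                       span = 0.75,
                       criterion = 0.5,
                       n_components = 2L,
                       composite_markers = NULL,
                       run_ebm = TRUE,
                       run_trajectories = TRUE) {
  cfg <- as.list(environment())
  stopifnot(cfg$mcmc_iter > cfg$mcmc_burnin, cfg$mcmc_burnin >= 0,
            cfg$alpha > 0, cfg$alpha < 1, cfg$m >= 1)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config A `"run_config"`.
#' @param path Destination (`.yaml`/`.yml` or `.json`).
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- unclass(run_config())
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown))
    stop("read_run_config: unknown field(s): ",
         paste(unknown, collapse = ", "))
  out <- lapply(names(defaults), function(nm)
    if (nm %in% names(x)) x[[nm]] else defaults[[nm]])
  names(out) <- names(defaults)
  for (nm in c("seed", "mcmc_iter", "mcmc_burnin", "greedy_starts", "m",
               "imp_iterations", "donors", "n_components"))
    out[[nm]] <- as.integer(out[[nm]])
  structure(out, class = "run_config")
}

write_json_num <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Run the full staging pipeline
#'
#' Executes, per the configuration: cohort simulation (or ingestion),
#' participant filtering, IQR outlier exclusion and ID-level
#' residualization, the Kruskal-Wallis screen, the event-based model
#' (mixtures, greedy + MCMC sequence inference, positional variance,
#' staging), and the age-trajectory arm (PMM imputation, pooled PCA, GAM
#' and LOESS smooths, composite z-score, maximal-change window). All
#' artifacts are written under `config$out_dir` as CSV/JSON; a manifest
#' records the configuration, per-stage flow counts and timestamps.
#' Outputs are identical for identical configuration and seed (the
#' manifest's timestamps aside).
#'
#' @param config A [run_config()].
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  manifest <- list(config = unclass(config),
                   version = as.character(utils::packageVersion("dsebm")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list())
  panel <- default_panel()

  if (isTRUE(config$simulate)) {
    scfg <- do.call(synthetic_config,
                    c(list(seed = config$seed), config$synthetic))
    cohort <- generate_cohort(scfg)
    write_cohort(cohort, out("cohort.csv"))
    write_truth(cohort, out("truth.json"))
    panel <- scfg$panel
    manifest$stages$simulate <- list(rows_out = nrow(cohort))
  } else {
    if (is.null(config$input)) stop("run_pipeline: no input cohort and simulate = FALSE")
    cohort <- read_cohort(config$input, panel = panel)
  }

  n_in <- nrow(cohort)
  if (!is.null(config$max_cognitive_missing)) {
    flt <- filter_participants(cohort, config$max_cognitive_missing)
    cohort <- flt$cohort
    manifest$stages$filter <- list(rows_in = flt$n_in,
                                   rows_excluded = flt$n_excluded,
                                   rows_out = flt$n_out)
  }

  excl <- apply_iqr_exclusion(cohort)
  clean <- excl$cohort
  write_cohort(clean, out("clean.csv"))
  screen <- kruskal_wallis_screen(clean, alpha = config$alpha,
                                  residualize = config$screen_residualize)
  write.csv(as.data.frame(screen), out("screen.csv"), row.names = FALSE)
  write_json_num(as.list(setNames(as.integer(excl$counts),
                                  names(excl$counts))),
                 out("outlier_counts.json"))
  manifest$stages$preprocess <- list(
    rows_in = nrow(cohort), rows_excluded = 0L, rows_out = nrow(clean),
    outlier_cells = as.list(setNames(as.integer(excl$counts),
                                     names(excl$counts))),
    markers_selected = screen$marker[screen$selected])

  if (isTRUE(config$run_ebm)) {
    ebm_markers <- if (!is.null(config$include_markers)) {
      config$include_markers
    } else {
      screen$marker[screen$selected]
    }
    resid <- residualize_cohort(clean)
    mix <- fit_cohort_mixtures(resid, markers = ebm_markers)
    post <- mcmc_sequences(resid, mix, n_iter = config$mcmc_iter,
                           burn_in = config$mcmc_burnin,
                           n_starts = config$greedy_starts,
                           seed = config$seed)
    stages <- stage_participants(resid, post$ml_sequence, mix)
    hist <- staging_histogram(stages, clean)
    write_json_num(list(ml_sequence = post$ml_sequence,
                        ml_loglik = post$ml_loglik,
                        acceptance_rate = post$acceptance_rate),
                   out("ml_sequence.json"))
    pv <- as.data.frame(post$positional_variance)
    pv <- cbind(event = rownames(post$positional_variance), pv)
    write.csv(pv, out("positional_variance.csv"), row.names = FALSE)
    write.csv(as.data.frame(stages), out("stages.csv"), row.names = FALSE)
    write.csv(as.data.frame.matrix(hist), out("stage_histogram.csv"))
    manifest$stages$ebm <- list(
      markers = ebm_markers, n_staged = sum(!is.na(stages$stage)),
      n_unstaged = sum(is.na(stages$stage)),
      acceptance_rate = post$acceptance_rate)
  }

  if (isTRUE(config$run_trajectories)) {
    pmarkers <- plasma_markers(panel)
    stack <- impute_pmm(clean, m = config$m,
                        iterations = config$imp_iterations,
                        donors = config$donors, markers = pmarkers,
                        seed = config$seed)
    pca <- pca_pooled(stack, n_components = config$n_components)
    ld <- cbind(marker = rownames(pca$loadings),
                as.data.frame(pca$loadings))
    write.csv(ld, out("pca_loadings.csv"), row.names = FALSE)
    write_json_num(list(
      explained_variance_fraction = pca$explained_variance_fraction,
      total = sum(pca$explained_variance_fraction)),
      out("pca_variance.json"))
    scores <- pc_scores(stack, pca)
    for (cmp in seq_len(config$n_components)) {
      fits <- lapply(scores, function(s)
        fit_gam(clean$age, s[, cmp]))
      pooled <- pool_smooths(fits)
      write.csv(data.frame(age = pooled$age_grid, fit = pooled$fitted,
                           lo = pooled$ci_lower, hi = pooled$ci_upper,
                           derivative = pooled$derivative),
                out(sprintf("gam_pc%d.csv", cmp)), row.names = FALSE)
    }
    comp <- composite_z(clean,
                        plasma_markers = config$composite_markers %||%
                          pmarkers)
    lo_fit <- fit_loess(clean$age, comp, span = config$span)
    write.csv(data.frame(age = lo_fit$age_grid, fit = lo_fit$fitted,
                         lo = lo_fit$ci_lower, hi = lo_fit$ci_upper,
                         derivative = lo_fit$derivative),
              out("composite_loess.csv"), row.names = FALSE)
    win <- max_change_window(lo_fit, criterion = config$criterion)
    write_json_num(unclass(win), out("change_window.json"))
    manifest$stages$trajectories <- list(
      m = config$m, markers = pmarkers,
      explained_variance_total = sum(pca$explained_variance_fraction),
      window = unclass(win))
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  write_json_num(manifest, out("manifest.json"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
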