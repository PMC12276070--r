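# Independent oracles and small fixture builders shared across tests.

# Brute-force EBM sequence log-likelihood: naive loops over participants,
# stages and events, written independently of the package's vectorized and
# C++ evaluators.
oracle_seq_loglik <- function(cohort, seq, mixtures) {
  K <- length(seq)
  total <- 0
  for (i in seq_len(nrow(cohort))) {
    s <- 0
    for (k in 0:K) {
      prod_k <- 1 / (K + 1)
      for (j in seq_len(K)) {
        x <- cohort[[seq[j]]][i]
        if (is.na(x)) next
        f <- mixtures[[seq[j]]]
        dens <- if (j <= k) {
          stats::dnorm(x, f$abnormal_mean, f$abnormal_sd)
        } else {
          stats::dnorm(x, f$normal_mean, f$normal_sd)
        }
        prod_k <- prod_k * max(dens, 1e-300)
      }
      s <- s + prod_k
    }
    total <- total + log(s)
  }
  total
}

# All permutations of a vector (K small).
all_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# Brute-force IQR fences with hand-coded linear-interpolation quartiles.
oracle_iqr_mask <- function(x, k = 1.5) {
  obs <- sort(x[!is.na(x)])
  n <- length(obs)
  qlin <- function(p) {
    h <- 1 + (n - 1) * p
    lo <- floor(h)
    hi <- ceiling(h)
    obs[lo] + (h - lo) * (obs[hi] - obs[lo])
  }
  q1 <- qlin(0.25)
  q3 <- qlin(0.75)
  iqr <- q3 - q1
  !is.na(x) & (x < q1 - k * iqr | x > q3 + k * iqr)
}

# Hand-made mixture_fit without going through the fitter.
make_mixture <- function(marker, normal_mean, normal_sd, abnormal_mean,
                         abnormal_sd, direction, mixing_weight = 0.5) {
  structure(list(marker = marker, normal_mean = normal_mean,
                 normal_sd = normal_sd, abnormal_mean = abnormal_mean,
                 abnormal_sd = abnormal_sd, mixing_weight = mixing_weight,
                 direction = direction, fallback = FALSE,
                 loglik = NA_real_),
            class = "mixture_fit")
}

# Minimal cohort from a matrix of marker values.
make_cohort <- function(values, group, id_level = NULL, age = NULL,
                        panel = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (is.null(id_level)) id_level <- rep("mild", n)
  if (is.null(age)) age <- ifelse(group == "YA", 28, 48)
  if (is.null(panel)) {
    panel <- do.call(rbind, lapply(colnames(values), function(m)
      marker_def(m, "plasma", "increase")))
  }
  df <- data.frame(participant_id = sprintf("S%03d", seq_len(n)),
                   age = age, group = group, id_level = id_level,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(values))
  structure(df, panel = panel, class = c("cohort", "data.frame"))
}

# Four-marker synthetic configuration with a planted ordering, small enough
# for exhaustive enumeration of all 24 sequences.
small_planted_config <- function(seed, n = 60L, effect = 3,
                                 missing_rate = 0, outlier_rate = 0) {
  panel <- rbind(marker_def("m1", "plasma", "decrease"),
                 marker_def("m2", "plasma", "increase"),
                 marker_def("m3", "cognitive", "decrease"),
                 marker_def("m4", "plasma", "increase"))
  synthetic_config(panel = panel, n_control = n, n_disease = n,
                   ordering = c("m1", "m2", "m3", "m4"),
                   onset_ages = c(38, 43, 48, 53),
                   effect_size = effect,
                   base_mean = c(m1 = 10, m2 = 5, m3 = 20, m4 = 50),
                   noise_sd = c(m1 = 2, m2 = 1, m3 = 4, m4 = 10),
                   id_effect = c(m1 = 0, m2 = 0, m3 = -1, m4 = 0),
                   missing_rate = missing_rate,
                   outlier_rate = outlier_rate, seed = seed)
}

# Cohort whose plasma markers follow logistic age trajectories (for the
# change-window analyses); returns the cohort plus the noiseless composite
# curve generator.
logistic_cohort <- function(seed, n = 120L, midpoints, width = 3,
                            noise = 0.35) {
  set.seed(seed)
  panel <- default_panel()
  pm <- plasma_markers(panel)
  stopifnot(length(midpoints) == length(pm))
  names(midpoints) <- pm
  age <- runif(n, 20, 59)
  vals <- sapply(pm, function(m) {
    dir <- panel$direction[match(m, panel$name)]
    trajectory_value(age, midpoints[[m]], width, dir, base = 0, delta = 1) +
      rnorm(n, 0, noise)
  })
  cg <- cognitive_markers(panel)
  cvals <- sapply(cg, function(m) rnorm(n))
  cohort <- make_cohort(cbind(vals, cvals),
                        group = ifelse(age <= 35, "YA", "OA"),
                        age = age, panel = panel)
  true_composite <- function(a) {
    rowSums(sapply(pm, function(m) {
      dir <- panel$direction[match(m, panel$name)]
      v <- trajectory_value(a, midpoints[[m]], width, dir, 0, 1)
      if (dir == "decrease") -v else v
    }))
  }
  list(cohort = cohort, true_composite = true_composite,
       midpoints = midpoints)
}

# Jaccard overlap of two closed age intervals.
interval_jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  union <- max(a[2], b[2]) - min(a[1], b[1])
  if (union <= 0) return(0)
  inter / union
}
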