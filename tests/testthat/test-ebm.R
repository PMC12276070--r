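# Planted four-marker cohort with mixtures, shared across EBM tests.
planted_setup <- function(seed = 61, effect = 3) {
  cfg <- small_planted_config(seed, effect = effect)
  co <- generate_cohort(cfg)
  res <- residualize_cohort(co)
  mix <- fit_cohort_mixtures(res)
  list(cfg = cfg, cohort = res, mix = mix,
       planted = attr(co, "truth")$ordering)
}

test_that("symmetric densities make the order irrelevant at K = 1", {
  co <- make_cohort(cbind(m1 = 0.7), group = "YA")
  mix <- list(m1 = make_mixture("m1", 0, 1, 0, 1, "increase"))
  d <- dnorm(0.7, 0, 1)
  expect_equal(as.numeric(sequence_loglik(co, "m1", mix)), log(d),
               tolerance = 1e-12)
})

test_that("sequence likelihood is invariant to participant order", {
  s <- planted_setup()
  shuffled <- s$cohort[sample(nrow(s$cohort)), ]
  expect_equal(as.numeric(sequence_loglik(s$cohort, s$planted, s$mix)),
               as.numeric(sequence_loglik(shuffled, s$planted, s$mix)),
               tolerance = 1e-10)
})

test_that("vectorized, C++ and brute-force evaluators agree on every K=4 permutation", {
  s <- planted_setup()
  mats <- dsebm:::ebm_logdens_matrices(s$cohort, s$mix)
  lls <- vapply(all_perms(names(s$mix)), function(p) {
    rll <- as.numeric(sequence_loglik(s$cohort, p, s$mix))
    oll <- oracle_seq_loglik(s$cohort, p, s$mix)
    cll <- dsebm:::seq_loglik_fast(mats, match(p, names(s$mix)))
    expect_equal(rll, oll, tolerance = 1e-9)
    expect_equal(cll, oll, tolerance = 1e-9)
    rll
  }, numeric(1))
  # exhaustive argmax identifies the planted ordering
  best <- all_perms(names(s$mix))[[which.max(lls)]]
  expect_equal(best, s$planted)
})

test_that("missing cells contribute a unit factor", {
  s <- planted_setup(seed = 62)
  co <- s$cohort
  co$m2[3] <- NA
  expect_equal(as.numeric(sequence_loglik(co, s$planted, s$mix)),
               oracle_seq_loglik(co, s$planted, s$mix), tolerance = 1e-9)
})

test_that("all-missing participants are excluded with a warning", {
  s <- planted_setup(seed = 63)
  co <- s$cohort
  co[5, names(s$mix)] <- NA
  expect_warning(ll <- sequence_loglik(co, s$planted, s$mix),
                 "all markers missing")
  expect_equal(attr(ll, "n_excluded"), 1L)
  expect_equal(as.numeric(ll),
               oracle_seq_loglik(co[-5, ], s$planted, s$mix),
               tolerance = 1e-9)
})

test_that("flipping a marker's sign and direction leaves the likelihood unchanged", {
  s <- planted_setup(seed = 64)
  ll1 <- as.numeric(sequence_loglik(s$cohort, s$planted, s$mix))
  co2 <- s$cohort
  co2$m2 <- -co2$m2
  mix2 <- s$mix
  mix2$m2$normal_mean <- -mix2$m2$normal_mean
  mix2$m2$abnormal_mean <- -mix2$m2$abnormal_mean
  mix2$m2$direction <- "decrease"
  expect_equal(as.numeric(sequence_loglik(co2, s$planted, mix2)), ll1,
               tolerance = 1e-10)
})

test_that("greedy ascent finds the exhaustive argmax", {
  s <- planted_setup(seed = 65)
  # K = 2: result must equal the better of the two orders
  mix2 <- s$mix[c("m1", "m2")]
  g2 <- greedy_ascent(s$cohort, mix2, n_starts = 1, seed = 1)
  lls <- sapply(list(c("m1", "m2"), c("m2", "m1")), function(p)
    as.numeric(sequence_loglik(s$cohort, p, mix2)))
  expect_equal(attr(g2, "loglik"), max(lls), tolerance = 1e-9)
  # K = 4: matches brute force over all 24 permutations
  g4 <- greedy_ascent(s$cohort, s$mix, n_starts = 10, seed = 1)
  lls4 <- vapply(all_perms(names(s$mix)), function(p)
    oracle_seq_loglik(s$cohort, p, s$mix), numeric(1))
  expect_equal(attr(g4, "loglik"), max(lls4), tolerance = 1e-9)
  expect_equal(as.character(g4), s$planted)
  # determinism
  expect_identical(greedy_ascent(s$cohort, s$mix, n_starts = 3, seed = 7),
                   greedy_ascent(s$cohort, s$mix, n_starts = 3, seed = 7))
})

test_that("a flat likelihood yields a uniform sequence posterior", {
  set.seed(66)
  co <- make_cohort(matrix(rnorm(40 * 3), 40, 3,
                           dimnames = list(NULL, c("a", "b", "c"))),
                    group = rep(c("YA", "OA"), 20))
  mix <- list(a = make_mixture("a", 0, 1, 0, 1, "increase"),
              b = make_mixture("b", 0, 1, 0, 1, "increase"),
              c = make_mixture("c", 0, 1, 0, 1, "increase"))
  post <- mcmc_sequences(co, mix, n_iter = 30000, burn_in = 5000, seed = 2)
  expect_gt(post$acceptance_rate, 0.95)  # all proposals are likelihood-neutral
  expect_true(all(abs(post$positional_variance - 1 / 3) < 0.05))
})

test_that("MCMC sample frequencies track the exhaustive posterior", {
  s <- planted_setup(seed = 67, effect = 1.2)  # moderate effect: real spread
  perms <- all_perms(names(s$mix))
  lls <- vapply(perms, function(p)
    oracle_seq_loglik(s$cohort, p, s$mix), numeric(1))
  truth_post <- exp(lls - max(lls))
  truth_post <- truth_post / sum(truth_post)
  post <- mcmc_sequences(s$cohort, s$mix, n_iter = 60000, burn_in = 10000,
                         seed = 3)
  key <- vapply(perms, paste, character(1), collapse = "|")
  emp <- table(factor(apply(post$samples, 1, paste, collapse = "|"),
                      levels = key)) / nrow(post$samples)
  tv <- 0.5 * sum(abs(as.numeric(emp) - truth_post))
  expect_lt(tv, 0.05)
  # ml_sequence attains the exhaustive argmax
  expect_equal(post$ml_sequence, perms[[which.max(lls)]])
})

test_that("positional variance is doubly stochastic and the chain deterministic", {
  s <- planted_setup(seed = 68)
  post <- mcmc_sequences(s$cohort, s$mix, n_iter = 5000, burn_in = 1000,
                         seed = 4)
  expect_equal(rowSums(post$positional_variance), rep(1, 4),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(colSums(post$positional_variance), rep(1, 4),
               tolerance = 1e-9, ignore_attr = TRUE)
  again <- mcmc_sequences(s$cohort, s$mix, n_iter = 5000, burn_in = 1000,
                          seed = 4)
  expect_identical(post$samples, again$samples)
})

test_that("staging recovers noiseless profiles and hand-computed posteriors", {
  mix <- list(a = make_mixture("a", 0, 1, 3, 1, "increase"),
              b = make_mixture("b", 0, 1, 3, 1, "increase"),
              c = make_mixture("c", 0, 1, 3, 1, "increase"))
  seqn <- c("a", "b", "c")
  prof <- rbind(c(0, 0, 0), c(3, 0, 0), c(3, 3, 0), c(3, 3, 3))
  co <- make_cohort(`colnames<-`(prof, seqn), group = rep("OA", 4))
  st <- stage_participants(co, seqn, mix)
  expect_equal(st$stage, 0:3)
  # hand-computed posterior for the two-events-abnormal profile (K = 3):
  # stage k likelihood is a product of unit-variance normal densities
  x <- prof[3, ]
  lk <- sapply(0:3, function(k)
    prod(dnorm(x, ifelse(seq_len(3) <= k, 3, 0), 1)))
  expect_equal(unlist(st[3, c("p0", "p1", "p2", "p3")]), lk / sum(lk),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("stage is monotone in the number of abnormal events and ties break low", {
  mix <- list(a = make_mixture("a", 0, 1, 3, 1, "increase"),
              b = make_mixture("b", 0, 1, 3, 1, "increase"))
  co <- make_cohort(cbind(a = c(0, 3), b = c(NA, NA)),
                    group = c("YA", "OA"))
  st <- stage_participants(co, c("a", "b"), mix)
  # with b missing, stages 1 and 2 are equally likely: tie breaks to 1
  expect_equal(st$stage, c(0L, 1L))
})

test_that("staging histogram conserves counts and flags unstaged rows", {
  s <- planted_setup(seed = 69)
  co <- s$cohort
  co[7, names(s$mix)] <- NA
  expect_warning(st <- stage_participants(co, s$planted, s$mix),
                 "unstaged")
  h <- staging_histogram(st, co)
  expect_equal(sum(h), nrow(co) - 1L)
})

test_that("kendall tau distance behaves on known permutations", {
  expect_equal(kendall_tau_distance(letters[1:4], letters[1:4]), 0)
  expect_equal(kendall_tau_distance(letters[1:4], letters[4:1]), 1)
  expect_equal(kendall_tau_distance(c("a", "b", "c"), c("b", "a", "c")),
               1 / 3)
})
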