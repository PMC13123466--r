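# Efficiencies, specificity, multi-round enrichment, logistic decline,
# and the summary-statistics t-test.

test_that("efficiencies are the correct-outlet fractions", {
  cc <- confusion_counts(100, 88, 12, 100, 94, 6)
  expect_equal(efficiency_competent(cc), 0.88)
  expect_equal(efficiency_deficient(cc), 0.94)
  all_b <- confusion_counts(50, 50, 0, 10, 10, 0)
  expect_equal(efficiency_competent(all_b), 1)
  expect_equal(efficiency_deficient(all_b), 1)
  none <- confusion_counts(50, 0, 50, 10, 0, 10)
  expect_equal(efficiency_competent(none), 0)
  expect_equal(efficiency_deficient(none), 0)
  expect_error(efficiency_competent(confusion_counts(0, 0, 0, 5, 5, 0)),
               "no competent")
  expect_error(confusion_counts(10, 8, 5, 10, 9, 1), "exceed")
  expect_error(confusion_counts(10, 2.5, 5, 10, 9, 1), "integers")
})

test_that("specificity is the true-positive fraction at the top outlet", {
  expect_equal(specificity(confusion_counts(100, 85, 15, 100, 85, 15)), 0.85)
  expect_equal(specificity(confusion_counts(100, 100, 0, 100, 90, 10)), 1)
  expect_equal(specificity(confusion_counts(100, 80, 20, 100, 20, 80)), 0.5)
  expect_error(specificity(confusion_counts(10, 10, 0, 10, 0, 10)),
               "undefined")
})

test_that("cumulative efficiency equals exhaustive path enumeration", {
  # oracle: enumerate every binary outcome path over K rounds; a worm is
  # recovered at the bottom in round k with probability eff_k, and only
  # worms never recovered survive all rounds
  enumerate_recovery <- function(eff) {
    K <- length(eff)
    paths <- expand.grid(rep(list(c(TRUE, FALSE)), K))
    total <- 0
    for (r in seq_len(nrow(paths))) {
      outcome <- unlist(paths[r, ])
      p <- 1; recovered <- FALSE
      for (k in seq_len(K)) {
        if (recovered) {           # already out: only one continuation
          if (outcome[k]) { p <- 0; break }
          next
        }
        p <- p * (if (outcome[k]) eff[k] else 1 - eff[k])
        if (outcome[k]) recovered <- TRUE
      }
      if (recovered) total <- total + p
    }
    total
  }
  set.seed(8)
  for (K in 1:4) {
    eff <- round(stats::runif(K), 3)
    expect_equal(cumulative_efficiency(eff), enumerate_recovery(eff),
                 tolerance = 1e-12)
  }
  expect_equal(cumulative_efficiency(c(0.9, 0.9, 0.9)), 0.999)
  expect_equal(cumulative_efficiency(round_series(0.73)), 0.73)
  expect_equal(cumulative_efficiency(c(0.4, 1, 0.2)), 1)
  expect_error(cumulative_efficiency(numeric(0)), "empty")
  # monotone non-decreasing in the number of rounds
  eff <- c(0.5, 0.1, 0.8, 0.3)
  cums <- vapply(1:4, function(k) cumulative_efficiency(eff[1:k]),
                 numeric(1))
  expect_true(all(diff(cums) >= 0))
})

test_that("multi-round recovery in simulation matches the product formula", {
  # drive the sorter repeatedly: after each round the device is drained and
  # every animal not recovered at the bottom is rested and re-sorted.
  # Quiescence makes the per-round efficiencies < 1.
  q <- quiescence_model(2, mean_bout = 45)
  run_round <- function(n, seed) {
    cfg <- sim_config(geometry = sorter_geometry(), fluid = blend_fluid(),
                      phenotypes = list(competent_phenotype(q)),
                      n_per_phenotype = n, field = default_field(),
                      dt = 0.01, max_time = 900, seed = seed)
    simulate_population(cfg)$outcome$counts$exited_bottom
  }
  n0 <- 80L
  n <- n0; eff <- numeric(0); recovered <- 0L
  for (k in 1:2) {
    b <- run_round(n, 20 + k)
    eff <- c(eff, b / n)
    recovered <- recovered + b
    n <- n - b
    expect_gt(n, 0)
  }
  expect_true(all(eff > 0 & eff < 1))
  measured <- recovered / n0
  predicted <- cumulative_efficiency(eff)
  expect_equal(measured, predicted, tolerance = 1e-12)
  expect_gt(predicted, eff[1])   # a second round strictly helps
})

test_that("logistic model evaluates, plateaus, and self-fits", {
  m <- logistic_decline(a = 0.49, b = -3.29, c = 0.41, d = 3.3)
  # plateaus a + c = 0.90 (early) and c = 0.41 (late)
  expect_equal(evaluate_logistic(m, -1e3), 0.90, tolerance = 1e-6)
  expect_equal(evaluate_logistic(m, 1e3), 0.41, tolerance = 1e-6)
  expect_equal(evaluate_logistic(m, 3.3), 0.49 / 2 + 0.41)
  m0 <- logistic_decline(0, -1, 0.6, 5)
  expect_equal(evaluate_logistic(m0, c(0, 10, 50)), rep(0.6, 3))
  # bounded by the two plateaus
  tt <- seq(-10, 50, by = 0.5)
  v <- evaluate_logistic(m, tt)
  expect_true(all(v >= 0.41 - 1e-12 & v <= 0.90 + 1e-12))
  # noiseless self-fit is exact
  y <- evaluate_logistic(m, seq(0, 20, by = 0.2))
  f <- fit_logistic_decline(seq(0, 20, by = 0.2), y)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_false(f$degenerate)
  # constant data are flagged degenerate
  fd <- fit_logistic_decline(1:10, rep(0.7, 10))
  expect_true(fd$degenerate)
  expect_equal(fd$model$a, 0)
  expect_equal(fd$model$c, 0.7)
})

test_that("logistic fit recovers known parameters from noisy curves", {
  true <- c(a = 0.49, b = -3.29, c = 0.41, d = 3.3)
  tt <- seq(0, 20, by = 0.2)
  est <- sapply(1:20, function(s) {
    set.seed(s)
    y <- 0.49 / (1 + exp(3.29 * (tt - 3.3))) + 0.41 +
      stats::rnorm(length(tt), 0, 0.01)
    f <- fit_logistic_decline(tt, pmin(pmax(y, 0), 1))
    unlist(f$model[c("a", "b", "c", "d")])
  })
  err <- abs(est - true) / abs(true)
  expect_true(all(apply(err, 1, max) < 0.10))
})

test_that("summary t-test matches a from-raw-data computation", {
  # the two outlet gait-frequency summaries give |t| of about 2.54
  g1 <- gait_summary(3.50, 0.46, 150)
  g2 <- gait_summary(3.62, 0.35, 150)
  r <- two_sample_t_from_summary(g1, g2)
  expect_equal(abs(r$t), 2.54, tolerance = 0.005)
  expect_lt(r$p, 0.05)
  expect_equal(r$p, 2 * stats::pt(-abs(r$t), r$df))
  # one-tailed halves the p-value
  r1 <- two_sample_t_from_summary(g1, g2, tails = 1)
  expect_equal(r1$p, r$p / 2)
  # identical summaries: no effect
  r0 <- two_sample_t_from_summary(g1, g1)
  expect_equal(r0$t, 0); expect_equal(r0$p, 1)
  # quadrupling both n doubles |t|
  r4 <- two_sample_t_from_summary(gait_summary(3.50, 0.46, 600),
                                  gait_summary(3.62, 0.35, 600))
  expect_equal(abs(r4$t), 2 * abs(r$t), tolerance = 1e-9)
  # oracle: synthesize samples with exactly these summaries and run t.test
  make <- function(m, s, n) {
    x <- stats::rnorm(n)
    m + (x - mean(x)) / stats::sd(x) * s
  }
  set.seed(11)
  x1 <- make(3.50, 0.46, 150); x2 <- make(3.62, 0.35, 150)
  ref_w <- stats::t.test(x1, x2)
  expect_equal(r$t, unname(ref_w$statistic), tolerance = 1e-9)
  expect_equal(r$df, unname(ref_w$parameter), tolerance = 1e-9)
  expect_equal(r$p, ref_w$p.value, tolerance = 1e-9)
  rp <- two_sample_t_from_summary(g1, g2, pooled = TRUE)
  ref_p <- stats::t.test(x1, x2, var.equal = TRUE)
  expect_equal(rp$t, unname(ref_p$statistic), tolerance = 1e-9)
  expect_equal(rp$df, unname(ref_p$parameter))
  expect_error(gait_summary(3.5, 0.4, 1), "n must be")
})
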