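## Sorting statistics. The device enriches taxis-deficient animals at the
## top outlet; performance is summarized by per-class efficiencies, the
## specificity of the top outlet, the cumulative efficiency of repeated
## rounds, a logistic model of efficiency decline with residence time, and a
## summary-statistics t-test for gait frequency comparisons.

#' Confusion counts of one sorting run
#'
#' Exit counts per class and outlet. Animals neither recovered at the top
#' nor at the bottom (still in the device, or lost) are the per-class
#' remainder `n_in - top - bottom`.
#'
#' @param n_competent_in,n_competent_bottom,n_competent_top counts for the
#'   taxis-competent class (bottom = true negatives, top = false positives).
#' @param n_deficient_in,n_deficient_top,n_deficient_bottom counts for the
#'   taxis-deficient class (top = true positives, bottom = false negatives).
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(n_competent_in, n_competent_bottom,
                             n_competent_top, n_deficient_in,
                             n_deficient_top, n_deficient_bottom) {
  v <- c(n_competent_in = n_competent_in,
         n_competent_bottom = n_competent_bottom,
         n_competent_top = n_competent_top,
         n_deficient_in = n_deficient_in,
         n_deficient_top = n_deficient_top,
         n_deficient_bottom = n_deficient_bottom)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (n_competent_bottom + n_competent_top > n_competent_in)
    stop("competent outlet counts exceed the input count", call. = FALSE)
  if (n_deficient_top + n_deficient_bottom > n_deficient_in)
    stop("deficient outlet counts exceed the input count", call. = FALSE)
  structure(as.list(v), class = "confusion_counts")
}

#' Build confusion counts from a simulated outcome
#'
#' @param outcome a `sort_outcome` from [simulate_population()].
#' @param competent,deficient phenotype ids of the two classes.
#' @return object of class `confusion_counts`.
#' @export
as_confusion_counts <- function(outcome, competent = "competent",
                                deficient = "deficient") {
  stopifnot(inherits(outcome, "sort_outcome"))
  cts <- outcome$counts
  gc_ <- cts[cts$phenotype == competent, ]
  gd <- cts[cts$phenotype == deficient, ]
  if (nrow(gc_) != 1L || nrow(gd) != 1L)
    stop("phenotype ids not found in the outcome", call. = FALSE)
  confusion_counts(gc_$n_in, gc_$exited_bottom, gc_$exited_top,
                   gd$n_in, gd$exited_top, gd$exited_bottom)
}

#' Sorting efficiency of the taxis-competent class
#'
#' Fraction of introduced competent animals discharged at the bottom (their
#' correct outlet): `eff_C = N_C_bottom / N_C_in`.
#'
#' @param counts a [confusion_counts()].
#' @return fraction in `[0, 1]`.
#' @export
efficiency_competent <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$n_competent_in <= 0)
    stop("no competent animals were introduced", call. = FALSE)
  counts$n_competent_bottom / counts$n_competent_in
}

#' Sorting efficiency of the taxis-deficient class
#'
#' Fraction of introduced deficient animals discharged at the top:
#' `eff_D = N_D_top / N_D_in`.
#'
#' @param counts a [confusion_counts()].
#' @return fraction in `[0, 1]`.
#' @export
efficiency_deficient <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$n_deficient_in <= 0)
    stop("no deficient animals were introduced", call. = FALSE)
  counts$n_deficient_top / counts$n_deficient_in
}

#' Specificity of the top outlet
#'
#' Fraction of animals collected at the top that are truly taxis-deficient:
#' `S_p = N_D_top / (N_D_top + N_C_top)`. This is the quantity a forward
#' genetic screen cares about, since top-collected animals go on to
#' sequencing.
#'
#' @param counts a [confusion_counts()].
#' @return fraction in `[0, 1]`.
#' @export
specificity <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tot <- counts$n_deficient_top + counts$n_competent_top
  if (tot <= 0)
    stop("specificity is undefined: the top outlet collected no animals",
         call. = FALSE)
  counts$n_deficient_top / tot
}

#' Per-round efficiency series
#'
#' Efficiencies of successive sorting rounds in which the top-collected
#' fraction is rested and re-sorted.
#'
#' @param efficiencies numeric vector of per-round efficiencies in `[0, 1]`.
#' @param counts optional list of per-round [confusion_counts()].
#' @param recovery_interval rest time between rounds, minutes.
#' @return object of class `round_series`.
#' @export
round_series <- function(efficiencies, counts = NULL,
                         recovery_interval = 120) {
  if (!length(efficiencies))
    stop("at least one round is required", call. = FALSE)
  if (any(!is.finite(efficiencies)) || any(efficiencies < 0) ||
      any(efficiencies > 1))
    stop("efficiencies must lie in [0, 1]", call. = FALSE)
  structure(list(efficiencies = as.numeric(efficiencies), counts = counts,
                 recovery_interval = recovery_interval),
            class = "round_series")
}

#' Cumulative efficiency of repeated sorting rounds
#'
#' When the top-collected fraction is re-sorted after each round, a
#' competent animal ends at the bottom unless it is misclassified in every
#' round, so after K rounds the cumulative efficiency is
#' `1 - prod(1 - eff_k)`. Monotone non-decreasing in K; three rounds at 0.9
#' reach 0.999.
#'
#' @param series a [round_series()] or a plain numeric vector of per-round
#'   efficiencies.
#' @return cumulative fraction in `[0, 1]`.
#' @export
cumulative_efficiency <- function(series) {
  eff <- if (inherits(series, "round_series")) series$efficiencies
  else as.numeric(series)
  if (!length(eff)) stop("empty round series", call. = FALSE)
  if (any(!is.finite(eff)) || any(eff < 0) || any(eff > 1))
    stop("efficiencies must lie in [0, 1]", call. = FALSE)
  1 - prod(1 - eff)
}

#' Four-parameter logistic decline model
#'
#' `eff(t) = a / (1 + exp(-b (t - d))) + c` with time in minutes. With
#' `b < 0` the curve declines from the plateau `a + c` to `c`; `d` is the
#' midpoint and `|b|` the steepness. The `form_id` records the variant so
#' fitted coefficients are unambiguous.
#'
#' @param a amplitude (dimensionless).
#' @param b rate, per minute (negative for a decline).
#' @param c baseline plateau.
#' @param d midpoint, minutes.
#' @param form_id identifier of the parameterization.
#' @return object of class `logistic_decline`.
#' @export
logistic_decline <- function(a, b, c, d, form_id = "a/(1+exp(-b(t-d)))+c") {
  for (v in list(a, b, c, d))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("logistic coefficients must be finite numbers", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d, form_id = form_id),
            class = "logistic_decline")
}

#' Evaluate the logistic decline model
#'
#' @param model a [logistic_decline()].
#' @param t time, minutes (vectorized).
#' @return model values, bounded by the two plateaus `c` and `a + c`.
#' @export
evaluate_logistic <- function(model, t) {
  stopifnot(inherits(model, "logistic_decline"))
  model$a / (1 + exp(-model$b * (t - model$d))) + model$c
}

#' Fit the logistic decline to efficiency-versus-time data
#'
#' Nonlinear least squares (Levenberg-Marquardt, multi-start over midpoint
#' and sign-appropriate rate guesses) of the 4-parameter logistic of
#' [logistic_decline()]. Constant data are flagged degenerate and returned
#' as `a = 0, c = mean`.
#'
#' @param times times, minutes (at least 5 points).
#' @param efficiencies observed efficiencies in `[0, 1]`.
#' @param n_starts number of multi-start initializations.
#' @return list with `model` ([logistic_decline()]), `r_squared`,
#'   `residuals`, `converged`, `degenerate`.
#' @export
fit_logistic_decline <- function(times, efficiencies, n_starts = 8) {
  if (length(times) != length(efficiencies) || length(times) < 5)
    stop("need at least 5 (time, efficiency) points", call. = FALSE)
  if (any(efficiencies < -1e-9) || any(efficiencies > 1 + 1e-9))
    stop("efficiencies must lie in [0, 1]", call. = FALSE)
  y <- as.numeric(efficiencies); tt <- as.numeric(times)
  if (stats::sd(y) < 1e-12) {
    return(list(model = logistic_decline(0, -1, mean(y), mean(tt)),
                r_squared = NA_real_, residuals = y - mean(y),
                converged = TRUE, degenerate = TRUE))
  }
  rng <- range(tt)
  amp <- max(y) - min(y)
  declining <- stats::cor(tt, y) < 0
  best <- NULL; best_rss <- Inf
  dgrid <- seq(rng[1], rng[2], length.out = max(3, ceiling(n_starts / 2)))
  bgrid <- (if (declining) -1 else 1) * c(0.2, 1, 4) * 4 / max(diff(rng), 1)
  starts <- expand.grid(d = dgrid, b = bgrid)
  starts <- starts[seq_len(min(nrow(starts), max(n_starts, 4))), ]
  for (r in seq_len(nrow(starts))) {
    st <- list(a = amp, b = starts$b[r], c = min(y), d = starts$d[r])
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a / (1 + exp(-b * (tt - d))) + c,
                        start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (rss < best_rss) { best <- fit; best_rss <- rss }
  }
  if (is.null(best))
    return(list(model = logistic_decline(0, -1, mean(y), mean(tt)),
                r_squared = NA_real_, residuals = y - mean(y),
                converged = FALSE, degenerate = FALSE))
  cf <- as.list(stats::coef(best))
  r2 <- 1 - best_rss / sum((y - mean(y))^2)
  list(model = logistic_decline(cf$a, cf$b, cf$c, cf$d),
       r_squared = r2, residuals = as.numeric(stats::residuals(best)),
       converged = TRUE, degenerate = FALSE)
}

#' Gait-frequency summary
#'
#' @param mean mean frequency, Hz.
#' @param sd standard deviation, Hz.
#' @param n sample size (at least 2).
#' @return object of class `gait_summary`.
#' @export
gait_summary <- function(mean, sd, n) {
  .check_nonneg(sd, "sd")
  if (n < 2 || n != round(n)) stop("n must be an integer >= 2", call. = FALSE)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "gait_summary")
}

#' Two-sample t-test from summary statistics
#'
#' Student's t-test computed from (mean, sd, n) summaries, as needed when
#' only published summaries are available. Welch's unequal-variance form is
#' the default; the pooled form and one-tailed p-values are available. With
#' zero variance in both groups and equal means, returns `t = 0, p = 1`.
#'
#' @param g1,g2 [gait_summary()] objects (or lists with `mean`, `sd`, `n`).
#' @param tails 1 or 2.
#' @param pooled use the pooled-variance (classical Student) form.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t_from_summary <- function(g1, g2, tails = 2, pooled = FALSE) {
  for (g in list(g1, g2))
    if (!all(c("mean", "sd", "n") %in% names(g)) || g$n < 2)
      stop("summaries need mean, sd and n >= 2", call. = FALSE)
  if (!tails %in% c(1, 2)) stop("tails must be 1 or 2", call. = FALSE)
  dm <- g1$mean - g2$mean
  if (g1$sd == 0 && g2$sd == 0) {
    if (dm == 0)
      return(list(t = 0, df = g1$n + g2$n - 2, p = 1))
    return(list(t = sign(dm) * Inf, df = g1$n + g2$n - 2, p = 0))
  }
  if (pooled) {
    df <- g1$n + g2$n - 2
    sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
    se <- sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  } else {
    v1 <- g1$sd^2 / g1$n; v2 <- g2$sd^2 / g2$n
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  }
  tstat <- dm / se
  p <- tails * stats::pt(-abs(tstat), df)
  list(t = tstat, df = df, p = p)
}
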