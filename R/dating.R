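#' Generations to the founder from autozygous segment lengths
#'
#' In a patient autozygous for a founder allele, both haplotypes descend
#' from the founder through lineages of `g` meioses, so each flank of the
#' shared segment beyond the variant is eroded by recombination as an
#' exponential of rate `2g` per Morgan. A patient's segment genetic length
#' is then the sum of two such flanks, `Gamma(2, rate 2g)`, and the total
#' length `S` (Morgans) over `n` independent patients is
#' `Gamma(2n, rate 2g)`. The maximum-likelihood estimate is `g_hat = n / S`
#' and an equal-tailed confidence interval follows from the exact pivot
#' `2 g S ~ Gamma(2n, 1)`:
#' `g_bound = qgamma(alpha/2 | 1 - alpha/2, shape = 2n) / (2 S)`.
#'
#' With `min_length_cm` set, the lengths are instead modelled as
#' `Gamma(2, 2g)` conditioned on exceeding that detection threshold (ROH
#' callers cannot see short segments, which biases the naive estimator
#' down); the truncated likelihood is maximised numerically and the interval
#' is a profile likelihood-ratio interval.
#'
#' @param lengths_cm Per-patient ROH genetic lengths around the variant
#'   (cM, sex-averaged). All must be positive.
#' @param conf.level Confidence level (default 0.95).
#' @param min_length_cm Optional detection threshold (cM) activating the
#'   truncated-likelihood variant. Default `NULL` (untruncated MLE).
#'
#' @return An object of class `founder_age`; see [tidy.founder_age()] and
#'   [years_from_generations()].
#' @examples
#' estimate_generations(c(25, 25, 25, 25)) # S = 1 Morgan, g_hat = 4
#' @export
estimate_generations <- function(lengths_cm, conf.level = 0.95,
                                 min_length_cm = NULL) {
  if (!length(lengths_cm)) stop_input("`lengths_cm` must be non-empty.")
  if (!is.numeric(lengths_cm) || any(is.na(lengths_cm)) ||
      any(lengths_cm <= 0)) {
    stop_input("all segment lengths must be positive (cM).")
  }
  conf.level <- check_proportion(conf.level, "conf.level", open = TRUE)
  n <- length(lengths_cm)
  s_morgans <- sum(lengths_cm) / 100
  alpha <- 1 - conf.level
  if (is.null(min_length_cm)) {
    g_hat <- n / s_morgans
    bounds <- qgamma(c(alpha / 2, 1 - alpha / 2), shape = 2 * n) /
      (2 * s_morgans)
    method <- "gamma"
  } else {
    if (min_length_cm < 0 || any(lengths_cm < min_length_cm)) {
      stop_input("`min_length_cm` must be >= 0 and below every length.")
    }
    fit <- fit_truncated_gamma(lengths_cm / 100, min_length_cm / 100, alpha)
    g_hat <- fit$g_hat
    bounds <- fit$bounds
    method <- "truncated"
  }
  structure(
    list(
      g_hat = g_hat, g_lower = bounds[1], g_upper = bounds[2],
      conf.level = conf.level, n = n, total_morgans = s_morgans,
      lengths_cm = as.numeric(lengths_cm), method = method,
      min_length_cm = min_length_cm,
      generation_years = NA_real_,
      age_years = NA_real_, age_lower = NA_real_, age_upper = NA_real_
    ),
    class = "founder_age"
  )
}

# log-likelihood of segment lengths (Morgans) under Gamma(2, 2g) left-
# truncated at `trunc`; MLE by 1-d optimisation, CI by profile LR
fit_truncated_gamma <- function(lengths_m, trunc, alpha) {
  loglik <- function(g) {
    sum(stats::dgamma(lengths_m, shape = 2, rate = 2 * g, log = TRUE)) -
      length(lengths_m) *
        stats::pgamma(trunc, shape = 2, rate = 2 * g, lower.tail = FALSE,
                      log.p = TRUE)
  }
  naive <- length(lengths_m) / sum(lengths_m)
  opt <- optimize(loglik, interval = c(naive * 1e-3, naive * 1e3),
                  maximum = TRUE, tol = 1e-10)
  g_hat <- opt$maximum
  cut <- opt$objective - stats::qchisq(1 - alpha, df = 1) / 2
  drop <- function(g) loglik(g) - cut
  lo <- uniroot(drop, lower = g_hat * 1e-6, upper = g_hat, tol = 1e-10)$root
  hi <- g_hat
  while (drop(hi * 2) > 0) hi <- hi * 2
  hi <- uniroot(drop, lower = g_hat, upper = hi * 2, tol = 1e-10)$root
  list(g_hat = g_hat, bounds = c(lo, hi))
}

#' Convert a generation estimate to calendar years
#'
#' Multiplies the generation estimate and both confidence bounds by the
#' generation interval (default 25 years, the usual human figure).
#'
#' @param age A `founder_age` from [estimate_generations()].
#' @param generation_years Years per generation (positive; default 25).
#' @return The `founder_age` with `age_years`, `age_lower`, `age_upper` set.
#' @examples
#' estimate_generations(c(25, 25, 25, 25)) |> years_from_generations()
#' @export
years_from_generations <- function(age, generation_years = 25) {
  if (!inherits(age, "founder_age")) stop_input("`age` must be founder_age")
  if (!is.numeric(generation_years) || length(generation_years) != 1L ||
      is.na(generation_years) || generation_years <= 0) {
    stop_input("`generation_years` must be a positive number.")
  }
  age$generation_years <- generation_years
  age$age_years <- age$g_hat * generation_years
  age$age_lower <- age$g_lower * generation_years
  age$age_upper <- age$g_upper * generation_years
  age
}

#' Date a founder mutation from physical ROH intervals
#'
#' End-to-end entry point: converts each patient's physical autozygous
#' interval to a genetic length on the map, estimates generations to the
#' common ancestor, and converts to years. Equivalent to chaining
#' [genetic_length()], [estimate_generations()] and
#' [years_from_generations()].
#'
#' @param intervals A tibble with columns `chrom`, `start_bp`, `end_bp`
#'   (one row per patient).
#' @param map A [genetic_map()] covering the intervals' chromosome.
#' @inheritParams estimate_generations
#' @inheritParams years_from_generations
#' @return A `founder_age` with both generation and year fields set.
#' @export
date_from_intervals <- function(intervals, map, conf.level = 0.95,
                                generation_years = 25,
                                min_length_cm = NULL) {
  if (!is.data.frame(intervals) || !nrow(intervals)) {
    stop_input("`intervals` must be a non-empty data frame.")
  }
  need <- c("chrom", "start_bp", "end_bp")
  miss <- setdiff(need, names(intervals))
  if (length(miss)) {
    stop_input(paste0("`intervals` lacks column(s): ",
                      paste(miss, collapse = ", ")))
  }
  if (length(unique(intervals$chrom)) != 1L) {
    stop_input("all intervals must lie on one mapped chromosome")
  }
  lengths_cm <- genetic_length(map, intervals$chrom[1],
                               intervals$start_bp, intervals$end_bp)
  estimate_generations(lengths_cm, conf.level = conf.level,
                       min_length_cm = min_length_cm) |>
    years_from_generations(generation_years)
}

#' @export
print.founder_age <- function(x, ...) {
  cat("Founder-allele age from autozygous segment lengths\n")
  cat(sprintf(
    "  model: per-patient ROH length ~ Gamma(2, rate 2g)%s; pooled MLE\n",
    if (x$method == "truncated") {
      sprintf(" truncated at %.3g cM", x$min_length_cm)
    } else ""
  ))
  cat(sprintf("  n = %d patients, total length %.4f Morgans\n",
              x$n, x$total_morgans))
  cat(sprintf("  generations to common ancestor: %.2f (%.0f%% CI %.2f-%.2f)\n",
              x$g_hat, 100 * x$conf.level, x$g_lower, x$g_upper))
  if (!is.na(x$age_years)) {
    cat(sprintf("  age: %.2f years (CI %.2f-%.2f) at %.3g years/generation\n",
                x$age_years, x$age_lower, x$age_upper, x$generation_years))
  }
  invisible(x)
}

#' Tidy a founder-age fit
#'
#' @param x A `founder_age`.
#' @param ... Unused.
#' @return `tidy()`: one row per quantity (`generations`, and `age_years`
#'   when set) with `estimate`, `conf.low`, `conf.high`. `glance()`: a
#'   one-row model summary.
#' @method tidy founder_age
#' @export
tidy.founder_age <- function(x, ...) {
  out <- tibble(
    term = "generations", estimate = x$g_hat,
    conf.low = x$g_lower, conf.high = x$g_upper
  )
  if (!is.na(x$age_years)) {
    out <- dplyr::bind_rows(out, tibble(
      term = "age_years", estimate = x$age_years,
      conf.low = x$age_lower, conf.high = x$age_upper
    ))
  }
  out
}

#' @rdname tidy.founder_age
#' @method glance founder_age
#' @export
glance.founder_age <- function(x, ...) {
  tibble(
    n = x$n, total_cm = 100 * x$total_morgans, method = x$method,
    conf.level = x$conf.level,
    generation_years = x$generation_years
  )
}
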