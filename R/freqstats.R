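#' Assemble a cohort carrier-count table
#'
#' Builds the validated tibble of binomial observations that the frequency
#' and incidence estimators consume: one row per population sample, with the
#' number of genotyped individuals and the number of variant *alleles*
#' observed among them (a homozygous carrier contributes `ploidy` alleles,
#' a heterozygous carrier one).
#'
#' @param population Character vector of population labels.
#' @param n_individuals Number of genotyped individuals per population.
#' @param n_carrier_alleles Number of variant alleles observed per population.
#' @param ploidy Chromosome copies per individual (default 2, autosomal).
#'
#' @return A tibble with columns `population`, `n_individuals`,
#'   `n_carrier_alleles`, `ploidy` and `n_alleles` (`ploidy * n_individuals`).
#'
#' @examples
#' cohort_counts(c("Mari", "Tatar", "Bashkir"), c(132, 87, 284), c(1, 0, 0))
#' @export
cohort_counts <- function(population, n_individuals, n_carrier_alleles,
                          ploidy = 2L) {
  n_individuals <- check_count(n_individuals, "n_individuals")
  n_carrier_alleles <- check_count(n_carrier_alleles, "n_carrier_alleles")
  ploidy <- check_count(ploidy, "ploidy", allow_zero = FALSE)
  out <- tibble(
    population = as.character(population),
    n_individuals = n_individuals,
    n_carrier_alleles = n_carrier_alleles,
    ploidy = ploidy
  )
  out$n_alleles <- out$ploidy * out$n_individuals
  bad <- out$n_carrier_alleles > out$n_alleles
  if (any(bad)) {
    stop_input(sprintf(
      "n_carrier_alleles exceeds ploidy * n_individuals for: %s",
      paste(out$population[bad], collapse = ", ")
    ))
  }
  out
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Inverts the binomial tail probabilities exactly, in the standard
#' beta-quantile form: the lower bound is the `alpha/2` quantile of
#' `Beta(x, n - x + 1)` and the upper bound the `1 - alpha/2` quantile of
#' `Beta(x + 1, n - x)`, with the boundary conventions `lower = 0` when
#' `x = 0` and `upper = 1` when `x = n`. The exact interval is conservative:
#' its coverage is at least the nominal level for every true proportion.
#'
#' @param successes Number of successes (vectorised).
#' @param trials Number of trials (vectorised; must be positive).
#' @param conf.level Confidence level, in (0, 1). Default 0.95.
#'
#' @return A tibble with columns `successes`, `trials`, `estimate`,
#'   `conf.low`, `conf.high`, `conf.level`.
#'
#' @examples
#' clopper_pearson(1, 264) # one variant allele among 264
#' @export
clopper_pearson <- function(successes, trials, conf.level = 0.95) {
  x <- check_count(successes, "successes")
  n <- check_count(trials, "trials")
  conf.level <- check_proportion(conf.level, "conf.level", open = TRUE)
  if (any(n == 0L)) stop_input("`trials` must be positive (degenerate input).")
  if (any(x > n)) stop_input("`successes` must not exceed `trials`.")
  alpha <- 1 - conf.level
  lower <- ifelse(x == 0L, 0, qbeta(alpha / 2, x, n - x + 1))
  upper <- ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x))
  tibble(
    successes = x, trials = n,
    estimate = x / n,
    conf.low = lower, conf.high = upper,
    conf.level = conf.level
  )
}

#' Carrier-allele frequency with exact confidence interval
#'
#' Estimates the variant-allele frequency `q = x / (ploidy * n)` for each
#' cohort row and, unless `ci = FALSE`, attaches the exact Clopper-Pearson
#' interval on the allele count.
#'
#' @param cohorts A tibble as returned by [cohort_counts()] (columns
#'   `n_individuals`, `n_carrier_alleles`; `ploidy` and `population`
#'   optional — ploidy defaults to 2).
#' @param conf.level Confidence level for the exact interval.
#' @param ci Attach the Clopper-Pearson interval? Default `TRUE`.
#'
#' @return The input tibble with columns `q_hat`, and (if `ci`) `ci_lower`,
#'   `ci_upper`, `conf.level` appended; plus `n_alleles` if absent.
#'
#' @examples
#' cohort_counts("Mari", 132, 1) |> allele_frequency()
#' @export
allele_frequency <- function(cohorts, conf.level = 0.95, ci = TRUE) {
  if (!is.data.frame(cohorts)) stop_input("`cohorts` must be a data frame.")
  need <- c("n_individuals", "n_carrier_alleles")
  miss <- setdiff(need, names(cohorts))
  if (length(miss)) {
    stop_input(paste0("`cohorts` lacks column(s): ",
                      paste(miss, collapse = ", ")))
  }
  cohorts <- as_tibble(cohorts)
  if (is.null(cohorts$ploidy)) cohorts$ploidy <- 2L
  if (any(cohorts$n_individuals == 0L)) {
    stop_input("n_individuals must be positive (degenerate input).")
  }
  cohorts$n_alleles <- cohorts$ploidy * cohorts$n_individuals
  cohorts$q_hat <- cohorts$n_carrier_alleles / cohorts$n_alleles
  if (ci) {
    cp <- clopper_pearson(cohorts$n_carrier_alleles, cohorts$n_alleles,
                          conf.level = conf.level)
    cohorts$ci_lower <- cp$conf.low
    cohorts$ci_upper <- cp$conf.high
    cohorts$conf.level <- conf.level
  }
  cohorts
}

#' Hardy-Weinberg projection of recessive disease incidence
#'
#' Squares the (unrounded) allele frequency and its confidence bounds and
#' rescales to cases per `scale` persons: under random mating an autosomal
#' recessive condition with allele frequency `q` affects `q^2` of births.
#' Squaring is monotone on \[0, 1\], so the transformed bounds remain a valid
#' interval at the same confidence level.
#'
#' @param freq A tibble from [allele_frequency()] with `q_hat` (and, if
#'   present, `ci_lower`/`ci_upper`) columns.
#' @param scale Population scale of the incidence (default 100,000).
#'
#' @return The input with `incidence`, and (when the CI columns exist)
#'   `incidence_ci_lower`, `incidence_ci_upper`, appended; all per `scale`.
#'
#' @examples
#' cohort_counts("Mari", 132, 1) |> allele_frequency() |> hwe_incidence()
#' @export
hwe_incidence <- function(freq, scale = 1e5) {
  if (!is.data.frame(freq) || is.null(freq$q_hat)) {
    stop_input("`freq` must be a data frame with a `q_hat` column.")
  }
  scale <- check_count(scale, "scale", allow_zero = FALSE)
  freq <- as_tibble(freq)
  freq$incidence <- freq$q_hat^2 * scale
  if (!is.null(freq$ci_lower)) {
    freq$incidence_ci_lower <- freq$ci_lower^2 * scale
    freq$incidence_ci_upper <- freq$ci_upper^2 * scale
  }
  freq$incidence_scale <- scale
  freq
}
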