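test_that("identical seeds give identical cohorts", {
  cfg <- simulation_config(true_g = 8, n_patients = 2, marker_count = 500,
                           missing_rate = 0.02, het_error_rate = 0.01,
                           seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$truth, b$truth)
  expect_identical(a$map$cm, b$map$cm)
})

test_that("planted segments contain the variant and honour the error model", {
  cfg <- simulation_config(true_g = 6, n_patients = 5, marker_count = 800,
                           seed = 3)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$truth$start_bp <= cfg$variant_position_bp))
  expect_true(all(sim$truth$end_bp >= cfg$variant_position_bp))
  # zero error rate: heterozygous calls are impossible inside the truth
  joined <- dplyr::inner_join(sim$genotypes, sim$truth,
                              by = c("sample_id", "chrom"))
  inside <- dplyr::filter(joined, pos >= start_bp, pos <= end_bp)
  expect_false(any(inside$call == "HET"))
  # founder concordance: where two patients' segments overlap, their
  # homozygous genotypes agree marker-by-marker
  ov <- dplyr::inner_join(
    dplyr::filter(inside, sample_id == "P001"),
    dplyr::filter(inside, sample_id == "P002"),
    by = c("chrom", "pos")
  )
  if (nrow(ov)) expect_true(all(ov$call.x == ov$call.y))
})

test_that("simulated segment lengths follow the two-flank exponential law", {
  map <- make_genetic_map_fixture(3e8, 400, seed = 21)
  iv <- simulate_roh_intervals(map, "chr9", true_g = 10, n = 2000,
                               variant_position_bp = 1.5e8, seed = 22)
  lens <- genetic_length(map, "chr9", iv$start_bp, iv$end_bp)
  # mean of two Exp(2g) flanks is 1/g Morgans = 10 cM at g = 10
  expect_lt(abs(mean(lens) - 10) / 10, 0.05)
  # deep genealogies leave almost nothing
  deep <- simulate_roh_intervals(map, "chr9", true_g = 10000, n = 200,
                                 variant_position_bp = 1.5e8, seed = 23)
  deep_lens <- genetic_length(map, "chr9", deep$start_bp, deep$end_bp)
  expect_lt(median(deep_lens), 0.1)
})

test_that("crossover-process simulator agrees with the exponential-flank path", {
  map <- make_genetic_map_fixture(3e8, 300, seed = 31)
  a <- simulate_roh_intervals(map, "chr9", 10, 1500, 1.5e8, seed = 41)
  b <- simulate_roh_intervals_crossover(map, "chr9", 10, 1500, 1.5e8,
                                        seed = 42)
  la <- genetic_length(map, "chr9", a$start_bp, a$end_bp)
  lb <- genetic_length(map, "chr9", b$start_bp, b$end_bp)
  # same law (sum of two Exp(2g) flanks): means within sampling noise
  se <- sqrt(var(la) / 1500 + var(lb) / 1500)
  expect_lt(abs(mean(la) - mean(lb)), 4 * se)
})

test_that("cohort-count draws follow the binomial sampling model", {
  expect_equal(
    simulate_cohort_counts(0, 132, seed = 1)$n_carrier_alleles, 0L
  )
  expect_equal(
    simulate_cohort_counts(1, 132, seed = 1)$n_carrier_alleles, 264L
  )
  set.seed(500)
  q <- 0.0038; n <- 132L
  draws <- vapply(1:10000, function(i) {
    simulate_cohort_counts(q, n)$n_carrier_alleles
  }, integer(1))
  se <- sqrt(2 * n * q * (1 - q) / 10000)
  expect_lt(abs(mean(draws) - 2 * n * q), 3 * se)
})

test_that("map fixtures are monotone, invertible, and exact at identity rate", {
  flat <- make_genetic_map_fixture(1e7, 50, mean_rate_cm_per_mb = 1,
                                   rate_shape = Inf)
  expect_equal(genetic_length(flat, "chr9", 1e6, 3e6), 2.0)
  # bp -> cM -> bp round-trips within one bp on the identity-rate map
  bp <- c(1, 12345, 999999, 5.5e6, 1e7)
  back <- interpolate_bp(flat, "chr9", interpolate_cm(flat, "chr9", bp))
  expect_lt(max(abs(back - bp)), 1)
  for (seed in 1:40) {
    m <- make_genetic_map_fixture(1e7, 100, seed = seed)
    expect_true(all(diff(m$cm) > 0), info = paste("seed", seed))
  }
})

test_that("simulation configs are validated", {
  expect_error(simulation_config(true_g = 0, n_patients = 5),
               class = "founderage_input_error")
  expect_error(
    simulation_config(true_g = 5, n_patients = 5,
                      variant_position_bp = 1e12),
    class = "founderage_input_error"
  )
  expect_error(
    simulation_config(true_g = 5, n_patients = 5, marker_count = 10,
                      marker_freq = rep(0.5, 3)),
    class = "founderage_input_error"
  )
})
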