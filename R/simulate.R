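#' Configuration of the founder-descent simulator
#'
#' Bundles and validates everything the forward simulator needs: the true
#' number of generations to the founder, cohort size, chromosome geometry,
#' the marker panel model and per-marker population allele frequencies, the
#' anchor variant position, optional genotyping-error and missingness rates,
#' and the seed.
#'
#' @param true_g True generations from each patient's two lineages back to
#'   the founder (positive).
#' @param n_patients Number of autozygous patients to simulate.
#' @param chrom Chromosome label.
#' @param chromosome_length_bp Chromosome length (bp).
#' @param marker_count Markers on the panel.
#' @param marker_spacing `"uniform"` (evenly spaced) or `"random"`
#'   (uniformly scattered, sorted).
#' @param marker_freq Per-marker population alternate-allele frequencies in
#'   \[0, 1\]; `NULL` (default) draws them `Uniform(0.1, 0.9)` from the seed.
#' @param variant_position_bp Position of the founder variant; default the
#'   chromosome midpoint.
#' @param het_error_rate Probability a truly homozygous call inside the
#'   autozygous segment is mis-genotyped as heterozygous. Default 0.
#' @param missing_rate Per-marker missing-call probability. Default 0.
#' @param seed Integer seed driving the whole simulation.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(true_g, n_patients, chrom = "chr9",
                              chromosome_length_bp = 141e6,
                              marker_count = 2000L,
                              marker_spacing = c("uniform", "random"),
                              marker_freq = NULL,
                              variant_position_bp = NULL,
                              het_error_rate = 0, missing_rate = 0,
                              seed = 1L) {
  if (!is.numeric(true_g) || true_g <= 0) stop_input("`true_g` must be > 0.")
  cfg <- list(
    true_g = as.numeric(true_g),
    n_patients = check_count(n_patients, "n_patients", FALSE),
    chrom = as.character(chrom),
    chromosome_length_bp = check_count(chromosome_length_bp,
                                       "chromosome_length_bp", FALSE),
    marker_count = check_count(marker_count, "marker_count", FALSE),
    marker_spacing = match.arg(marker_spacing),
    marker_freq = marker_freq,
    variant_position_bp = variant_position_bp %||%
      round(chromosome_length_bp / 2),
    het_error_rate = check_proportion(het_error_rate, "het_error_rate"),
    missing_rate = check_proportion(missing_rate, "missing_rate"),
    seed = check_count(seed, "seed")
  )
  if (!is.null(cfg$marker_freq)) {
    check_proportion(cfg$marker_freq, "marker_freq")
    if (length(cfg$marker_freq) != cfg$marker_count) {
      stop_input("`marker_freq` must have length `marker_count`.")
    }
  }
  if (cfg$variant_position_bp < 1 ||
      cfg$variant_position_bp > cfg$chromosome_length_bp) {
    stop_input("`variant_position_bp` must lie on the chromosome.")
  }
  structure(cfg, class = "simulation_config")
}

#' Synthetic genetic-map fixture
#'
#' Builds a monotone genetic map with locally varying recombination rate:
#' knot spacings get independent Gamma-distributed rates around
#' `mean_rate_cm_per_mb`, so the cM track is strictly increasing and hence
#' invertible (the simulator maps Morgans back to bp through it). With
#' `rate_shape = Inf` the rate is constant, giving the identity-rate map
#' `cm = bp * mean_rate_cm_per_mb / 1e6`.
#'
#' @param chromosome_length_bp Chromosome length (bp).
#' @param knot_count Number of knots (>= 2), placed from bp 1 to the end.
#' @param mean_rate_cm_per_mb Mean recombination rate (cM/Mb), default 1.
#' @param seed Optional integer seed (`NULL` uses the current RNG state).
#' @param chrom Chromosome label.
#' @param rate_shape Gamma shape of the per-interval rate variation; larger
#'   is smoother, `Inf` is constant. Default 8.
#' @return A [genetic_map()].
#' @export
make_genetic_map_fixture <- function(chromosome_length_bp, knot_count,
                                     mean_rate_cm_per_mb = 1, seed = NULL,
                                     chrom = "chr9", rate_shape = 8) {
  knot_count <- check_count(knot_count, "knot_count", FALSE)
  if (knot_count < 2L) stop_input("`knot_count` must be at least 2.")
  if (mean_rate_cm_per_mb <= 0) stop_input("mean rate must be positive")
  if (!is.null(seed)) set.seed(seed)
  bp <- round(seq(1, chromosome_length_bp, length.out = knot_count))
  rates <- if (is.infinite(rate_shape)) {
    rep(mean_rate_cm_per_mb, knot_count - 1L)
  } else {
    mean_rate_cm_per_mb *
      stats::rgamma(knot_count - 1L, shape = rate_shape, rate = rate_shape)
  }
  cm <- c(0, cumsum(rates * diff(bp) / 1e6))
  genetic_map(chrom, bp, cm, build = "synthetic")
}

#' Marker panel shared by a simulated cohort
#'
#' Positions, population allele frequencies and the founder haplotype's
#' allele at each marker. The founder allele is drawn once per panel, so
#' autozygous segments are allele-concordant across patients sharing the
#' founder wherever they overlap.
#'
#' @param config A [simulation_config()]. Uses the current RNG state; seed
#'   via [simulate_cohort()] or `set.seed()`.
#' @return A tibble `pos`, `freq`, `founder_allele` (0 = reference,
#'   1 = alternate).
#' @export
marker_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  pos <- switch(config$marker_spacing,
    uniform = round(seq(1, config$chromosome_length_bp,
                        length.out = config$marker_count)),
    random = sort(sample.int(config$chromosome_length_bp,
                             config$marker_count))
  )
  pos <- as.integer(pos)
  freq <- config$marker_freq %||% runif(config$marker_count, 0.1, 0.9)
  tibble(
    pos = pos, freq = freq,
    founder_allele = rbinom(config$marker_count, 1L, freq)
  )
}

# one autozygous interval: two Exp(2g) flanks in Morgans around the variant,
# mapped to bp through the (invertible) map and clipped to map support
draw_roh_interval <- function(map, chrom, true_g, variant_bp, n = 1L) {
  variant_cm <- interpolate_cm(map, chrom, variant_bp)
  left_cm <- rexp(n, rate = 2 * true_g) * 100
  right_cm <- rexp(n, rate = 2 * true_g) * 100
  sub <- map_chrom(map, chrom)
  start_cm <- pmax(variant_cm - left_cm, min(sub$cm))
  end_cm <- pmin(variant_cm + right_cm, max(sub$cm))
  start_bp <- as.integer(round(interpolate_bp(map, chrom, start_cm)))
  end_bp <- as.integer(round(interpolate_bp(map, chrom, end_cm)))
  tibble(chrom = chrom, start_bp = start_bp, end_bp = end_bp)
}

#' Simulate true autozygous intervals only
#'
#' The fast path for estimator-recovery studies: draws each patient's two
#' segment flanks as `Exponential(rate 2 * true_g)` in Morgans (two
#' lineages of `true_g` meioses each erode every side; the surviving flank
#' is the minimum of two `Exp(true_g)` draws) and converts them to physical
#' coordinates through the map. No marker genotypes are generated.
#'
#' @param map A [genetic_map()] with strictly increasing cM.
#' @param chrom Chromosome label on the map.
#' @param true_g True generations to the founder.
#' @param n Number of patients.
#' @param variant_position_bp Anchor variant position (bp).
#' @param seed Optional integer seed.
#' @return A tibble `chrom`, `start_bp`, `end_bp`, one row per patient.
#' @export
simulate_roh_intervals <- function(map, chrom, true_g, n,
                                   variant_position_bp, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (true_g <= 0) stop_input("`true_g` must be > 0.")
  n <- check_count(n, "n", FALSE)
  draw_roh_interval(map, chrom, true_g, variant_position_bp, n)
}

#' Simulate one autozygous patient
#'
#' Draws the patient's true autozygous interval (exponential flank erosion,
#' see [simulate_roh_intervals()]), then fills the marker panel: inside the
#' segment every marker is homozygous for the founder allele (optionally
#' flipped to a heterozygous call at `het_error_rate`); outside, genotypes
#' are drawn under Hardy-Weinberg from the per-marker population
#' frequencies; any call may be masked missing at `missing_rate`.
#'
#' @param config A [simulation_config()].
#' @param map A [genetic_map()] (e.g. [make_genetic_map_fixture()]).
#' @param panel A [marker_panel()]; built from `config` if `NULL`.
#' @param sample_id Sample label.
#' @return A list: `genotypes` (tibble as [marker_genotypes()]) and `truth`
#'   (one-row tibble `chrom`, `start_bp`, `end_bp` of the planted segment).
#' @export
simulate_patient <- function(config, map, panel = NULL,
                             sample_id = "patient1") {
  stopifnot(inherits(config, "simulation_config"))
  panel <- panel %||% marker_panel(config)
  truth <- draw_roh_interval(map, config$chrom, config$true_g,
                             config$variant_position_bp)
  m <- nrow(panel)
  inside <- panel$pos >= truth$start_bp & panel$pos <= truth$end_bp
  call <- character(m)
  # outside the segment: Hardy-Weinberg draws from population frequencies
  alt_dose <- rbinom(m, 2L, panel$freq)
  call[!inside] <- c("HOM_REF", "HET", "HOM_ALT")[alt_dose[!inside] + 1L]
  # inside: homozygous for the founder haplotype's allele
  call[inside] <- ifelse(panel$founder_allele[inside] == 1L,
                         "HOM_ALT", "HOM_REF")
  if (config$het_error_rate > 0) {
    flip <- inside & runif(m) < config$het_error_rate
    call[flip] <- "HET"
  }
  if (config$missing_rate > 0) {
    call[runif(m) < config$missing_rate] <- "MISSING"
  }
  list(
    genotypes = marker_genotypes(config$chrom, panel$pos, call, sample_id),
    truth = dplyr::mutate(truth, sample_id = sample_id)
  )
}

#' Simulate a cohort of autozygous patients
#'
#' Seeds the RNG from the configuration, builds (or reuses) the map and the
#' shared marker panel, and simulates `n_patients` patients descending from
#' one founder haplotype.
#'
#' @param config A [simulation_config()].
#' @param map A [genetic_map()]; a 1 cM/Mb-scale synthetic fixture with 500
#'   knots is built from the config seed if `NULL`.
#' @return A list: `genotypes` (all samples stacked), `truth` (one row per
#'   patient), `panel`, `map`, `config`.
#' @export
simulate_cohort <- function(config, map = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  map <- map %||% make_genetic_map_fixture(
    config$chromosome_length_bp, knot_count = 500L, chrom = config$chrom
  )
  panel <- marker_panel(config)
  patients <- purrr::map(seq_len(config$n_patients), function(i) {
    simulate_patient(config, map, panel, sample_id = sprintf("P%03d", i))
  })
  list(
    genotypes = purrr::list_rbind(purrr::map(patients, "genotypes")),
    truth = purrr::list_rbind(purrr::map(patients, "truth")),
    panel = panel, map = map, config = config
  )
}

#' Crossover-process cross-check simulator
#'
#' An independent generative path for the same quantity: instead of drawing
#' flank lengths from their exponential law directly, each haplotype's
#' lineage of `true_g` meioses receives crossovers as a Poisson process of
#' rate `true_g` per Morgan along the chromosome's genetic length; the
#' retained founder segment of a haplotype is the interval between the
#' nearest crossovers around the variant, and the patient's autozygous
#' segment is the intersection of the two haplotypes' retained segments
#' (which is what makes each side's surviving flank `Exp(2 * true_g)`).
#' Used in tests to cross-validate the exponential-flank model.
#'
#' @inheritParams simulate_roh_intervals
#' @return A tibble `chrom`, `start_bp`, `end_bp`, one row per patient.
#' @export
simulate_roh_intervals_crossover <- function(map, chrom, true_g, n,
                                             variant_position_bp,
                                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- check_count(n, "n", FALSE)
  sub <- map_chrom(map, chrom)
  total_m <- (max(sub$cm) - min(sub$cm)) / 100
  variant_m <- (interpolate_cm(map, chrom, variant_position_bp) -
                  min(sub$cm)) / 100
  one_haplotype <- function() {
    # one lineage of true_g meioses: crossovers fall as a Poisson process
    # of rate true_g per Morgan along the chromosome
    breaks <- runif(rpois(1L, true_g * total_m), 0, total_m)
    left <- c(0, breaks[breaks <= variant_m])
    right <- c(breaks[breaks > variant_m], total_m)
    c(max(left), min(right))
  }
  purrr::map_dfr(seq_len(n), function(i) {
    h1 <- one_haplotype()
    h2 <- one_haplotype()
    seg_m <- c(max(h1[1], h2[1]), min(h1[2], h2[2]))
    bp <- interpolate_bp(map, chrom, seg_m * 100 + min(sub$cm))
    tibble(chrom = chrom, start_bp = as.integer(round(bp[1])),
           end_bp = as.integer(round(bp[2])))
  })
}

#' Simulate a carrier-screening cohort count
#'
#' Binomial sampling model behind a population carrier screen: the observed
#' variant-allele count is `Binomial(ploidy * n_individuals, q)`.
#'
#' @param q True population allele frequency.
#' @param n_individuals Individuals genotyped.
#' @param population Population label.
#' @param ploidy Chromosome copies per individual (default 2).
#' @param seed Optional integer seed.
#' @return A [cohort_counts()] tibble (one row).
#' @export
simulate_cohort_counts <- function(q, n_individuals,
                                   population = "simulated", ploidy = 2L,
                                   seed = NULL) {
  q <- check_proportion(q, "q")
  n_individuals <- check_count(n_individuals, "n_individuals", FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- rbinom(1L, ploidy * n_individuals, q)
  cohort_counts(population, n_individuals, x, ploidy)
}

#' Deterministic RFLP assay fixture
#'
#' Constructs the 357-bp amplicon pair of the diagnostic assay at the
#' fragment-arithmetic level: the published primer pair flanks a sequence
#' carrying one constitutive Hpy188III site (TCNNGA) cutting 189 bp in, so
#' the wild-type amplicon digests to 189 + 168 bp; the mutant allele
#' differs by a two-base substitution that creates exactly one additional
#' site splitting the 189-bp fragment into 122 + 67 bp. Filler bases
#' contain no T, so no spurious site can arise, and the construction is
#' verified by digestion before returning. The sequence encodes the printed
#' fragment sizes, not the genomic locus.
#'
#' @param flank_bp Template filler added on each side of the amplicon
#'   (default 40 bp), exercising in-silico PCR.
#' @return A list: `wt_template`, `mut_template`, `primers`
#'   ([primer_pair()]), `wt_amplicon`, `mut_amplicon` (357 bp each),
#'   `wt_pattern` (189, 168), `mut_pattern` (168, 122, 67), `enzyme`
#'   ([hpy188iii()]).
#' @export
make_rflp_fixture <- function(flank_bp = 40L) {
  flank_bp <- check_count(flank_bp, "flank_bp")
  primers <- primer_pair("GTGAGAGCCAAGTACCACAACA",
                         "GGAGAGTCACACATAAGTGGAGGT")
  rc_rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(primers$reverse)
  ))
  filler <- function(n) {
    paste(rep_len(c("A", "C", "G"), n), collapse = "")
  }
  # 0-based layout: constitutive site at 187..192 cuts at 189 (189 + 168);
  # latent site at 120..125 becomes TCAAGA in the mutant, cutting at 122
  wt_mid <- "ACAAGA"
  mut_mid <- "TCAAGA"
  site <- "TCAAGA"
  assemble <- function(mid) {
    paste0(primers$forward, filler(98L), mid, filler(61L), site,
           filler(140L), rc_rev)
  }
  wt <- assemble(wt_mid)
  mut <- assemble(mut_mid)
  stopifnot(nchar(wt) == 357L, nchar(mut) == 357L)
  enzyme <- hpy188iii()
  # construction verified by digestion: the fixture must reproduce the
  # assay's fragment patterns exactly
  stopifnot(
    identical(sort(fragment_lengths(digest(wt, enzyme))),
              sort(c(189L, 168L))),
    identical(sort(fragment_lengths(digest(mut, enzyme))),
              sort(c(168L, 122L, 67L)))
  )
  list(
    wt_template = paste0(filler(flank_bp), wt, filler(flank_bp)),
    mut_template = paste0(filler(flank_bp), mut, filler(flank_bp)),
    primers = primers,
    wt_amplicon = wt, mut_amplicon = mut,
    wt_pattern = c(189, 168), mut_pattern = c(168, 122, 67),
    enzyme = enzyme
  )
}
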