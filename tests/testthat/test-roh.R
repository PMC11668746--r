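test_that("an all-homozygous track yields one segment spanning all markers", {
  pos <- as.integer(seq(1e6, 6e6, length.out = 1000))
  g <- marker_genotypes("chr9", pos, rep("HOM_REF", 1000), "S1")
  segs <- detect_roh(g)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start_bp, pos[1])
  expect_equal(segs$end_bp, pos[1000])
  expect_equal(segs$n_markers, 1000L)
  expect_equal(segs$n_het_inside, 0L)
})

test_that("alternating heterozygotes suppress every window at zero allowance", {
  pos <- as.integer(seq(1e6, 9e6, length.out = 800))
  calls <- rep(c("HOM_REF", "HET"), 400)
  g <- marker_genotypes("chr9", pos, calls, "S1")
  segs <- detect_roh(g, roh_params(max_het_per_window = 0))
  expect_equal(nrow(segs), 0)
})

test_that("too few markers warns and returns empty, not an error", {
  g <- marker_genotypes("chr9", 1:10 * 1000L, rep("HOM_REF", 10), "S1")
  expect_warning(segs <- detect_roh(g), "window")
  expect_equal(nrow(segs), 0)
})

test_that("a planted autozygous segment is recovered with stable boundaries", {
  cfg <- simulation_config(true_g = 5, n_patients = 1, marker_count = 3000,
                           seed = 404)
  sim <- simulate_cohort(cfg)
  params <- roh_params(min_markers = 25)
  segs <- detect_roh(sim$genotypes, params)
  truth <- sim$truth
  hit <- segs[segs$start_bp <= truth$start_bp + 1e5 &
                segs$end_bp >= truth$end_bp - 1e5, ]
  expect_equal(nrow(hit), 1)
  # boundary stability: overshoot bounded by one window of markers
  spacing <- cfg$chromosome_length_bp / cfg$marker_count
  slack <- params$window_markers * spacing
  expect_lte(truth$start_bp - hit$start_bp, slack)
  expect_lte(hit$end_bp - truth$end_bp, slack)
  # prepending/appending HET-dense flanks does not move the call
  flank_n <- 200L
  base <- dplyr::filter(sim$genotypes, pos > flank_n)
  left <- marker_genotypes("chr9", seq_len(flank_n),
                           rep("HET", flank_n), "P001")
  pos_max <- max(base$pos)
  right <- marker_genotypes("chr9", pos_max + seq_len(flank_n) * 10L,
                            rep("HET", flank_n), "P001")
  padded <- dplyr::bind_rows(left, base, right) |>
    dplyr::arrange(pos)
  segs2 <- detect_roh(padded, params)
  hit2 <- segs2[segs2$start_bp <= truth$start_bp + 1e5 &
                  segs2$end_bp >= truth$end_bp - 1e5, ]
  expect_equal(hit2$start_bp, hit$start_bp)
  expect_equal(hit2$end_bp, hit$end_bp)
})

test_that("caller equals the exhaustive window oracle on random tracks", {
  params <- roh_params(window_markers = 10, max_het_per_window = 1,
                       max_missing_per_window = 2, min_length_bp = 2e4,
                       min_markers = 15)
  for (seed in 1:50) {
    trk <- random_genotype_track(600L, seed)
    g <- marker_genotypes("chr1", trk$pos, trk$call, "S1")
    got <- detect_roh(g, params)
    want <- roh_oracle(trk$pos, trk$call, params)
    expect_equal(nrow(got), nrow(want), info = paste("seed", seed))
    if (nrow(want)) {
      expect_equal(got$start_bp, want$start_bp, info = paste("seed", seed))
      expect_equal(got$end_bp, want$end_bp, info = paste("seed", seed))
      expect_equal(got$n_markers, want$n_markers,
                   info = paste("seed", seed))
    }
    # structural invariants: non-overlap, homozygous terminal markers
    if (nrow(got) > 1) {
      expect_true(all(got$start_bp[-1] > got$end_bp[-nrow(got)]))
    }
    for (i in seq_len(nrow(got))) {
      expect_true(
        trk$call[match(got$start_bp[i], trk$pos)] %in%
          c("HOM_REF", "HOM_ALT")
      )
      expect_true(
        trk$call[match(got$end_bp[i], trk$pos)] %in%
          c("HOM_REF", "HOM_ALT")
      )
    }
  }
})

test_that("segment intersection recovers the shared autozygous core", {
  segs <- tibble::tibble(
    sample_id = c("WES1", "WGS1"),
    chrom = "chr9",
    start_bp = c(35096634, 35805740),
    end_bp = c(38543655, 40610122)
  )
  # anchor at the disease locus, contained in both segments
  core <- intersect_segments(segs, 36214441, 36279281)
  expect_equal(core$start_bp, 35805740)
  expect_equal(core$end_bp, 38543655)
  one <- intersect_segments(segs[1, ], 36214441)
  expect_equal(one$start_bp, segs$start_bp[1])
  expect_equal(one$end_bp, segs$end_bp[1])
  same <- intersect_segments(segs[c(1, 1), ], 36214441)
  expect_equal(same$start_bp, segs$start_bp[1])
  expect_error(intersect_segments(segs, 35096634, 35200000), "WGS1")
})

test_that("physical lengths report in Mb with half-up display rounding", {
  expect_equal(segment_length_mb(35805740, 40610122, display = TRUE), 4.8)
  expect_equal(segment_length_mb(35096634, 38543655), 3.447022)
  expect_equal(segment_length_mb(35096634, 38543655, display = TRUE), 3.4)
  expect_equal(segment_length_mb(100, 100), 1e-6)
  expect_error(segment_length_mb(10, 5), class = "founderage_input_error")
})
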