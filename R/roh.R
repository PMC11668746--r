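GENOTYPE_CALLS <- c("HOM_REF", "HET", "HOM_ALT", "MISSING")

#' Assemble a per-marker genotype table
#'
#' @param chrom Chromosome label (recycled).
#' @param pos Strictly increasing 1-based marker positions (per sample).
#' @param call Genotype call per marker: `"HOM_REF"`, `"HET"`, `"HOM_ALT"`
#'   or `"MISSING"`.
#' @param sample_id Sample label (recycled).
#' @return A tibble with columns `sample_id`, `chrom`, `pos`, `call`.
#' @export
marker_genotypes <- function(chrom, pos, call, sample_id = "sample1") {
  pos <- check_count(pos, "pos", allow_zero = FALSE)
  if (!all(call %in% GENOTYPE_CALLS)) {
    stop_input(paste0("`call` values must be one of: ",
                      paste(GENOTYPE_CALLS, collapse = ", ")))
  }
  if (length(pos) != length(call)) {
    stop_input("`pos` and `call` must have equal length.")
  }
  out <- tibble(sample_id = as.character(sample_id),
                chrom = as.character(chrom),
                pos = pos, call = as.character(call))
  bad <- out |>
    dplyr::group_by(.data$sample_id, .data$chrom) |>
    dplyr::summarise(ok = !is.unsorted(.data$pos, strictly = TRUE),
                     .groups = "drop")
  if (any(!bad$ok)) {
    stop_input("`pos` must be strictly increasing within sample/chromosome.")
  }
  out
}

#' ROH caller parameters
#'
#' Thresholds for the sliding-window run-of-homozygosity caller. The
#' defaults are tuned for exome-scale marker density, in the spirit of
#' window-based autozygosity mappers; none is canonical, so all are exposed.
#'
#' @param window_markers Markers per sliding window.
#' @param max_het_per_window Maximum heterozygous calls tolerated per window.
#' @param max_missing_per_window Maximum missing calls tolerated per window.
#' @param min_length_bp Minimum physical length (bp) of a reported segment.
#' @param min_markers Minimum markers supporting a reported segment.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_markers = 25L, max_het_per_window = 1L,
                       max_missing_per_window = 2L, min_length_bp = 1e6,
                       min_markers = 50L) {
  p <- list(
    window_markers = check_count(window_markers, "window_markers", FALSE),
    max_het_per_window = check_count(max_het_per_window,
                                     "max_het_per_window"),
    max_missing_per_window = check_count(max_missing_per_window,
                                         "max_missing_per_window"),
    min_length_bp = check_count(min_length_bp, "min_length_bp", FALSE),
    min_markers = check_count(min_markers, "min_markers", FALSE)
  )
  if (p$max_het_per_window >= p$window_markers) {
    stop_input("max_het_per_window must be smaller than window_markers")
  }
  structure(p, class = "roh_params")
}

# core single-sample, single-chromosome caller on a call vector + positions;
# returns row indices of segments as a tibble
detect_roh_runs <- function(pos, call, params) {
  m <- length(call)
  w <- params$window_markers
  if (m < w) {
    warn(sprintf("only %d marker(s) for a %d-marker window; no ROH called",
                 m, w))
    return(tibble(start_i = integer(), end_i = integer()))
  }
  het <- cumsum(c(0L, call == "HET"))
  mis <- cumsum(c(0L, call == "MISSING"))
  i <- seq_len(m - w + 1L)
  pass <- (het[i + w] - het[i]) <= params$max_het_per_window &
    (mis[i + w] - mis[i]) <= params$max_missing_per_window
  if (!any(pass)) return(tibble(start_i = integer(), end_i = integer()))
  # union of markers covered by passing windows -> maximal covered runs
  covered <- logical(m)
  for (j in i[pass]) covered[j:(j + w - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble(start_i = starts[r$values], end_i = ends[r$values])
  # trim so terminal markers are homozygous and non-missing
  hom <- call %in% c("HOM_REF", "HOM_ALT")
  runs <- purrr::pmap_dfr(runs, function(start_i, end_i) {
    idx <- start_i:end_i
    hom_idx <- idx[hom[idx]]
    if (!length(hom_idx)) return(tibble(start_i = integer(),
                                        end_i = integer()))
    tibble(start_i = min(hom_idx), end_i = max(hom_idx))
  })
  runs
}

#' Detect runs of homozygosity
#'
#' Slides a `window_markers`-marker window over each sample x chromosome
#' track; windows with at most `max_het_per_window` heterozygous and
#' `max_missing_per_window` missing calls seed a segment; markers covered by
#' any passing window are merged into maximal runs; each run is trimmed so
#' its first and last markers are homozygous non-missing; runs shorter than
#' `min_length_bp` or supported by fewer than `min_markers` markers are
#' dropped. Missing calls never terminate a run by themselves — only
#' heterozygote excess does. Output segments never overlap within a sample.
#'
#' @param genotypes A tibble as from [marker_genotypes()] or
#'   [read_vcf_genotypes()] (columns `sample_id`, `chrom`, `pos`, `call`).
#' @param params A [roh_params()].
#' @return A tibble of class `roh_segments`: `sample_id`, `chrom`,
#'   `start_bp`, `end_bp` (1-based inclusive), `n_markers`, `n_het_inside`,
#'   `length_bp`, sorted by sample and start.
#' @export
detect_roh <- function(genotypes, params = roh_params()) {
  if (!is.data.frame(genotypes)) stop_input("`genotypes` must be a data frame")
  if (!inherits(params, "roh_params")) stop_input("`params` must be roh_params")
  need <- c("sample_id", "chrom", "pos", "call")
  miss <- setdiff(need, names(genotypes))
  if (length(miss)) {
    stop_input(paste0("`genotypes` lacks column(s): ",
                      paste(miss, collapse = ", ")))
  }
  segs <- genotypes |>
    dplyr::group_by(.data$sample_id, .data$chrom) |>
    dplyr::group_modify(function(g, key) {
      runs <- detect_roh_runs(g$pos, g$call, params)
      if (!nrow(runs)) {
        return(tibble(start_bp = integer(), end_bp = integer(),
                      n_markers = integer(), n_het_inside = integer()))
      }
      purrr::pmap_dfr(runs, function(start_i, end_i) {
        idx <- start_i:end_i
        tibble(
          start_bp = g$pos[start_i], end_bp = g$pos[end_i],
          n_markers = length(idx),
          n_het_inside = sum(g$call[idx] == "HET")
        )
      })
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(length_bp = .data$end_bp - .data$start_bp + 1L) |>
    dplyr::filter(.data$length_bp >= params$min_length_bp,
                  .data$n_markers >= params$min_markers) |>
    dplyr::arrange(.data$sample_id, .data$chrom, .data$start_bp)
  class(segs) <- c("roh_segments", class(segs))
  segs
}

#' Shared autozygous core across samples
#'
#' Intersects one segment per sample around an anchor locus (the variant or
#' gene): every segment must contain the anchor, and the shared core is
#' `[max(start_bp), min(end_bp)]` — the region autozygous in all samples.
#'
#' @param segments A tibble with columns `chrom`, `start_bp`, `end_bp` (and
#'   optionally `sample_id`), one row per sample, all on one chromosome.
#' @param anchor_start,anchor_end Anchor interval (1-based inclusive bp);
#'   give a single position as `anchor_start` alone.
#' @return A one-row tibble `chrom`, `start_bp`, `end_bp`, `length_bp`.
#' @examples
#' segs <- tibble::tibble(
#'   sample_id = c("P1", "P2"), chrom = "chr9",
#'   start_bp = c(35096634, 35805740), end_bp = c(38543655, 40610122)
#' )
#' intersect_segments(segs, 36214441, 36279281) # GNE locus
#' @export
intersect_segments <- function(segments, anchor_start,
                               anchor_end = anchor_start) {
  if (!is.data.frame(segments) || !nrow(segments)) {
    stop_input("`segments` must be a data frame with at least one row")
  }
  if (anchor_end < anchor_start) stop_input("anchor_end < anchor_start")
  if (length(unique(segments$chrom)) != 1L) {
    stop_input("all segments must lie on one chromosome")
  }
  ids <- segments$sample_id %||% paste0("segment ", seq_len(nrow(segments)))
  missing_anchor <- segments$start_bp > anchor_start |
    segments$end_bp < anchor_end
  if (any(missing_anchor)) {
    stop_input(paste0("segment(s) not containing the anchor: ",
                      paste(ids[missing_anchor], collapse = ", ")))
  }
  start <- max(segments$start_bp)
  end <- min(segments$end_bp)
  if (start > end) stop_input("segments have empty intersection")
  tibble(chrom = segments$chrom[1], start_bp = start, end_bp = end,
         length_bp = end - start + 1)
}

#' Physical length of a segment in megabases
#'
#' `(end_bp - start_bp + 1) / 1e6`, unrounded; `display = TRUE` rounds
#' half-up to one decimal, the convention used when printing ROH sizes.
#'
#' @param start_bp,end_bp 1-based inclusive bounds (vectorised).
#' @param display Round half-up to 1 decimal for reporting?
#' @return Numeric vector of lengths (Mb).
#' @examples
#' segment_length_mb(35805740, 40610122, display = TRUE) # 4.8
#' @export
segment_length_mb <- function(start_bp, end_bp, display = FALSE) {
  if (any(end_bp < start_bp)) stop_input("end_bp < start_bp")
  mb <- (end_bp - start_bp + 1) / 1e6
  if (display) round_half_up(mb, 1) else mb
}
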