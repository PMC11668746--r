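#' Construct a genetic map
#'
#' A genetic map is a per-chromosome table of knots pairing a 1-based
#' physical position (bp) with a cumulative sex-averaged genetic position
#' (Kosambi cM). Physical positions must be strictly increasing within a
#' chromosome and genetic positions non-decreasing (cM ties allowed —
#' recombination deserts). Duplicate bp rows are collapsed keeping the
#' first, with a warning.
#'
#' @param chrom Chromosome label per knot.
#' @param bp 1-based physical position per knot.
#' @param cm Sex-averaged genetic position (cM) per knot.
#' @param build Optional genome-build string, recorded verbatim in outputs;
#'   the map itself is build-agnostic.
#'
#' @return A tibble of class `genetic_map`, sorted by chromosome and bp.
#' @examples
#' genetic_map("chr9", c(100, 200, 300), c(0, 1, 2))
#' @export
genetic_map <- function(chrom, bp, cm, build = NA_character_) {
  bp <- check_count(bp, "bp", allow_zero = FALSE)
  if (!is.numeric(cm) || any(is.na(cm)) || any(cm < 0)) {
    stop_input("`cm` must be non-negative numbers.")
  }
  map <- tibble(chrom = as.character(chrom), bp = bp, cm = as.numeric(cm)) |>
    dplyr::arrange(.data$chrom, .data$bp)
  dup <- duplicated(map[c("chrom", "bp")])
  if (any(dup)) {
    warn(sprintf("collapsed %d duplicate bp knot(s), keeping the first",
                 sum(dup)))
    map <- map[!dup, ]
  }
  bad <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::filter(dplyr::row_number() > 1 & diff(c(0, .data$cm)) < 0) |>
    dplyr::ungroup()
  if (nrow(bad)) {
    stop_input(paste0(
      "cM must be non-decreasing in bp; offending knot(s): ",
      paste(sprintf("%s:%d (%.6g cM)", bad$chrom, bad$bp, bad$cm),
            collapse = ", ")
    ))
  }
  attr(map, "build") <- build
  class(map) <- c("genetic_map", class(map))
  map
}

#' Read a genetic-map knot table
#'
#' Reads a Rutgers-map-like delimited text table of (chromosome, physical
#' bp, sex-averaged cM) knots and validates it into a [genetic_map()].
#'
#' @param path File path.
#' @param dialect Column convention: `"rutgers"` (whitespace/tab-delimited,
#'   columns chromosome, bp, cM, header detected automatically) is the only
#'   built-in; use `col_order` to permute columns of other tables.
#' @param col_order Integer vector of length 3 giving the positions of the
#'   chromosome, bp and cM columns in the file.
#' @param build Optional genome-build string recorded on the map.
#' @return A `genetic_map`.
#' @export
read_genetic_map <- function(path, dialect = "rutgers", col_order = 1:3,
                             build = NA_character_) {
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  if (!identical(dialect, "rutgers")) {
    stop_input(sprintf("unknown dialect: %s", dialect))
  }
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", strsplit(trimws(first), "[ \t]+")[[1]][2])
  tab <- read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop_input("map table needs at least 3 columns")
  genetic_map(
    chrom = tab[[col_order[1]]],
    bp = tab[[col_order[2]]],
    cm = tab[[col_order[3]]],
    build = build
  )
}

#' Write a genetic map as a three-column table
#'
#' @param map A `genetic_map`.
#' @param path Output path. Tab-delimited with a header line.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  utils::write.table(
    map[c("chrom", "bp", "cm")], path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

map_chrom <- function(map, chrom) {
  if (!inherits(map, "genetic_map")) stop_input("`map` must be a genetic_map")
  sub <- map[map$chrom == chrom, ]
  if (!nrow(sub)) {
    stop_input(sprintf("chromosome '%s' not in map (has: %s)", chrom,
                       paste(unique(map$chrom), collapse = ", ")))
  }
  sub
}

#' Interpolate genetic position at physical positions
#'
#' Piecewise-linear interpolation of the map between flanking knots. At a
#' knot the knot's cM is returned exactly. Queries outside the knot range
#' are extrapolated as a constant at the terminal cM value (no
#' recombination is fabricated beyond map support) with a warning.
#'
#' @param map A [genetic_map()].
#' @param chrom Chromosome label (single value).
#' @param bp Physical positions to interpolate (vectorised).
#' @return Numeric vector of cM positions.
#' @examples
#' m <- genetic_map("chr9", c(100, 200, 300), c(0, 1, 2))
#' interpolate_cm(m, "chr9", 150)
#' @export
interpolate_cm <- function(map, chrom, bp) {
  sub <- map_chrom(map, chrom)
  if (!is.numeric(bp) || any(is.na(bp))) stop_input("`bp` must be numeric.")
  outside <- bp < min(sub$bp) | bp > max(sub$bp)
  if (any(outside)) {
    warn(sprintf(
      "%d quer%s outside map support on %s; constant extrapolation applied",
      sum(outside), if (sum(outside) == 1) "y lies" else "ies lie", chrom
    ))
  }
  if (nrow(sub) == 1L) return(rep(sub$cm, length(bp)))
  approx(sub$bp, sub$cm, xout = bp, method = "linear", rule = 2,
         ties = "ordered")$y
}

#' Invert a genetic map: physical position at genetic positions
#'
#' Linear interpolation of bp against cM; requires strictly increasing cM on
#' the chromosome (an invertible map), as produced by
#' [make_genetic_map_fixture()]. Used by the forward simulator to convert
#' exponentially drawn genetic flank lengths into physical coordinates.
#'
#' @inheritParams interpolate_cm
#' @param cm Genetic positions (cM) to invert (vectorised). Values outside
#'   map support clamp to the terminal knots.
#' @return Numeric vector of bp positions.
#' @export
interpolate_bp <- function(map, chrom, cm) {
  sub <- map_chrom(map, chrom)
  if (any(diff(sub$cm) <= 0)) {
    stop_input("map cM must be strictly increasing to invert")
  }
  approx(sub$cm, sub$bp, xout = cm, method = "linear", rule = 2,
         ties = "ordered")$y
}

#' Genetic length of physical intervals
#'
#' The cM spanned between the interpolated genetic positions of the interval
#' ends; non-negative by map monotonicity, and additive over abutting
#' intervals.
#'
#' @inheritParams interpolate_cm
#' @param start_bp,end_bp 1-based inclusive interval bounds (vectorised;
#'   `start_bp <= end_bp`).
#' @return Numeric vector of genetic lengths (cM).
#' @examples
#' m <- genetic_map("chr9", c(100, 200, 300), c(0, 1, 2))
#' genetic_length(m, "chr9", 100, 300)
#' @export
genetic_length <- function(map, chrom, start_bp, end_bp) {
  if (any(start_bp > end_bp)) stop_input("start_bp must be <= end_bp")
  interpolate_cm(map, chrom, end_bp) - interpolate_cm(map, chrom, start_bp)
}

#' Kosambi map function and its inverse
#'
#' Converts between map distance and recombination fraction under Kosambi's
#' interference model: `r = tanh(2 d) / 2` and
#' `d = log((1 + 2 r) / (1 - 2 r)) / 4`, with `d` in Morgans. The two are
#' mutually inverse; `kosambi_rf` is strictly increasing and bounded by 1/2.
#'
#' @param d Map distance in Morgans (non-negative, vectorised).
#' @return `kosambi_rf`: recombination fraction in \[0, 0.5).
#' @examples
#' kosambi_rf(0.1)
#' kosambi_d(kosambi_rf(0.1))
#' @export
kosambi_rf <- function(d) {
  if (!is.numeric(d) || any(is.na(d)) || any(d < 0)) {
    stop_input("`d` must be non-negative (Morgans).")
  }
  tanh(2 * d) / 2
}

#' @rdname kosambi_rf
#' @param r Recombination fraction in \[0, 0.5), vectorised.
#' @return `kosambi_d`: map distance in Morgans.
#' @export
kosambi_d <- function(r) {
  if (!is.numeric(r) || any(is.na(r)) || any(r < 0) || any(r >= 0.5)) {
    stop_input("`r` must lie in [0, 0.5).")
  }
  log((1 + 2 * r) / (1 - 2 * r)) / 4
}
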