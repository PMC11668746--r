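#' Define a restriction enzyme
#'
#' @param name Enzyme name, e.g. `"Hpy188III"`.
#' @param recognition Recognition site as an IUPAC degenerate DNA string
#'   (e.g. `"TCNNGA"`).
#' @param cut_offset Position of the top-strand cut within the site: the
#'   number of bases of the site left of the cut, `0..nchar(recognition)`.
#'
#' @details At construction the recognition site is checked for
#'   self-complementarity (reverse complement of the degenerate pattern
#'   equals the pattern, as for TCNNGA). Self-complementary sites are
#'   scanned on one strand only; others are scanned on both strands by
#'   [find_sites()].
#'
#' @return An object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("Hpy188III", "TCNNGA", 2)
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  if (!is.character(recognition) || length(recognition) != 1L ||
      nchar(recognition) == 0L) {
    stop_input("`recognition` must be a non-empty string.")
  }
  recognition <- toupper(recognition)
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  if (!all(strsplit(recognition, "")[[1]] %in% iupac)) {
    stop_input("`recognition` must contain only IUPAC nucleotide codes.")
  }
  cut_offset <- check_count(cut_offset, "cut_offset")
  if (cut_offset > nchar(recognition)) {
    stop_input("`cut_offset` must not exceed the recognition-site length.")
  }
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(recognition)
  ))
  structure(
    list(
      name = as.character(name),
      recognition = recognition,
      cut_offset = cut_offset,
      self_complementary = identical(rc, recognition)
    ),
    class = "restriction_enzyme"
  )
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf(
    "<restriction_enzyme> %s  %s^ at +%d%s\n", x$name, x$recognition,
    x$cut_offset,
    if (x$self_complementary) "  (self-complementary site)" else ""
  ))
  invisible(x)
}

#' Hpy188III, the assay enzyme
#'
#' Convenience constructor for Hpy188III, recognition TC^NNGA. The site is
#' self-complementary, so a single-strand scan finds every cut.
#'
#' @return A `restriction_enzyme`.
#' @export
hpy188iii <- function() restriction_enzyme("Hpy188III", "TCNNGA", 2L)

#' Define a PCR primer pair
#'
#' @param forward Forward primer, 5'->3' on the template strand.
#' @param reverse Reverse primer, 5'->3' on the opposite strand (its reverse
#'   complement must occur on the template, downstream of the forward hit).
#'
#' @return An object of class `primer_pair`.
#' @examples
#' primer_pair("GTGAGAGCCAAGTACCACAACA", "GGAGAGTCACACATAAGTGGAGGT")
#' @export
primer_pair <- function(forward, reverse) {
  structure(
    list(forward = check_dna(forward, "forward"),
         reverse = check_dna(reverse, "reverse")),
    class = "primer_pair"
  )
}

#' In-silico PCR by exact primer matching
#'
#' Extracts the amplicon: the template substring from the first base of the
#' forward-primer match through the last base of the reverse-primer binding
#' site (the reverse complement of `reverse` on the template strand).
#' Primer binding is exact-match; mismatch thermodynamics are out of scope.
#'
#' @param template Template DNA (single string, A/C/G/T).
#' @param primers A [primer_pair()].
#'
#' @return The amplicon as a single string.
#'
#' @section Errors: if either primer has no valid binding site the function
#'   aborts with class `founderage_no_amplification`; if more than one
#'   product is possible it aborts with class
#'   `founderage_nonspecific_amplification`, listing all product lengths.
#' @export
simulate_pcr <- function(template, primers) {
  template <- check_dna(template, "template")
  if (!inherits(primers, "primer_pair")) {
    stop_input("`primers` must be a primer_pair.")
  }
  subj <- Biostrings::DNAString(template)
  f_hits <- Biostrings::start(Biostrings::matchPattern(primers$forward, subj))
  rc_rev <- Biostrings::reverseComplement(
    Biostrings::DNAString(primers$reverse)
  )
  r_hits <- Biostrings::end(Biostrings::matchPattern(rc_rev, subj))
  # every forward hit paired with every downstream reverse binding site is a
  # potential product; exactly one is specific amplification
  rev_len <- nchar(primers$reverse)
  products <- tidyr::expand_grid(f = f_hits, r = r_hits) |>
    dplyr::filter(.data$r - rev_len + 1L >= .data$f + nchar(primers$forward))
  if (nrow(products) == 0L) {
    abort("no amplification: primer pair has no valid binding sites",
          class = "founderage_no_amplification")
  }
  if (nrow(products) > 1L) {
    lens <- products$r - products$f + 1L
    abort(
      paste0("non-specific amplification: ", nrow(products),
             " products of lengths ", paste(sort(lens), collapse = ", "),
             " bp"),
      class = "founderage_nonspecific_amplification"
    )
  }
  substr(template, products$f, products$r)
}

#' Locate restriction cut positions
#'
#' Scans a sequence for the enzyme's (possibly degenerate) recognition site
#' and returns the cut coordinates: each coordinate is the number of bases
#' to the left of the cut, so a cut coordinate `k` splits the sequence into
#' `seq[1..k]` and `seq[(k+1)..len]`. Overlapping site matches are all
#' reported. Self-complementary sites are scanned on the top strand only;
#' otherwise the bottom strand is scanned too (cut placed `cut_offset`
#' bases from the site's 5' end on that strand). Cuts falling at position 0
#' or at the sequence end are dropped (they produce no fragmentation of a
#' linear molecule).
#'
#' @param seq DNA sequence (single string, A/C/G/T).
#' @param enzyme A [restriction_enzyme()].
#' @return Sorted integer vector of cut coordinates.
#' @examples
#' find_sites("TCGGGA", hpy188iii()) # cut after "TC"
#' @export
find_sites <- function(seq, enzyme) {
  seq <- check_dna(seq, "seq")
  if (!inherits(enzyme, "restriction_enzyme")) {
    stop_input("`enzyme` must be a restriction_enzyme.")
  }
  subj <- Biostrings::DNAString(seq)
  pat <- Biostrings::DNAString(enzyme$recognition)
  w <- nchar(enzyme$recognition)
  starts <- Biostrings::start(Biostrings::matchPattern(pat, subj,
                                                       fixed = FALSE))
  cuts <- starts - 1L + enzyme$cut_offset
  if (!enzyme$self_complementary) {
    rc_starts <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::reverseComplement(pat), subj, fixed = FALSE
    ))
    cuts <- c(cuts, rc_starts - 1L + (w - enzyme$cut_offset))
  }
  cuts <- sort(unique(cuts))
  cuts[cuts > 0L & cuts < nchar(seq)]
}

#' Digest a linear molecule
#'
#' Cuts the sequence at every recognition site and returns the fragments in
#' left-to-right order. For a linear molecule with `k` internal cuts there
#' are `k + 1` fragments whose lengths sum to the sequence length.
#'
#' @inheritParams find_sites
#' @return A tibble of class `digest_result` with columns `fragment`
#'   (index), `start`, `end` (1-based inclusive) and `length` (bp), and an
#'   attribute `n_sites` (number of cuts). [fragment_lengths()] extracts the
#'   length multiset.
#' @examples
#' digest(make_rflp_fixture()$wt_amplicon, hpy188iii())
#' @export
digest <- function(seq, enzyme) {
  seq <- check_dna(seq, "seq")
  cuts <- find_sites(seq, enzyme)
  bounds <- c(0L, cuts, nchar(seq))
  out <- tibble(
    fragment = seq_len(length(bounds) - 1L),
    start = head(bounds, -1L) + 1L,
    end = tail(bounds, -1L)
  )
  out$length <- out$end - out$start + 1L
  structure(out, n_sites = length(cuts),
            class = c("digest_result", class(out)))
}

#' @rdname digest
#' @param x A `digest_result`.
#' @export
fragment_lengths <- function(x) {
  if (!inherits(x, "digest_result")) stop_input("not a digest_result")
  x$length
}

# merge sizes that would co-migrate on a gel: values within tolerance_bp of
# an already-kept (larger) size collapse onto it
merge_comigrating <- function(sizes, tolerance_bp) {
  sizes <- sort(unique(sizes), decreasing = TRUE)
  kept <- numeric(0)
  for (s in sizes) {
    if (!length(kept) || all(abs(kept - s) > tolerance_bp)) kept <- c(kept, s)
  }
  sort(kept)
}

# TRUE if the observed multiset equals the pattern as read off a gel:
# observed bands (deduplicated within tolerance) match the pattern's bands
# one-to-one within tolerance_bp
bands_match <- function(observed, pattern, tolerance_bp) {
  obs <- merge_comigrating(observed, tolerance_bp)
  pat <- merge_comigrating(pattern, tolerance_bp)
  length(obs) == length(pat) && all(abs(obs - pat) <= tolerance_bp)
}

#' Call a genotype from restriction-fragment sizes
#'
#' Matches an observed fragment-size pattern against the expected wild-type
#' pattern, the mutant pattern, and the heterozygote pattern (their union,
#' with sizes shared between alleles appearing once, as they co-migrate on a
#' gel). Sizes within `tolerance_bp` are treated as one band. An observed
#' pattern matching none, or more than one, of the three references is
#' `uncalled` — a value, not an error.
#'
#' @param observed Observed fragment sizes (bp).
#' @param wt_pattern,mut_pattern Expected sizes for the homozygous wild-type
#'   and homozygous mutant alleles; must be non-empty and distinct.
#' @param tolerance_bp Size tolerance for band identity (default 0, exact
#'   in-silico sizes; set > 0 for gel-read sizes).
#'
#' @return One of `"WT/WT"`, `"WT/mut"`, `"mut/mut"`, `"uncalled"`.
#' @examples
#' genotype_from_fragments(c(189, 168, 122, 67), c(189, 168), c(168, 122, 67))
#' @export
genotype_from_fragments <- function(observed, wt_pattern, mut_pattern,
                                    tolerance_bp = 0L) {
  if (!length(wt_pattern) || !length(mut_pattern)) {
    stop_input("patterns must be non-empty")
  }
  tolerance_bp <- check_count(tolerance_bp, "tolerance_bp")
  if (bands_match(wt_pattern, mut_pattern, tolerance_bp)) {
    stop_input("wt and mut patterns are indistinguishable at this tolerance")
  }
  het_pattern <- c(wt_pattern, mut_pattern)
  hits <- c(
    "WT/WT"   = bands_match(observed, wt_pattern, tolerance_bp),
    "mut/mut" = bands_match(observed, mut_pattern, tolerance_bp),
    "WT/mut"  = bands_match(observed, het_pattern, tolerance_bp)
  )
  if (sum(hits) == 1L) names(hits)[hits] else "uncalled"
}
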