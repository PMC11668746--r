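#' Read genotype calls from a minimal VCF
#'
#' Extracts the GT field of one sample from a VCF and recodes it to the
#' four-level calls the ROH caller uses. Support is deliberately minimal:
#' biallelic rows only; rows with other ALT structures are skipped with a
#' counted warning; every field other than GT is ignored.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param sample Sample name; `NULL` (default) takes the first sample.
#' @return A tibble `sample_id`, `chrom`, `pos`, `call` as
#'   [marker_genotypes()] produces.
#' @export
read_vcf_genotypes <- function(path, sample = NULL) {
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  v <- suppressMessages(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(sample)) sample <- colnames(gt)[1]
  if (!sample %in% colnames(gt)) {
    stop_input(sprintf("sample '%s' not in VCF (has: %s)", sample,
                       paste(colnames(gt), collapse = ", ")))
  }
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT) | fix$ALT == "."
  if (any(multi)) {
    warn(sprintf("skipped %d non-biallelic row(s)", sum(multi)))
  }
  g <- gt[!multi, sample]
  g <- gsub("|", "/", g, fixed = TRUE)
  call <- dplyr::case_match(
    g,
    "0/0" ~ "HOM_REF",
    c("0/1", "1/0") ~ "HET",
    "1/1" ~ "HOM_ALT",
    .default = "MISSING"
  )
  call[is.na(g)] <- "MISSING"
  marker_genotypes(
    chrom = fix$CHROM[!multi],
    pos = as.integer(fix$POS[!multi]),
    call = call,
    sample_id = sample
  )
}

#' Write genotype calls as a minimal single-sample VCF
#'
#' Emits a plain-text VCFv4.2 with GT-only FORMAT; the inverse of
#' [read_vcf_genotypes()] for simulator output. `HOM_REF` becomes `0/0`,
#' `HET` `0/1`, `HOM_ALT` `1/1`, `MISSING` `./.`; REF/ALT are placeholder
#' A/C alleles (only the genotype codes carry information downstream).
#'
#' @param genotypes A single-sample tibble as from [marker_genotypes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(genotypes, path) {
  if (length(unique(genotypes$sample_id)) != 1L) {
    stop_input("`genotypes` must contain exactly one sample")
  }
  gt <- dplyr::case_match(
    genotypes$call,
    "HOM_REF" ~ "0/0", "HET" ~ "0/1", "HOM_ALT" ~ "1/1",
    "MISSING" ~ "./."
  )
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", genotypes$sample_id[1], sep = "\t")
  )
  body <- paste(genotypes$chrom, genotypes$pos, ".", "A", "C", ".", ".",
                ".", "GT", gt, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write segments as BED
#'
#' Converts the package's 1-based inclusive coordinates to BED's 0-based
#' half-open convention at the I/O boundary.
#'
#' @param segments A tibble with `chrom`, `start_bp`, `end_bp` (and
#'   optionally `sample_id`, written as the BED name column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(segments, path) {
  name <- segments$sample_id %||% "."
  writeLines(
    paste(segments$chrom, segments$start_bp - 1L, segments$end_bp, name,
          sep = "\t"),
    path
  )
  invisible(path)
}

#' Read and write FASTA sequences
#'
#' Thin wrappers returning/accepting named character vectors of sequences.
#'
#' @param path File path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of DNA sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) {
    names(x) <- paste0("seq", seq_along(seqs))
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
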