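#' Read a Freebayes-annotated VCF into a marker record table
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) and extracts the fields used for
#' marker filtering: `QUAL`, and the INFO keys `AO`, `SAF`, `SAR`, `RPR`,
#' `RPL`, `MQM`, `MQMR`. Multiallelic records (comma in ALT) and indels
#' (REF/ALT longer than one base, or a `TYPE` other than `snp`) are flagged,
#' not dropped — [filter_snps()] applies the exclusion rules.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return A tibble with `chrom`, `pos` (1-based), `ref`, `alt`, `qual`,
#'   `ao`, `saf`, `sar`, `rpr`, `rpl`, `mqm`, `mqmr`, `is_indel`,
#'   `is_multiallelic`.
#' @export
read_freebayes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info_num <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    # multiallelic records carry comma-separated per-allele values; use the
    # first allele's value (such records are excluded downstream anyway)
    suppressWarnings(as.numeric(sub(",.*$", "", x)))
  }
  tibble(
    chrom = fx$CHROM,
    pos = as.integer(fx$POS),
    ref = fx$REF,
    alt = fx$ALT,
    qual = suppressWarnings(as.numeric(fx$QUAL)),
    ao = info_num("AO"),
    saf = info_num("SAF"),
    sar = info_num("SAR"),
    rpr = info_num("RPR"),
    rpl = info_num("RPL"),
    mqm = info_num("MQM"),
    mqmr = info_num("MQMR"),
    is_multiallelic = grepl(",", fx$ALT, fixed = TRUE),
    is_indel = nchar(fx$REF) != 1L |
      (nchar(sub(",.*$", "", fx$ALT)) != 1L)
  )
}

#' Read a samtools-depth per-base depth table
#'
#' @param path Path to a headerless TSV with columns chromosome, 1-based
#'   position, depth (the `samtools depth` output format).
#' @return A tibble with `chrom`, `pos`, `depth`.
#' @export
read_depth_tsv <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "pos", "depth"),
                  col_types = "cid", progress = FALSE)
}

#' Read a two-column chromosome-length table
#'
#' @param path Path to a headerless TSV with columns chromosome, length.
#' @return Named numeric vector of lengths.
#' @export
read_chrom_lengths <- function(path) {
  tb <- readr::read_tsv(path, col_names = c("chrom", "length"),
                        col_types = "cd", progress = FALSE)
  setNames(tb$length, tb$chrom)
}

#' Read a BED file of intervals
#'
#' @param path Path to a BED file (first three columns used; 0-based
#'   half-open coordinates).
#' @return A tibble with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  tb <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                        progress = FALSE)
  tibble(chrom = as.character(tb[[1]]), start = as.numeric(tb[[2]]),
         end = as.numeric(tb[[3]]))
}

#' Read a long-format plate-reader OD export
#'
#' @param path CSV with columns `well`, `time_min`, `od` (extra columns such
#'   as `strain_id` are kept).
#' @return A tibble.
#' @export
read_growth_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
}

#' Write LOH segments as a BED track
#'
#' Writes segments in 0-based half-open BED coordinates, with the segment
#' kind as the name field and the marker count as the score.
#'
#' @param segments A [detect_loh()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loh_bed <- function(segments, path) {
  bed <- tibble(
    chrom = segments$chrom,
    start = as.integer(segments$start - 1L),
    end = as.integer(segments$end),
    name = segments$kind,
    score = segments$n_markers
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
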