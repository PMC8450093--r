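#' The bespoke library-size denominator
#'
#' Sense rRNA and sense mRNA reads are possible degradation fragments,
#' so the library-size denominator excludes them: total genome-mapped
#' reads minus sense rRNA reads minus sense mRNA reads. By the category
#' partition this equals `risiRNA + antisense_mRNA`.
#'
#' @param counts A `category_counts`.
#' @return Integer normalization number.
#' @export
normalization_factor <- function(counts) {
  stopifnot(inherits(counts, "category_counts"))
  nf <- counts$total_mapped - counts$sense_rRNA - counts$sense_mRNA
  if (nf <= 0L) stop("empty normalization basis: no antisense reads mapped")
  nf
}

#' Normalized risiRNA abundance (reads per million)
#'
#' risiRNA reads per million of the bespoke normalization number.
#'
#' @param counts A `category_counts`.
#' @return Numeric RPM.
#' @export
risirna_rpm <- function(counts) {
  1e6 * counts$risiRNA / normalization_factor(counts)
}

#' Region-of-origin proportions of risiRNAs
#'
#' Assigns each antisense alignment on the unit to the region containing
#' its midpoint, `floor((start + end - 1) / 2)` — deterministic and
#' symmetric for boundary-spanning reads, ties broken toward the lower
#' coordinate — then divides region counts by the risiRNA total.
#'
#' @param alignments `data.frame` with `start`, `end` (0-based
#'   half-open) and `strand` of risiRNA alignments on the unit; strand
#'   must be `-`.
#' @param unit An `rdna_unit`.
#' @return Named numeric vector over the unit's regions summing to 1;
#'   with zero reads, an all-zero vector with attribute
#'   `undefined = TRUE`.
#' @export
region_proportions <- function(alignments, unit) {
  stopifnot(inherits(unit, "rdna_unit"))
  regions <- unit$regions$name
  if (nrow(alignments) == 0L) {
    out <- setNames(rep(0, length(regions)), regions)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  if (!all(alignments$strand == "-"))
    stop("region_proportions expects antisense (strand '-') alignments")
  mid <- (alignments$start + alignments$end - 1L) %/% 2L
  reg <- locate(unit, mid)
  tab <- table(factor(reg, levels = regions))
  out <- as.numeric(tab) / nrow(alignments)
  names(out) <- regions
  out
}

#' Length histogram of risiRNA reads
#'
#' @param classified Classified read table; rows with
#'   `category == "risiRNA"` are used (pass a pre-filtered table to
#'   histogram another set).
#' @param min_len,max_len Histogram support (defaults 18 and 30).
#' @return Named integer vector over `min_len..max_len`; total equals
#'   the risiRNA read count.
#' @export
length_histogram <- function(classified, min_len = 18L, max_len = 30L) {
  lens <- risirna_rows(classified)$length
  tab <- table(factor(lens, levels = min_len:max_len))
  setNames(as.integer(tab), min_len:max_len)
}

#' 5'-nucleotide preference of risiRNA reads
#'
#' Fractions of A/C/G/T at the first sequenced position — the 5' base of
#' the antisense RNA, i.e. the complement of the unit plus-strand base
#' at `end - 1` of the alignment. Reads with `N` first are excluded from
#' the denominator.
#'
#' @param classified Classified read table (risiRNA rows are used).
#' @return Named numeric vector over A, C, G, T summing to 1 (all zero,
#'   flagged `undefined`, when there are no risiRNA reads).
#' @export
first_nt_preference <- function(classified) {
  s <- substr(risirna_rows(classified)$sequence, 1L, 1L)
  s <- s[s %in% c("A", "C", "G", "T")]
  if (length(s) == 0L) {
    out <- setNames(rep(0, 4), c("A", "C", "G", "T"))
    attr(out, "undefined") <- TRUE
    return(out)
  }
  tab <- table(factor(s, levels = c("A", "C", "G", "T")))
  setNames(as.numeric(tab) / length(s), c("A", "C", "G", "T"))
}

risirna_rows <- function(classified) {
  if ("category" %in% names(classified))
    classified[classified$category == "risiRNA", , drop = FALSE]
  else classified
}

#' Per-base antisense coverage over the unit
#'
#' `coverage[i]` is the number of antisense reads overlapping base `i`
#' (0-based); the sum over the track equals the summed lengths of the
#' contributing reads.
#'
#' @param alignments risiRNA alignments on the unit (`start`, `end`).
#' @param unit An `rdna_unit`.
#' @return Integer vector of length `nchar(unit$sequence)`.
#' @export
coverage_track <- function(alignments, unit) {
  stopifnot(inherits(unit, "rdna_unit"))
  n <- nchar(unit$sequence)
  if (nrow(alignments) == 0L) return(integer(n))
  ir <- IRanges::IRanges(start = alignments$start + 1L,
                         end = alignments$end)
  as.integer(IRanges::coverage(ir, width = n))
}

#' Write a coverage track as bedGraph
#'
#' Adjacent equal-depth bases are merged into one interval; zero-depth
#' runs are kept so the track tiles the unit.
#'
#' @param coverage Integer vector from [coverage_track()].
#' @param unit An `rdna_unit`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(coverage, unit, path) {
  r <- rle(coverage)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  gr <- GenomicRanges::GRanges(
    seqnames = unit$name,
    ranges = IRanges::IRanges(start = starts + 1L, end = ends),
    score = r$values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Full risiRNA profile of a classified library
#'
#' Bundles the headline quantities: the normalization number, risiRNA
#' reads per million of it, region-proportion vector (midpoint rule),
#' 18-30 nt length histogram, 5'-nucleotide table and per-base antisense
#' coverage over the unit.
#'
#' @param classified Output of [classify_reads()] / [process_reads()].
#' @param unit An `rdna_unit`.
#' @return Object of class `risirna_profile`.
#' @export
risirna_profile <- function(classified, unit) {
  counts <- count_categories(classified)
  risi <- classified[classified$category == "risiRNA" &
                       classified$target == unit$name &
                       !is.na(classified$target), , drop = FALSE]
  structure(list(
    counts = counts,
    norm_factor = normalization_factor(counts),
    risiRNA_rpm = risirna_rpm(counts),
    region_proportions = region_proportions(risi, unit),
    length_hist = length_histogram(classified),
    first_nt = first_nt_preference(classified),
    coverage = coverage_track(risi, unit),
    unit_name = unit$name), class = "risirna_profile")
}

#' @export
print.risirna_profile <- function(x, ...) {
  cat(sprintf("risiRNA profile on '%s'\n", x$unit_name))
  cat(sprintf("  normalization number: %d reads\n", x$norm_factor))
  cat(sprintf("  risiRNA abundance:    %.1f RPM (%d reads)\n",
              x$risiRNA_rpm, x$counts$risiRNA))
  cat("  region proportions:   ",
      paste(sprintf("%s=%.3f", names(x$region_proportions),
                    x$region_proportions), collapse = " "), "\n")
  mode_len <- names(x$length_hist)[which.max(x$length_hist)]
  cat(sprintf("  modal length: %s nt; 5' nt: %s\n", mode_len,
              paste(sprintf("%s=%.2f", names(x$first_nt), x$first_nt),
                    collapse = " ")))
  invisible(x)
}

#' Write a risiRNA profile as JSON (plus TSV tables)
#'
#' @param profile A `risirna_profile`.
#' @param json_path Output JSON path.
#' @return The path, invisibly.
#' @export
write_profile_json <- function(profile, json_path) {
  x <- list(
    unit = profile$unit_name,
    counts = profile$counts[READ_CATEGORIES],
    total_mapped = profile$counts$total_mapped,
    norm_factor = profile$norm_factor,
    risiRNA_rpm = profile$risiRNA_rpm,
    region_proportions = as.list(profile$region_proportions),
    length_hist = as.list(profile$length_hist),
    first_nt = as.list(profile$first_nt),
    coverage_total = sum(profile$coverage))
  jsonlite::write_json(x, json_path, auto_unbox = TRUE, digits = NA)
  invisible(json_path)
}
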