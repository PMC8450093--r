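#' rDNA transcription-unit reference
#'
#' An `rdna_unit` bundles the plus-strand (sense pre-rRNA) sequence of one
#' representative rDNA repeat with an ordered region annotation. The ~50
#' genomic rDNA copies of *C. elegans* are collapsed into this single unit:
#' a read hitting the unit counts once, since per-copy assignment is
#' meaningless for identical repeats. Coordinates are 0-based, half-open
#' (BED convention); the regions must tile the unit without gaps or
#' overlaps.
#'
#' @param sequence Single nucleotide string over `{A,C,G,T}`.
#' @param regions `data.frame` with columns `name`, `start` (0-based
#'   inclusive), `end` (0-based exclusive), in 5' to 3' order.
#' @param name Unit identifier used in FASTA/BED output.
#' @return An object of class `rdna_unit`: a list with elements
#'   `name`, `sequence`, `regions`.
#' @examples
#' seq <- paste(rep("ACGT", 25), collapse = "")
#' reg <- data.frame(
#'   name  = c("5ETS", "18S", "ITS1", "5.8S", "ITS2", "26S", "3ETS"),
#'   start = c(0, 10, 40, 50, 55, 60, 95),
#'   end   = c(10, 40, 50, 55, 60, 95, 100))
#' unit <- rdna_unit(seq, reg)
#' @export
rdna_unit <- function(sequence, regions, name = "rDNA_unit") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence))
    stop("unit sequence must be non-empty over the alphabet {A,C,G,T}")
  regions <- as.data.frame(regions)
  if (!all(c("name", "start", "end") %in% names(regions)))
    stop("regions must have columns name, start, end")
  regions <- regions[, c("name", "start", "end")]
  regions$name <- as.character(regions$name)
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  validate_regions(regions, nchar(sequence))
  structure(list(name = name, sequence = sequence, regions = regions),
            class = "rdna_unit")
}

# Region invariants: sorted, start < end, non-overlapping, gap-free tiling
# of [0, unit_length).
validate_regions <- function(regions, unit_length) {
  if (nrow(regions) == 0L) stop("no regions annotated")
  if (anyDuplicated(regions$name)) stop("duplicated region names")
  if (any(regions$start >= regions$end))
    stop("invalid region: start must be < end")
  o <- order(regions$start)
  if (!identical(o, seq_len(nrow(regions))))
    stop("regions must be sorted by start coordinate")
  if (regions$start[1L] != 0L)
    stop("gap at 5' end: first region must start at 0")
  gaps <- regions$start[-1L] - regions$end[-nrow(regions)]
  if (any(gaps > 0L)) stop("gap between regions: tiling must be complete")
  if (any(gaps < 0L)) stop("overlapping regions")
  if (regions$end[nrow(regions)] < unit_length)
    stop("gap at 3' end: regions do not cover the unit")
  if (regions$end[nrow(regions)] > unit_length)
    stop("region annotation exceeds sequence length")
  invisible(regions)
}

#' @export
print.rdna_unit <- function(x, ...) {
  cat(sprintf("rDNA transcription unit '%s': %d nt, %d regions\n",
              x$name, nchar(x$sequence), nrow(x$regions)))
  print(transform(x$regions, length = end - start), row.names = FALSE)
  invisible(x)
}

#' Load an rDNA unit from FASTA + BED
#'
#' Reads a single-record FASTA and a BED (3 columns plus name) region
#' annotation and returns a validated [rdna_unit()]. The BED intervals
#' must tile the sequence exactly; gaps, overlaps or out-of-bounds
#' records raise an error.
#'
#' @param fasta_path FASTA with exactly one record (the unit).
#' @param bed_path BED3+name file whose chrom field matches the FASTA
#'   record name.
#' @return An `rdna_unit`.
#' @export
load_reference <- function(fasta_path, bed_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty FASTA: ", fasta_path)
  if (length(seqs) != 1L)
    stop("reference FASTA must contain exactly one record")
  unit_name <- sub("\\s.*$", "", names(seqs)[1L])
  gr <- rtracklayer::import(bed_path, format = "BED")
  if (length(gr) == 0L) stop("empty BED: ", bed_path)
  if (!all(as.character(GenomicRanges::seqnames(gr)) == unit_name))
    stop("BED chrom does not match FASTA record name '", unit_name, "'")
  if (is.null(gr$name) || anyNA(gr$name))
    stop("missing region names in BED")
  regions <- data.frame(
    name  = gr$name,
    start = GenomicRanges::start(gr) - 1L,  # BED is 0-based; GRanges 1-based
    end   = GenomicRanges::end(gr))
  regions <- regions[order(regions$start), , drop = FALSE]
  rdna_unit(as.character(seqs[[1L]]), regions, name = unit_name)
}

#' Write an rDNA unit as FASTA + BED
#'
#' Inverse of [load_reference()]: round-trip is lossless.
#'
#' @param unit An `rdna_unit`.
#' @param fasta_path,bed_path Output paths.
#' @return Invisibly, the paths.
#' @export
write_reference <- function(unit, fasta_path, bed_path) {
  stopifnot(inherits(unit, "rdna_unit"))
  seqs <- Biostrings::DNAStringSet(setNames(unit$sequence, unit$name))
  Biostrings::writeXStringSet(seqs, fasta_path)
  gr <- GenomicRanges::GRanges(
    seqnames = unit$name,
    ranges = IRanges::IRanges(start = unit$regions$start + 1L,
                              end = unit$regions$end),
    name = unit$regions$name)
  rtracklayer::export(gr, bed_path, format = "BED")
  invisible(c(fasta = fasta_path, bed = bed_path))
}

#' Decoy transcript set
#'
#' Sense transcripts used to absorb non-risiRNA reads: the 5S rRNA (an
#' RNA polymerase III transcript from a separate locus, so it lives here
#' rather than inside the transcription unit) and protein-coding mRNAs.
#' Names must be unique and, for unambiguous classification, no decoy may
#' share an exact substring of >= 18 nt with the rDNA unit on either
#' strand — [build_default_reference()] enforces this at generation.
#'
#' @param transcripts Named character vector of sequences; must include
#'   one named `"5S"`.
#' @return Object of class `decoy_set` (a validated named character
#'   vector).
#' @export
decoy_set <- function(transcripts) {
  stopifnot(is.character(transcripts), length(transcripts) >= 1L)
  if (is.null(names(transcripts)) || anyDuplicated(names(transcripts)))
    stop("decoy transcripts must have unique names")
  transcripts <- toupper(transcripts)
  if (!all(grepl("^[ACGT]+$", transcripts)))
    stop("decoy sequences must be over {A,C,G,T}")
  if (!"5S" %in% names(transcripts))
    stop("decoy set must contain a transcript named '5S'")
  structure(transcripts, class = "decoy_set")
}

#' @export
print.decoy_set <- function(x, ...) {
  cat(sprintf("decoy set: %d transcripts (%s)\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Write / load decoy transcripts as FASTA
#' @param decoys A `decoy_set`.
#' @param fasta_path File path.
#' @return `write_decoys` returns the path invisibly; `load_decoys`
#'   returns a `decoy_set`.
#' @export
write_decoys <- function(decoys, fasta_path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unclass(decoys)), fasta_path)
  invisible(fasta_path)
}

#' @rdname write_decoys
#' @export
load_decoys <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty decoy FASTA: ", fasta_path)
  decoy_set(setNames(as.character(seqs), sub("\\s.*$", "", names(seqs))))
}

# All k-mers of a sequence string (both strands when both = TRUE).
kmer_set <- function(seq, k, both = FALSE) {
  n <- nchar(seq)
  if (n < k) return(character())
  km <- substring(seq, 1:(n - k + 1L), k:n)
  if (both) km <- c(km, substring(revcomp(seq), 1:(n - k + 1L), k:n))
  unique(km)
}

#' Build the default desk-scale reference
#'
#' Generates a deterministic pseudo-random rDNA transcription unit with
#' the canonical region schema (default lengths 700/1750/500/160/350/
#' 3500/150 nt for 5'ETS/18S/ITS1/5.8S/ITS2/26S/3'ETS, echoing the
#' relative sizes of the *C. elegans* regions) plus a decoy set: one
#' 120 nt 5S rRNA and `n_mrna` protein-coding mRNAs of 500-2000 nt.
#' Decoys are re-drawn until none shares an exact >= 18 nt substring
#' with the unit on either strand, so exact-match classification of
#' synthetic reads is unambiguous.
#'
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param region_lengths Named integer vector over the seven canonical
#'   region names (schematic stand-ins; override with measured lengths
#'   for a real repeat).
#' @param n_mrna Number of mRNA decoys (>= 5).
#' @return `list(unit = rdna_unit, decoys = decoy_set)`.
#' @examples
#' ref <- build_default_reference(seed = 1)
#' ref$unit
#' @export
build_default_reference <- function(seed = 1L,
                                    region_lengths = DEFAULT_REGION_LENGTHS,
                                    n_mrna = 6L) {
  stopifnot(n_mrna >= 5L)
  if (!identical(sort(names(region_lengths)), sort(RDNA_REGIONS)))
    stop("region_lengths must name exactly the seven canonical regions")
  region_lengths <- region_lengths[RDNA_REGIONS]
  with_seed(scramble_seed(seed, "reference"), {
    total <- sum(region_lengths)
    unit_seq <- random_dna(total)
    ends <- cumsum(as.integer(region_lengths))
    regions <- data.frame(name = RDNA_REGIONS,
                          start = c(0L, ends[-length(ends)]),
                          end = ends)
    unit <- rdna_unit(unit_seq, regions)
    unit_kmers <- kmer_set(unit_seq, 18L, both = TRUE)
    draw_decoy <- function(len) {
      repeat {
        s <- random_dna(len)
        if (!any(kmer_set(s, 18L) %in% unit_kmers)) return(s)
      }
    }
    decoys <- c("5S" = draw_decoy(120L))
    mrna_len <- sample(500:2000, n_mrna, replace = TRUE)
    for (i in seq_len(n_mrna))
      decoys[[sprintf("mRNA_%02d", i)]] <- draw_decoy(mrna_len[i])
    list(unit = unit, decoys = decoy_set(decoys))
  })
}

#' Locate positions within the region annotation
#'
#' Maps 0-based unit positions to the name of the region whose
#' half-open interval `[start, end)` contains them.
#'
#' @param unit An `rdna_unit`.
#' @param position Integer vector of 0-based positions,
#'   `0 <= position < unit length`.
#' @return Character vector of region names, one per position.
#' @examples
#' ref <- build_default_reference(seed = 1)
#' locate(ref$unit, c(0, 699, 700))  # "5ETS" "5ETS" "18S"
#' @export
locate <- function(unit, position) {
  stopifnot(inherits(unit, "rdna_unit"))
  position <- as.integer(position)
  if (any(position < 0L | position >= nchar(unit$sequence)))
    stop("position out of range [0, ", nchar(unit$sequence), ")")
  idx <- findInterval(position, unit$regions$start)
  unit$regions$name[idx]
}
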