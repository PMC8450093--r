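#' Library profile for the small-RNA simulator
#'
#' Describes the statistical structure of a synthetic small-RNA library:
#' the mixture over read categories, where on the rDNA unit risiRNA
#' 5' ends fall (`region_weights`), the read-length distribution over
#' the small-RNA size range, and the 5'-guanosine bias characteristic
#' of 22G-RNAs. All randomness is driven by `seed`.
#'
#' @param n_reads Number of reads to emit.
#' @param frac_risiRNA,frac_sense_rRNA,frac_sense_mRNA,frac_antisense_mRNA,frac_unmapped
#'   Category mixture; must sum to 1. `frac_sense_rRNA` covers sense
#'   fragments of both the transcription unit and the 5S decoy
#'   (rRNA degradation background); `frac_unmapped` is random sequence.
#' @param region_weights Named numeric vector over the seven canonical
#'   region names, summing to 1: sampling weights for the rDNA region a
#'   risiRNA is antisense to.
#' @param length_dist Named numeric probability vector; names are read
#'   lengths in nt (support must lie in 16..35 so the 18-30 clean-read
#'   filter can be exercised), values sum to 1. Default concentrates
#'   mass at 22 nt.
#' @param p_first_G Probability that a risiRNA's 5' nucleotide is G
#'   (default 0.75). Implemented by conditioning the placement on the
#'   reference base, so reads stay exact matches; see the methods
#'   vignette.
#' @param frac_rRNA_5S Share of the sense-rRNA category drawn from the
#'   5S decoy rather than the unit.
#' @param seed Integer seed.
#' @return Object of class `library_profile`.
#' @export
library_profile <- function(n_reads = 100000L,
                            frac_risiRNA = 0.02,
                            frac_sense_rRNA = 0.55,
                            frac_sense_mRNA = 0.28,
                            frac_antisense_mRNA = 0.05,
                            frac_unmapped = 0.10,
                            region_weights = NULL,
                            length_dist = default_length_dist(),
                            p_first_G = 0.75,
                            frac_rRNA_5S = 0.1,
                            seed = 1L) {
  if (is.null(region_weights)) {
    # default: antisense mass proportional to region length
    region_weights <- DEFAULT_REGION_LENGTHS / sum(DEFAULT_REGION_LENGTHS)
  }
  p <- structure(list(
    n_reads = as.integer(n_reads),
    fractions = c(risiRNA = frac_risiRNA, sense_rRNA = frac_sense_rRNA,
                  sense_mRNA = frac_sense_mRNA,
                  antisense_mRNA = frac_antisense_mRNA,
                  unmapped = frac_unmapped),
    region_weights = region_weights,
    length_dist = length_dist,
    p_first_G = p_first_G,
    frac_rRNA_5S = frac_rRNA_5S,
    seed = as.integer(seed)), class = "library_profile")
  validate_profile(p)
}

validate_profile <- function(p) {
  if (p$n_reads < 0L) stop("n_reads must be >= 0")
  if (any(p$fractions < 0) || abs(sum(p$fractions) - 1) > 1e-9)
    stop("category fractions must be non-negative and sum to 1")
  if (!identical(sort(names(p$region_weights)), sort(RDNA_REGIONS)))
    stop("region_weights must name exactly the seven canonical regions")
  if (any(p$region_weights < 0) || abs(sum(p$region_weights) - 1) > 1e-9)
    stop("region_weights must be non-negative and sum to 1")
  lens <- as.integer(names(p$length_dist))
  if (anyNA(lens) || any(lens < 16L) || any(lens > 35L))
    stop("length_dist support must lie within 16..35 nt")
  if (any(p$length_dist < 0) || abs(sum(p$length_dist) - 1) > 1e-9)
    stop("length_dist must be a probability vector")
  if (p$p_first_G < 0 || p$p_first_G > 1) stop("p_first_G must be in [0,1]")
  if (p$frac_rRNA_5S < 0 || p$frac_rRNA_5S > 1)
    stop("frac_rRNA_5S must be in [0,1]")
  p
}

#' Default small-RNA length distribution (22 nt mode)
#'
#' Probability vector over 18..30 nt with the bulk of the mass at 22 nt,
#' the canonical 22G-RNA length.
#' @return Named numeric vector summing to 1.
#' @export
default_length_dist <- function() {
  d <- c("18" = 0.010, "19" = 0.020, "20" = 0.050, "21" = 0.120,
         "22" = 0.550, "23" = 0.120, "24" = 0.060, "25" = 0.030,
         "26" = 0.020, "27" = 0.010, "28" = 0.005, "29" = 0.003,
         "30" = 0.002)
  d / sum(d)
}

#' @export
print.library_profile <- function(x, ...) {
  cat(sprintf("library profile: %d reads, seed %d\n", x$n_reads, x$seed))
  cat("  fractions: ",
      paste(sprintf("%s=%.3g", names(x$fractions), x$fractions),
            collapse = " "), "\n")
  cat("  region weights: ",
      paste(sprintf("%s=%.3g", names(x$region_weights), x$region_weights),
            collapse = " "), "\n")
  cat(sprintf("  p_first_G = %.3g; length mode = %s nt\n", x$p_first_G,
              names(x$length_dist)[which.max(x$length_dist)]))
  invisible(x)
}

#' Genotype presets for the simulator
#'
#' Ships the library profiles used throughout: total small-RNA libraries
#' for wild-type-like, disl-2-like, dis-3-like, exos-1-like and
#' rrp-8-like backgrounds, and NRDE-3 immunoprecipitation variants
#' (eri-1;rrp-8, eri-1;dis-3). disl-2 puts 65% of the antisense mass in
#' 26S and the eri-1;rrp-8 IP preset 90%; the exosome mutants are
#' ITS-dominated. Presets are stored as editable JSON under
#' `inst/extdata/presets/` — the weights are parameters, not hard-coded
#' truths.
#'
#' @param name Preset name; see [list_presets()].
#' @param n_reads,seed Override the preset's library size and seed.
#' @return A `library_profile`.
#' @examples
#' preset_profile("disl-2", n_reads = 1000, seed = 7)
#' @export
preset_profile <- function(name, n_reads = NULL, seed = NULL) {
  path <- system.file("extdata", "presets", paste0(name, ".json"),
                      package = "risiRNAkit")
  if (path == "")
    stop("unknown preset '", name, "'; available: ",
         paste(list_presets(), collapse = ", "))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  rw <- unlist(cfg$region_weights); rw <- rw / sum(rw)
  ld <- unlist(cfg$length_dist); ld <- ld / sum(ld)
  p <- library_profile(
    n_reads = if (is.null(n_reads)) cfg$n_reads else n_reads,
    frac_risiRNA = cfg$fractions[["risiRNA"]],
    frac_sense_rRNA = cfg$fractions[["sense_rRNA"]],
    frac_sense_mRNA = cfg$fractions[["sense_mRNA"]],
    frac_antisense_mRNA = cfg$fractions[["antisense_mRNA"]],
    frac_unmapped = cfg$fractions[["unmapped"]],
    region_weights = rw,
    length_dist = ld,
    p_first_G = cfg$p_first_G,
    frac_rRNA_5S = cfg$frac_rRNA_5S,
    seed = if (is.null(seed)) cfg$seed else seed)
  p
}

#' @rdname preset_profile
#' @export
list_presets <- function() {
  dir <- system.file("extdata", "presets", package = "risiRNAkit")
  sort(sub("\\.json$", "", list.files(dir, pattern = "\\.json$")))
}

# Sample alignment intervals for risiRNA reads. Each read is placed
# entirely inside its assigned region (a positively weighted region must
# be at least as long as the longest possible read). The 5'-G bias is
# realised by conditioning the placement: the antisense 5' base is the
# complement of the unit plus-strand base at end-1, so G-starting reads
# are those whose alignment ends on a plus-strand C.
place_risirna <- function(unit, region, len, want_g) {
  regions <- unit$regions
  is_c <- strsplit(unit$sequence, "", fixed = TRUE)[[1]] == "C"
  n <- length(region)
  start <- integer(n)
  key <- paste(region, len, want_g)
  for (k in unique(key)) {
    i <- which(key == k)
    r <- regions[regions$name == region[i[1]], ]
    L <- len[i[1]]
    # candidate 0-based end-1 positions within the region
    cand <- (r$start + L - 1L):(r$end - 1L)
    g_end <- is_c[cand + 1L]
    pool <- if (want_g[i[1]]) cand[g_end] else cand[!g_end]
    if (length(pool) == 0L) pool <- cand  # degenerate composition fallback
    ends <- pool[sample.int(length(pool), length(i), replace = TRUE)]
    start[i] <- ends - L + 1L
  }
  start
}

#' Simulate a small-RNA library with truth table
#'
#' Draws `n_reads` reads from the category mixture of `profile`:
#' risiRNAs (exact reverse complements of unit substrings, region drawn
#' from `region_weights`, placed wholly within the region, 5' nucleotide
#' G with probability `p_first_G`), sense rRNA degradation fragments
#' (unit or 5S), sense/antisense mRNA decoy fragments, and random
#' unmapped sequence. Deterministic given `profile$seed`.
#'
#' @param profile A `library_profile`.
#' @param unit An `rdna_unit`.
#' @param decoys A `decoy_set`.
#' @param fastq_path Optional path; when given, reads are written as
#'   Phred+33 FASTQ (constant quality 'I' — qualities are never used by
#'   the analysis).
#' @return `list(reads = data.frame(id, sequence),
#'   truth = data.frame(id, category, target, region, start, end,
#'   strand))` with one truth row per emitted read; coordinates are
#'   0-based half-open on the target plus strand; `strand` is `-` for
#'   antisense placements.
#' @export
simulate_library <- function(profile, unit, decoys, fastq_path = NULL) {
  stopifnot(inherits(profile, "library_profile"),
            inherits(unit, "rdna_unit"), inherits(decoys, "decoy_set"))
  validate_profile(profile)
  max_len <- max(as.integer(names(profile$length_dist))[profile$length_dist > 0])
  wpos <- names(profile$region_weights)[profile$region_weights > 0]
  rlen <- setNames(unit$regions$end - unit$regions$start, unit$regions$name)
  short <- wpos[rlen[wpos] < max_len]
  if (length(short) > 0L)
    stop("region weight on a region shorter than max read length: ",
         paste(short, collapse = ", "))
  n <- profile$n_reads
  with_seed(scramble_seed(profile$seed, "library"), {
    category <- sample(names(profile$fractions), n, replace = TRUE,
                       prob = profile$fractions)
    lens <- as.integer(names(profile$length_dist))
    len <- lens[sample.int(length(lens), n, replace = TRUE,
                           prob = profile$length_dist)]
    sequence <- character(n)
    target <- rep(NA_character_, n)
    region <- rep(NA_character_, n)
    start <- rep(NA_integer_, n)
    strand <- rep(NA_character_, n)

    i <- which(category == "risiRNA")
    if (length(i)) {
      reg <- sample(names(profile$region_weights), length(i), replace = TRUE,
                    prob = profile$region_weights)
      want_g <- stats::runif(length(i)) < profile$p_first_G
      s <- place_risirna(unit, reg, len[i], want_g)
      sequence[i] <- revcomp(substring(unit$sequence, s + 1L, s + len[i]))
      target[i] <- unit$name; region[i] <- reg
      start[i] <- s; strand[i] <- "-"
    }

    i <- which(category == "sense_rRNA")
    if (length(i)) {
      from_5s <- stats::runif(length(i)) < profile$frac_rRNA_5S
      tgt <- ifelse(from_5s, "5S", unit$name)
      tlen <- ifelse(from_5s, nchar(decoys[["5S"]]), nchar(unit$sequence))
      l <- pmin(len[i], tlen)  # 5S is short; clip, still >= 18 for defaults
      s <- floor(stats::runif(length(i)) * (tlen - l + 1L))
      src <- ifelse(from_5s, decoys[["5S"]], unit$sequence)
      sequence[i] <- substring(src, s + 1L, s + l)
      target[i] <- tgt; start[i] <- as.integer(s); strand[i] <- "+"
      len[i] <- l
    }

    for (cat_m in c("sense_mRNA", "antisense_mRNA")) {
      i <- which(category == cat_m)
      if (!length(i)) next
      mr <- setdiff(names(decoys), "5S")
      tgt <- mr[sample.int(length(mr), length(i), replace = TRUE)]
      tlen <- nchar(unclass(decoys))[match(tgt, names(decoys))]
      s <- floor(stats::runif(length(i)) * (tlen - len[i] + 1L))
      frag <- substring(unclass(decoys)[match(tgt, names(decoys))],
                        s + 1L, s + len[i])
      sequence[i] <- if (cat_m == "antisense_mRNA") revcomp(frag) else frag
      target[i] <- tgt; start[i] <- as.integer(s)
      strand[i] <- if (cat_m == "antisense_mRNA") "-" else "+"
    }

    i <- which(category == "unmapped")
    if (length(i)) {
      sequence[i] <- vapply(len[i], random_dna, character(1))
    }

    id <- sprintf("read_%07d", seq_len(n))
    reads <- data.frame(id = id, sequence = sequence,
                        stringsAsFactors = FALSE)
    truth <- data.frame(id = id, category = category, target = target,
                        region = region, start = start,
                        end = start + len, strand = strand,
                        stringsAsFactors = FALSE)
    if (!is.null(fastq_path)) write_fastq(reads, fastq_path)
    list(reads = reads, truth = truth)
  })
}

#' FASTQ input/output for read tables
#'
#' Reads are carried as `data.frame(id, sequence)`. Output is Phred+33
#' with constant quality `I`.
#'
#' @param reads `data.frame` with columns `id`, `sequence`.
#' @param path FASTQ path (uncompressed).
#' @return `write_fastq` returns `path` invisibly; `read_fastq` returns
#'   a read table.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$id))
  qual <- Biostrings::PhredQuality(
    vapply(nchar(reads$sequence), function(w)
      paste(rep("I", w), collapse = ""), character(1)))
  qs <- Biostrings::QualityScaledDNAStringSet(seqs, qual)
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = sub("\\s.*$", "", names(seqs)),
             sequence = unname(as.character(seqs)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Append the 3' sequencing adapter to inserts
#'
#' Models library construction: each sequenced read is the insert
#' followed by the 3' adaptor (DNA form of the ligated RNA adaptor),
#' optionally truncated to a fixed machine read length.
#'
#' @param reads Read table (`id`, `sequence` = inserts).
#' @param three_prime_adapter Adapter in DNA alphabet; `""` leaves reads
#'   unchanged.
#' @param read_length Optional fixed read length to truncate to.
#' @return Read table with adapter-bearing sequences.
#' @export
attach_adapters <- function(reads, three_prime_adapter = DEFAULT_ADAPTER_3P,
                            read_length = NULL) {
  stopifnot(is.character(three_prime_adapter), length(three_prime_adapter) == 1L)
  if (nchar(three_prime_adapter) > 0 &&
      !grepl("^[ACGT]+$", three_prime_adapter))
    stop("adapter must be in the DNA alphabet {A,C,G,T}")
  out <- reads
  out$sequence <- paste0(reads$sequence, three_prime_adapter)
  if (!is.null(read_length))
    out$sequence <- substr(out$sequence, 1L, read_length)
  out
}

#' qPCR experiment design for the Ct simulator
#'
#' Describes a ChIP/RIP-qPCR experiment: which samples and amplicons are
#' assayed, the true enrichment (fraction of dilution-corrected input
#' recovered in the IP) per sample x locus, the input dilution, and
#' Gaussian technical noise on the Ct scale. Amplification efficiency is
#' fixed at 2 (one doubling per cycle).
#'
#' @param enrichment `data.frame` with columns `sample`, `locus`,
#'   `enrichment` (> 0) and optionally `treatment`.
#' @param input_fraction Input dilution, e.g. 0.01 for 1% input.
#' @param replicates Number of technical replicates (>= 2).
#' @param ct_noise_sd SD of Gaussian Ct noise, in cycles.
#' @param base_ct Named vector of per-locus input-well base Cts;
#'   defaults to 20 for every locus.
#' @param seed Integer seed.
#' @return Object of class `qpcr_design`.
#' @export
qpcr_design <- function(enrichment, input_fraction = 0.01, replicates = 4L,
                        ct_noise_sd = 0.15, base_ct = NULL, seed = 1L) {
  enrichment <- as.data.frame(enrichment)
  if (!all(c("sample", "locus", "enrichment") %in% names(enrichment)))
    stop("enrichment must have columns sample, locus, enrichment")
  if (!"treatment" %in% names(enrichment)) enrichment$treatment <- "none"
  if (any(enrichment$enrichment <= 0)) stop("enrichments must be > 0")
  if (input_fraction <= 0 || input_fraction >= 1)
    stop("input_fraction must be in (0,1)")
  if (replicates < 2L) stop("replicates must be >= 2")
  loci <- unique(enrichment$locus)
  if (is.null(base_ct)) base_ct <- setNames(rep(20, length(loci)), loci)
  if (!all(loci %in% names(base_ct))) stop("base_ct missing some loci")
  structure(list(enrichment = enrichment,
                 input_fraction = input_fraction,
                 replicates = as.integer(replicates),
                 ct_noise_sd = ct_noise_sd, base_ct = base_ct,
                 seed = as.integer(seed)), class = "qpcr_design")
}

#' Simulate replicate qPCR Ct tables
#'
#' For every (sample, locus, replicate) an input well and an IP well are
#' emitted. With per-cycle doubling, the IP Ct sits
#' `log2(1/input_fraction) + log2(enrichment)` cycles below the input
#' Ct, plus `Normal(0, ct_noise_sd)` technical noise on each well, so
#' noise-free data recover `100 * enrichment` percent input exactly.
#'
#' @param design A `qpcr_design`.
#' @return `data.frame` with columns `sample`, `treatment`, `locus`,
#'   `role` (`IP` | `input`), `fraction_input`, `replicate`, `ct`.
#' @export
simulate_qpcr <- function(design) {
  stopifnot(inherits(design, "qpcr_design"))
  e <- design$enrichment
  with_seed(scramble_seed(design$seed, "qpcr"), {
    rows <- do.call(rbind, lapply(seq_len(nrow(e)), function(i) {
      ct_in0 <- design$base_ct[[e$locus[i]]]
      ct_ip0 <- ct_in0 - log2(1 / design$input_fraction) -
        log2(e$enrichment[i])
      reps <- seq_len(design$replicates)
      data.frame(
        sample = e$sample[i], treatment = e$treatment[i], locus = e$locus[i],
        role = rep(c("input", "IP"), each = design$replicates),
        fraction_input = c(rep(design$input_fraction, design$replicates),
                           rep(NA_real_, design$replicates)),
        replicate = c(reps, reps),
        ct = c(ct_in0 + stats::rnorm(design$replicates, 0, design$ct_noise_sd),
               ct_ip0 + stats::rnorm(design$replicates, 0, design$ct_noise_sd)),
        stringsAsFactors = FALSE)
    }))
    rownames(rows) <- NULL
    rows
  })
}

#' Read / write Ct tables as CSV
#' @param ct_table `data.frame` as produced by [simulate_qpcr()].
#' @param path CSV path.
#' @return `write_ct_table` returns `path` invisibly; `read_ct_table`
#'   the table.
#' @export
write_ct_table <- function(ct_table, path) {
  write.csv(ct_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "treatment", "locus", "role", "fraction_input",
            "replicate", "ct")
  if (!all(need %in% names(x)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  if (nrow(x) == 0L) stop("empty Ct table: ", path)
  x
}
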