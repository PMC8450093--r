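#' Trim the 3' adapter from reads
#'
#' Truncates each read at the leftmost exact occurrence of the first
#' `min_overlap` nucleotides of the adapter; reads without a match are
#' returned untouched. This mirrors the clean-read preprocessing of
#' small-RNA libraries where the insert is shorter than the machine read
#' and the 3' adaptor is sequenced through.
#'
#' @param reads Read table (`id`, `sequence`).
#' @param adapter 3' adapter in DNA alphabet (default
#'   [DEFAULT_ADAPTER_3P]).
#' @param min_overlap Number of adapter-prefix nucleotides that must
#'   match (>= 1; default 8).
#' @return Read table with trimmed sequences.
#' @export
trim_adapter <- function(reads, adapter = DEFAULT_ADAPTER_3P,
                         min_overlap = 8L) {
  stopifnot(min_overlap >= 1L)
  if (nchar(adapter) < min_overlap)
    stop("adapter shorter than min_overlap")
  anchor <- substr(adapter, 1L, min_overlap)
  pos <- regexpr(anchor, reads$sequence, fixed = TRUE)
  out <- reads
  hit <- pos > 0L
  out$sequence[hit] <- substr(reads$sequence[hit], 1L, pos[hit] - 1L)
  out
}

#' Clean-read length filter
#'
#' Keeps reads whose length lies in `[min_len, max_len]`, inclusive at
#' both ends — the 18-30 nt window that defines clean small-RNA reads.
#'
#' @param reads Read table.
#' @param min_len,max_len Inclusive bounds (defaults 18 and 30).
#' @return Filtered read table.
#' @export
length_filter <- function(reads, min_len = 18L, max_len = 30L) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  keep <- nchar(reads$sequence) >= min_len & nchar(reads$sequence) <= max_len
  reads[keep, , drop = FALSE]
}

# Targets as a named character vector: the unit plus every decoy.
target_set <- function(unit, decoys) {
  c(setNames(unit$sequence, unit$name), unclass(decoys))
}

#' Map reads by exact matching on both strands
#'
#' Places every read on every target (the rDNA unit and each decoy
#' transcript) by exact, 0-mismatch matching: strand `+` hits are
#' positions where the read equals a target substring, strand `-` hits
#' where it equals the reverse complement of one. All hits are returned,
#' sorted by (target name, start, strand, read id). Reads containing `N`
#' never match. Matching hashes every target substring of each read
#' width against the unique read sequences, so large libraries with
#' heavy sequence duplication map quickly; the semantics are exactly
#' those of a brute-force both-strand scan at every offset.
#'
#' @param reads Read table (`id`, `sequence`).
#' @param unit An `rdna_unit`.
#' @param decoys A `decoy_set`.
#' @return `data.frame(id, target, start, end, strand)`; coordinates are
#'   0-based half-open on the target plus strand, `end - start` equals
#'   the read length.
#' @export
map_reads <- function(reads, unit, decoys) {
  stopifnot(inherits(unit, "rdna_unit"), inherits(decoys, "decoy_set"))
  targets <- target_set(unit, decoys)
  useq <- unique(reads$sequence)
  clean <- useq[grepl("^[ACGT]+$", useq)]
  hit_list <- list()
  if (length(clean)) {
    widths <- nchar(clean)
    for (w in unique(widths)) {
      pats <- clean[widths == w]
      rc_pats <- revcomp(pats)  # read == revcomp(substring) <=> strand -
      for (tn in names(targets)) {
        tseq <- targets[[tn]]
        n <- nchar(tseq)
        if (n < w) next
        offs <- seq_len(n - w + 1L)
        subs <- substring(tseq, offs, offs + w - 1L)
        for (st in c("+", "-")) {
          m <- match(subs, if (st == "+") pats else rc_pats)
          sel <- which(!is.na(m))
          if (length(sel) == 0L) next
          hit_list[[length(hit_list) + 1L]] <- data.frame(
            sequence = pats[m[sel]],
            target = tn,
            start = offs[sel] - 1L,
            strand = st, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hit_list) == 0L) {
    return(data.frame(id = character(), target = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  uh <- do.call(rbind, hit_list)
  uh$end <- uh$start + nchar(uh$sequence)
  # expand unique-sequence hits back to individual reads
  per_read <- split(seq_len(nrow(uh)), uh$sequence)
  rows <- per_read[reads$sequence]
  n_per <- lengths(rows)
  keep <- n_per > 0L
  hits <- uh[unlist(rows[keep]), c("target", "start", "end", "strand")]
  hits$id <- rep(reads$id[keep], n_per[keep])
  hits <- hits[, c("id", "target", "start", "end", "strand")]
  ord <- order(hits$target, hits$start,
               match(hits$strand, c("+", "-")), hits$id)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Category priority: antisense-to-rRNA first, then sense rRNA, then the
# mRNA decoys; a read with no hit is unmapped.
category_of_hits <- function(target, strand, unit_name, is_rrna_target) {
  if (length(target) == 0L) return("unmapped")
  rr <- is_rrna_target
  if (any(rr & strand == "-")) return("risiRNA")
  if (any(rr & strand == "+")) return("sense_rRNA")
  if (any(!rr & strand == "+")) return("sense_mRNA")
  "antisense_mRNA"
}

#' Classify reads from their alignments
#'
#' Assigns every read exactly one category by the fixed priority:
#' any minus-strand hit on the rDNA unit or 5S makes it a risiRNA;
#' otherwise a plus-strand rRNA hit makes it a sense rRNA degradation
#' fragment; otherwise mRNA-decoy hits give sense/antisense mRNA; no hit
#' means unmapped. The reported alignment is the first hit of the
#' winning class in (target, start, strand) order, so multi-mapping
#' reads count once, deterministically.
#'
#' @param reads Read table (post trim/filter).
#' @param hits Alignments from [map_reads()].
#' @param unit An `rdna_unit` (names the rRNA targets).
#' @return `data.frame(id, sequence, length, category, target, start,
#'   end, strand)`, one row per read; alignment columns are `NA` for
#'   unmapped reads.
#' @export
classify_reads <- function(reads, hits, unit) {
  stopifnot(inherits(unit, "rdna_unit"))
  rrna_targets <- c(unit$name, "5S")
  out <- data.frame(id = reads$id, sequence = reads$sequence,
                    length = nchar(reads$sequence),
                    category = "unmapped",
                    target = NA_character_, start = NA_integer_,
                    end = NA_integer_, strand = NA_character_,
                    stringsAsFactors = FALSE)
  if (nrow(hits) > 0L) {
    hits$.rr <- hits$target %in% rrna_targets
    # class rank under the priority order; 1 wins
    rank <- ifelse(hits$.rr & hits$strand == "-", 1L,
            ifelse(hits$.rr & hits$strand == "+", 2L,
            ifelse(hits$strand == "+", 3L, 4L)))
    # hits are sorted by (target, start, strand); stable order(rank)
    # within read keeps the first hit of the winning class
    by_read <- split(seq_len(nrow(hits)), hits$id)
    ids <- names(by_read)
    best <- vapply(by_read, function(i) i[which.min(rank[i])], integer(1))
    cats <- c("risiRNA", "sense_rRNA", "sense_mRNA", "antisense_mRNA")
    m <- match(ids, out$id)
    out$category[m] <- cats[rank[best]]
    out$target[m] <- hits$target[best]
    out$start[m] <- hits$start[best]
    out$end[m] <- hits$end[best]
    out$strand[m] <- hits$strand[best]
  }
  rownames(out) <- NULL
  out
}

#' Tally classified reads into category counts
#'
#' @param classified Output of [classify_reads()].
#' @return Object of class `category_counts`: a list with the five
#'   category totals plus `total_mapped`, and a per-target count table
#'   in attribute `by_target`. Counts always sum to the library size.
#' @export
count_categories <- function(classified) {
  tab <- table(factor(classified$category, levels = READ_CATEGORIES))
  counts <- as.list(as.integer(tab))
  names(counts) <- READ_CATEGORIES
  counts$total_mapped <- counts$risiRNA + counts$sense_rRNA +
    counts$sense_mRNA + counts$antisense_mRNA
  by_target <- if ("target" %in% names(classified))
    table(target = classified$target, category = classified$category)
  structure(counts, by_target = by_target, class = "category_counts")
}

#' @export
print.category_counts <- function(x, ...) {
  n <- x$total_mapped + x$unmapped
  cat(sprintf("category counts (%d reads, %d mapped):\n", n, x$total_mapped))
  for (k in READ_CATEGORIES)
    cat(sprintf("  %-15s %d\n", k, x[[k]]))
  invisible(x)
}

#' Run the read-processing front end
#'
#' Convenience composition: adapter trim, clean-read length filter,
#' exact-match mapping, classification.
#'
#' @param reads Raw read table (adapter-bearing or clean).
#' @param unit,decoys Reference.
#' @param adapter Adapter for [trim_adapter()]; `""` skips trimming.
#' @param min_overlap Adapter anchor length.
#' @param min_len,max_len Clean-read bounds.
#' @return `classify_reads()` output for the surviving reads.
#' @export
process_reads <- function(reads, unit, decoys,
                          adapter = DEFAULT_ADAPTER_3P, min_overlap = 8L,
                          min_len = 18L, max_len = 30L) {
  if (nchar(adapter) > 0)
    reads <- trim_adapter(reads, adapter, min_overlap)
  reads <- length_filter(reads, min_len, max_len)
  hits <- map_reads(reads, unit, decoys)
  classify_reads(reads, hits, unit)
}
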