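# Shared fixtures and independent oracles.

CANON <- c("5ETS", "18S", "ITS1", "5.8S", "ITS2", "26S", "3ETS")

# Minimal valid tiling on a 100 nt unit (random but seed-fixed sequence).
tiny_regions <- function() {
  data.frame(name = CANON,
             start = c(0, 10, 40, 50, 55, 60, 95),
             end   = c(10, 40, 50, 55, 60, 95, 100))
}

tiny_unit <- function(seed = 42) {
  seq <- withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
          collapse = ""))
  rdna_unit(seq, tiny_regions())
}

# Brute-force both-strand exact mapper: substring comparison at every
# offset of every target. Independent of the package's matcher.
brute_map <- function(sequences, targets) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  out <- list()
  for (i in seq_along(sequences)) {
    s <- sequences[i]
    w <- nchar(s)
    if (grepl("N", s, fixed = TRUE)) next
    s_rc <- rc(s)
    for (tn in names(targets)) {
      tseq <- targets[[tn]]
      if (nchar(tseq) < w) next
      for (off in 0:(nchar(tseq) - w)) {
        sub <- substr(tseq, off + 1, off + w)
        if (sub == s)
          out[[length(out) + 1]] <- data.frame(
            read = i, target = tn, start = off, end = off + w,
            strand = "+", stringsAsFactors = FALSE)
        if (sub == s_rc)
          out[[length(out) + 1]] <- data.frame(
            read = i, target = tn, start = off, end = off + w,
            strand = "-", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(read = integer(), target = character(),
                      start = integer(), end = integer(),
                      strand = character()))
  do.call(rbind, out)
}

# Exact two-sample permutation test on the absolute mean difference,
# enumerating every relabelling (feasible for n <= 8 per group).
perm_t_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  obs <- abs(mean(a) - mean(b))
  splits <- utils::combn(length(pooled), na)
  stats <- apply(splits, 2, function(i)
    abs(mean(pooled[i]) - mean(pooled[-i])))
  mean(stats >= obs - 1e-12)
}

# One read table from sequences.
as_reads <- function(sequences, prefix = "r") {
  data.frame(id = sprintf("%s%03d", prefix, seq_along(sequences)),
             sequence = sequences, stringsAsFactors = FALSE)
}

default_ref <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_default_reference(seed = 1)
    cache
  }
})
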