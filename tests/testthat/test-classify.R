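test_that("trim_adapter cuts at the leftmost anchor match only", {
  adapter <- DEFAULT_ADAPTER_3P
  insert <- "ACGTACGTACGTACGTACGTAC"
  reads <- as_reads(c(
    paste0(insert, adapter),               # full adapter
    insert,                                # no adapter at all
    paste0(insert, substr(adapter, 1, 8),  # anchor occurs twice
           "AAAA", substr(adapter, 1, 8))))
  out <- trim_adapter(reads, adapter, min_overlap = 8)
  expect_equal(out$sequence, c(insert, insert, insert))
  # leftmost rule against an all-occurrence scan oracle
  s <- reads$sequence[3]
  anchor <- substr(adapter, 1, 8)
  occ <- which(vapply(1:(nchar(s) - 7),
                      function(i) substr(s, i, i + 7) == anchor,
                      logical(1)))
  expect_equal(nchar(out$sequence[3]), min(occ) - 1)
  expect_error(trim_adapter(reads, adapter, min_overlap = 0), "min_overlap")
  expect_error(trim_adapter(reads, "ACG", min_overlap = 8), "shorter")
})

test_that("length_filter keeps exactly the 18-30 nt window", {
  reads <- as_reads(vapply(10:40, function(n)
    paste(rep("A", n), collapse = ""), character(1)))
  kept <- length_filter(reads)
  expect_equal(nrow(kept), 13)
  expect_equal(range(nchar(kept$sequence)), c(18, 30))
  expect_equal(nrow(length_filter(reads[0, ])), 0)
  expect_error(length_filter(reads, 30, 18), "min_len")
})

test_that("map_reads places constructed reads on the right strand", {
  ref <- default_ref()
  unit <- ref$unit
  fwd <- substr(unit$sequence, 101, 122)  # unit[100:122), 0-based
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(fwd, "")[[1]]),
                                     collapse = ""))
  hits <- map_reads(as_reads(c(fwd, rc, "NNNNNNNNNNNNNNNNNNNNNN")),
                    unit, ref$decoys)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$target, rep(unit$name, 2))
  expect_equal(hits$start, c(100, 100))
  expect_equal(hits$end, c(122, 122))
  expect_setequal(hits$strand, c("+", "-"))
  expect_true(all(hits$end - hits$start == 22))
})

test_that("mapper agrees with the brute-force both-strand scan", {
  # random 2 kb reference split into two targets
  withr::with_seed(7, {
    t1 <- paste(sample(c("A", "C", "G", "T"), 1200, TRUE), collapse = "")
    t2 <- paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = "")
  })
  unit <- rdna_unit(t1, data.frame(name = CANON,
                                   start = c(0, 100, 400, 500, 550, 600, 1100),
                                   end = c(100, 400, 500, 550, 600, 1100, 1200)))
  decoys <- decoy_set(c("5S" = substr(t2, 1, 120), "mRNA_01" = t2))
  targets <- c(setNames(t1, unit$name), "5S" = substr(t2, 1, 120),
               "mRNA_01" = t2)
  withr::with_seed(8, {
    picks <- lapply(1:30, function(i) {
      tn <- sample(names(targets), 1)
      w <- sample(18:30, 1)
      s <- sample(nchar(targets[[tn]]) - w + 1, 1)
      frag <- substr(targets[[tn]], s, s + w - 1)
      if (runif(1) < 0.5)
        frag <- chartr("ACGT", "TGCA",
                       paste(rev(strsplit(frag, "")[[1]]), collapse = ""))
      frag
    })
    randoms <- replicate(10, paste(sample(c("A", "C", "G", "T"),
                                          sample(18:30, 1), TRUE),
                                   collapse = ""))
  })
  seqs <- c(unlist(picks), randoms)
  reads <- as_reads(seqs)
  got <- map_reads(reads, unit, decoys)
  want <- brute_map(seqs, targets)
  want$id <- reads$id[want$read]
  key <- function(d) sort(paste(d$id, d$target, d$start, d$end, d$strand))
  expect_equal(key(got), key(want))
})

test_that("classification follows the stated priority for every 2-hit pair", {
  ref <- default_ref()
  unit_name <- ref$unit$name
  mk <- function(target, strand)
    data.frame(id = "r001", target = target, start = 0L, end = 22L,
               strand = strand, stringsAsFactors = FALSE)
  classes <- list(risiRNA = mk(unit_name, "-"),
                  risiRNA_5S = mk("5S", "-"),
                  sense_rRNA = mk(unit_name, "+"),
                  sense_rRNA_5S = mk("5S", "+"),
                  sense_mRNA = mk("mRNA_01", "+"),
                  antisense_mRNA = mk("mRNA_01", "-"))
  expected <- c(risiRNA = "risiRNA", risiRNA_5S = "risiRNA",
                sense_rRNA = "sense_rRNA", sense_rRNA_5S = "sense_rRNA",
                sense_mRNA = "sense_mRNA",
                antisense_mRNA = "antisense_mRNA")
  rank <- c(risiRNA = 1, sense_rRNA = 2, sense_mRNA = 3,
            antisense_mRNA = 4)
  read <- as_reads(paste(rep("A", 22), collapse = ""))
  for (a in names(classes)) {
    # single hit
    got <- classify_reads(read, classes[[a]], ref$unit)
    expect_equal(got$category, unname(expected[a]))
    for (b in names(classes)) {
      two <- rbind(classes[[a]], classes[[b]])
      got2 <- classify_reads(read, two, ref$unit)
      win <- names(which.min(rank[c(expected[a], expected[b])]))
      expect_equal(got2$category, win,
                   label = sprintf("pair %s + %s", a, b))
    }
  }
  # empty hits -> unmapped
  none <- classify_reads(read, classes[[1]][0, ], ref$unit)
  expect_equal(none$category, "unmapped")
  expect_true(is.na(none$target))
})

test_that("multi-mapping reads count once via the sorted-first-hit rule", {
  ref <- default_ref()
  hits <- data.frame(id = "r001",
                     target = ref$unit$name,
                     start = c(500L, 100L), end = c(522L, 122L),
                     strand = "-", stringsAsFactors = FALSE)
  # classify_reads takes hits in map_reads order (sorted by start)
  hits <- hits[order(hits$start), ]
  got <- classify_reads(as_reads(paste(rep("A", 22), collapse = "")),
                        hits, ref$unit)
  expect_equal(nrow(got), 1)
  expect_equal(got$start, 100)
})

test_that("count_categories partitions every read exactly once", {
  ref <- default_ref()
  p <- preset_profile("disl-2", n_reads = 5000, seed = 21)
  sim <- simulate_library(p, ref$unit, ref$decoys)
  cl <- process_reads(sim$reads, ref$unit, ref$decoys, adapter = "")
  cc <- count_categories(cl)
  expect_equal(cc$risiRNA + cc$sense_rRNA + cc$sense_mRNA +
                 cc$antisense_mRNA + cc$unmapped, nrow(sim$reads))
  expect_equal(cc$total_mapped, cc$risiRNA + cc$sense_rRNA +
                 cc$sense_mRNA + cc$antisense_mRNA)
  # empty input
  cc0 <- count_categories(cl[0, ])
  expect_equal(cc0$total_mapped + cc0$unmapped, 0)
})

test_that("strand involution swaps sense and antisense categories", {
  ref <- default_ref()
  unit <- ref$unit
  rc1 <- function(s) chartr("ACGT", "TGCA",
                            paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  withr::with_seed(3, starts <- sample(0:(nchar(unit$sequence) - 22), 20))
  sense <- substring(unit$sequence, starts + 1, starts + 22)
  anti <- vapply(sense, rc1, character(1), USE.NAMES = FALSE)
  cs <- classify_reads(as_reads(sense),
                       map_reads(as_reads(sense), unit, ref$decoys), unit)
  ca <- classify_reads(as_reads(anti),
                       map_reads(as_reads(anti), unit, ref$decoys), unit)
  expect_true(all(cs$category == "sense_rRNA"))
  expect_true(all(ca$category == "risiRNA"))
  mseq <- substring(ref$decoys[["mRNA_01"]], 51, 72)
  cm <- process_reads(as_reads(c(mseq, rc1(mseq))), unit, ref$decoys,
                      adapter = "")
  expect_equal(cm$category, c("sense_mRNA", "antisense_mRNA"))
})

test_that("noise-free simulate -> classify recovers every truth category", {
  ref <- default_ref()
  p <- preset_profile("dis-3", n_reads = 10000, seed = 17)
  sim <- simulate_library(p, ref$unit, ref$decoys)
  cl <- process_reads(attach_adapters(sim$reads), ref$unit, ref$decoys)
  truth <- sim$truth$category[match(cl$id, sim$truth$id)]
  expect_equal(mean(cl$category == truth), 1)
  # and the recovered counts equal the truth marginals on the survivors
  cc <- count_categories(cl)
  for (k in names(p$fractions))
    expect_equal(cc[[k]], sum(truth == k))
})
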