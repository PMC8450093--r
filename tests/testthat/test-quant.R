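mock_counts <- function(risi, srrna, smrna, anti, unmapped = 0) {
  cl <- data.frame(
    category = rep(c("risiRNA", "sense_rRNA", "sense_mRNA",
                     "antisense_mRNA", "unmapped"),
                   c(risi, srrna, smrna, anti, unmapped)))
  count_categories(cl)
}

test_that("normalization_factor implements the stated subtraction", {
  cc <- mock_counts(150000, 300000, 500000, 50000)
  expect_equal(normalization_factor(cc), 200000)
  # with no degradation background the factor is everything mapped
  cc2 <- mock_counts(1000, 0, 0, 500)
  expect_equal(normalization_factor(cc2), 1500)
  expect_error(normalization_factor(mock_counts(0, 10, 10, 0, 5)),
               "empty normalization basis")
})

test_that("factor == risiRNA + antisense_mRNA on random counts", {
  withr::with_seed(13, {
    for (i in 1:20) {
      x <- sample(0:5000, 4)
      if (x[1] + x[4] == 0) x[1] <- 1
      cc <- mock_counts(x[1], x[2], x[3], x[4], sample(0:1000, 1))
      expect_equal(normalization_factor(cc), x[1] + x[4])
    }
  })
})

test_that("risirna_rpm is the documented ratio and scale-invariant", {
  expect_equal(risirna_rpm(mock_counts(200000, 0, 0, 0)), 1e6)
  cc <- mock_counts(1000, 300000, 500000, 199000)
  expect_equal(risirna_rpm(cc), 1e6 * 1000 / 200000)
  cc2 <- mock_counts(2000, 600000, 1000000, 398000)  # doubled library
  expect_equal(risirna_rpm(cc2), risirna_rpm(cc))
})

test_that("region_proportions follows the midpoint rule", {
  ref <- default_ref()
  unit <- ref$unit
  r26 <- unit$regions[unit$regions$name == "26S", ]
  its1 <- unit$regions[unit$regions$name == "ITS1", ]
  mid26 <- (r26$start + r26$end) %/% 2
  mid_its1 <- (its1$start + its1$end) %/% 2
  aln <- data.frame(start = c(rep(mid26, 4), mid_its1),
                    end = c(rep(mid26 + 22, 4), mid_its1 + 22),
                    strand = "-")
  rp <- region_proportions(aln, unit)
  expect_equal(rp[["26S"]], 0.8)
  expect_equal(rp[["ITS1"]], 0.2)
  expect_equal(sum(rp), 1)

  # read straddling the 18S/ITS1 boundary, midpoint in ITS1
  b <- its1$start
  straddle <- data.frame(start = b - 10, end = b + 12, strand = "-")
  # midpoint = floor((start+end-1)/2) = b (first base of ITS1)
  expect_equal(region_proportions(straddle, unit)[["ITS1"]], 1)
  # one base earlier the midpoint stays in 18S
  straddle2 <- data.frame(start = b - 11, end = b + 11, strand = "-")
  expect_equal(region_proportions(straddle2, unit)[["18S"]], 1)

  expect_error(region_proportions(transform(aln, strand = "+"), unit),
               "antisense")
  empty <- region_proportions(aln[0, ], unit)
  expect_true(attr(empty, "undefined"))
  expect_equal(sum(empty), 0)
})

test_that("simulated disl-2 library recovers its programmed region weights", {
  ref <- default_ref()
  p <- preset_profile("disl-2", n_reads = 50000, seed = 31)
  sim <- simulate_library(p, ref$unit, ref$decoys)
  cl <- process_reads(attach_adapters(sim$reads), ref$unit, ref$decoys)
  risi <- cl[cl$category == "risiRNA" & cl$target == ref$unit$name &
               !is.na(cl$target), ]
  rp <- region_proportions(risi, ref$unit)
  n <- nrow(risi)
  for (r in CANON) {
    w <- p$region_weights[[r]]
    expect_lt(abs(rp[[r]] - w), 3 * sqrt(max(w * (1 - w), 1e-6) / n) + 1e-3)
  }
})

test_that("length_histogram conserves counts with the mode at 22", {
  cl22 <- data.frame(category = "risiRNA", length = rep(22L, 7),
                     sequence = "x")
  h <- length_histogram(cl22)
  expect_equal(unname(h[["22"]]), 7)
  expect_equal(sum(h), 7)

  ref <- default_ref()
  p <- preset_profile("wild-type", n_reads = 30000, seed = 41)
  sim <- simulate_library(p, ref$unit, ref$decoys)
  cl <- process_reads(attach_adapters(sim$reads), ref$unit, ref$decoys)
  h2 <- length_histogram(cl)
  expect_equal(sum(h2), sum(cl$category == "risiRNA"))
  expect_equal(names(h2)[which.max(h2)], "22")
})

test_that("first_nt_preference sums to 1, excludes N, and matches the reference complement", {
  allg <- data.frame(category = "risiRNA",
                     sequence = c("GAT", "GGT", "GCC"))
  expect_equal(first_nt_preference(allg)[["G"]], 1)
  withn <- data.frame(category = "risiRNA",
                      sequence = c("NAA", "GTT", "ATT"))
  fn <- first_nt_preference(withn)
  expect_equal(sum(fn), 1)
  expect_equal(fn[["G"]], 0.5)  # N read out of the denominator

  ref <- default_ref()
  p <- preset_profile("rrp-8", n_reads = 20000, seed = 51)
  sim <- simulate_library(p, ref$unit, ref$decoys)
  cl <- process_reads(attach_adapters(sim$reads), ref$unit, ref$decoys)
  risi <- cl[cl$category == "risiRNA" & cl$target == ref$unit$name, ]
  # G fraction recovers the programmed bias
  fn2 <- first_nt_preference(risi)
  expect_lt(abs(fn2[["G"]] - 0.75), 3 * sqrt(0.75 * 0.25 / nrow(risi)))
  # the 5' base as sequenced equals the complement of the plus-strand
  # base under the alignment's 3' end
  ref_base <- substr(rep(ref$unit$sequence, nrow(risi)),
                     risi$end, risi$end)  # 1-based index of end-1
  expect_equal(substr(risi$sequence, 1, 1),
               chartr("ACGT", "TGCA", ref_base))
})

test_that("coverage_track conserves read bases and exports valid bedGraph", {
  ref <- default_ref()
  unit <- ref$unit
  one <- data.frame(start = 100L, end = 122L, strand = "-")
  cov <- coverage_track(one, unit)
  expect_length(cov, nchar(unit$sequence))
  expect_equal(sum(cov), 22)
  expect_equal(unique(cov[101:122]), 1)
  two <- rbind(one, one)
  expect_equal(sum(coverage_track(two, unit)), 44)

  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(coverage_track(two, unit), unit, f)
  bg <- read.table(f, sep = "\t")
  expect_equal(sum((bg$V3 - bg$V2) * bg$V4), 44)
  expect_equal(bg$V2[1], 0)
  expect_equal(bg$V3[nrow(bg)], nchar(unit$sequence))
  # depth-2 interval is exactly [100, 122)
  expect_equal(bg[bg$V4 == 2, 2:3], data.frame(V2 = 100, V3 = 122),
               ignore_attr = TRUE)

  # fixed-length library: total coverage = 22 * number of reads
  p <- preset_profile("disl-2", n_reads = 3000, seed = 61)
  p$length_dist <- c("22" = 1)
  sim <- simulate_library(p, ref$unit, ref$decoys)
  cl <- process_reads(sim$reads, ref$unit, ref$decoys, adapter = "")
  risi <- cl[cl$category == "risiRNA" & cl$target == unit$name, ]
  expect_equal(sum(coverage_track(risi, unit)), 22 * nrow(risi))
})

test_that("risirna_profile bundles consistent quantities and writes JSON", {
  ref <- default_ref()
  p <- preset_profile("disl-2", n_reads = 8000, seed = 71)
  sim <- simulate_library(p, ref$unit, ref$decoys)
  cl <- process_reads(attach_adapters(sim$reads), ref$unit, ref$decoys)
  prof <- risirna_profile(cl, ref$unit)
  expect_equal(sum(prof$region_proportions), 1)
  expect_equal(sum(prof$first_nt), 1)
  expect_equal(sum(prof$length_hist), prof$counts$risiRNA)
  risi <- cl[cl$category == "risiRNA" & cl$target == ref$unit$name, ]
  expect_equal(sum(prof$coverage), sum(risi$length))
  expect_equal(prof$norm_factor,
               prof$counts$risiRNA + prof$counts$antisense_mRNA)
  f <- withr::local_tempfile(fileext = ".json")
  write_profile_json(prof, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$norm_factor, prof$norm_factor)
  expect_equal(j$region_proportions$`26S`,
               unname(prof$region_proportions[["26S"]]))
})
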