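#' End-to-end pipeline runs
#'
#' `run_profile()` executes the full small-RNA analysis — reference,
#' simulation (or FASTQ input), adapter trim, 18-30 nt clean-read
#' filter, exact-match mapping, classification, profiling — and writes
#' the profile JSON, a classification TSV, a bedGraph coverage track and
#' a run manifest recording parameters, package version and output
#' checksums, so any run is reproducible from its manifest.
#'
#' @param config A list (or path to a JSON file) with elements:
#'   `outdir` (required); `seed` (default 1); either `fastq` plus
#'   `reference_fasta`/`reference_bed`/`decoy_fasta`, or `preset` (a
#'   [preset_profile()] name) with `n_reads` to simulate the input;
#'   optional `adapter`, `min_overlap`, `min_len`, `max_len`.
#' @return Invisibly, a list with the `risirna_profile` and the output
#'   file paths.
#' @export
run_profile <- function(config) {
  cfg <- load_config(config)
  if (is.null(cfg$outdir)) stop("config must give an output directory")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)

  if (!is.null(cfg$reference_fasta)) {
    for (f in c(cfg$reference_fasta, cfg$reference_bed, cfg$decoy_fasta))
      if (!file.exists(f)) stop("missing input file: ", f)
    unit <- load_reference(cfg$reference_fasta, cfg$reference_bed)
    decoys <- load_decoys(cfg$decoy_fasta)
  } else {
    ref <- build_default_reference(seed = seed)
    unit <- ref$unit; decoys <- ref$decoys
  }

  if (!is.null(cfg$fastq)) {
    if (!file.exists(cfg$fastq)) stop("missing input file: ", cfg$fastq)
    reads <- read_fastq(cfg$fastq)
    truth <- NULL
  } else {
    profile_cfg <- preset_profile(cfg$preset %||% "wild-type",
                                  n_reads = cfg$n_reads, seed = seed)
    sim <- simulate_library(profile_cfg, unit, decoys)
    reads <- attach_adapters(sim$reads,
                             cfg$adapter %||% DEFAULT_ADAPTER_3P)
    truth <- sim$truth
  }

  classified <- process_reads(
    reads, unit, decoys,
    adapter = cfg$adapter %||% DEFAULT_ADAPTER_3P,
    min_overlap = as.integer(cfg$min_overlap %||% 8L),
    min_len = as.integer(cfg$min_len %||% 18L),
    max_len = as.integer(cfg$max_len %||% 30L))
  prof <- risirna_profile(classified, unit)

  paths <- c(
    profile = file.path(cfg$outdir, "profile.json"),
    classified = file.path(cfg$outdir, "classified.tsv"),
    coverage = file.path(cfg$outdir, "coverage.bedGraph"),
    manifest = file.path(cfg$outdir, "manifest.json"))
  write_profile_json(prof, paths[["profile"]])
  write.table(classified[, c("id", "category", "target", "start", "end",
                             "strand")],
              paths[["classified"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_bedgraph(prof$coverage, unit, paths[["coverage"]])
  if (!is.null(truth))
    write.csv(truth, file.path(cfg$outdir, "truth.csv"),
              row.names = FALSE, quote = FALSE)
  write_manifest(paths[["manifest"]], "profile", cfg, seed,
                 paths[names(paths) != "manifest"])
  invisible(list(profile = prof, paths = paths))
}

#' @rdname run_profile
#' @details `run_chip()` turns a Ct table into per-replicate percent
#'   input, replicate summaries and the comparisons named in the config
#'   (fold change plus two-tailed Student's t-test), writing TSVs and a
#'   manifest. Config elements: `outdir`; either `ct_csv` (path) or
#'   `design` (a [qpcr_design()] specification with `enrichment` rows,
#'   `input_fraction`, `replicates`, `ct_noise_sd`) simulated under
#'   `seed`; optional `comparisons` rows for [summarize_enrichment()].
#' @export
run_chip <- function(config) {
  cfg <- load_config(config)
  if (is.null(cfg$outdir)) stop("config must give an output directory")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)

  if (!is.null(cfg$ct_csv)) {
    if (!file.exists(cfg$ct_csv)) stop("missing input file: ", cfg$ct_csv)
    ct <- read_ct_table(cfg$ct_csv)
  } else if (!is.null(cfg$design)) {
    d <- cfg$design
    design <- qpcr_design(as.data.frame(d$enrichment),
                          input_fraction = d$input_fraction %||% 0.01,
                          replicates = d$replicates %||% 4L,
                          ct_noise_sd = d$ct_noise_sd %||% 0.15,
                          seed = seed)
    ct <- simulate_qpcr(design)
  } else stop("config must give ct_csv or a design to simulate")
  if (nrow(ct) == 0L) stop("empty Ct table")

  enr <- percent_input_table(ct)
  cmp <- if (!is.null(cfg$comparisons)) as.data.frame(cfg$comparisons)
  res <- summarize_enrichment(enr, cmp)

  paths <- c(enrichment = file.path(cfg$outdir, "percent_input.tsv"),
             summary = file.path(cfg$outdir, "summary.tsv"),
             manifest = file.path(cfg$outdir, "manifest.json"))
  write.table(enr, paths[["enrichment"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(res$summary, paths[["summary"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(res$comparisons)) {
    paths[["comparisons"]] <- file.path(cfg$outdir, "comparisons.tsv")
    write.table(res$comparisons, paths[["comparisons"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write_manifest(paths[["manifest"]], "chip", cfg, seed,
                 paths[names(paths) != "manifest"])
  invisible(list(results = res, enrichment = enr, paths = paths))
}

#' @rdname run_profile
#' @details `run_simulate()` writes a simulated FASTQ (with adapters),
#'   its truth table and the reference FASTA/BED files. Config elements:
#'   `outdir`, `preset`, `n_reads`, `seed`, optional `adapter`.
#' @export
run_simulate <- function(config) {
  cfg <- load_config(config)
  if (is.null(cfg$outdir)) stop("config must give an output directory")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)
  ref <- build_default_reference(seed = seed)
  profile_cfg <- preset_profile(cfg$preset %||% "wild-type",
                                n_reads = cfg$n_reads, seed = seed)
  sim <- simulate_library(profile_cfg, ref$unit, ref$decoys)
  withad <- attach_adapters(sim$reads, cfg$adapter %||% DEFAULT_ADAPTER_3P)
  paths <- c(fastq = file.path(cfg$outdir, "reads.fastq"),
             truth = file.path(cfg$outdir, "truth.csv"),
             fasta = file.path(cfg$outdir, "reference.fasta"),
             bed = file.path(cfg$outdir, "reference.bed"),
             decoys = file.path(cfg$outdir, "decoys.fasta"),
             manifest = file.path(cfg$outdir, "manifest.json"))
  write_fastq(withad, paths[["fastq"]])
  write.csv(sim$truth, paths[["truth"]], row.names = FALSE, quote = FALSE)
  write_reference(ref$unit, paths[["fasta"]], paths[["bed"]])
  write_decoys(ref$decoys, paths[["decoys"]])
  write_manifest(paths[["manifest"]], "simulate", cfg, seed,
                 paths[names(paths) != "manifest"])
  invisible(list(sim = sim, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("missing config file: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  config
}

write_manifest <- function(path, subcommand, cfg, seed, outputs) {
  outputs <- unlist(outputs)
  manifest <- list(
    tool = "risiRNAkit",
    version = as.character(packageVersion("risiRNAkit")),
    subcommand = subcommand,
    seed = seed,
    config = cfg[!vapply(cfg, is.null, logical(1))],
    outputs = as.list(setNames(unname(md5sum(outputs)), names(outputs))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Command-line entry point
#'
#' Subcommand interface: `simulate`, `profile` and `chip`, each taking
#' `--config <json>` plus optional overrides (`--outdir`, `--seed`,
#' `--preset`, `--n-reads`, `--fastq`, `--ct-csv`, `--adapter`,
#' `--min-len`, `--max-len`, `--min-overlap`). Progress is logged to
#' stderr. Typical use from a shell:
#' \preformatted{Rscript -e 'risiRNAkit::risi_main()' profile \
#'     --preset disl-2 --n-reads 100000 --outdir out --seed 1}
#'
#' @param args Character vector of arguments (defaults to the command
#'   line).
#' @return Invisibly, the subcommand's result.
#' @export
risi_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: risi_main <simulate|profile|chip> [--config file.json] ",
         "[--key value ...]")
  sub <- args[1L]
  if (!sub %in% c("simulate", "profile", "chip"))
    stop("unknown subcommand '", sub, "'")
  flags <- args[-1L]
  cfg <- list()
  i <- 1L
  while (i <= length(flags)) {
    key <- flags[i]
    if (!startsWith(key, "--")) stop("expected a --flag, got '", key, "'")
    if (i + 1L > length(flags)) stop("flag ", key, " needs a value")
    val <- flags[i + 1L]
    key <- gsub("-", "_", substring(key, 3L))
    if (key == "config") {
      cfg <- utils::modifyList(load_config(val), cfg)
    } else {
      num <- suppressWarnings(as.numeric(val))
      cfg[[key]] <- if (!is.na(num)) num else val
    }
    i <- i + 2L
  }
  message(sprintf("[risiRNAkit] %s: seed=%s outdir=%s", sub,
                  cfg$seed %||% 1, cfg$outdir %||% "?"))
  res <- switch(sub,
                simulate = run_simulate(cfg),
                profile = run_profile(cfg),
                chip = run_chip(cfg))
  message(sprintf("[risiRNAkit] %s: done", sub))
  invisible(res)
}
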