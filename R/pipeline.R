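#' Pipeline configuration
#'
#' Bundles inputs and thresholds for [run_pipeline()]. Input is either a
#' FASTQ path (`fastq`, plus an optional `control_fastq` for two-sample
#' fold-change mode) or a [sim_config()] to simulate the sample library.
#'
#' @param fastq Sample FASTQ path, or `NULL` when simulating.
#' @param control_fastq Optional control (e.g. non-transfected) FASTQ path.
#' @param sim Optional [sim_config()] used when `fastq` is `NULL`.
#' @param guides Mimic reference tibble or guides FASTA path.
#' @param endogenous Endogenous tibble or FASTA path.
#' @param contaminants Contaminant tibble or FASTA path (`NULL`: none).
#' @param out_dir Output directory (created; writes are atomic).
#' @param adapter3,min_overlap,max_error_rate,min_len,max_len,min_frac
#'   Preprocessing thresholds (see [preprocess_fastq()]).
#' @param params Classifier parameters ([classify_params()]).
#' @param fc_window Length-window bounds for [hmw_fold_change()].
#' @param seed Integer seed recorded in the manifest (drives simulation).
#' @return A `pipeline_config` list, validated.
#' @export
pipeline_config <- function(fastq = NULL, control_fastq = NULL, sim = NULL,
                            guides = mir17_92_guides(),
                            endogenous = example_endogenous(),
                            contaminants = NULL,
                            out_dir = tempfile("mimicqc_run_"),
                            adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                            min_overlap = 3, max_error_rate = 0.1,
                            min_len = 15, max_len = 80, min_frac = 0.001,
                            params = classify_params(),
                            fc_window = c(30, 60), seed = 1L) {
  as_tbl <- function(x, reader) {
    if (is.null(x) || is.data.frame(x)) return(x)
    if (!file.exists(x)) stop("referenced path does not exist: ", x)
    reader(x)
  }
  guides <- as_tbl(guides, read_guides_fasta)
  endogenous <- as_tbl(endogenous, read_fasta_tbl)
  contaminants <- as_tbl(contaminants, read_fasta_tbl)
  if (is.null(fastq) && is.null(sim))
    stop("either a FASTQ path or a sim_config is required")
  for (p in c(fastq, control_fastq)) {
    if (!file.exists(p)) stop("referenced path does not exist: ", p)
  }
  stopifnot(min_len >= 1, max_len >= min_len,
            is.null(min_frac) || (min_frac >= 0 && min_frac < 1))
  cfg <- list(fastq = fastq, control_fastq = control_fastq, sim = sim,
              guides = guides, endogenous = endogenous,
              contaminants = contaminants, out_dir = out_dir,
              adapter3 = adapter3, min_overlap = min_overlap,
              max_error_rate = max_error_rate, min_len = min_len,
              max_len = max_len, min_frac = min_frac, params = params,
              fc_window = fc_window, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_stage <- function(cfg, fastq) {
  tab <- preprocess_fastq(fastq, adapter3 = cfg$adapter3,
                          min_overlap = cfg$min_overlap,
                          max_error_rate = cfg$max_error_rate,
                          min_len = cfg$min_len, max_len = cfg$max_len,
                          contaminants = cfg$contaminants,
                          min_frac = cfg$min_frac)
  classified <- classify_inserts(tab, cfg$guides, cfg$endogenous, cfg$params)
  list(table = tab, classified = classified, stats = preprocess_stats(tab))
}

#' Run the full artifact-detection pipeline
#'
#' Simulate (or read) -> preprocess -> classify -> histogram (-> fold change
#' in two-sample mode), writing TSV outputs, a JSON run manifest (parameters,
#' seed, package version, input checksums, per-stage read conservation) and a
#' plain-text summary. Outputs are written to a temporary directory and moved
#' into place on success, so a failed run leaves no partial results.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `classified`, `histogram`, `fold_change`
#'   (NULL in single-sample mode), `stats`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  stage_dir <- tempfile("mimicqc_stage_")
  dir.create(stage_dir, recursive = TRUE)
  on.exit(unlink(stage_dir, recursive = TRUE), add = TRUE)

  inputs <- list()
  if (!is.null(config$fastq)) {
    sample_fastq <- config$fastq
    inputs$fastq <- config$fastq
  } else {
    say("simulating library (seed ", config$sim$rng_seed, ")")
    sim <- simulate_library(config$sim)
    sample_fastq <- file.path(stage_dir, "simulated.fastq")
    write_simulated_library(sim, sample_fastq,
                            file.path(stage_dir, "truth.tsv"))
    inputs$simulated <- TRUE
  }

  say("preprocessing sample")
  s <- pipeline_stage(config, sample_fastq)
  say("  conservation: in=", s$stats$reads_in,
      " retained=", s$stats$retained,
      " short=", s$stats$discarded_short,
      " long=", s$stats$discarded_long,
      " contaminant=", s$stats$contaminant)
  write_classification(s$classified,
                       file.path(stage_dir, "classification.tsv"))
  hist <- length_histogram(s$classified)
  write.table(hist, file.path(stage_dir, "length_histogram.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  fc <- NULL
  ctrl_stats <- NULL
  if (!is.null(config$control_fastq)) {
    say("preprocessing control")
    ctl <- pipeline_stage(config, config$control_fastq)
    ctrl_stats <- ctl$stats
    fc <- hmw_fold_change(s$classified, ctl$classified,
                          lo = config$fc_window[1], hi = config$fc_window[2])
    write.table(fc$fold_change, file.path(stage_dir, "fold_change.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(fc$composition, file.path(stage_dir, "hmw_composition.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    say("single-sample mode: fold-change output skipped")
  }

  checksums <- lapply(inputs[vapply(inputs, is.character, logical(1))],
                      function(p) unname(tools::md5sum(p)))
  manifest <- list(
    package = "mimicqc",
    version = as.character(utils::packageVersion("mimicqc")),
    seed = config$seed,
    parameters = list(adapter3 = config$adapter3,
                      min_overlap = config$min_overlap,
                      max_error_rate = config$max_error_rate,
                      min_len = config$min_len, max_len = config$max_len,
                      min_frac = config$min_frac,
                      classifier = config$params,
                      fc_window = config$fc_window),
    sim = if (!is.null(config$sim))
      config$sim[c("n_reads", "read_length", "per_base_error", "polya_min",
                   "rng_seed")],
    input_checksums = checksums,
    sample_stats = as.list(s$stats),
    control_stats = if (!is.null(ctrl_stats)) as.list(ctrl_stats)
  )
  jsonlite::write_json(manifest, file.path(stage_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  summary_lines <- c(
    "mimicqc run summary",
    sprintf("reads in: %d; retained: %d (short %d, long %d, contaminant %d)",
            s$stats$reads_in, s$stats$retained, s$stats$discarded_short,
            s$stats$discarded_long, s$stats$contaminant),
    sprintf("enriched species: %d", nrow(s$classified)),
    paste(utils::capture.output(print(
      dplyr::count(s$classified, .data$class, wt = .data$count,
                   sort = TRUE), n = 20)), collapse = "\n"))
  writeLines(summary_lines, file.path(stage_dir, "summary.txt"))

  # atomic move into place
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  for (f in list.files(stage_dir, full.names = TRUE)) {
    ok <- file.copy(f, file.path(config$out_dir, basename(f)),
                    overwrite = TRUE)
    if (!ok) stop("failed to move output ", basename(f))
  }
  say("outputs in ", config$out_dir)
  invisible(list(classified = s$classified, histogram = hist,
                 fold_change = fc, stats = s$stats, manifest = manifest,
                 out_dir = config$out_dir))
}
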