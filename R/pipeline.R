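# Pipeline orchestration: simulate -> qc -> profile -> report, each stage
# writing its outputs plus a run manifest so results are reproducible.

write_manifest <- function(out_dir, subcommand, config, paths, seed,
                           started) {
  manifest <- list(
    subcommand = subcommand,
    config = if (inherits(config, "sim_config")) {
      x <- unclass(config)
      x$tn5_pwm <- NULL  # matrices live in the config file itself
      x
    } else config,
    paths = paths,
    seed = seed,
    package_version = as.character(utils::packageVersion("chipexosim")),
    wall_time_s = round(as.numeric(Sys.time()) - started, 3)
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Simulate a library and write all outputs
#'
#' Runs [simulate_library()] over a genome generated (or supplied) for the
#' configured protocol version and writes: genome FASTA, site BED6, tag
#' TSV, per-read BED6, paired FASTQ, truth TSV, the effective config, and
#' a run manifest. Deterministic per seed: re-running with the same
#' arguments reproduces every file byte-identically.
#'
#' @param config A [sim_config()] or path to a YAML/JSON config file.
#' @param out_dir Output directory (created if needed).
#' @param genome,sites Optional pre-built genome string and site
#'   data.frame; generated from `genome_length` / `n_sites` otherwise.
#' @param genome_length,n_sites,motif Synthetic-genome parameters used when
#'   `genome` is NULL.
#' @param seed Overrides `config$seed` when non-NULL.
#' @return Invisibly, the [simulate_library()] result with `$paths` added.
#' @export
run_simulate <- function(config, out_dir, genome = NULL, sites = NULL,
                         genome_length = 1e6, n_sites = 200L,
                         motif = default_motif(), seed = NULL) {
  started <- as.numeric(Sys.time())
  if (is.character(config)) config <- read_sim_config(config)
  validate_sim_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(genome)) {
    genome <- generate_genome(genome_length,
                              seed = derive_seed(config$seed, "genome"))
    planted <- plant_motifs(genome, motif, n_sites,
                            min_spacing = max(1000L, 2L * 500L),
                            seed = derive_seed(config$seed, "sites"))
    genome <- planted$sequence
    sites <- planted$sites
  }
  if (is.null(sites)) sites <- empty_sites()
  lib <- simulate_library(genome, sites, config)
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    sites = file.path(out_dir, "sites.bed"),
    tags = file.path(out_dir, "tags.tsv"),
    reads_bed = file.path(out_dir, "tags_r1.bed"),
    fastq_prefix = file.path(out_dir, "reads"),
    truth = file.path(out_dir, "truth.tsv"),
    config = file.path(out_dir, "config.yaml")
  )
  write_fasta(genome, paths$genome)
  if (nrow(sites)) write_sites_bed(sites, paths$sites)
  write_tags_tsv(lib$tags, paths$tags)
  write_reads_bed(lib$tags, paths$reads_bed, "read1", config$read_len)
  write_fastq_pair(lib$tags, paths$fastq_prefix)
  write_truth_tsv(lib$truth, paths$truth)
  write_sim_config(config, paths$config)
  write_manifest(out_dir, "simulate", config, paths, config$seed, started)
  lib$paths <- paths
  lib$sites <- sites
  invisible(lib)
}

#' QC report for a library
#'
#' Dedupe counts and duplicate rate, insert-size mode +/- SD, per-read-end
#' bias calls, and (for ChIP-nexus input) barcode QC. Written as JSON and
#' as a plain-text table when `out_dir` is given.
#'
#' @param tags A [tag_set()] or path to a tag TSV.
#' @param out_dir Optional output directory.
#' @param background Background base composition for bias calling.
#' @param n_positions Bias/barcode profile window.
#' @param version Protocol version (defaults to the TagSet metadata).
#' @return A `qc_report` list.
#' @export
run_qc <- function(tags, out_dir = NULL,
                   background = default_base_probs(), n_positions = 15L,
                   version = NULL) {
  started <- as.numeric(Sys.time())
  if (is.character(tags)) tags <- read_tags_tsv(tags)
  version <- version %||% tags$metadata$version %||% "unknown"
  deduped <- dedupe(tags, "sequence")
  report <- list(
    version = version,
    n_input = length(tags),
    n_after_dedupe = length(deduped),
    duplicate_rate = duplicate_rate(tags, deduped)
  )
  ins <- insert_sizes(deduped)
  ms <- insert_mode_sd(ins)
  report$insert_mode <- unname(ms["mode"])
  report$insert_sd <- unname(ms["sd"])
  r <- deduped$records
  bias1 <- call_bias(nt_freq(r$r1_seq, n_positions), background)
  bias2 <- call_bias(nt_freq(r$r2_seq, n_positions), background)
  report$bias_read1 <- list(iupac = bias1$iupac,
                            n_flagged = bias1$n_flagged_positions)
  report$bias_read2 <- list(iupac = bias2$iupac,
                            n_flagged = bias2$n_flagged_positions)
  if (identical(version, "nexus")) {
    bq <- barcode_qc(r$r1_seq, n_positions)
    report$barcode <- list(n_pass = bq$n_pass, n_fail = bq$n_fail,
                           fail_static_presence =
                             as.list(bq$fail_static_presence))
  }
  class(report) <- "qc_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "qc_report.txt"))
    write_manifest(out_dir, "qc", NULL,
                   list(report = file.path(out_dir, "qc_report.json")),
                   NA, started)
  }
  report
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report —", x$version, "\n")
  cat(sprintf("  records: %d input, %d after dedupe (duplicate rate %.3f)\n",
              x$n_input, x$n_after_dedupe, x$duplicate_rate))
  cat(sprintf("  insert size: mode %d bp, sd %.1f bp\n", x$insert_mode,
              x$insert_sd))
  cat(sprintf("  Read_1 5' bias: %d position(s) [%s]\n",
              x$bias_read1$n_flagged, x$bias_read1$iupac))
  cat(sprintf("  Read_2 5' bias: %d position(s) [%s]\n",
              x$bias_read2$n_flagged, x$bias_read2$iupac))
  if (!is.null(x$barcode)) {
    cat(sprintf("  barcode filter: %d pass, %d fail\n", x$barcode$n_pass,
                x$barcode$n_fail))
  }
  invisible(x)
}

#' Motif-anchored profiling of one or more libraries
#'
#' Builds strand-separated matrices around the sites for every input
#' TagSet, applies one linked row order to all of them, and computes
#' composites and the comparison metrics (peak offsets, shoulder fraction,
#' strand segregation). With no tags in any window the metrics are
#' reported absent (with a warning), not an error.
#'
#' @param tag_sets A [tag_set()], list of them, or character vector of tag
#'   TSV paths (names become dataset labels).
#' @param sites Site data.frame or BED6 path.
#' @param window Profile half-width (bp).
#' @param sort `"reference"` or `"average_rank"`.
#' @param reference_index Reference dataset for `sort = "reference"`.
#' @param core,outer Shoulder-fraction half-widths (bp).
#' @param out_dir Optional output directory for TSV matrices, composites
#'   and a metrics JSON.
#' @return A `profile_run` list: `matrices`, `composites`, `metrics`
#'   (per-dataset list), `row_order`.
#' @export
run_profile <- function(tag_sets, sites, window = 500L,
                        sort = c("reference", "average_rank"),
                        reference_index = 1L, core = 50L, outer = 500L,
                        out_dir = NULL) {
  started <- as.numeric(Sys.time())
  sort <- match.arg(sort)
  if (is.character(sites)) sites <- read_sites_bed(sites)
  if (inherits(tag_sets, "tag_set")) tag_sets <- list(tag_sets)
  if (is.character(tag_sets)) {
    paths <- tag_sets
    tag_sets <- lapply(paths, read_tags_tsv)
    if (is.null(names(paths))) {
      names(tag_sets) <- sub("\\.tsv$", "", basename(paths))
    } else names(tag_sets) <- names(paths)
  }
  if (is.null(names(tag_sets))) {
    names(tag_sets) <- paste0("dataset", seq_along(tag_sets))
  }
  matrices <- lapply(tag_sets, function(ts) {
    anchor_matrix(five_prime_ends(ts, "read1"), sites, window)
  })
  ord <- sort_rows(matrices, sort, reference_index)
  matrices <- lapply(matrices, apply_row_order, order = ord)
  composites <- lapply(matrices, composite)
  metrics <- lapply(names(matrices), function(nm) {
    m <- matrices[[nm]]
    total <- sum(m$counts_same) + sum(m$counts_opposite)
    if (total == 0L) {
      warning("no tags within the profile window for ", nm)
      return(list(dataset = nm, n_in_window = 0L))
    }
    pk <- peak_offsets(composites[[nm]])
    list(dataset = nm, n_in_window = total,
         peak_same = unname(pk["same"]),
         peak_opposite = unname(pk["opposite"]),
         shoulder_fraction = if (m$window >= outer)
           shoulder_fraction(m, core, outer) else NA_real_,
         strand_segregation =
           if (sum(m$counts_same) > 0 && sum(m$counts_opposite) > 0)
             strand_segregation_score(m) else NA_real_)
  })
  names(metrics) <- names(matrices)
  out <- list(matrices = matrices, composites = composites,
              metrics = metrics, row_order = ord)
  class(out) <- "profile_run"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(matrices)) {
      write_matrix_tsv(matrices[[nm]], file.path(out_dir, nm))
      write_composite_tsv(composites[[nm]],
                          file.path(out_dir, paste0(nm, "_composite.tsv")))
    }
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_manifest(out_dir, "profile", NULL,
                   list(metrics = file.path(out_dir, "metrics.json")),
                   NA, started)
  }
  out
}

#' Aggregate per-version metrics into one comparison table
#'
#' @param profile_run A [run_profile()] result, or a list of metrics
#'   lists.
#' @param qc_reports Optional named list of [run_qc()] reports to merge.
#' @return data.frame, one row per dataset.
#' @export
run_report <- function(profile_run, qc_reports = NULL) {
  metrics <- if (inherits(profile_run, "profile_run"))
    profile_run$metrics else profile_run
  rows <- lapply(metrics, function(m) {
    data.frame(dataset = m$dataset, n_in_window = m$n_in_window,
               peak_same = m$peak_same %||% NA_integer_,
               peak_opposite = m$peak_opposite %||% NA_integer_,
               shoulder_fraction = m$shoulder_fraction %||% NA_real_,
               strand_segregation = m$strand_segregation %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(qc_reports)) {
    qc <- do.call(rbind, lapply(names(qc_reports), function(nm) {
      q <- qc_reports[[nm]]
      data.frame(dataset = nm, duplicate_rate = q$duplicate_rate,
                 insert_mode = q$insert_mode, insert_sd = q$insert_sd,
                 bias_read1 = q$bias_read1$n_flagged,
                 bias_read2 = q$bias_read2$n_flagged,
                 stringsAsFactors = FALSE)
    }))
    out <- merge(out, qc, by = "dataset", all.x = TRUE, sort = FALSE)
  }
  out
}
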