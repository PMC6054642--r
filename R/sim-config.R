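# Simulator configuration: one validated record holding every protocol
# parameter, with version-aware defaults.

PROTOCOL_VERSIONS <- c("seq", "mentation", "exo1.1", "exo3.1", "exo4.0",
                       "exo4.1", "exo5.0", "nexus")

TAGMENTED_VERSIONS <- c("mentation", "exo3.1")
EXO_VERSIONS <- c("exo1.1", "exo3.1", "exo4.0", "exo4.1", "exo5.0", "nexus")

# Nexus Read_1 layout: 5 random nt then a fixed 4-nt spacer. The spacer is
# written 5'->3' in read orientation; over-trimming erodes it from its 3'
# (genomic-proximal) end, i.e. A first, then G, T, C.
NEXUS_RANDOM_BARCODE_LEN <- 5L
NEXUS_STATIC_BARCODE <- "CTGA"

#' Width of the Tn5 recognition sequence (bp)
#' @return 19L, the width of the transposase DNA recognition sequence that
#'   the tagmentation cut-site preference model is scored over.
#' @export
tn5_recognition_width <- function() 19L

#' Default Tn5 cut-site preference matrix
#'
#' A 4 x 19 column-stochastic probability matrix (rows A, C, G, T) over the
#' transposase recognition window, centered on the insertion point. The
#' default carries a strong preference in the central positions so that the
#' simulated tagmentation bias is detectable against the default genome
#' background; real preference matrices can be supplied instead.
#' @return Numeric matrix, rows named A/C/G/T, 19 columns.
#' @export
default_tn5_pwm <- function() {
  bg <- default_base_probs()[c("A", "C", "G", "T")]
  pwm <- matrix(rep(bg, tn5_recognition_width()), nrow = 4L,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  # Peaked palindromic-ish core: dominant base at 0.70, rest proportional
  # to background.
  core <- c(`6` = "G", `7` = "T", `8` = "A", `9` = "C", `10` = "G",
            `11` = "T", `12` = "A", `13` = "C", `14` = "G")
  for (j in names(core)) {
    col <- as.integer(j)
    dom <- core[[j]]
    rest <- setdiff(rownames(pwm), dom)
    pwm[dom, col] <- 0.70
    pwm[rest, col] <- 0.30 * bg[rest] / sum(bg[rest])
  }
  pwm
}

#' Build a simulator configuration
#'
#' All parameters of the library simulator in one validated record. Defaults
#' depend on `version` where the protocols genuinely differ (shouldering,
#' carryover, inner-stop ligation, over-trimming); everything else is shared
#' so that cross-version comparisons isolate the protocol mechanism.
#'
#' @param version Protocol variant: one of `"seq"` (ChIP-seq),
#'   `"mentation"` (ChIPmentation), `"exo1.1"`, `"exo3.1"`, `"exo4.0"`,
#'   `"exo4.1"`, `"exo5.0"`, `"nexus"`.
#' @param n_fragments Number of sonication fragments to draw.
#' @param frag_size_mode,frag_size_sd Mode and standard deviation (bp) of
#'   the truncated lognormal sonication size distribution.
#' @param frag_size_min,frag_size_max Clipping bounds (bp) for fragment
#'   sizes.
#' @param enrichment Immunoprecipitation weight (>= 1) of site-derived over
#'   background molecules.
#' @param background_frac Fraction of input chromatin molecules that carry
#'   no crosslink.
#' @param crosslink_offset Distance (bp) of each strand's crosslink from the
#'   motif midpoint.
#' @param stop_offset Distance (bp) 5' of the crosslink at which the
#'   exonuclease halts.
#' @param p_shoulder Per-molecule probability that exonuclease digestion
#'   fails, leaving a sonication (ChIP-seq-like) 5' end.
#' @param p_inner Fraction of site molecules whose crosslink sits at the
#'   motif midpoint (the secondary, inner stop site).
#' @param p_inner_ligation Probability that an inner stop is ligatable and
#'   so appears in the library (low in the 4.x single-stranded-ligation
#'   versions).
#' @param tn5_pwm 4 x 19 probability matrix of tagmentation cut-site
#'   preference.
#' @param p_tagment_per_bp Per-bp Tn5 insertion probability; a fragment of
#'   length L is tagmented with probability `1 - (1 - p)^L`.
#' @param p_carry Probability that the distal sub-fragment stays
#'   noncovalently bound and its ends are also sequenced (carryover).
#' @param p_overtrim ChIP-nexus only: probability that end-polishing
#'   over-trims the static barcode; trim depth is geometric with this
#'   continuation probability, capped at 4.
#' @param dup_mean Mean PCR copy number per molecule (shifted Poisson,
#'   >= 1).
#' @param read_len Read length in bp (2 x 40 bp sequencing by default).
#' @param seed Integer seed controlling every random draw of the run.
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config("exo5.0", n_fragments = 1000, seed = 7)
#' cfg$stop_offset
#' @export
sim_config <- function(version = "exo5.0",
                       n_fragments = 10000L,
                       frag_size_mode = 180,
                       frag_size_sd = 80,
                       frag_size_min = 100,
                       frag_size_max = 500,
                       enrichment = 12,
                       background_frac = 0.985,
                       crosslink_offset = 8L,
                       stop_offset = 6L,
                       p_shoulder = NULL,
                       p_inner = 0.25,
                       p_inner_ligation = NULL,
                       tn5_pwm = default_tn5_pwm(),
                       p_tagment_per_bp = 0.004,
                       p_carry = NULL,
                       p_overtrim = NULL,
                       dup_mean = 1.5,
                       read_len = 40L,
                       seed = 1L) {
  version <- match.arg(version, PROTOCOL_VERSIONS)
  # Version-specific defaults, overridable by the caller.
  p_shoulder <- p_shoulder %||% switch(version,
    "exo1.1" = 0.10, "exo3.1" = 0.40, "exo4.0" = 0.40, "exo4.1" = 0.40,
    "exo5.0" = 0.10, "nexus" = 0.10, 1.0)
  p_inner_ligation <- p_inner_ligation %||% switch(version,
    "exo4.0" = 0.10, "exo4.1" = 0.10, 1.0)
  p_carry <- p_carry %||% switch(version, "mentation" = 0.15, 0.0)
  p_overtrim <- p_overtrim %||% switch(version, "nexus" = 0.30, 0.0)

  cfg <- structure(list(
    version = version,
    n_fragments = as.integer(n_fragments),
    frag_size_mode = frag_size_mode,
    frag_size_sd = frag_size_sd,
    frag_size_min = frag_size_min,
    frag_size_max = frag_size_max,
    enrichment = enrichment,
    background_frac = background_frac,
    crosslink_offset = as.integer(crosslink_offset),
    stop_offset = as.integer(stop_offset),
    p_shoulder = p_shoulder,
    p_inner = p_inner,
    p_inner_ligation = p_inner_ligation,
    tn5_pwm = tn5_pwm,
    p_tagment_per_bp = p_tagment_per_bp,
    p_carry = p_carry,
    p_overtrim = p_overtrim,
    dup_mean = dup_mean,
    read_len = as.integer(read_len),
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

#' Validate a simulator configuration
#' @param cfg A `sim_config` (or plain list with the same fields).
#' @return The validated config, invisibly classed as `sim_config`.
#' @export
validate_sim_config <- function(cfg) {
  if (!cfg$version %in% PROTOCOL_VERSIONS) {
    stop("'version' must be one of: ", paste(PROTOCOL_VERSIONS,
                                             collapse = ", "))
  }
  if (cfg$n_fragments < 0) stop("'n_fragments' must be non-negative")
  for (f in c("p_shoulder", "p_inner", "p_inner_ligation",
              "p_tagment_per_bp", "p_carry", "p_overtrim",
              "background_frac")) {
    check_prob(cfg[[f]], f)
  }
  if (cfg$enrichment < 1) stop("'enrichment' must be >= 1")
  if (cfg$dup_mean < 1) stop("'dup_mean' must be >= 1")
  if (cfg$frag_size_min > cfg$frag_size_max) {
    stop("'frag_size_min' must not exceed 'frag_size_max'")
  }
  if (cfg$frag_size_min < 2 * (cfg$crosslink_offset + cfg$stop_offset) + 2 ||
      cfg$frag_size_min < cfg$read_len) {
    stop("'frag_size_min' is below the read/crosslink geometry floor")
  }
  if (!is.matrix(cfg$tn5_pwm) || nrow(cfg$tn5_pwm) != 4L ||
      ncol(cfg$tn5_pwm) != tn5_recognition_width()) {
    stop("'tn5_pwm' must be a 4 x ", tn5_recognition_width(), " matrix")
  }
  if (!setequal(rownames(cfg$tn5_pwm), c("A", "C", "G", "T"))) {
    stop("'tn5_pwm' rows must be named A, C, G, T")
  }
  if (any(abs(colSums(cfg$tn5_pwm) - 1) > 1e-6)) {
    stop("'tn5_pwm' columns must each sum to 1")
  }
  if (cfg$read_len < 1) stop("'read_len' must be positive")
  class(cfg) <- "sim_config"
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$version, "\n")
  cat(sprintf("  fragments: %d, sizes %g-%g bp (mode %g, sd %g)\n",
              x$n_fragments, x$frag_size_min, x$frag_size_max,
              x$frag_size_mode, x$frag_size_sd))
  cat(sprintf("  geometry: crosslink +/-%d bp, stop %d bp; p_shoulder %.2f\n",
              x$crosslink_offset, x$stop_offset, x$p_shoulder))
  cat(sprintf("  tagmentation p/bp %.4g, carryover %.2f; overtrim %.2f\n",
              x$p_tagment_per_bp, x$p_carry, x$p_overtrim))
  cat(sprintf("  dup_mean %.2f, read_len %d, seed %d\n",
              x$dup_mean, x$read_len, x$seed))
  invisible(x)
}

#' Read a simulator configuration from YAML or JSON
#'
#' Fields absent from the file take the `sim_config()` defaults for the
#' file's `version`. The effective (fully resolved) config is validated.
#' @param path YAML (or JSON) file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$tn5_pwm)) {
    pwm <- do.call(rbind, raw$tn5_pwm)
    rownames(pwm) <- names(raw$tn5_pwm)
    raw$tn5_pwm <- pwm
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, raw)
}

#' Write a simulator configuration to YAML or JSON
#' @param cfg A `sim_config`.
#' @param path Output file; extension selects the format.
#' @export
write_sim_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$tn5_pwm <- lapply(seq_len(nrow(cfg$tn5_pwm)),
                      function(i) unname(cfg$tn5_pwm[i, ]))
  names(x$tn5_pwm) <- rownames(cfg$tn5_pwm)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
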