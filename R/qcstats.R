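# Library-level diagnostics: 5'-end nucleotide-frequency profiles, bias
# calling with IUPAC summaries, ChIP-nexus barcode QC, insert-size
# mode +/- SD, duplicate-rate reporting.

IUPAC_CODES <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AC" = "M", "AG" = "R", "AT" = "W", "CG" = "S", "CT" = "Y", "GT" = "K",
  "ACG" = "V", "ACT" = "H", "AGT" = "D", "CGT" = "B", "ACGT" = "N"
)

#' Per-position nucleotide frequencies at read 5' ends
#'
#' Column-wise base frequencies over the first `n_positions` of each read.
#' Reads shorter than `n_positions` contribute only to the positions they
#' cover; positions covered by no read get `NA` frequencies.
#'
#' @param reads Character vector of read sequences.
#' @param n_positions Number of 5'-proximal positions to profile.
#' @return An `nt_freq_profile`: list with `freq` (n_positions x 4 matrix,
#'   columns A, C, G, T), `n_positions`, `n_reads`.
#' @examples
#' nt_freq(c("ACGT", "ACGT"), 4)$freq
#' @export
nt_freq <- function(reads, n_positions = 15L) {
  if (length(reads) == 0L) stop("empty read list")
  if (n_positions < 1L) stop("'n_positions' must be >= 1")
  bases <- c("A", "C", "G", "T")
  freq <- matrix(NA_real_, nrow = n_positions, ncol = 4L,
                 dimnames = list(NULL, bases))
  for (j in seq_len(n_positions)) {
    ch <- substr(reads, j, j)
    ch <- ch[ch != ""]
    if (!length(ch)) next
    counts <- table(factor(ch, levels = bases))
    freq[j, ] <- as.numeric(counts) / length(ch)
  }
  structure(list(freq = freq, n_positions = as.integer(n_positions),
                 n_reads = length(reads)),
            class = "nt_freq_profile")
}

#' @export
print.nt_freq_profile <- function(x, ...) {
  cat(sprintf("<nt_freq_profile> %d positions, %d reads\n",
              x$n_positions, x$n_reads))
  print(round(x$freq, 3))
  invisible(x)
}

#' IUPAC code for a set of nucleotides
#'
#' Standard degenerate-base nomenclature; the empty set maps to `"-"`.
#' @param flagged Character vector, a subset of A, C, G, T.
#' @return Single IUPAC character.
#' @examples
#' iupac_symbol(c("A", "T"))  # "W"
#' @export
iupac_symbol <- function(flagged) {
  flagged <- unique(flagged)
  if (length(flagged) == 0L) return("-")
  if (!all(flagged %in% c("A", "C", "G", "T"))) {
    stop("'flagged' must be a subset of A, C, G, T")
  }
  IUPAC_CODES[[paste(sort(flagged), collapse = "")]]
}

#' Call per-position sequence bias against a background composition
#'
#' A nucleotide is flagged at a position iff its frequency strictly exceeds
#' `background * (1 + margin)` — a relative margin, so a 10% margin over a
#' 31%/19% background gives display thresholds of 34% and 21%. The rule is
#' evaluated on unrounded frequencies; only the reported thresholds are
#' rounded to the nearest integer percent. Flagged sets are summarized per
#' position as an IUPAC string (`"-"` where nothing is flagged).
#'
#' @param profile An [nt_freq()] profile.
#' @param background Named background frequencies (A, C, G, T, sum 1).
#' @param margin Relative margin (default 0.10).
#' @return A `bias_call`: list with `flagged` (logical matrix), `iupac`
#'   (string of length n_positions), `n_flagged_positions`,
#'   `thresholds_pct` (displayed integer percent per nucleotide),
#'   `background`, `margin`.
#' @examples
#' p <- nt_freq(c("AAAA", "AACA", "AAAT"), 4)
#' call_bias(p, default_base_probs())$iupac
#' @export
call_bias <- function(profile, background = default_base_probs(),
                      margin = 0.10) {
  if (margin < 0) stop("'margin' must be non-negative")
  validate_base_probs(background)
  bases <- colnames(profile$freq)
  thr <- background[bases] * (1 + margin)
  flagged <- sweep(profile$freq, 2L, thr, `>`)
  flagged[is.na(flagged)] <- FALSE
  iupac <- vapply(seq_len(nrow(flagged)), function(i) {
    iupac_symbol(bases[flagged[i, ]])
  }, character(1))
  structure(list(
    flagged = flagged,
    iupac = paste(iupac, collapse = ""),
    n_flagged_positions = sum(rowSums(flagged) > 0L),
    thresholds_pct = round(100 * thr),
    background = background,
    margin = margin
  ), class = "bias_call")
}

#' @export
print.bias_call <- function(x, ...) {
  cat("<bias_call>", x$n_flagged_positions, "biased position(s)\n")
  cat("  IUPAC:", x$iupac, "\n")
  cat("  thresholds (%):",
      paste(names(x$thresholds_pct), x$thresholds_pct, sep = ">",
            collapse = " "), "\n")
  invisible(x)
}

#' ChIP-nexus barcode filter
#'
#' A Read_1 passes iff its (1-based) positions 6-9 equal the static spacer
#' `"CTGA"`; reads shorter than 9 nt fail with reason `"short"`.
#'
#' @param reads Character vector of Read_1 sequences.
#' @return Logical vector (`TRUE` = pass) with a `reason` attribute
#'   (`"ok"`, `"mismatch"` or `"short"`).
#' @export
nexus_filter <- function(reads) {
  short <- nchar(reads) < 9L
  pass <- !short & substr(reads, 6L, 9L) == NEXUS_STATIC_BARCODE
  reason <- ifelse(pass, "ok", ifelse(short, "short", "mismatch"))
  structure(pass, reason = reason)
}

#' Barcode QC report
#'
#' Partitions reads by [nexus_filter()] and profiles each partition's first
#' `n_positions` positions. Additionally reports, for the failing
#' partition, the presence frequency of the expected static-barcode base at
#' each spacer position (C at 6, T at 7, G at 8, A at 9): progressive
#' 3'-to-5' erosion of the spacer shows up as a C >= T >= G >= A ordering.
#'
#' @param reads Character vector of Read_1 sequences.
#' @param n_positions Profile window (default 15).
#' @return A `barcode_qc`: list with `n_pass`, `n_fail`, `pass_profile`,
#'   `fail_profile` (either may be NULL if its partition is empty), and
#'   `fail_static_presence`.
#' @export
barcode_qc <- function(reads, n_positions = 15L) {
  if (length(reads) == 0L) stop("empty read list")
  pass <- as.logical(nexus_filter(reads))
  fails <- reads[!pass]
  expected <- strsplit(NEXUS_STATIC_BARCODE, "")[[1]]
  presence <- if (length(fails)) {
    vapply(seq_along(expected), function(i) {
      mean(substr(fails, 5L + i, 5L + i) == expected[i])
    }, numeric(1))
  } else rep(NA_real_, length(expected))
  names(presence) <- paste0(expected, "@", 5L + seq_along(expected))
  structure(list(
    n_pass = sum(pass),
    n_fail = sum(!pass),
    pass_profile = if (any(pass)) nt_freq(reads[pass], n_positions),
    fail_profile = if (any(!pass)) nt_freq(fails, n_positions),
    fail_static_presence = presence
  ), class = "barcode_qc")
}

#' @export
print.barcode_qc <- function(x, ...) {
  cat(sprintf("<barcode_qc> pass %d, fail %d (%.1f%% fail)\n", x$n_pass,
              x$n_fail, 100 * x$n_fail / (x$n_pass + x$n_fail)))
  if (!anyNA(x$fail_static_presence)) {
    cat("  static-base presence among fails:",
        paste(names(x$fail_static_presence),
              sprintf("%.2f", x$fail_static_presence), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Insert-size mode and standard deviation
#'
#' The mode is the most frequent integer size (smallest on ties, so the
#' statistic is deterministic); the standard deviation is the population
#' SD.
#' @param sizes Integer insert sizes (bp).
#' @return Named numeric vector `c(mode, sd)`.
#' @export
insert_mode_sd <- function(sizes) {
  if (length(sizes) == 0L) stop("empty size list")
  tab <- table(sizes)
  mode <- min(as.integer(names(tab)[tab == max(tab)]))
  sdev <- sqrt(mean((sizes - mean(sizes))^2))
  c(mode = mode, sd = sdev)
}

#' Duplicate rate between a library and its deduplicated version
#'
#' `1 - |after| / |before|`.
#' @param tags_before,tags_after [tag_set()]s or record counts.
#' @return Fraction of records removed as duplicates.
#' @export
duplicate_rate <- function(tags_before, tags_after) {
  n_of <- function(x) if (inherits(x, "tag_set")) nrow(x$records) else
    as.numeric(x)
  nb <- n_of(tags_before)
  na_ <- n_of(tags_after)
  if (nb == 0) stop("empty input library")
  if (na_ > nb) stop("deduplicated set larger than input")
  1 - na_ / nb
}
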