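# Canonical tag container and I/O: duplicate removal, 5'-end and
# insert-size extraction, subsampling, TSV/BED/FASTQ readers and writers.

#' Construct a TagSet
#'
#' An ordered collection of TagRecords plus bookkeeping metadata. The
#' metadata counts are kept in step with the records by every transforming
#' operation.
#'
#' @param records TagRecord data.frame (see [apply_barcode_scheme()] for
#'   the columns).
#' @param metadata Named list; `n_input` defaults to `nrow(records)`.
#' @return An object of class `tag_set`.
#' @export
tag_set <- function(records, metadata = list()) {
  stopifnot(is.data.frame(records))
  metadata$n_input <- metadata$n_input %||% nrow(records)
  metadata$n_after_dedupe <- metadata$n_after_dedupe %||% NA_integer_
  structure(list(records = records, metadata = metadata),
            class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<tag_set> %d records (version: %s)\n", nrow(x$records),
              md$version %||% "unknown"))
  if (!is.na(md$n_after_dedupe %||% NA)) {
    cat(sprintf("  deduplicated: %d of %d input\n", md$n_after_dedupe,
                md$n_input))
  }
  invisible(x)
}

#' @export
length.tag_set <- function(x) nrow(x$records)

#' @export
as.data.frame.tag_set <- function(x, ...) x$records

#' Remove PCR duplicates
#'
#' Duplicates are reads with identical Read_1 and Read_2 sequences
#' (`mode = "sequence"`, the canonical definition) or identical 5'
#' coordinate/strand pairs (`mode = "coordinate"`, equivalent in practice
#' because Read_2 has a heterogeneous 5' end). The first record of each
#' equivalence class is retained; input order is otherwise preserved.
#'
#' @param tags A [tag_set()].
#' @param mode `"sequence"` or `"coordinate"`.
#' @return A deduplicated `tag_set` with `n_after_dedupe` set.
#' @export
dedupe <- function(tags, mode = c("sequence", "coordinate")) {
  mode <- match.arg(mode)
  r <- tags$records
  key <- if (mode == "sequence") {
    if (is.null(r$r1_seq) || is.null(r$r2_seq) ||
        (nrow(r) > 0L && (anyNA(r$r1_seq) || anyNA(r$r2_seq)))) {
      stop("sequence mode requires r1_seq and r2_seq")
    }
    paste(r$r1_seq, r$r2_seq, sep = "\r")
  } else {
    need <- c("chrom", "r1_pos5", "r1_strand", "r2_pos5", "r2_strand")
    if (!all(need %in% names(r))) {
      stop("coordinate mode requires both reads' coordinates and strands")
    }
    paste(r$chrom, r$r1_pos5, r$r1_strand, r$r2_pos5, r$r2_strand,
          sep = "\r")
  }
  out <- r[!duplicated(key), , drop = FALSE]
  md <- tags$metadata
  md$n_input <- nrow(r)
  md$n_after_dedupe <- nrow(out)
  tag_set(out, md)
}

#' Extract tag 5' ends
#'
#' One `(chrom, pos, strand)` per record; `pos` is the 5'-most base of the
#' chosen read in genome coordinates (for a minus-strand read occupying the
#' half-open interval `[start, end)` that is `end - 1`).
#'
#' @param tags A [tag_set()].
#' @param which `"read1"` or `"read2"`.
#' @return data.frame with columns chrom, pos, strand.
#' @export
five_prime_ends <- function(tags, which = c("read1", "read2")) {
  which <- match.arg(which)
  r <- tags$records
  if (which == "read1") {
    data.frame(chrom = r$chrom, pos = r$r1_pos5, strand = r$r1_strand,
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = r$chrom, pos = r$r2_pos5, strand = r$r2_strand,
               stringsAsFactors = FALSE)
  }
}

#' 5' end of a read interval
#'
#' Convention helper for reads stored as 0-based half-open intervals: the
#' 5' end is `start` on the plus strand and `end - 1` on the minus strand.
#' @param start,end Interval (0-based half-open).
#' @param strand `"+"` or `"-"`.
#' @return Integer 5'-end positions.
#' @export
five_prime_from_interval <- function(start, end, strand) {
  as.integer(ifelse(strand == "+", start, end - 1L))
}

#' Paired-end insert sizes
#'
#' Outer-coordinate span of each pair: rightmost covered base minus leftmost
#' covered base plus one, computed from the two 5' ends (the plus-strand
#' read's 5' end is the leftmost base, the minus-strand read's the
#' rightmost). Always positive for a proper pair; inter-chromosomal pairs
#' are an error.
#'
#' @param tags A [tag_set()].
#' @return Integer vector of insert sizes (bp).
#' @export
insert_sizes <- function(tags) {
  r <- tags$records
  if (nrow(r) == 0L) return(integer(0))
  if (any(is.na(r$r1_pos5) | is.na(r$r2_pos5))) {
    stop("both reads' coordinates are required")
  }
  same_chrom <- rep(TRUE, nrow(r))
  if (!is.null(r$r2_chrom)) same_chrom <- r$chrom == r$r2_chrom
  if (!all(same_chrom)) stop("inter-chromosomal pair")
  if (any(r$r1_strand == r$r2_strand)) {
    stop("improper pair: both reads on the same strand")
  }
  plus_pos <- ifelse(r$r1_strand == "+", r$r1_pos5, r$r2_pos5)
  minus_pos <- ifelse(r$r1_strand == "-", r$r1_pos5, r$r2_pos5)
  ins <- as.integer(minus_pos - plus_pos + 1L)
  if (any(ins <= 0L)) stop("non-positive insert: malformed pair")
  ins
}

#' Bernoulli subsampling of a TagSet
#'
#' Emulates lower-input libraries (e.g. cell titrations) by thinning each
#' record independently with probability `fraction`. Deterministic under
#' `seed`.
#'
#' @param tags A [tag_set()].
#' @param fraction Retention probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A thinned `tag_set`; metadata records `subsample_fraction`.
#' @export
subsample <- function(tags, fraction, seed = 1L) {
  check_prob(fraction, "fraction")
  r <- tags$records
  keep <- if (fraction >= 1) rep(TRUE, nrow(r)) else if (fraction <= 0)
    rep(FALSE, nrow(r)) else
    with_seed(seed, stats::runif(nrow(r)) < fraction)
  md <- tags$metadata
  md$subsample_fraction <- fraction
  md$n_input <- sum(keep)
  md$n_after_dedupe <- NA_integer_
  tag_set(r[keep, , drop = FALSE], md)
}

# ---- readers / writers ------------------------------------------------------

TAGS_TSV_COLS <- c("molecule_id", "chrom", "r1_pos5", "r1_strand",
                   "r2_pos5", "r2_strand", "r1_seq", "r2_seq", "shoulder",
                   "carryover", "duplicate_of", "barcode_trim_k")

#' Write a TagSet as 12-column TSV
#'
#' Columns: molecule_id, chrom, r1_pos5, r1_strand, r2_pos5, r2_strand,
#' r1_seq, r2_seq, shoulder, carryover, duplicate_of, barcode_trim_k.
#' Round-trips losslessly with [read_tags_tsv()].
#' @param tags A [tag_set()].
#' @param path Output file.
#' @export
write_tags_tsv <- function(tags, path) {
  df <- tags$records[, TAGS_TSV_COLS, drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = ".")
  invisible(path)
}

#' Read a 12-column tag TSV
#' @param path File written by [write_tags_tsv()].
#' @return A [tag_set()].
#' @export
read_tags_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(
                            molecule_id = "character", chrom = "character",
                            r1_pos5 = "integer", r1_strand = "character",
                            r2_pos5 = "integer", r2_strand = "character",
                            r1_seq = "character", r2_seq = "character",
                            shoulder = "logical", carryover = "logical",
                            duplicate_of = "character",
                            barcode_trim_k = "integer"),
                          na.strings = ".", stringsAsFactors = FALSE)
  tag_set(df, metadata = list(source = path))
}

#' Write per-read BED6
#'
#' One line per record for the chosen read: the read's occupied interval
#' (0-based half-open, from the 5' end and `read_len`), name =
#' molecule_id, score = 0, strand in column 6.
#' @param tags A [tag_set()].
#' @param path Output file.
#' @param which `"read1"` or `"read2"`.
#' @param read_len Read length used to draw the interval.
#' @export
write_reads_bed <- function(tags, path, which = c("read1", "read2"),
                            read_len = 40L) {
  which <- match.arg(which)
  e <- five_prime_ends(tags, which)
  start <- ifelse(e$strand == "+", e$pos, e$pos - read_len + 1L)
  df <- data.frame(chrom = e$chrom, start = start, end = start + read_len,
                   name = tags$records$molecule_id, score = 0L,
                   strand = e$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-read BED6 tag ends
#'
#' Accepts an optional 7th column as a mappability flag: rows with a
#' non-zero flag are dropped. This is the hook for real data, where
#' non-unique alignments are filtered out; simulated truth is always
#' uniquely placed.
#' @param path BED6(+1) file.
#' @return data.frame chrom, pos (5' end), strand, name.
#' @export
read_reads_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("expected at least 6 BED columns")
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  if (ncol(df) >= 7L) df <- df[df[[7L]] == 0, , drop = FALSE]
  data.frame(chrom = df$chrom,
             pos = five_prime_from_interval(df$start, df$end, df$strand),
             strand = df$strand, name = df$name,
             stringsAsFactors = FALSE)
}

#' Write paired FASTQ
#'
#' Two files (`<prefix>_R1.fastq`, `<prefix>_R2.fastq`), constant Q40
#' qualities, read names = molecule_id. Provided so simulated libraries can
#' be run through a real aligner; the package's own analyses use the truth
#' coordinates.
#' @param tags A [tag_set()].
#' @param prefix Output path prefix.
#' @return Character vector of the two paths.
#' @export
write_fastq_pair <- function(tags, prefix) {
  r <- tags$records
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  for (i in 1:2) {
    seqs <- if (i == 1L) r$r1_seq else r$r2_seq
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- r$molecule_id
    qual <- Biostrings::PhredQuality(
      vapply(nchar(seqs), function(w) strrep("I", w), character(1)))
    Biostrings::writeXStringSet(x, paths[i], format = "fastq",
                                qualities = qual)
  }
  invisible(paths)
}

#' Read sequences from a FASTQ file
#' @param path FASTQ file.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write the ground-truth table
#' @param truth Truth data.frame from [simulate_library()].
#' @param path Output TSV.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Read a ground-truth table
#' @param path TSV written by [write_truth_tsv()].
#' @return data.frame.
#' @export
read_truth_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                    stringsAsFactors = FALSE)
}
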