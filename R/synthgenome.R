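# Synthetic genomes with controlled base composition, and planted oriented
# motif sites. Coordinates are 0-based half-open throughout; BED output is
# native 0-based.

#' Default base composition
#'
#' Budding-yeast-like single-nucleotide composition: A and T at 31% each,
#' G and C at 19% each.
#'
#' @return Named numeric vector over A, C, G, T summing to 1.
#' @export
default_base_probs <- function() {
  c(A = 0.31, C = 0.19, G = 0.19, T = 0.31)
}

#' Fixed default motif used in examples and tests
#'
#' A 10-mer whose letters are balanced across the strand-orientation
#' classes of stop-site reads, so that planting it as exact text does not
#' itself register as 5'-end sequence bias under the default study
#' conditions (real site sets carry degenerate motif instances; planted
#' sites are identical, which would otherwise masquerade as chemistry
#' bias). Any ACGT string can be supplied instead.
#' @return A character scalar.
#' @export
default_motif <- function() "AAAGCTAGAG"

#' Generate a random genome sequence
#'
#' Bases are drawn i.i.d. from `base_probs`. Identical `(length, base_probs,
#' seed)` give byte-identical sequences.
#'
#' @param length Genome length in bp (non-negative integer).
#' @param base_probs Named frequencies for A, C, G, T; must sum to 1.
#' @param seed Integer seed.
#' @return A single character string of `length` bases.
#' @examples
#' g <- generate_genome(1000, seed = 1)
#' table(strsplit(g, "")[[1]])
#' @export
generate_genome <- function(length, base_probs = default_base_probs(),
                            seed = 1L) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) ||
      length < 0) {
    stop("'length' must be a single non-negative number")
  }
  validate_base_probs(base_probs)
  if (length == 0) return("")
  with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), size = length, replace = TRUE,
                 prob = base_probs[c("A", "C", "G", "T")]),
          collapse = "")
  })
}

validate_base_probs <- function(base_probs) {
  if (is.null(names(base_probs)) ||
      !setequal(names(base_probs), c("A", "C", "G", "T"))) {
    stop("'base_probs' must be named with A, C, G, T")
  }
  if (any(base_probs < 0) || abs(sum(base_probs) - 1) > 1e-9) {
    stop("'base_probs' must be non-negative and sum to 1")
  }
  invisible(base_probs)
}

#' Plant oriented motif sites into a genome
#'
#' Substitutes `motif` (or its reverse complement, for minus-strand sites)
#' at `n_sites` non-overlapping positions at least `min_spacing` bp apart.
#' Strands are drawn uniformly. Minus-strand sites store the forward-strand
#' interval; orientation is applied downstream, never by mutating the
#' coordinates.
#'
#' @param sequence Genome string.
#' @param motif ACGT motif string.
#' @param n_sites Number of sites to plant.
#' @param min_spacing Minimum gap in bp between the end of one site and the
#'   start of the next.
#' @param seed Integer seed.
#' @param chrom Chromosome name recorded in the site table.
#' @return A list with `sequence` (modified genome) and `sites`, a
#'   data.frame with columns chrom, start, end (0-based half-open), strand,
#'   site_id, rank_score, sorted by coordinate.
#' @examples
#' g <- generate_genome(2000, seed = 3)
#' p <- plant_motifs(g, "ACGTAACG", n_sites = 3, min_spacing = 100, seed = 7)
#' p$sites
#' @export
plant_motifs <- function(sequence, motif, n_sites, min_spacing = 0L,
                         seed = 1L, chrom = "chrS") {
  if (grepl("[^ACGT]", motif) || nchar(motif) == 0L) {
    stop("'motif' must be a non-empty string over A, C, G, T")
  }
  if (n_sites < 0) stop("'n_sites' must be non-negative")
  L <- nchar(sequence)
  m <- nchar(motif)
  if (n_sites == 0L) {
    return(list(sequence = sequence, sites = empty_sites(chrom)))
  }
  if (n_sites * (m + min_spacing) > L) {
    stop("capacity exceeded: n_sites * (motif length + min_spacing) ",
         "exceeds the genome length")
  }
  with_seed(seed, {
    # Sorted-uniform construction: distribute the slack left over after
    # reserving n motifs plus (n-1) gaps, guaranteeing the spacing.
    slack <- L - n_sites * m - (n_sites - 1L) * min_spacing
    u <- sort(sample.int(slack + 1L, n_sites, replace = TRUE) - 1L)
    starts <- u + (seq_len(n_sites) - 1L) * (m + min_spacing)
    strands <- sample(c("+", "-"), n_sites, replace = TRUE)
    inserted <- ifelse(strands == "+", motif, revcomp(motif))
    for (i in seq_len(n_sites)) {
      substr(sequence, starts[i] + 1L, starts[i] + m) <- inserted[i]
    }
    sites <- data.frame(
      chrom = chrom,
      start = as.integer(starts),
      end = as.integer(starts + m),
      strand = strands,
      site_id = sprintf("site_%04d", seq_len(n_sites)),
      rank_score = as.numeric(rev(seq_len(n_sites))),
      stringsAsFactors = FALSE
    )
    list(sequence = sequence, sites = sites)
  })
}

empty_sites <- function(chrom = character(0)) {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), site_id = character(0),
             rank_score = numeric(0), stringsAsFactors = FALSE)
}

#' Motif-site midpoint
#'
#' `start + floor(width / 2)`: for even-width motifs the midpoint lies just
#' right of center. Profile stripes move by 1 bp under the other convention,
#' so it is fixed here once.
#' @param sites Site data.frame.
#' @return Integer vector of midpoints (0-based).
#' @export
site_midpoint <- function(sites) {
  as.integer(sites$start + (sites$end - sites$start) %/% 2L)
}

# ---- FASTA / BED I/O --------------------------------------------------------

#' Write a genome to FASTA
#' @param sequence Genome string (or named character vector of sequences).
#' @param path Output file.
#' @param name Sequence name used when `sequence` is unnamed.
#' @export
write_fasta <- function(sequence, path, name = "chrS") {
  if (is.null(names(sequence))) {
    names(sequence) <- if (length(sequence) == 1L) name else
      paste0(name, seq_along(sequence))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequence), path,
                              width = 60L)
  invisible(path)
}

#' Read a FASTA file
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  # keep only the first word of the header, as aligners do
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write motif sites as BED6
#'
#' name = site_id, score = rank_score, column 6 = strand. BED is 0-based
#' half-open, matching the in-memory representation.
#' @param sites Site data.frame.
#' @param path Output file.
#' @export
write_sites_bed <- function(sites, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$start + 1L, end = sites$end),
    strand = sites$strand
  )
  gr$name <- sites$site_id
  gr$score <- sites$rank_score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read motif sites from BED6
#' @param path BED file.
#' @return Site data.frame (chrom, start, end, strand, site_id, rank_score).
#' @export
read_sites_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    site_id = if (!is.null(gr$name)) gr$name else
      sprintf("site_%04d", seq_along(gr)),
    rank_score = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
    stringsAsFactors = FALSE
  )
}
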