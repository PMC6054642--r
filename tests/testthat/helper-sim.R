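# Shared simulation fixtures. Libraries are cached on disk (tempdir) keyed
# by their parameters, so the same simulated library is reused across test
# files without re-running the generator.

fixture_genome <- function() {
  path <- file.path(tempdir(), "chipexosim_fixture_genome.rds")
  if (file.exists(path)) return(readRDS(path))
  g <- generate_genome(6e5, seed = 11)
  p <- plant_motifs(g, default_motif(), n_sites = 200, min_spacing = 1500,
                    seed = 12)
  saveRDS(p, path)
  p
}

sim_lib <- function(version, n = 50000L, seed = 101L, ...) {
  extra <- list(...)
  key <- paste(version, n, seed,
               paste(names(extra), unlist(extra), collapse = "_"),
               sep = "_")
  key <- gsub("[^A-Za-z0-9_.]", "-", key)
  path <- file.path(tempdir(), paste0("chipexosim_lib_", key, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  fx <- fixture_genome()
  cfg <- do.call(sim_config, c(list(version = version,
                                    n_fragments = as.integer(n),
                                    seed = as.integer(seed)), extra))
  lib <- simulate_library(fx$sequence, fx$sites, cfg)
  saveRDS(lib, path)
  lib
}

r1_profile_matrix <- function(lib, window = 500L) {
  fx <- fixture_genome()
  anchor_matrix(five_prime_ends(dedupe(lib$tags), "read1"), fx$sites,
                window)
}

# Minimal TagSet builder for toy cases.
toy_tags <- function(r1_pos, r1_strand, r2_pos, r2_strand,
                     r1_seq = NULL, r2_seq = NULL, chrom = "chrS") {
  n <- length(r1_pos)
  tag_set(data.frame(
    molecule_id = sprintf("t%03d", seq_len(n)),
    chrom = rep_len(chrom, n),
    r1_pos5 = as.integer(r1_pos), r1_strand = r1_strand,
    r2_pos5 = as.integer(r2_pos), r2_strand = r2_strand,
    r1_seq = r1_seq %||% strrep("A", 40),
    r2_seq = r2_seq %||% strrep("C", 40),
    shoulder = FALSE, carryover = FALSE,
    duplicate_of = NA_character_, barcode_trim_k = 0L,
    origin_site = "background", stringsAsFactors = FALSE))
}

# Build a profile_matrix directly from per-site counts (toy oracle input).
toy_matrix <- function(counts_same, counts_opposite, window) {
  offsets <- seq.int(-window, window)
  stopifnot(ncol(counts_same) == length(offsets))
  ids <- rownames(counts_same) %||% sprintf("site_%04d",
                                            seq_len(nrow(counts_same)))
  structure(list(sites = ids, offsets = offsets,
                 counts_same = counts_same,
                 counts_opposite = counts_opposite,
                 window = as.integer(window)),
            class = "profile_matrix")
}

# O(n^2) reference implementation of duplicate marking (first occurrence
# kept), used as the independent oracle for dedupe().
dedupe_oracle <- function(records, mode) {
  keep <- rep(TRUE, nrow(records))
  eq <- function(i, j) {
    if (mode == "sequence") {
      records$r1_seq[i] == records$r1_seq[j] &&
        records$r2_seq[i] == records$r2_seq[j]
    } else {
      records$chrom[i] == records$chrom[j] &&
        records$r1_pos5[i] == records$r1_pos5[j] &&
        records$r1_strand[i] == records$r1_strand[j] &&
        records$r2_pos5[i] == records$r2_pos5[j] &&
        records$r2_strand[i] == records$r2_strand[j]
    }
  }
  for (i in seq_len(nrow(records))) {
    if (!keep[i]) next
    for (j in seq_len(i - 1L)) {
      if (keep[j] && eq(i, j)) { keep[i] <- FALSE; break }
    }
  }
  records[keep, , drop = FALSE]
}

random_base_string <- function(n, len, probs = default_base_probs()) {
  m <- matrix(sample(names(probs), n * len, replace = TRUE, prob = probs),
              nrow = n)
  apply(m, 1L, paste, collapse = "")
}
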