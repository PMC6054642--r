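# Library-construction simulator: sonication fragments, exonuclease
# stop-site geometry, Tn5 tagmentation, barcode schemes, PCR duplication.
# All coordinates 0-based half-open; a read's stored position is its 5'-most
# base in genome coordinates.

# Solve the lognormal sigma giving a requested (mode, sd); mu follows from
# the mode. Used to parameterize the sonication size distribution.
lognormal_params <- function(mode, sd) {
  stopifnot(mode > 0, sd >= 0)
  if (sd == 0) return(c(mu = log(mode), sigma = 0))
  f <- function(sigma) {
    mu <- log(mode) + sigma^2
    exp(mu + sigma^2 / 2) * sqrt(exp(sigma^2) - 1) - sd
  }
  sigma <- stats::uniroot(f, c(1e-6, 3), tol = 1e-10)$root
  c(mu = log(mode) + sigma^2, sigma = sigma)
}

# Truncated lognormal sizes: redraw outside [lo, hi] so the distribution
# keeps its shape inside the range (no boundary pile-up).
draw_truncated_sizes <- function(n, lp, lo, hi) {
  if (lp["sigma"] == 0) return(rep(as.integer(exp(lp["mu"])), n))
  sizes <- round(stats::rlnorm(n, lp["mu"], lp["sigma"]))
  for (iter in 1:50) {
    bad <- which(sizes < lo | sizes > hi)
    if (!length(bad)) break
    sizes[bad] <- round(stats::rlnorm(length(bad), lp["mu"], lp["sigma"]))
  }
  # pathological parameterizations: clamp the stragglers
  as.integer(pmin(pmax(sizes, lo), hi))
}

#' Draw sonication fragments over a genome
#'
#' Fragment sizes follow a truncated lognormal parameterized by its mode and
#' standard deviation, truncated to `[frag_size_min, frag_size_max]`. Each
#' fragment is site-derived with probability
#' `(1 - bf) * enrichment / ((1 - bf) * enrichment + bf)` where `bf` is
#' `background_frac`: the immunoprecipitation up-weights crosslinked
#' molecules by `enrichment` relative to the crosslink-free background.
#' Site-derived fragments cover the motif midpoint with both the crosslinks
#' (midpoint -/+ `crosslink_offset`) and their stop sites inside the
#' fragment; background fragments are placed uniformly, avoiding sites.
#'
#' @param genome Genome string.
#' @param sites Motif-site data.frame (may have zero rows).
#' @param config A [sim_config()].
#' @param chrom Chromosome name for background fragments when `sites` is
#'   empty.
#' @return A data.frame of fragments: chrom, start, end, origin_site
#'   (`"background"` or a site_id), mid, xl_fwd, xl_rev (crosslink
#'   positions; NA for background).
#' @export
simulate_fragments <- function(genome, sites, config, chrom = "chrS") {
  if (nchar(genome) == 0L) stop("empty genome")
  L <- nchar(genome)
  n <- config$n_fragments
  if (n == 0L) return(empty_fragments())
  lp <- lognormal_params(config$frag_size_mode, config$frag_size_sd)
  sizes <- draw_truncated_sizes(n, lp, config$frag_size_min,
                                min(config$frag_size_max, L))

  bf <- config$background_frac
  p_site <- if (nrow(sites) == 0L) 0 else {
    (1 - bf) * config$enrichment / ((1 - bf) * config$enrichment + bf)
  }
  is_site <- stats::runif(n) < p_site
  chrom_out <- rep(if (nrow(sites)) sites$chrom[1L] else chrom, n)
  start <- integer(n)
  origin <- rep("background", n)
  mid_out <- rep(NA_integer_, n)

  margin <- config$crosslink_offset + config$stop_offset
  if (any(is_site)) {
    idx <- which(is_site)
    mids <- site_midpoint(sites)
    for (iter in 1:20) {
      pick <- sample.int(nrow(sites), length(idx), replace = TRUE)
      mid <- mids[pick]
      lo <- pmax(mid + margin + 1L - sizes[idx], 0L)
      hi <- pmin(mid - margin, L - sizes[idx])
      ok <- hi >= lo
      st <- lo + as.integer(floor(stats::runif(length(idx)) * (hi - lo + 1L)))
      start[idx[ok]] <- st[ok]
      origin[idx[ok]] <- sites$site_id[pick[ok]]
      mid_out[idx[ok]] <- mid[ok]
      chrom_out[idx[ok]] <- sites$chrom[pick[ok]]
      idx <- idx[!ok]
      if (!length(idx)) break
      sizes[idx] <- draw_truncated_sizes(length(idx), lp,
                                         config$frag_size_min,
                                         min(config$frag_size_max, L))
    }
    if (length(idx)) {
      stop("could not place site fragments: sites too close to the ",
           "genome edge for the configured geometry")
    }
  }

  if (any(!is_site)) {
    idx <- which(!is_site)
    site_ir <- IRanges::IRanges(start = sites$start + 1L, end = sites$end)
    for (iter in 1:25) {
      st <- as.integer(floor(stats::runif(length(idx)) * (L - sizes[idx] + 1L)))
      if (nrow(sites)) {
        frag_ir <- IRanges::IRanges(start = st + 1L, width = sizes[idx])
        hit <- IRanges::countOverlaps(frag_ir, site_ir) > 0L
      } else hit <- rep(FALSE, length(idx))
      start[idx[!hit]] <- st[!hit]
      idx <- idx[hit]
      if (!length(idx)) break
    }
    # pathological genomes saturated with sites: accept the leftover draws
    if (length(idx)) {
      start[idx] <- as.integer(floor(stats::runif(length(idx)) *
                                       (L - sizes[idx] + 1L)))
    }
  }

  data.frame(
    chrom = chrom_out,
    start = start,
    end = start + sizes,
    origin_site = origin,
    mid = mid_out,
    xl_fwd = ifelse(is.na(mid_out), NA_integer_,
                    mid_out - config$crosslink_offset),
    xl_rev = ifelse(is.na(mid_out), NA_integer_,
                    mid_out + config$crosslink_offset),
    stringsAsFactors = FALSE
  )
}

empty_fragments <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             origin_site = character(0), mid = integer(0),
             xl_fwd = integer(0), xl_rev = integer(0),
             stringsAsFactors = FALSE)
}

#' Exonuclease digestion geometry
#'
#' Maps fragments to tag geometry (Read_1/Read_2 5' coordinates and
#' strands). For exonuclease versions, each crosslinked molecule is digested
#' on one strand (chosen uniformly among the crosslinks it carries): with
#' probability `1 - p_shoulder` the Read_1 5' end is the stop site
#' (`crosslink - stop_offset` on the plus strand, mirrored on minus); with
#' probability `p_shoulder` digestion fails and Read_1 starts at the
#' sonication end, indistinguishable from ChIP-seq. Crosslink-free
#' (background) fragments always yield sonication ends, as do the `seq` and
#' `mentation` versions, where digestion is skipped entirely. Read_2 is
#' always the opposite sonication end. With probability `p_inner` a site
#' molecule's crosslink sits at the motif midpoint (the inner, secondary
#' stop); inner stops enter the library only with probability
#' `p_inner_ligation` (`kept = FALSE` otherwise).
#'
#' @param fragments Fragment data.frame from [simulate_fragments()] (a
#'   single row is fine).
#' @param config A [sim_config()].
#' @return A data.frame: chrom, r1_pos5, r1_strand, r2_pos5, r2_strand,
#'   shoulder, inner, kept, origin_site, plus the fragment boundaries.
#' @export
exo_process <- function(fragments, config) {
  n <- nrow(fragments)
  if (n == 0L) return(empty_geometry())
  st <- fragments$start
  en <- fragments$end
  has_fwd <- !is.na(fragments$xl_fwd)
  has_rev <- !is.na(fragments$xl_rev)
  exo <- config$version %in% EXO_VERSIONS

  # digested strand: uniform among the crosslinks present, uniform for none
  u <- stats::runif(n)
  r1_strand <- ifelse(has_fwd & !has_rev, "+",
               ifelse(has_rev & !has_fwd, "-",
                      ifelse(u < 0.5, "+", "-")))

  inner <- rep(FALSE, n)
  shoulder <- rep(FALSE, n)
  kept <- rep(TRUE, n)
  r1 <- ifelse(r1_strand == "+", st, en - 1L)

  if (exo) {
    site_mol <- (has_fwd | has_rev)
    inner <- site_mol & !is.na(fragments$mid) &
      stats::runif(n) < config$p_inner
    shoulder <- site_mol & stats::runif(n) < config$p_shoulder
    xl <- ifelse(inner, fragments$mid,
                 ifelse(r1_strand == "+", fragments$xl_fwd,
                        fragments$xl_rev))
    stop_pos <- ifelse(r1_strand == "+", xl - config$stop_offset,
                       xl + config$stop_offset)
    digested <- site_mol & !shoulder
    if (any(digested & (stop_pos < st | stop_pos >= en), na.rm = TRUE)) {
      stop("stop coordinate outside fragment")
    }
    r1[digested] <- stop_pos[digested]
    kept <- !(digested & inner & stats::runif(n) >= config$p_inner_ligation)
  }

  r2 <- ifelse(r1_strand == "+", en - 1L, st)
  data.frame(
    chrom = fragments$chrom,
    r1_pos5 = as.integer(r1),
    r1_strand = r1_strand,
    r2_pos5 = as.integer(r2),
    r2_strand = ifelse(r1_strand == "+", "-", "+"),
    shoulder = shoulder,
    inner = inner & exo,
    kept = kept,
    origin_site = fragments$origin_site,
    frag_start = st,
    frag_end = en,
    cut_pos = if (!is.null(fragments$cut_pos)) fragments$cut_pos else
      rep(NA_integer_, n),
    carryover = rep(FALSE, n),
    stringsAsFactors = FALSE
  )
}

empty_geometry <- function() {
  data.frame(chrom = character(0), r1_pos5 = integer(0),
             r1_strand = character(0), r2_pos5 = integer(0),
             r2_strand = character(0), shoulder = logical(0),
             inner = logical(0), kept = logical(0),
             origin_site = character(0), frag_start = integer(0),
             frag_end = integer(0), cut_pos = integer(0),
             carryover = logical(0), stringsAsFactors = FALSE)
}

# Per-position log-weight of the Tn5 recognition window starting at each
# 1-based genome position (window fully inside the genome).
tn5_window_logweights <- function(genome, pwm) {
  w <- ncol(pwm)
  L <- nchar(genome)
  if (L < w) stop("genome shorter than the recognition window")
  code <- utf8ToInt(genome)
  idx <- integer(128)
  idx[utf8ToInt("A")] <- 1L; idx[utf8ToInt("C")] <- 2L
  idx[utf8ToInt("G")] <- 3L; idx[utf8ToInt("T")] <- 4L
  base <- idx[code]
  base[base == 0L] <- NA_integer_
  logp <- log(pwm[c("A", "C", "G", "T"), , drop = FALSE])
  n <- L - w + 1L
  lw <- numeric(n)
  for (j in seq_len(w)) {
    b <- base[j:(n + j - 1L)]
    contrib <- logp[cbind(b, j)]
    contrib[is.na(contrib)] <- -30  # ambiguous base: effectively never cut
    lw <- lw + contrib
  }
  lw
}

#' Tagment fragments
#'
#' Each fragment is tagmented with probability `1 - (1 - p)^L` (`p =
#' p_tagment_per_bp`, `L` the fragment length), reproducing the preferential
#' reaction of longer molecules. For tagmented fragments, a cut position is
#' drawn proportional to the recognition-sequence match score across the
#' fragment (window fully inside the fragment; the cut is the window
#' center). The fragment's sonication boundaries are kept — the spent
#' transposase holds the cut molecule together through library
#' construction — and the cut is recorded as an annotation that determines
#' (a) where Read_2 sequencing begins and (b) carryover: with probability
#' `p_carry` the distal sub-fragment's ends are also sequenced as tags
#' attributed to the same molecule.
#'
#' @param fragments Fragment data.frame.
#' @param config A [sim_config()]; `tn5_pwm` must be 4 x 19.
#' @param genome Genome string (for cut-site preference scoring).
#' @return `fragments` with added columns `tagmented`, `cut_pos` (0-based
#'   cut coordinate, NA if untagmented) and `carry`.
#' @export
tagment <- function(fragments, config, genome) {
  pwm <- config$tn5_pwm
  if (ncol(pwm) != tn5_recognition_width()) {
    stop("'tn5_pwm' must have width ", tn5_recognition_width())
  }
  n <- nrow(fragments)
  len <- fragments$end - fragments$start
  if (any(len < ncol(pwm))) stop("fragment shorter than the recognition window")
  fragments$tagmented <- stats::runif(n) <
    1 - (1 - config$p_tagment_per_bp)^len
  fragments$cut_pos <- rep(NA_integer_, n)
  fragments$carry <- rep(FALSE, n)
  if (!any(fragments$tagmented)) return(fragments)

  lw <- tn5_window_logweights(genome, pwm)
  w <- ncol(pwm)
  half <- w %/% 2L
  for (i in which(fragments$tagmented)) {
    s1 <- fragments$start[i] + 1L          # first 1-based window start
    e1 <- fragments$end[i] - w + 1L        # last 1-based window start
    wts <- lw[s1:e1]
    wts <- exp(wts - max(wts))
    pick <- if (length(wts) == 1L) 1L else
      sample.int(length(wts), 1L, prob = wts)
    fragments$cut_pos[i] <- (s1 - 1L) + (pick - 1L) + half  # 0-based center
  }
  fragments$carry[fragments$tagmented] <-
    stats::runif(sum(fragments$tagmented)) < config$p_carry
  fragments
}

# Carryover geometry: the distal sub-fragment (the side of the cut away
# from the crosslink, or a random side for background molecules) is held by
# spent Tn5 and its ends sequenced like a ChIP-seq molecule. Both interior
# (cut-side) strand orientations occur, which is what mixes tag strands
# downstream of the motif.
carryover_geometry <- function(fragments, config) {
  sel <- which(fragments$tagmented & fragments$carry)
  if (!length(sel)) return(empty_geometry())
  f <- fragments[sel, , drop = FALSE]
  ref <- ifelse(is.na(f$mid), (f$start + f$end) %/% 2L, f$mid)
  right <- f$cut_pos > ref
  p_start <- ifelse(right, f$cut_pos, f$start)
  p_end <- ifelse(right, f$end, f$cut_pos)
  ok <- (p_end - p_start) >= config$read_len + 1L
  f <- f[ok, , drop = FALSE]
  p_start <- p_start[ok]; p_end <- p_end[ok]
  if (!nrow(f)) return(empty_geometry())
  strand <- ifelse(stats::runif(nrow(f)) < 0.5, "+", "-")
  data.frame(
    chrom = f$chrom,
    r1_pos5 = as.integer(ifelse(strand == "+", p_start, p_end - 1L)),
    r1_strand = strand,
    r2_pos5 = as.integer(ifelse(strand == "+", p_end - 1L, p_start)),
    r2_strand = ifelse(strand == "+", "-", "+"),
    shoulder = FALSE, inner = FALSE, kept = TRUE,
    origin_site = f$origin_site,
    frag_start = as.integer(p_start), frag_end = as.integer(p_end),
    cut_pos = f$cut_pos,
    carryover = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Attach read sequences and version-specific barcodes
#'
#' Builds `TagRecord`s from tag geometry. ChIP-nexus Read_1 is 5 random
#' nucleotides, the 4-nt static spacer `"CTGA"`, then genomic sequence from
#' the stop site; with probability `p_overtrim` a geometric number `k` (cap
#' 4) of terminal spacer bases is eroded in the order A, G, T, C,
#' frame-shifting the read. ChIP-exo 4.0 Read_1 begins with the random
#' pentamer, and the record's mapped `r1_pos5` is displaced 5 bp in the 5'
#' direction of the read strand. Read_2 sequence starts at the tagmentation
#' cut for tagmented versions (that is where the transposed adapter sits),
#' and at the sonication end otherwise.
#'
#' @param geometry Geometry data.frame from [exo_process()] (rows with
#'   `kept = FALSE` must be removed first).
#' @param genome Genome string.
#' @param config A [sim_config()].
#' @return A TagRecord data.frame: molecule_id, chrom, r1_pos5, r1_strand,
#'   r2_pos5, r2_strand, r1_seq, r2_seq, shoulder, carryover, duplicate_of,
#'   barcode_trim_k, origin_site.
#' @export
apply_barcode_scheme <- function(geometry, genome, config) {
  n <- nrow(geometry)
  rl <- config$read_len
  L <- nchar(genome)
  if (n == 0L) return(empty_tag_records())
  if (any(geometry$r1_pos5 < 0 | geometry$r1_pos5 >= L |
          geometry$r2_pos5 < 0 | geometry$r2_pos5 >= L)) {
    stop("stop site outside the genome")
  }

  trim_k <- rep(0L, n)
  version <- config$version
  r2_anchor <- geometry$r2_pos5
  tagged <- version %in% TAGMENTED_VERSIONS & !is.na(geometry$cut_pos) &
    !geometry$carryover
  r2_anchor[tagged] <- geometry$cut_pos[tagged]

  random_mer <- function(k) {
    if (k == 0L) return(character(n))
    m <- matrix(sample(c("A", "C", "G", "T"), n * k, replace = TRUE),
                nrow = n)
    apply(m, 1L, paste, collapse = "")
  }

  r1_pos_out <- geometry$r1_pos5
  if (version == "nexus") {
    trimmed <- stats::runif(n) < config$p_overtrim
    depth <- 1L + stats::rgeom(n, prob = 1 - config$p_overtrim)
    trim_k <- ifelse(trimmed, pmin(depth, nchar(NEXUS_STATIC_BARCODE)), 0L)
    static_kept <- substr(rep(NEXUS_STATIC_BARCODE, n), 1L,
                          nchar(NEXUS_STATIC_BARCODE) - trim_k)
    n_genomic <- rl - NEXUS_RANDOM_BARCODE_LEN - nchar(static_kept)
    genomic <- vapply(seq_len(n), function(i) {
      extract_read_seq(genome, geometry$r1_pos5[i], geometry$r1_strand[i],
                       n_genomic[i])
    }, character(1))
    r1_seq <- paste0(random_mer(NEXUS_RANDOM_BARCODE_LEN), static_kept,
                     genomic)
  } else if (version == "exo4.0") {
    genomic <- extract_read_seq(genome, geometry$r1_pos5,
                                geometry$r1_strand,
                                rl - NEXUS_RANDOM_BARCODE_LEN)
    r1_seq <- paste0(random_mer(NEXUS_RANDOM_BARCODE_LEN), genomic)
    # the aligned 5' coordinate absorbs the pentamer: 5 bp more 5'
    r1_pos_out <- ifelse(geometry$r1_strand == "+",
                         geometry$r1_pos5 - NEXUS_RANDOM_BARCODE_LEN,
                         geometry$r1_pos5 + NEXUS_RANDOM_BARCODE_LEN)
  } else {
    r1_seq <- extract_read_seq(genome, geometry$r1_pos5,
                               geometry$r1_strand, rl)
  }
  r2_seq <- extract_read_seq(genome, r2_anchor, geometry$r2_strand, rl)

  data.frame(
    molecule_id = sprintf("m%07d", seq_len(n)),
    chrom = geometry$chrom,
    r1_pos5 = as.integer(r1_pos_out),
    r1_strand = geometry$r1_strand,
    r2_pos5 = as.integer(geometry$r2_pos5),
    r2_strand = geometry$r2_strand,
    r1_seq = r1_seq,
    r2_seq = r2_seq,
    shoulder = geometry$shoulder,
    carryover = geometry$carryover,
    duplicate_of = NA_character_,
    barcode_trim_k = trim_k,
    origin_site = geometry$origin_site,
    stringsAsFactors = FALSE
  )
}

empty_tag_records <- function() {
  data.frame(molecule_id = character(0), chrom = character(0),
             r1_pos5 = integer(0), r1_strand = character(0),
             r2_pos5 = integer(0), r2_strand = character(0),
             r1_seq = character(0), r2_seq = character(0),
             shoulder = logical(0), carryover = logical(0),
             duplicate_of = character(0), barcode_trim_k = integer(0),
             origin_site = character(0), stringsAsFactors = FALSE)
}

#' PCR-duplicate molecules
#'
#' Each molecule is emitted `1 + Poisson(dup_mean - 1)` times; copies are
#' byte-identical in both read sequences and flagged with `duplicate_of`
#' pointing at the original molecule. `dup_mean = 1` reproduces the input
#' exactly.
#'
#' @param records TagRecord data.frame.
#' @param config A [sim_config()] with `dup_mean >= 1`.
#' @return Expanded TagRecord data.frame, originals first within each
#'   molecule.
#' @export
pcr_duplicate <- function(records, config) {
  if (config$dup_mean < 1) stop("'dup_mean' must be >= 1")
  n <- nrow(records)
  if (n == 0L) return(records)
  counts <- 1L + stats::rpois(n, config$dup_mean - 1)
  idx <- rep.int(seq_len(n), counts)
  out <- records[idx, , drop = FALSE]
  copy_no <- sequence(counts) - 1L
  dup <- copy_no > 0L
  out$duplicate_of[dup] <- records$molecule_id[idx[dup]]
  out$molecule_id[dup] <- paste0(out$molecule_id[dup], "_d", copy_no[dup])
  rownames(out) <- NULL
  out
}

# Drop geometry rows whose reads would run past a genome edge; the genomes
# used here are large relative to the read length, so this loses only
# edge molecules.
filter_edge_geometry <- function(geometry, config, L) {
  rl <- config$read_len
  ok <- function(pos, strand) {
    ifelse(strand == "+", pos + rl <= L, pos - rl + 1L >= 0L)
  }
  r2a <- ifelse(!is.na(geometry$cut_pos) & !geometry$carryover &
                  config$version %in% TAGMENTED_VERSIONS,
                geometry$cut_pos, geometry$r2_pos5)
  keep <- geometry$r1_pos5 >= 0 & geometry$r1_pos5 < L &
    ok(geometry$r1_pos5, geometry$r1_strand) &
    ok(r2a, geometry$r2_strand) & r2a >= 0 & r2a < L
  if (config$version == "exo4.0") {
    keep <- keep & ifelse(geometry$r1_strand == "+",
                          geometry$r1_pos5 - 5L >= 0L,
                          geometry$r1_pos5 + 5L < L)
  }
  geometry[keep, , drop = FALSE]
}

#' Simulate a full sequencing library
#'
#' Orchestrates the pipeline fragments -> (tagmentation and/or exonuclease
#' digestion) -> barcode/sequence construction -> PCR duplication for the
#' configured protocol version. All randomness flows from `config$seed`
#' through one generator in a fixed stage order, so identical inputs give
#' identical libraries.
#'
#' @param genome Genome string.
#' @param sites Motif-site data.frame.
#' @param config A [sim_config()].
#' @return A list with `tags` (a [tag_set()]), `truth` (data.frame mapping
#'   molecule_id to origin_site and ground-truth flags), `fragments`, and
#'   the effective `config`.
#' @examples
#' g <- generate_genome(50000, seed = 2)
#' p <- plant_motifs(g, default_motif(), n_sites = 5, min_spacing = 2000,
#'                   seed = 2)
#' lib <- simulate_library(p$sequence, p$sites,
#'                         sim_config("exo5.0", n_fragments = 500, seed = 9))
#' lib$tags
#' @export
simulate_library <- function(genome, sites, config) {
  validate_sim_config(config)
  L <- nchar(genome)
  with_seed(config$seed, {
    frags <- simulate_fragments(genome, sites, config)
    n_tagmented <- NA_integer_
    if (config$version %in% TAGMENTED_VERSIONS) {
      frags <- tagment(frags, config, genome)
      n_tagmented <- sum(frags$tagmented)
      kept_frags <- frags[frags$tagmented, , drop = FALSE]
      geom <- exo_process(kept_frags, config)
      geom <- rbind(geom, carryover_geometry(kept_frags, config))
    } else {
      geom <- exo_process(frags, config)
    }
    n_inner_lost <- sum(!geom$kept)
    geom <- geom[geom$kept, , drop = FALSE]
    n_before_edge <- nrow(geom)
    geom <- filter_edge_geometry(geom, config, L)
    records <- apply_barcode_scheme(geom, genome, config)
    n_molecules <- nrow(records)
    records <- pcr_duplicate(records, config)

    truth <- records[, c("molecule_id", "origin_site", "shoulder",
                         "carryover", "barcode_trim_k", "duplicate_of")]
    tags <- tag_set(records, metadata = list(
      version = config$version,
      source = "simulate_library",
      n_fragments = nrow(frags),
      n_tagmented = n_tagmented,
      n_inner_lost = n_inner_lost,
      n_edge_lost = n_before_edge - nrow(geom),
      n_molecules = n_molecules,
      n_input = nrow(records),
      n_after_dedupe = NA_integer_,
      seed = config$seed
    ))
    list(tags = tags, truth = truth, fragments = frags, config = config)
  })
}
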