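test_that("sim_config validates fields and applies version defaults", {
  cfg <- sim_config("exo5.0")
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$read_len, 40L)
  expect_equal(ncol(cfg$tn5_pwm), 19L)
  expect_equal(sim_config("exo4.0")$p_inner_ligation, 0.10)
  expect_equal(sim_config("exo5.0")$p_inner_ligation, 1.0)
  expect_gt(sim_config("exo4.1")$p_shoulder, sim_config("exo5.0")$p_shoulder)
  expect_error(sim_config("exo5.0", p_shoulder = 2), "p_shoulder")
  expect_error(sim_config("exo5.0", dup_mean = 0.5), "dup_mean")
  expect_error(sim_config("bogus"), "version|arg")
  bad_pwm <- matrix(0.25, 4, 10, dimnames = list(c("A", "C", "G", "T")))
  expect_error(sim_config("exo3.1", tn5_pwm = bad_pwm), "tn5_pwm")
})

test_that("config YAML and JSON round-trip with full validation", {
  cfg <- sim_config("nexus", n_fragments = 1234L, p_overtrim = 0.42,
                    seed = 99L)
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    write_sim_config(cfg, path)
    cfg2 <- read_sim_config(path)
    expect_equal(cfg2$version, "nexus")
    expect_equal(cfg2$n_fragments, 1234L)
    expect_equal(cfg2$p_overtrim, 0.42)
    expect_equal(cfg2$seed, 99L)
    expect_equal(unname(cfg2$tn5_pwm), unname(cfg$tn5_pwm),
                 tolerance = 1e-6)
  }
})

test_that("sonication fragment sizes honor the 100-500 bp clipping", {
  fx <- fixture_genome()
  cfg <- sim_config("seq", n_fragments = 10000L, seed = 21L)
  set.seed(21)
  frags <- simulate_fragments(fx$sequence, fx$sites, cfg)
  sizes <- frags$end - frags$start
  expect_true(all(sizes >= 100 & sizes <= 500))
  expect_equal(nrow(frags), 10000L)
})

test_that("background-only configuration carries no crosslinks", {
  fx <- fixture_genome()
  cfg <- sim_config("exo5.0", n_fragments = 500L, background_frac = 1,
                    enrichment = 1, seed = 3L)
  set.seed(3)
  frags <- simulate_fragments(fx$sequence, fx$sites, cfg)
  expect_true(all(is.na(frags$xl_fwd)))
  expect_true(all(is.na(frags$xl_rev)))
  expect_true(all(frags$origin_site == "background"))
})

test_that("site overlap fraction matches the weighted-sampling expectation", {
  g <- generate_genome(1e5, seed = 31)
  p <- plant_motifs(g, default_motif(), n_sites = 10, min_spacing = 2000,
                    seed = 32)
  cfg <- sim_config("exo5.0", n_fragments = 20000L, enrichment = 50,
                    background_frac = 0.5, seed = 33L)
  set.seed(33)
  frags <- simulate_fragments(p$sequence, p$sites, cfg)
  site_ir <- IRanges::IRanges(p$sites$start + 1L, p$sites$end)
  frag_ir <- IRanges::IRanges(frags$start + 1L, frags$end)
  observed <- mean(IRanges::countOverlaps(frag_ir, site_ir) > 0)
  expected <- 0.5 * 50 / (0.5 * 50 + 0.5)
  se <- sqrt(expected * (1 - expected) / nrow(frags))
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("exonuclease stop geometry follows crosslink - stop_offset", {
  frag <- data.frame(chrom = "chrS", start = 1000L, end = 1300L,
                     origin_site = "site_0001", mid = NA_integer_,
                     xl_fwd = 1150L, xl_rev = NA_integer_)
  cfg <- sim_config("exo5.0", p_shoulder = 0, p_inner = 0)
  geom <- exo_process(frag, cfg)
  expect_equal(geom$r1_pos5, 1144L)
  expect_equal(geom$r1_strand, "+")
  expect_equal(geom$r2_pos5, 1299L)
  expect_equal(geom$r2_strand, "-")

  # reverse-strand crosslink mirrors the geometry
  frag_r <- transform(frag, xl_fwd = NA_integer_, xl_rev = 1150L)
  geom_r <- exo_process(frag_r, cfg)
  expect_equal(geom_r$r1_pos5, 1156L)
  expect_equal(geom_r$r1_strand, "-")
  expect_equal(geom_r$r2_pos5, 1000L)
})

test_that("failed digestion and control protocols give sonication ends", {
  frag <- data.frame(chrom = "chrS", start = 1000L, end = 1300L,
                     origin_site = "site_0001", mid = NA_integer_,
                     xl_fwd = 1150L, xl_rev = NA_integer_)
  geom <- exo_process(frag, sim_config("exo5.0", p_shoulder = 1,
                                       p_inner = 0))
  expect_equal(geom$r1_pos5, 1000L)
  expect_true(geom$shoulder)
  geom_seq <- exo_process(frag, sim_config("seq"))
  expect_true(geom_seq$r1_pos5 %in% c(1000L, 1299L))
  expect_false(geom_seq$shoulder)
})

test_that("stop coordinates outside the fragment are an error", {
  frag <- data.frame(chrom = "chrS", start = 1000L, end = 1010L,
                     origin_site = "s", mid = NA_integer_,
                     xl_fwd = 1002L, xl_rev = NA_integer_)
  cfg <- sim_config("exo5.0", p_shoulder = 0, p_inner = 0)
  expect_error(exo_process(frag, cfg), "outside fragment")
})

test_that("tagmentation probability follows 1 - (1-p)^L", {
  g <- generate_genome(5000, seed = 41)
  mk_frags <- function(len, n) {
    data.frame(chrom = "chrS", start = 100L, end = 100L + len,
               origin_site = "background", mid = NA_integer_,
               xl_fwd = NA_integer_, xl_rev = NA_integer_)[rep(1, n), ]
  }
  uniform_pwm <- matrix(0.25, 4, 19, dimnames = list(c("A", "C", "G", "T")))
  cfg <- sim_config("mentation", p_tagment_per_bp = 0.01,
                    tn5_pwm = uniform_pwm)
  set.seed(42)
  for (len in c(100L, 300L)) {
    frags <- tagment(mk_frags(len, 4000L), cfg, g)
    expected <- 1 - 0.99^len
    se <- sqrt(expected * (1 - expected) / 4000)
    expect_lt(abs(mean(frags$tagmented) - expected), 3 * se)
  }
})

test_that("uniform cut-site preference gives uniform cut positions", {
  g <- generate_genome(1000, seed = 43)
  n <- 20000L
  frags <- data.frame(chrom = "chrS", start = 300L, end = 519L,
                      origin_site = "background", mid = NA_integer_,
                      xl_fwd = NA_integer_,
                      xl_rev = NA_integer_)[rep(1, n), ]
  uniform_pwm <- matrix(0.25, 4, 19, dimnames = list(c("A", "C", "G", "T")))
  cfg <- sim_config("mentation", p_tagment_per_bp = 0.5,
                    tn5_pwm = uniform_pwm)
  set.seed(44)
  out <- tagment(frags, cfg, g)
  cuts <- out$cut_pos[out$tagmented]
  # eligible window starts: 201 positions; centers span [309, 509]
  expect_true(all(cuts >= 309 & cuts <= 509))
  gof <- suppressWarnings(stats::chisq.test(tabulate(cuts - 308L,
                                                     nbins = 201L)))
  expect_gt(gof$p.value, 0.01)
})

test_that("carryover off means one record per molecule and no flags", {
  lib <- sim_lib("mentation", n = 5000L, seed = 51L, p_carry = 0)
  expect_false(any(lib$tags$records$carryover))
  originals <- lib$tags$records[is.na(lib$tags$records$duplicate_of), ]
  expect_equal(nrow(originals), lib$tags$metadata$n_molecules)
  expect_error(tagment(data.frame(chrom = "chrS", start = 0L, end = 10L,
                                  origin_site = "b", mid = NA_integer_,
                                  xl_fwd = NA_integer_,
                                  xl_rev = NA_integer_),
                       sim_config("mentation"), generate_genome(100, 1)),
               "shorter")
})

test_that("PCR duplication matches its shifted-Poisson expectation", {
  recs <- empty_tag_records()
  n <- 10000L
  recs <- data.frame(
    molecule_id = sprintf("m%05d", 1:n), chrom = "chrS",
    r1_pos5 = 1:n, r1_strand = "+", r2_pos5 = 1:n + 100L,
    r2_strand = "-",
    r1_seq = random_base_string(n, 12), r2_seq = random_base_string(n, 12),
    shoulder = FALSE, carryover = FALSE, duplicate_of = NA_character_,
    barcode_trim_k = 0L, origin_site = "background",
    stringsAsFactors = FALSE)
  expect_identical(pcr_duplicate(recs, sim_config("seq", dup_mean = 1)),
                   recs)
  set.seed(52)
  out <- pcr_duplicate(recs, sim_config("seq", dup_mean = 3))
  se <- sqrt(n * 2)  # Var(1 + Pois(2)) = 2 per molecule
  expect_lt(abs(nrow(out) - 3 * n), 3 * se)
  # copies are byte-identical and flagged
  dups <- out[!is.na(out$duplicate_of), ]
  expect_true(all(dups$r1_seq ==
                    recs$r1_seq[match(dups$duplicate_of,
                                      recs$molecule_id)]))
  expect_error(pcr_duplicate(recs, list(dup_mean = 0.9)), "dup_mean")
})

test_that("dedupe inverts PCR duplication for distinct originals", {
  lib <- sim_lib("exo5.0", n = 4000L, seed = 53L, dup_mean = 2.5)
  originals <- lib$tags$records[is.na(lib$tags$records$duplicate_of), ]
  key <- paste(originals$r1_seq, originals$r2_seq)
  # restrict to originals whose sequence pairs are unique, per the contract
  distinct <- originals[key %in% names(which(table(key) == 1L)), ]
  dd <- dedupe(lib$tags, "sequence")$records
  expect_true(all(distinct$molecule_id %in% dd$molecule_id))
  expect_true(all(is.na(dd$duplicate_of) |
                    !dd$molecule_id %in% distinct$molecule_id))
})

test_that("nexus reads carry the CTGA spacer at positions 6-9", {
  lib <- sim_lib("nexus", n = 3000L, seed = 61L, p_overtrim = 0)
  r1 <- lib$tags$records$r1_seq
  expect_true(all(nchar(r1) == 40L))
  expect_true(all(substr(r1, 6, 9) == "CTGA"))
  expect_true(all(lib$tags$records$barcode_trim_k == 0L))
})

test_that("over-trimming erodes the spacer from its 3' end, frame-shifting", {
  lib <- sim_lib("nexus", n = 20000L, seed = 62L, p_overtrim = 0.5)
  r <- lib$tags$records
  expect_true(any(r$barcode_trim_k > 0L))
  expect_true(all(nchar(r$r1_seq) == 40L))
  k1 <- r[r$barcode_trim_k == 1L, ]
  expect_true(all(substr(k1$r1_seq, 6, 8) == "CTG"))
  k2 <- r[r$barcode_trim_k == 2L, ]
  expect_true(all(substr(k2$r1_seq, 6, 7) == "CT"))
  # every untrimmed read passes the filter; every failing read is trimmed
  pass <- as.logical(nexus_filter(r$r1_seq))
  expect_true(all(pass[r$barcode_trim_k == 0L]))
  expect_true(all(r$barcode_trim_k[!pass] > 0L))
  # trim depths are geometric: shallower trims are more frequent
  tab <- table(factor(r$barcode_trim_k, levels = 0:4))
  expect_true(all(diff(as.integer(tab[-1])) <= 0))
})

test_that("the random pentamer displaces mapped stops by exactly 5 bp", {
  fx <- fixture_genome()
  frag <- data.frame(chrom = "chrS", start = 5000L, end = 5300L,
                     origin_site = "s", mid = NA_integer_,
                     xl_fwd = 5150L, xl_rev = NA_integer_)
  out <- lapply(c("exo4.0", "exo5.0"), function(v) {
    cfg <- sim_config(v, p_shoulder = 0, p_inner = 0, dup_mean = 1)
    set.seed(7)
    geom <- exo_process(frag, cfg)
    apply_barcode_scheme(geom, fx$sequence, cfg)
  })
  expect_equal(out[[1]]$r1_pos5, out[[2]]$r1_pos5 - 5L)
  # minus-strand stop displaces in the opposite direction
  frag_r <- transform(frag, xl_fwd = NA_integer_, xl_rev = 5150L)
  out_r <- lapply(c("exo4.0", "exo5.0"), function(v) {
    cfg <- sim_config(v, p_shoulder = 0, p_inner = 0, dup_mean = 1)
    set.seed(7)
    geom <- exo_process(frag_r, cfg)
    apply_barcode_scheme(geom, fx$sequence, cfg)
  })
  expect_equal(out_r[[1]]$r1_pos5, out_r[[2]]$r1_pos5 + 5L)
})

test_that("simulated libraries are deterministic under the config seed", {
  fx <- fixture_genome()
  cfg <- sim_config("exo5.0", n_fragments = 2000L, seed = 17L)
  lib1 <- simulate_library(fx$sequence, fx$sites, cfg)
  lib2 <- simulate_library(fx$sequence, fx$sites, cfg)
  expect_identical(lib1$tags$records, lib2$tags$records)
  expect_identical(lib1$truth, lib2$truth)
})

test_that("tagmentation length selection raises the emitted insert size", {
  lib <- sim_lib("mentation", n = 50000L, seed = 101L)
  input_mean <- mean(lib$fragments$end - lib$fragments$start)
  emitted <- insert_sizes(dedupe(lib$tags))
  se <- stats::sd(emitted) / sqrt(length(emitted))
  expect_gt(mean(emitted), input_mean + 3 * se)
})

test_that("barcode failure-mode presence follows the C>T>G>A order", {
  lib <- sim_lib("nexus", n = 30000L, seed = 63L, p_overtrim = 0.5)
  qc <- barcode_qc(dedupe(lib$tags)$records$r1_seq)
  pres <- qc$fail_static_presence
  expect_equal(names(pres), c("C@6", "T@7", "G@8", "A@9"))
  expect_true(all(diff(pres) < 0))  # strictly decreasing C > T > G > A
})
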