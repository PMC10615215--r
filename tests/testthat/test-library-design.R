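test_that("protospacer scan finds every CCN site at all allowed lengths", {
  # one CC early in a 60-nt target with >= 23 nt of room
  seqs <- c(chr = paste0("ATATATATAT", "CCG",
                         paste(rep("ACGT", 12), collapse = ""), "AT"))
  tg <- data.frame(target_id = "g", target_type = "gene", seqid = "chr",
                   strand = "+", start = 1L, end = nchar(seqs[["chr"]]))
  cand <- scan_protospacers(tg, seqs, design_params())
  # CC occurs at position 11 only (ACGT repeats contain no CC)
  expect_equal(sort(unique(cand$length)), 18:23)
  expect_true(all(cand$distance_to_start == 10L))
  # spacer is the reverse complement of the downstream protospacer
  proto18 <- substr(seqs[["chr"]], 14, 31)
  expect_equal(cand$spacer[cand$length == 18],
               rc_chr(proto18))

  # no CC at all -> empty
  no_cc <- c(chr = paste(rep("AT", 40), collapse = ""))
  tg2 <- tg; tg2$end <- 80L
  expect_equal(nrow(scan_protospacers(tg2, no_cc, design_params())), 0L)

  # CC at the end of the target, no room for an 18-nt protospacer
  tail_cc <- c(chr = paste0(paste(rep("AT", 20), collapse = ""), "CC"))
  tg3 <- tg; tg3$end <- 42L
  expect_equal(nrow(scan_protospacers(tg3, tail_cc, design_params())), 0L)

  expect_error(scan_protospacers(transform(tg, end = 1000L), seqs,
                                 design_params()),
               "outside sequence bounds")
})

test_that("composition filters flag GC, homopolymers, bad seeds and length", {
  base <- data.frame(target_id = "g",
                     spacer = "GCGCAGCGATCGATCGATAC", pam = "TGG",
                     length = 20L, strand = "+", start = 0L,
                     distance_to_start = 0L, gc = 0.5, seqid = "chr",
                     site_strand = "-", site_pos = 1L, flank5 = "", flank3 = "",
                     filter_flags = "", stringsAsFactors = FALSE)
  p <- design_params(bad_seeds = c("GATAC"))
  # bad seed is the PAM-proximal (last) 5-mer
  expect_match(composition_filter(base, p)$filter_flags, "bad_seed")

  run_g <- base; run_g$spacer <- "ATATGGGGGGATATATCGCG"
  expect_match(composition_filter(run_g, design_params())$filter_flags,
               "homopolymer")
  run_t <- base; run_t$spacer <- "GCGCGCTTTTGCGCGCGCAT"
  expect_match(composition_filter(run_t, design_params())$filter_flags,
               "homopolymer")

  low_gc <- base; low_gc$spacer <- "ATATATATATATATGCGCGC"  # GC = 0.30
  expect_match(composition_filter(low_gc, design_params())$filter_flags, "gc")

  clean <- base; clean$spacer <- "GAGAGCGCGCATATATATCG"  # GC = 0.5, no runs
  expect_equal(composition_filter(clean, design_params())$filter_flags, "")

  bad_chr <- base; bad_chr$spacer <- "GCGCNGCGATCGATCGATAC"
  expect_error(composition_filter(bad_chr, design_params()), "non-ACGT")
})

test_that("off-target flags follow the 15-mer Hamming rule at NGG and NAG PAMs", {
  set.seed(5)
  filler <- function(n) paste(sample(c("A", "C"), n, replace = TRUE),
                              collapse = "")
  spacer <- "GTCAGTCAGGACGTTACGGT"
  seed15 <- substr(spacer, 6, 20)
  # genome: the intended site (CCN + revcomp(spacer)) plus a decoy where
  # seed15 sits next to an AG PAM (forward strand: seed then NAG)
  own_site <- paste0("CCT", rc_chr(spacer))
  decoy_exact <- paste0(seed15, "TAG")
  g1 <- c(chr = paste0(filler(30), own_site, filler(30), decoy_exact,
                       filler(10)))
  cand <- data.frame(target_id = "g", spacer = spacer, pam = "AGG",
                     length = 20L, strand = "+", start = 0L,
                     distance_to_start = 0L, gc = 0.55, seqid = "chr",
                     site_strand = "-", site_pos = 31L, flank5 = "",
                     flank3 = "", filter_flags = "", stringsAsFactors = FALSE)
  out <- offtarget_screen(cand, g1, design_params())
  expect_match(out$filter_flags, "off_target")

  # two mismatches in the decoy seed -> no flag
  seed_mm2 <- paste0("GG", substr(seed15, 3, 15))
  g2 <- c(chr = paste0(filler(30), own_site, filler(30),
                       paste0(seed_mm2, "TAG"), filler(10)))
  out2 <- offtarget_screen(cand, g2, design_params())
  expect_false(grepl("off_target", out2$filter_flags))

  expect_error(offtarget_screen(cand, c(chr = ""), design_params()), "empty")
})

test_that("greedy spacing selection follows the hand-traced rule", {
  starts <- c(0L, 3L, 10L, 12L, 20L, 40L, 60L)
  cand <- data.frame(target_id = "g", spacer = strrep("ACGT", 5), pam = "TGG",
                     length = 20L, strand = "+", start = starts,
                     distance_to_start = starts, gc = 0.5, seqid = "chr",
                     site_strand = "-", site_pos = starts + 1L,
                     flank5 = "", flank3 = "", filter_flags = "",
                     stringsAsFactors = FALSE)
  sel <- select_guides(cand, design_params())
  expect_equal(sel$distance_to_start, c(0L, 10L, 20L, 40L, 60L))
  expect_equal(sel$position_index, 1:5)

  one <- select_guides(cand[1, ], design_params())
  expect_equal(one$position_index, 1L)

  close_pair <- select_guides(cand[3:4, ], design_params())
  expect_equal(close_pair$distance_to_start, 10L)
})

test_that("designer output matches the exhaustive brute-force oracle on random genomes", {
  p <- design_params()
  for (seed in c(101L, 202L)) {
    genome_str <- rand_genome(20000L, seed)
    genome <- c(chr = genome_str)
    set.seed(seed + 1L)
    starts <- sort(sample(500:18000, 6L))
    targets <- data.frame(
      target_id = sprintf("t%d", seq_along(starts)), target_type = "gene",
      seqid = "chr", strand = rep(c("+", "-"), 3L),
      start = starts, end = pmin(19900L, starts + 600L),
      stringsAsFactors = FALSE)
    lib <- design_library(genome, targets, p)
    for (i in seq_len(nrow(targets))) {
      expected <- oracle_design_target(genome_str, targets[i, ],
                                       bad_seeds = p$bad_seeds)
      got <- lib$spacer[lib$target_id == targets$target_id[i]]
      expect_equal(got, expected,
                   info = sprintf("seed %d target %d", seed, i))
    }
  }
})

test_that("designer invariants hold: filters, spacing, cap, monotone guide count", {
  p <- design_params()
  genome <- c(chr = rand_genome(8000L, 77L))
  lens <- c(60L, 150L, 400L, 1200L)
  n_guides <- integer(length(lens))
  for (k in seq_along(lens)) {
    tg <- data.frame(target_id = "t", target_type = "gene", seqid = "chr",
                     strand = "+", start = 3000L, end = 3000L + lens[k] - 1L)
    lib <- design_library(genome, tg, p)
    n_guides[k] <- nrow(lib)
    expect_lte(nrow(lib), 5L)
    if (nrow(lib) > 1L) {
      d <- sort(lib$distance_to_start)
      expect_true(all(diff(d) >= p$min_spacing))
    }
    # no selected guide violates a composition filter
    if (nrow(lib) > 0L) {
      cand <- data.frame(target_id = "t", spacer = lib$spacer, pam = lib$pam,
                         length = nchar(lib$spacer), strand = "+",
                         start = lib$distance_to_start,
                         distance_to_start = lib$distance_to_start,
                         gc = NA_real_, seqid = "chr",
                         site_strand = lib$site_strand,
                         site_pos = lib$site_pos,
                         flank5 = "", flank3 = "", filter_flags = "",
                         stringsAsFactors = FALSE)
      expect_true(all(composition_filter(cand, p)$filter_flags == ""))
    }
  }
  # shorter targets never get more guides
  expect_true(all(diff(n_guides) >= 0L))
})
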