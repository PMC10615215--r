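# sgRNA library design: protospacer scan, composition filters, off-target
# seed screen, and spacing-aware selection of up to 5 guides per target.
#
# Sequence conventions used throughout this file:
#   * Protospacers are found by scanning the coding strand of a target for
#     the pattern 5'-CCN-(N18..N23)-3'. The CCN is the reverse complement of
#     an NGG PAM, so the guide binds the coding (non-template) strand and the
#     repression machinery blocks transcription elongation.
#   * Spacers are stored 5'->3' with the 3' end PAM-proximal (the SpCas9
#     seed is therefore the spacer suffix). The bad-seed window is the last
#     5 nt of the spacer; the off-target seed is the last 15 nt.
#   * Genomic sites are keyed by (seqid, strand carrying protospacer+PAM,
#     forward coordinate of the PAM triplet's lowest-coordinate base), so
#     the intended site can be excluded from its own off-target scan by
#     coordinate identity (duplicated loci still flag each other).

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

gc_fraction <- function(spacer) {
  chars <- strsplit(spacer, "", fixed = TRUE)[[1L]]
  sum(chars %in% c("G", "C")) / length(chars)
}

# default PAM-proximal 5-mers associated with dCas9 toxicity irrespective of
# target ("bad seeds"); configurable, any 5-nt set may be supplied
DEFAULT_BAD_SEEDS <- c("AGGAA", "TAGGA", "ACCCA", "TTGGA", "GAGGC")

#' Designer parameters
#'
#' Bundles the rule set of the sgRNA designer: composition bounds, the
#' configurable bad-seed blocklist, homopolymer limits, the off-target seed
#' rule (15 nt adjacent to the PAM, at most 1 mismatch, NGG or NAG PAM on
#' either strand), minimum spacing between selected guides, and the maximum
#' number of guides per target.
#'
#' @param gc_min,gc_max Allowed GC fraction of the spacer (defaults 0.40 and
#'   0.80).
#' @param len_min,len_max Allowed spacer length in nt (defaults 18 and 23).
#' @param bad_seeds Character vector of forbidden 5-nt PAM-proximal seeds.
#' @param forbid_g_run Minimum run of consecutive G that disqualifies a
#'   spacer (default 6).
#' @param forbid_t_run Minimum run of consecutive T that disqualifies a
#'   spacer (default 4).
#' @param seed_len Length of the PAM-adjacent region screened for off-targets
#'   (default 15).
#' @param max_seed_mismatch Off-target sites within this Hamming distance of
#'   the seed are disqualifying (default 1).
#' @param pams_offtarget PAM patterns considered in the off-target scan
#'   (default `c("NGG", "NAG")`).
#' @param min_spacing Minimum distance in bp between starts of selected
#'   guides (default 5).
#' @param max_guides Maximum guides selected per target (default 5).
#' @param circular Treat genome sequences as circular in the off-target scan
#'   (default `FALSE`; linear).
#' @return A list of class `design_params`.
#' @export
design_params <- function(gc_min = 0.40, gc_max = 0.80,
                          len_min = 18L, len_max = 23L,
                          bad_seeds = DEFAULT_BAD_SEEDS,
                          forbid_g_run = 6L, forbid_t_run = 4L,
                          seed_len = 15L, max_seed_mismatch = 1L,
                          pams_offtarget = c("NGG", "NAG"),
                          min_spacing = 5L, max_guides = 5L,
                          circular = FALSE) {
  stopifnot(gc_min >= 0, gc_min < gc_max, gc_max <= 1, len_min <= len_max)
  structure(list(gc_min = gc_min, gc_max = gc_max,
                 len_min = as.integer(len_min), len_max = as.integer(len_max),
                 bad_seeds = toupper(bad_seeds),
                 forbid_g_run = as.integer(forbid_g_run),
                 forbid_t_run = as.integer(forbid_t_run),
                 seed_len = as.integer(seed_len),
                 max_seed_mismatch = as.integer(max_seed_mismatch),
                 pams_offtarget = pams_offtarget,
                 min_spacing = as.integer(min_spacing),
                 max_guides = as.integer(max_guides),
                 circular = circular),
            class = "design_params")
}

#' Scan a target for candidate protospacers
#'
#' Scans the coding strand of one target for the pattern
#' 5'-CCN-(N18..N23)-3' (an NGG PAM on the opposite strand) and emits one
#' candidate per site and allowed spacer length. The protospacer must lie
#' entirely within the target. `distance_to_start` is the 0-based distance
#' of the CCN motif from the annotated start.
#'
#' @param target One row of a target table (see [read_targets()]).
#' @param sequence Named character vector of reference sequences (names are
#'   seqids), or a single unnamed sequence.
#' @param params A [design_params()] object.
#' @return `data.frame` of candidates with columns `target_id`, `spacer`,
#'   `pam`, `length`, `strand`, `start` (0-based position of the site within
#'   the target, equal to `distance_to_start`), `distance_to_start`, `gc`,
#'   `seqid`, `site_strand`, `site_pos` (genomic site key), `flank5`,
#'   `flank3`, and `filter_flags` (empty at this stage).
#' @export
scan_protospacers <- function(target, sequence, params = design_params()) {
  if (is.null(names(sequence)) && length(sequence) == 1L) {
    names(sequence) <- target$seqid
  }
  if (!target$seqid %in% names(sequence)) {
    stop("sequence '", target$seqid, "' not provided")
  }
  ref <- toupper(sequence[[target$seqid]])
  if (is.na(target$start) || is.na(target$end) ||
      target$start < 1L || target$end > nchar(ref)) {
    stop("target '", target$target_id, "' outside sequence bounds")
  }
  region <- substr(ref, target$start, target$end)
  coding <- if (target$strand == "+") region else revcomp(region)
  n <- nchar(coding)
  chars <- strsplit(coding, "", fixed = TRUE)[[1L]]
  cc_pos <- which(chars == "C")
  cc_pos <- cc_pos[cc_pos < n & chars[pmin(cc_pos + 1L, n)] == "C"]
  rows <- list()
  for (i in cc_pos) {
    if (i + 2L > n) next
    for (L in params$len_min:params$len_max) {
      if (i + 2L + L > n) next
      proto <- substr(coding, i + 3L, i + 2L + L)
      spacer <- revcomp(proto)
      pam <- revcomp(substr(coding, i, i + 2L))
      # genomic key of the protospacer+PAM strand site (see header comment)
      if (target$strand == "+") {
        site_strand <- "-"
        site_pos <- target$start + i - 1L
      } else {
        site_strand <- "+"
        site_pos <- target$end - i - 1L
      }
      # genomic flanks (coding-strand orientation) for ML feature windows
      fl5 <- flank_coding(ref, target, i, "5p", 12L)
      fl3 <- flank_coding(ref, target, i + 2L + L, "3p", 12L)
      rows[[length(rows) + 1L]] <- data.frame(
        target_id = target$target_id, spacer = spacer, pam = pam,
        length = L, strand = target$strand,
        start = i - 1L, distance_to_start = i - 1L,
        gc = gc_fraction(spacer),
        seqid = target$seqid, site_strand = site_strand,
        site_pos = site_pos,
        flank5 = fl5, flank3 = fl3,
        filter_flags = "", stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(empty_candidates())
  }
  do.call(rbind, rows)
}

empty_candidates <- function() {
  data.frame(target_id = character(), spacer = character(), pam = character(),
             length = integer(), strand = character(), start = integer(),
             distance_to_start = integer(), gc = numeric(),
             seqid = character(), site_strand = character(),
             site_pos = integer(), flank5 = character(), flank3 = character(),
             filter_flags = character(), stringsAsFactors = FALSE)
}

# flank of the CCN..protospacer block in coding-strand orientation; clipped
# at the reference bounds
flank_coding <- function(ref, target, coding_pos, side, width) {
  # map a coding-strand position to forward genomic coordinates
  if (target$strand == "+") {
    g <- target$start + coding_pos - 1L
    if (side == "5p") {
      lo <- max(1L, g - width); hi <- g - 1L
      if (hi < lo) return("")
      substr(ref, lo, hi)
    } else {
      lo <- g + 1L; hi <- min(nchar(ref), g + width)
      if (hi < lo) return("")
      substr(ref, lo, hi)
    }
  } else {
    g <- target$end - coding_pos + 1L
    if (side == "5p") {
      lo <- g + 1L; hi <- min(nchar(ref), g + width)
      if (hi < lo) return("")
      revcomp(substr(ref, lo, hi))
    } else {
      lo <- max(1L, g - width); hi <- g - 1L
      if (hi < lo) return("")
      revcomp(substr(ref, lo, hi))
    }
  }
}

has_run <- function(spacer, base, len) {
  grepl(strrep(base, len), spacer, fixed = TRUE)
}

#' Apply composition filters to candidates
#'
#' Flags candidates for GC fraction outside the allowed band, homopolymer
#' runs (>= 6 consecutive G or >= 4 consecutive T by default), a
#' PAM-proximal 5-mer on the bad-seed blocklist, or spacer length outside
#' bounds. Flags accumulate in the `filter_flags` column (comma-separated);
#' a candidate is accepted iff the column stays empty.
#'
#' @param candidates Candidate `data.frame` from [scan_protospacers()].
#' @param params A [design_params()] object.
#' @return The candidates with updated `filter_flags`.
#' @export
composition_filter <- function(candidates, params = design_params()) {
  if (nrow(candidates) == 0L) return(candidates)
  for (i in seq_len(nrow(candidates))) {
    sp <- candidates$spacer[i]
    if (grepl("[^ACGT]", sp)) {
      stop("non-ACGT character in spacer '", sp, "'")
    }
    flags <- strsplit(candidates$filter_flags[i], ",", fixed = TRUE)[[1L]]
    L <- nchar(sp)
    if (L < params$len_min || L > params$len_max) flags <- c(flags, "length")
    gc <- gc_fraction(sp)
    if (gc < params$gc_min || gc > params$gc_max) flags <- c(flags, "gc")
    if (has_run(sp, "G", params$forbid_g_run) ||
        has_run(sp, "T", params$forbid_t_run)) {
      flags <- c(flags, "homopolymer")
    }
    seed5 <- substr(sp, L - 4L, L)   # PAM-proximal 5-mer
    if (seed5 %in% params$bad_seeds) flags <- c(flags, "bad_seed")
    candidates$filter_flags[i] <- paste(unique(flags[flags != ""]),
                                        collapse = ",")
  }
  candidates
}

#' Enumerate PAM-adjacent sites in a genome
#'
#' Lists every NGG/NAG (configurable) PAM occurrence on both strands of each
#' sequence together with the `seed_len`-nt protospacer region adjacent to
#' the PAM (read 5'->3' on the protospacer strand, PAM-proximal base last).
#' Sites too close to a sequence end to have a full seed are skipped (with
#' `circular = TRUE` in the parameters, the sequence wraps instead).
#'
#' @param genome Named character vector of sequences.
#' @param params A [design_params()] object.
#' @return `data.frame` with columns `seqid`, `strand`, `pos` (forward
#'   coordinate of the PAM triplet's lowest-coordinate base), `pam`, `seed`.
#' @export
enumerate_pam_sites <- function(genome, params = design_params()) {
  if (length(genome) == 0L || all(nchar(genome) == 0L)) {
    stop("genome is empty")
  }
  sl <- params$seed_len
  # forward patterns: PAM on forward strand is N[GA]G at pos j..j+2 with the
  # seed ending at j-1; PAM on reverse strand appears on the forward strand
  # as C[CT]N at j..j+2 with the seed being revcomp of j+3..j+2+sl
  fwd_mid <- sub("^N(.)G$", "\\1", params$pams_offtarget)  # G or A
  out <- list()
  for (sq in names(genome)) {
    s <- toupper(genome[[sq]])
    n <- nchar(s)
    work <- if (isTRUE(params$circular)) paste0(s, substr(s, 1L, sl + 2L)) else s
    chars <- strsplit(work, "", fixed = TRUE)[[1L]]
    m <- length(chars)
    # forward-strand PAMs: positions j (1-based, within original seq)
    j <- which(chars[seq_len(min(n, m - 2L))] != "" )
    j <- j[j + 2L <= m]
    is_pam_f <- chars[j + 1L] %in% fwd_mid & chars[j + 2L] == "G"
    jf <- j[is_pam_f]
    if (isTRUE(params$circular)) {
      # seed may wrap the origin: prepend the suffix
      work5 <- paste0(substr(s, n - sl + 1L, n), s)
      offset <- sl
    } else {
      work5 <- s
      offset <- 0L
    }
    jf_ok <- jf[jf - sl >= 1L - offset]
    if (length(jf_ok) > 0L) {
      seeds <- substring(work5, jf_ok + offset - sl, jf_ok + offset - 1L)
      pams <- substring(work, jf_ok, jf_ok + 2L)
      out[[length(out) + 1L]] <- data.frame(
        seqid = sq, strand = "+", pos = jf_ok, pam = pams, seed = seeds,
        stringsAsFactors = FALSE)
    }
    # reverse-strand PAMs: forward motif C[CT]N
    is_pam_r <- chars[j] == "C" & chars[j + 1L] %in% c("C", "T")
    jr <- j[is_pam_r]
    jr_ok <- jr[jr + 2L + sl <= m]
    if (length(jr_ok) > 0L) {
      seeds <- revcomp(substring(work, jr_ok + 3L, jr_ok + 2L + sl))
      pams <- revcomp(substring(work, jr_ok, jr_ok + 2L))
      out[[length(out) + 1L]] <- data.frame(
        seqid = sq, strand = "-", pos = jr_ok, pam = pams, seed = seeds,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(seqid = character(), strand = character(),
                      pos = integer(), pam = character(), seed = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Screen candidates for off-target seed matches
#'
#' Sets the `off_target` flag on any candidate whose PAM-adjacent seed
#' (last `seed_len` nt of the spacer) occurs, with at most
#' `max_seed_mismatch` mismatches, next to an NGG or NAG PAM anywhere in the
#' genome on either strand — excluding the candidate's own intended site,
#' identified by genomic coordinates (not sequence), so that duplicated loci
#' flag each other.
#'
#' @param candidates Candidate `data.frame` (needs `seqid`, `site_strand`,
#'   `site_pos` from [scan_protospacers()]).
#' @param genome Named character vector of genome sequences.
#' @param params A [design_params()] object.
#' @param sites Optional precomputed site table from
#'   [enumerate_pam_sites()]; recomputed when `NULL`.
#' @return The candidates with updated `filter_flags`.
#' @export
offtarget_screen <- function(candidates, genome, params = design_params(),
                             sites = NULL) {
  if (nrow(candidates) == 0L) return(candidates)
  if (is.null(sites)) sites <- enumerate_pam_sites(genome, params)
  sl <- params$seed_len
  site_mat <- matrix(unlist(strsplit(sites$seed, "", fixed = TRUE)),
                     nrow = sl)
  for (i in seq_len(nrow(candidates))) {
    sp <- candidates$spacer[i]
    L <- nchar(sp)
    seed <- substr(sp, L - sl + 1L, L)
    cch <- strsplit(seed, "", fixed = TRUE)[[1L]]
    mism <- colSums(site_mat != cch)
    hit <- mism <= params$max_seed_mismatch
    own <- sites$seqid == candidates$seqid[i] &
      sites$strand == candidates$site_strand[i] &
      sites$pos == candidates$site_pos[i]
    if (any(hit & !own)) {
      flags <- strsplit(candidates$filter_flags[i], ",", fixed = TRUE)[[1L]]
      flags <- unique(c(flags[flags != ""], "off_target"))
      candidates$filter_flags[i] <- paste(flags, collapse = ",")
    }
  }
  candidates
}

# one candidate per site: among passing lengths keep the one closest to
# 20 nt (canonical spacer length); ties broken toward the shorter spacer
collapse_lengths <- function(candidates) {
  if (nrow(candidates) == 0L) return(candidates)
  keep <- unlist(lapply(split(seq_len(nrow(candidates)),
                              candidates$start), function(idx) {
    sub <- candidates[idx, ]
    ord <- order(abs(sub$length - 20L), sub$length)
    idx[ord[1L]]
  }))
  out <- candidates[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select up to `max_guides` spaced guides per target
#'
#' Greedy selection in order of increasing distance to the annotated start:
#' a candidate is skipped if its site start is closer than `min_spacing` bp
#' to any already-selected guide. Selected guides receive `position_index`
#' 1..k by proximity to the start (1 = most promoter-proximal).
#'
#' @param candidates Accepted candidates (empty `filter_flags`) for a single
#'   target, at most one per site.
#' @param params A [design_params()] object.
#' @return `data.frame` of selected guides with columns `sgrna_id`,
#'   `target_id`, `spacer`, `pam`, `position_index`, `distance_to_start`,
#'   `flank5`, `flank3` (plus site bookkeeping columns).
#' @export
select_guides <- function(candidates, params = design_params()) {
  if (nrow(candidates) == 0L) return(candidates_to_records(empty_candidates()))
  if (any(candidates$filter_flags != "")) {
    stop("select_guides expects only candidates passing all filters")
  }
  candidates <- candidates[order(candidates$distance_to_start), , drop = FALSE]
  chosen <- integer()
  for (i in seq_len(nrow(candidates))) {
    st <- candidates$start[i]
    if (length(chosen) > 0L &&
        any(abs(candidates$start[chosen] - st) < params$min_spacing)) next
    chosen <- c(chosen, i)
    if (length(chosen) >= params$max_guides) break
  }
  sel <- candidates[chosen, , drop = FALSE]
  sel$position_index <- seq_len(nrow(sel))
  candidates_to_records(sel)
}

candidates_to_records <- function(sel) {
  if (nrow(sel) == 0L) {
    return(data.frame(sgrna_id = character(), target_id = character(),
                      spacer = character(), pam = character(),
                      position_index = integer(), distance_to_start = integer(),
                      flank5 = character(), flank3 = character(),
                      seqid = character(), site_strand = character(),
                      site_pos = integer(), stringsAsFactors = FALSE))
  }
  data.frame(
    sgrna_id = sprintf("%s_%d", sel$target_id, sel$position_index),
    target_id = sel$target_id, spacer = sel$spacer, pam = sel$pam,
    position_index = sel$position_index,
    distance_to_start = sel$distance_to_start,
    flank5 = sel$flank5, flank3 = sel$flank3,
    seqid = sel$seqid, site_strand = sel$site_strand, site_pos = sel$site_pos,
    stringsAsFactors = FALSE)
}

#' Design an sgRNA library for a set of targets
#'
#' Full designer: per target, scan protospacers, apply composition filters,
#' screen off-targets genome-wide, keep one spacer length per site (closest
#' to 20 nt), and select up to 5 guides spaced at least 5 bp apart, indexed
#' by proximity to the start.
#'
#' @param genome Named character vector of genome sequences.
#' @param targets Target table from [read_targets()] (control rows are
#'   ignored by the designer).
#' @param params A [design_params()] object.
#' @return `data.frame` of guide records for all targets.
#' @export
design_library <- function(genome, targets, params = design_params()) {
  sites <- enumerate_pam_sites(genome, params)
  res <- lapply(seq_len(nrow(targets)), function(i) {
    tg <- targets[i, ]
    if (tg$target_type == "control") return(NULL)
    cand <- scan_protospacers(tg, genome, params)
    cand <- composition_filter(cand, params)
    cand <- cand[cand$filter_flags == "", , drop = FALSE]
    cand <- offtarget_screen(cand, genome, params, sites = sites)
    cand <- cand[cand$filter_flags == "", , drop = FALSE]
    cand <- collapse_lengths(cand)
    select_guides(cand, params)
  })
  out <- do.call(rbind, c(res, list(candidates_to_records(empty_candidates()))))
  rownames(out) <- NULL
  out
}

#' Write guide records as a spacer FASTA
#'
#' @param library Guide table from [design_library()].
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_spacer_fasta <- function(library, path) {
  seqs <- Biostrings::DNAStringSet(library$spacer)
  names(seqs) <- library$sgrna_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
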