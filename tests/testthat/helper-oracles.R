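# Independent brute-force oracles and small fixture builders. These
# deliberately avoid the package's code paths (plain loops, substr,
# chartr) so they can serve as ground truth.

rc_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

rand_genome <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

hamming_chr <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

# exhaustive off-target check for one spacer: every position, both strands,
# NGG/NAG PAM, 15-mer Hamming <= 1, own site excluded by coordinates
oracle_offtarget <- function(spacer, genome_str, own_strand, own_pos,
                             seed_len = 15L, max_mm = 1L) {
  L <- nchar(spacer)
  seed <- substr(spacer, L - seed_len + 1L, L)
  n <- nchar(genome_str)
  rcg <- rc_chr(genome_str)
  for (j in seq_len(n - 2L)) {
    # forward-strand PAM at j..j+2
    p2 <- substr(genome_str, j + 1L, j + 1L)
    p3 <- substr(genome_str, j + 2L, j + 2L)
    if ((p2 == "G" || p2 == "A") && p3 == "G" && j - seed_len >= 1L) {
      site_seed <- substr(genome_str, j - seed_len, j - 1L)
      if (!(own_strand == "+" && own_pos == j) &&
          hamming_chr(seed, site_seed) <= max_mm) {
        return(TRUE)
      }
    }
    # reverse-strand PAM: forward coordinates j..j+2 hold C[CT]N
    q1 <- substr(genome_str, j, j)
    q2 <- p2
    if (q1 == "C" && (q2 == "C" || q2 == "T") && j + 2L + seed_len <= n) {
      site_seed <- rc_chr(substr(genome_str, j + 3L, j + 2L + seed_len))
      if (!(own_strand == "-" && own_pos == j) &&
          hamming_chr(seed, site_seed) <= max_mm) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# full designer oracle for one target on one sequence (plain loops)
oracle_design_target <- function(genome_str, tg, bad_seeds,
                                 gc_min = 0.40, gc_max = 0.80,
                                 len_rng = c(18L, 23L), seed_len = 15L,
                                 max_mm = 1L, min_spacing = 5L,
                                 max_guides = 5L) {
  region <- substr(genome_str, tg$start, tg$end)
  coding <- if (tg$strand == "+") region else rc_chr(region)
  n <- nchar(coding)
  sites <- list()
  for (i in seq_len(max(0L, n - 1L))) {
    if (substr(coding, i, i + 1L) != "CC") next
    if (i + 2L > n) next
    best <- NULL
    for (L in len_rng[1L]:len_rng[2L]) {
      if (i + 2L + L > n) next
      proto <- substr(coding, i + 3L, i + 2L + L)
      spacer <- rc_chr(proto)
      ch <- strsplit(spacer, "", fixed = TRUE)[[1L]]
      gc <- sum(ch %in% c("G", "C")) / L
      if (gc < gc_min || gc > gc_max) next
      if (grepl("GGGGGG", spacer, fixed = TRUE)) next
      if (grepl("TTTT", spacer, fixed = TRUE)) next
      if (substr(spacer, L - 4L, L) %in% bad_seeds) next
      if (tg$strand == "+") {
        own_strand <- "-"; own_pos <- tg$start + i - 1L
      } else {
        own_strand <- "+"; own_pos <- tg$end - i - 1L
      }
      if (oracle_offtarget(spacer, genome_str, own_strand, own_pos,
                           seed_len, max_mm)) next
      if (is.null(best) ||
          abs(L - 20L) < abs(best$L - 20L) ||
          (abs(L - 20L) == abs(best$L - 20L) && L < best$L)) {
        best <- list(L = L, spacer = spacer, dist = i - 1L)
      }
    }
    if (!is.null(best)) sites[[length(sites) + 1L]] <- best
  }
  if (length(sites) == 0L) return(character())
  d <- vapply(sites, function(s) s$dist, numeric(1L))
  ord <- order(d)
  chosen <- integer()
  for (k in ord) {
    if (length(chosen) > 0L &&
        any(abs(d[chosen] - d[k]) < min_spacing)) next
    chosen <- c(chosen, k)
    if (length(chosen) >= max_guides) break
  }
  vapply(sites[chosen], function(s) s$spacer, character(1L))
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of C(n+m, n)
# group assignments (tie-free inputs), using the same tail-doubling
# convention as the distribution-based test
oracle_wilcoxon <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  w_all <- apply(combs, 2L, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  if (w_obs > n * m / 2) {
    p <- mean(w_all >= w_obs)
  } else {
    p <- mean(w_all <= w_obs)
  }
  min(1, 2 * p)
}

# BH step-up: p * m / rank with cumulative minimum from the largest p
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# classic quantile normalization by sort/mean/reinsert (average ties)
oracle_quantile_norm <- function(x) {
  ranks <- apply(x, 2L, rank, ties.method = "average")
  sorted <- apply(x, 2L, sort)
  means <- rowMeans(sorted)
  out <- x
  for (j in seq_len(ncol(x))) {
    lookup <- function(r) {
      lo <- floor(r); hi <- ceiling(r)
      (means[lo] + means[hi]) / 2
    }
    out[, j] <- vapply(ranks[, j], lookup, numeric(1L))
  }
  out
}

# trapezoid AUC by the textbook sum
oracle_trapz <- function(t, v) {
  sum(diff(t) * (head(v, -1) + tail(v, -1)) / 2)
}

# small synthetic screen shared by several test files
small_screen <- function(seed = 11L, analytic = TRUE, ...) {
  cfg <- sim_config(n_targets = 25L, n_conditions = 3L, n_controls = 10L,
                    depth = 5e5, replicates = 2L, seed = seed, ...)
  sim <- simulate_library(cfg)
  cm <- simulate_counts(sim$library, sim$truth, cfg, analytic = analytic)
  list(cfg = cfg, sim = sim, cm = cm)
}

write_targets_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
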