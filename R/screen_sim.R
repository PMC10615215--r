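# Synthetic pooled-competition generator. Ground truth is fully known, so
# every downstream stage (quantification, fitness, hit calling, ML) can be
# tested without external sequencing data.
#
# Growth model: turbidostat competition. A mutant with realized fitness s
# changes abundance as 2^(s * g / G) over generations g, G = final
# generation, so the endpoint log2 fold change versus neutral controls
# equals s by construction. Sequencing is a multinomial draw per sample at
# a configured depth; an analytic mode returns expected counts instead for
# exact regression tests.

rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1L))
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a target catalog
#' with up to 5 guides per target plus non-targeting controls, per-position
#' repression efficacy declining with distance from the start codon (median
#' 0.68 at position 1 down to 0.47 at position 5), a mixture distribution of
#' true gene fitness (mostly neutral, a deleterious tail, a small beneficial
#' fraction), sampling at generations 0/4/8/10 with 4 replicates, and
#' multinomial sequencing at a configurable depth.
#'
#' @param n_targets Number of gene targets.
#' @param guides_per_target Guides per target (max 5).
#' @param n_controls Number of non-targeting control sgRNAs (default 10).
#' @param n_conditions Number of cultivation conditions (default 4).
#' @param frac_neutral,frac_deleterious,frac_beneficial Mixture weights of
#'   the true-fitness distribution (defaults 0.7 / 0.25 / 0.05; must sum
#'   to 1). Deleterious fitness is uniform on \[-4, -1\], beneficial on
#'   \[1, 2\], neutral is exactly 0.
#' @param efficacy_by_position Median repression efficacy at guide positions
#'   1..5 (default linear decline 0.68 -> 0.47).
#' @param efficacy_noise SD of the Gaussian jitter around the position
#'   median, clamped to \[0.05, 1\] (default 0.15).
#' @param condition_sd SD of the per-(target, condition) lognormal scaling
#'   of gene fitness (default 0.25); gives each target a cross-condition
#'   fitness profile so that guide-correlation weights are informative.
#' @param generations Sampling generations (default `c(0, 4, 8, 10)`).
#' @param depth Total reads per sample (default 1e6).
#' @param replicates Biological replicates per condition (default 4).
#' @param spacer_len Spacer length for generated guides (default 20).
#' @param flank_len Flank length carried by each guide record (default 12).
#' @param seed Integer seed; every draw is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_targets = 100L, guides_per_target = 5L,
                       n_controls = 10L, n_conditions = 4L,
                       frac_neutral = 0.70, frac_deleterious = 0.25,
                       frac_beneficial = 0.05,
                       efficacy_by_position = seq(0.68, 0.47, length.out = 5L),
                       efficacy_noise = 0.15, condition_sd = 0.25,
                       generations = c(0, 4, 8, 10),
                       depth = 1e6, replicates = 4L,
                       spacer_len = 20L, flank_len = 12L, seed = 1L) {
  if (guides_per_target > 5L) stop("guides_per_target must be <= 5")
  if (depth <= 0) stop("depth must be positive")
  if (is.unsorted(generations) || generations[1L] != 0) {
    stop("generations must be ascending and start at 0")
  }
  fr <- c(frac_neutral, frac_deleterious, frac_beneficial)
  if (abs(sum(fr) - 1) > 1e-8) stop("mixture fractions must sum to 1")
  structure(list(n_targets = as.integer(n_targets),
                 guides_per_target = as.integer(guides_per_target),
                 n_controls = as.integer(n_controls),
                 n_conditions = as.integer(n_conditions),
                 frac_neutral = frac_neutral,
                 frac_deleterious = frac_deleterious,
                 frac_beneficial = frac_beneficial,
                 efficacy_by_position = efficacy_by_position,
                 efficacy_noise = efficacy_noise,
                 condition_sd = condition_sd,
                 generations = generations, depth = depth,
                 replicates = as.integer(replicates),
                 spacer_len = as.integer(spacer_len),
                 flank_len = as.integer(flank_len),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an sgRNA library with known ground truth
#'
#' Generates `n_targets` targets with `guides_per_target` guides each (plus
#' non-targeting controls), random spacer/flank sequences, per-guide
#' efficacies declining with position index, a per-target base fitness drawn
#' from the configured mixture, and a per-(target, condition) fitness matrix
#' obtained by lognormal scaling of the base fitness. Realized per-guide
#' fitness is `s = f_gc * e_i`; controls have `s = 0` in every condition.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `library` (guide records: `sgrna_id`,
#'   `target_id`, `target_type`, `position_index`, `distance_to_start`,
#'   `spacer`, `flank5`, `flank3`) and `truth` (list: `targets` with base
#'   fitness `f_g`, `fitness` matrix target x condition, `sgrnas` with
#'   efficacy `e` and realized fitness matrix `s` sgRNA x condition).
#' @export
simulate_library <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  tids <- sprintf("T%04d", seq_len(cfg$n_targets))
  k <- cfg$guides_per_target
  comp <- sample(c("neutral", "deleterious", "beneficial"),
                 cfg$n_targets, replace = TRUE,
                 prob = c(cfg$frac_neutral, cfg$frac_deleterious,
                          cfg$frac_beneficial))
  f_g <- numeric(cfg$n_targets)
  f_g[comp == "deleterious"] <- stats::runif(sum(comp == "deleterious"), -4, -1)
  f_g[comp == "beneficial"] <- stats::runif(sum(comp == "beneficial"), 1, 2)
  conds <- sprintf("C%02d", seq_len(cfg$n_conditions))
  fit_mat <- matrix(f_g, nrow = cfg$n_targets, ncol = cfg$n_conditions) *
    matrix(exp(stats::rnorm(cfg$n_targets * cfg$n_conditions,
                            sd = cfg$condition_sd)),
           nrow = cfg$n_targets)
  dimnames(fit_mat) <- list(tids, conds)

  lib <- data.frame(
    sgrna_id = sprintf("%s_%d", rep(tids, each = k), rep(seq_len(k), cfg$n_targets)),
    target_id = rep(tids, each = k),
    target_type = "gene",
    position_index = rep(seq_len(k), cfg$n_targets),
    distance_to_start = rep((seq_len(k) - 1L) * 30L, cfg$n_targets),
    stringsAsFactors = FALSE)
  med <- cfg$efficacy_by_position[lib$position_index]
  e <- pmin(1, pmax(0.05, med + stats::rnorm(nrow(lib), sd = cfg$efficacy_noise)))
  s_mat <- fit_mat[lib$target_id, , drop = FALSE] * e
  rownames(s_mat) <- lib$sgrna_id

  if (cfg$n_controls > 0L) {
    ctrl <- data.frame(
      sgrna_id = sprintf("ctrl_%02d", seq_len(cfg$n_controls)),
      target_id = sprintf("ctrl_%02d", seq_len(cfg$n_controls)),
      target_type = "control",
      position_index = 1L, distance_to_start = 0L,
      stringsAsFactors = FALSE)
    lib <- rbind(lib, ctrl)
    s_ctrl <- matrix(0, nrow = cfg$n_controls, ncol = cfg$n_conditions,
                     dimnames = list(ctrl$sgrna_id, conds))
    s_mat <- rbind(s_mat, s_ctrl)
    e <- c(e, rep(NA_real_, cfg$n_controls))
  }
  lib$spacer <- rand_dna(nrow(lib), cfg$spacer_len)
  lib$flank5 <- rand_dna(nrow(lib), cfg$flank_len)
  lib$flank3 <- rand_dna(nrow(lib), cfg$flank_len)

  truth <- list(
    targets = data.frame(target_id = tids, f_g = f_g,
                         class = comp, stringsAsFactors = FALSE),
    fitness = fit_mat,
    sgrnas = data.frame(sgrna_id = lib$sgrna_id, target_id = lib$target_id,
                        e = e, stringsAsFactors = FALSE),
    s = s_mat)
  list(library = lib, truth = truth)
}

#' Simulate sequencing counts for a pooled competition
#'
#' For each condition, replicate and generation `g`, the expected abundance
#' fraction of guide `i` is
#' `p_i(g) = p_i(0) 2^(s_i g / G) / sum_j p_j(0) 2^(s_j g / G)` with `G` the
#' final generation, so a mutant's endpoint log2 fold change versus the
#' neutral controls equals its realized fitness `s_i`. Counts are drawn
#' multinomially at the configured depth (replicates differ only by the
#' draw); with `analytic = TRUE` the expected counts themselves are
#' returned, making the whole downstream pipeline deterministic.
#'
#' @param lib Library table from [simulate_library()].
#' @param truth Truth list from [simulate_library()].
#' @param cfg The [sim_config()] used.
#' @param analytic Return expected (non-integer) counts instead of
#'   multinomial draws.
#' @return A [count_matrix()].
#' @export
simulate_counts <- function(lib, truth, cfg, analytic = FALSE) {
  set.seed(cfg$seed + 1L)
  s <- truth$s[lib$sgrna_id, , drop = FALSE]
  G <- max(cfg$generations)
  n <- nrow(lib)
  p0 <- rep(1 / n, n)
  samples <- expand.grid(replicate = seq_len(cfg$replicates),
                         generation = cfg$generations,
                         condition_id = colnames(s),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_g%d_r%d", samples$condition_id,
                               samples$generation, samples$replicate)
  counts <- matrix(0, nrow = n, ncol = nrow(samples),
                   dimnames = list(lib$sgrna_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    g <- samples$generation[j]
    w <- p0 * 2^(s[, samples$condition_id[j]] * g / G)
    p <- w / sum(w)
    counts[, j] <- if (analytic) cfg$depth * p else
      stats::rmultinom(1L, size = cfg$depth, prob = p)[, 1L]
  }
  meta <- data.frame(sample_id = samples$sample_id,
                     condition_id = samples$condition_id,
                     generation = samples$generation,
                     replicate = samples$replicate,
                     stringsAsFactors = FALSE)
  count_matrix(counts, meta)
}

#' Write a simulated screen to disk
#'
#' Writes counts, sample metadata, library and truth tables as TSV, the
#' on-disk interface of the quantification stage.
#'
#' @param sim List from [simulate_library()].
#' @param cm A [count_matrix()] from [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("counts.tsv", "metadata.tsv", "library.tsv",
                            "truth_sgrna.tsv"))
  counts_df <- data.frame(sgrna_id = rownames(cm$counts), cm$counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(counts_df, paths[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cm$meta, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$library, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tr <- data.frame(sim$truth$sgrnas,
                   sim$truth$s[sim$truth$sgrnas$sgrna_id, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(tr, paths[4L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
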