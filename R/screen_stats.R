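# Significance calling and screen-level statistics: Wilcoxon rank-sum tests
# against non-targeting controls, Benjamini-Hochberg adjustment, the
# combined score S = |F_wmean| * -log10(p_adj), per-class hit summaries,
# condition-effect regression, paired fitness correlations and per-pathway
# medians.

#' Wilcoxon rank-sum test of guide fitness against controls
#'
#' Two-sided Wilcoxon rank-sum p-value comparing the fitness scores of a
#' target's guides (n = 1..5) with the non-targeting control guides
#' (n = 10). The exact null distribution is used when there are no ties and
#' both groups are small (as `stats::wilcox.test` does); with ties, the
#' normal approximation with tie correction applies. If every value in both
#' groups is identical, p = 1 is returned with attribute `tied = TRUE`.
#'
#' @param sgrna_F Guide fitness scores.
#' @param control_F Control fitness scores.
#' @return The two-sided p-value (attribute `tied` when degenerate).
#' @export
wilcoxon_vs_controls <- function(sgrna_F, control_F) {
  if (length(sgrna_F) == 0L || length(control_F) == 0L) {
    stop("both groups must be non-empty")
  }
  if (length(unique(c(sgrna_F, control_F))) == 1L) {
    return(structure(1, tied = TRUE))
  }
  suppressWarnings(
    stats::wilcox.test(sgrna_F, control_F, alternative = "two.sided")$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#' `NA` entries pass through unadjusted (they do not enter the ranking).
#'
#' @param p_values Raw p-values in (0, 1\].
#' @return Adjusted p-values in (0, 1\].
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] <= 0 | p_values[ok] > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  out <- p_values
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Combined significance score
#'
#' `S = |F_wmean| * -log10(p_adj)`, combining effect size and adjusted
#' p-value; S = 4 corresponds to an absolute fitness of 2 at p_adj = 0.01,
#' the usual significance anchor. A zero p_adj is capped at `p_floor` with
#' a warning to keep S finite.
#'
#' @param F_wmean Weighted gene fitness (any sign).
#' @param p_adj Adjusted p-value in (0, 1\].
#' @param p_floor Smallest admissible p_adj (default 1e-300).
#' @return S >= 0 (vectorized).
#' @export
combined_score <- function(F_wmean, p_adj, p_floor = 1e-300) {
  if (any(p_adj <= 0, na.rm = TRUE)) {
    warning("p_adj of 0 capped at p_floor = ", p_floor)
    p_adj <- pmax(p_adj, p_floor)
  }
  abs(F_wmean) * (-log10(p_adj))
}

#' Per-class hit summary
#'
#' A target counts as significant if its combined score reaches the
#' threshold in at least one condition. Percentages are rounded to two
#' decimals, the convention of published per-class summary tables.
#'
#' @param calls Per-(target, condition) table with `target_id` and `S`.
#' @param classes Named character vector mapping target_id to class label.
#' @param threshold Combined-score threshold (default 4).
#' @return `data.frame` with `class`, `n_targets`, `n_significant`,
#'   `percent`.
#' @export
class_summary <- function(calls, classes, threshold = 4) {
  if (!all(calls$target_id %in% names(classes))) {
    miss <- setdiff(calls$target_id, names(classes))[1L]
    stop("target without class label: ", miss)
  }
  sig_by_target <- vapply(split(calls$S, calls$target_id),
                          function(s) any(!is.na(s) & s >= threshold),
                          logical(1L))
  cls <- classes[names(sig_by_target)]
  agg <- lapply(split(sig_by_target, cls), function(x) {
    data.frame(n_targets = length(x), n_significant = sum(x),
               percent = round(100 * sum(x) / length(x), 2L))
  })
  out <- do.call(rbind, agg)
  out <- data.frame(class = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}

#' Per-target condition-effect regression
#'
#' Ordinary least-squares decomposition of each target's fitness profile
#' into the cultivation variables: CO2 level (binary, high = 1), light
#' intensity (numeric photon flux) and the treatment flags, using the
#' condition design table. Errors on a rank-deficient design, listing the
#' aliased terms.
#'
#' @param F_mat Fitness matrix, targets x conditions.
#' @param design Condition design `data.frame` (see
#'   [read_condition_design()]), one row per column of `F_mat`.
#' @param terms Model terms (default CO2, light and all four treatment
#'   flags).
#' @return `data.frame` with one row per (target, term): `estimate`,
#'   `std_error`.
#' @export
condition_regression <- function(F_mat, design,
                                 terms = c("co2_high", "light",
                                           "fluctuating_light", "glucose",
                                           "DCMU", "N_limitation")) {
  design <- design[match(colnames(F_mat), design$condition_id), , drop = FALSE]
  if (anyNA(design$condition_id)) {
    stop("design must describe every condition in the fitness matrix")
  }
  X <- data.frame(co2_high = as.numeric(design$co2 == "high"),
                  light = as.numeric(design$light),
                  fluctuating_light = as.numeric(design$fluctuating_light),
                  glucose = as.numeric(design$glucose),
                  DCMU = as.numeric(design$DCMU),
                  N_limitation = as.numeric(design$N_limitation))
  X <- X[, terms, drop = FALSE]
  mm <- cbind(`(Intercept)` = 1, as.matrix(X))
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1L):ncol(mm)]]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  rows <- lapply(rownames(F_mat), function(tg) {
    fit <- stats::lm(F_mat[tg, ] ~ ., data = X)
    sm <- summary(fit)$coefficients
    data.frame(target_id = tg, term = rownames(sm),
               estimate = sm[, "Estimate"], std_error = sm[, "Std. Error"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation between matched fitness sets
#'
#' Pearson correlation over matched (target, condition) fitness pairs — for
#' example a gene versus its antisense RNA — with the p-value that the
#' correlation is zero.
#'
#' @param set_a,set_b Matched numeric vectors (>= 3 pairs).
#' @return List with `R`, `p` and `n`; `R` is `NA` with attribute
#'   `degenerate = TRUE` if either set has zero variance.
#' @export
paired_fitness_correlation <- function(set_a, set_b) {
  stopifnot(length(set_a) == length(set_b))
  ok <- !is.na(set_a) & !is.na(set_b)
  a <- set_a[ok]; b <- set_b[ok]
  if (length(a) < 3L) stop("need at least 3 matched pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(structure(list(R = NA_real_, p = NA_real_, n = length(a)),
                     degenerate = TRUE))
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  list(R = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Median fitness per pathway and condition
#'
#' @param target_table Per-(target, condition) table with `target_id`,
#'   `condition_id`, `F_wmean`.
#' @param pathways Named character vector mapping target_id to pathway (may
#'   cover only a subset of targets; unmapped targets are dropped).
#' @return `data.frame` with `pathway`, `condition_id`, `median_F`, `n`.
#' @export
pathway_median_fitness <- function(target_table, pathways) {
  sub <- target_table[target_table$target_id %in% names(pathways), ,
                      drop = FALSE]
  if (nrow(sub) == 0L) {
    return(data.frame(pathway = character(), condition_id = character(),
                      median_F = numeric(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  sub$pathway <- pathways[sub$target_id]
  key <- interaction(sub$pathway, sub$condition_id, drop = TRUE)
  rows <- lapply(split(sub, key), function(g) {
    data.frame(pathway = g$pathway[1L], condition_id = g$condition_id[1L],
               median_F = stats::median(g$F_wmean), n = nrow(g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$pathway, out$condition_id), , drop = FALSE]
}
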