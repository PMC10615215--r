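# Fitness scoring: per-sgRNA area-under-the-curve fitness from log2FC
# trajectories, repression efficacy, cross-condition guide correlation, and
# correlation x efficacy weighted gene-level aggregation.

#' Per-sgRNA fitness score from a log2FC trajectory
#'
#' `F = AUC(t, log2FC) * 2 / max(t)`, with the area under the curve taken by
#' the trapezoidal rule over generations. The `2/max(t)` factor makes the
#' score equal to the endpoint log2 fold change for any linear trajectory
#' (the trapezoid is exact for piecewise-linear integrands, and a linear
#' trajectory's AUC is `endpoint * max(t) / 2`).
#'
#' @param times Generations, strictly increasing, first element 0.
#' @param values log2 fold changes at `times` (first element 0 by
#'   construction).
#' @return The fitness score, a scalar.
#' @export
sgrna_fitness <- function(times, values) {
  if (length(times) < 2L) stop("need at least 2 time points")
  if (max(times) == 0) stop("max(times) must be positive")
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  pracma::trapz(times, values) * 2 / max(times)
}

#' Fitness scores for every guide and condition
#'
#' Builds one trajectory per (guide, condition, replicate) from a log2FC
#' matrix — prepending the generation-0 anchor (log2FC = 0) — scores each
#' with [sgrna_fitness()], and averages over replicates.
#'
#' @param l2fc log2FC matrix with a `meta` attribute, as produced by
#'   [log2fc()] (optionally quantile-normalized).
#' @return Matrix of fitness scores, guides x conditions.
#' @export
fitness_scores <- function(l2fc) {
  meta <- attr(l2fc, "meta")
  if (is.null(meta)) stop("l2fc must carry a 'meta' attribute")
  conds <- unique(meta$condition_id)
  out <- matrix(NA_real_, nrow = nrow(l2fc), ncol = length(conds),
                dimnames = list(rownames(l2fc), conds))
  for (cond in conds) {
    sel <- meta$condition_id == cond
    reps <- unique(meta$replicate[sel])
    per_rep <- vapply(reps, function(r) {
      idx <- which(sel & meta$replicate == r)
      idx <- idx[order(meta$generation[idx])]
      times <- c(0, meta$generation[idx])
      apply(l2fc[, idx, drop = FALSE], 1L, function(v) {
        sgrna_fitness(times, c(0, v))
      })
    }, numeric(nrow(l2fc)))
    out[, cond] <- rowMeans(per_rep)
  }
  out
}

#' Repression efficacy of guides sharing a target
#'
#' `E_i = |F_i| / max_j |F_j|` over the guides of one target (one condition
#' or averaged), so the guide with the strongest fitness effect has E = 1
#' and E is always in \[0, 1\]. If every F is zero, all E are 0.
#'
#' @param F_vec Fitness scores of the guides of one target.
#' @return Efficacies in \[0, 1\], same length as `F_vec`.
#' @export
repression_efficacy <- function(F_vec) {
  mx <- max(abs(F_vec))
  if (mx == 0) return(rep(0, length(F_vec)))
  abs(F_vec) / mx
}

#' Rescaled cross-condition correlation of each guide
#'
#' For every guide, the Pearson correlation of its fitness profile across
#' conditions with the mean profile of the other guides of the same target,
#' affinely rescaled from \[-1, 1\] to \[0, 1\] via `(R + 1) / 2`. Guides
#' that are their target's only guide get 1; undefined correlations (zero
#' variance on either side) get 0.5.
#'
#' @param F_mat Fitness matrix, guides x conditions.
#' @param target_ids Target id per row of `F_mat`.
#' @return Named vector of rescaled correlations in \[0, 1\].
#' @export
sgrna_correlation <- function(F_mat, target_ids) {
  stopifnot(nrow(F_mat) == length(target_ids))
  out <- stats::setNames(rep(NA_real_, nrow(F_mat)), rownames(F_mat))
  for (idx in split(seq_len(nrow(F_mat)), target_ids)) {
    if (length(idx) == 1L) { out[idx] <- 1; next }
    for (i in idx) {
      others <- setdiff(idx, i)
      mean_prof <- colMeans(F_mat[others, , drop = FALSE])
      xi <- F_mat[i, ]
      if (ncol(F_mat) < 2L || stats::sd(xi) == 0 || stats::sd(mean_prof) == 0) {
        out[i] <- 0.5
      } else {
        out[i] <- (stats::cor(xi, mean_prof) + 1) / 2
      }
    }
  }
  out
}

#' Weighted gene-level fitness
#'
#' `F_wmean = sum_i(F_i w_i) / n` with `w_i = R_scaled_i * E_i` — the sum of
#' weighted guide scores divided by the guide count `n` (mode `"printed"`,
#' the published formula, which shrinks genes with poorly-performing guides
#' toward 0). Mode `"normalized"` divides by `sum(w)` instead.
#'
#' @param F_list Guide fitness scores.
#' @param w_list Guide weights (same length).
#' @param mode `"printed"` (divide by n) or `"normalized"` (divide by
#'   `sum(w)`).
#' @return Scalar gene fitness.
#' @export
gene_fitness <- function(F_list, w_list, mode = c("printed", "normalized")) {
  mode <- match.arg(mode)
  n <- length(F_list)
  if (n == 0L) stop("no guide fitness values supplied")
  stopifnot(length(w_list) == n)
  if (mode == "printed") {
    sum(F_list * w_list) / n
  } else {
    sw <- sum(w_list)
    if (sw == 0) 0 else sum(F_list * w_list) / sw
  }
}

#' Full fitness table from a fitness matrix
#'
#' Assembles the per-(guide, condition) and per-(target, condition) fitness
#' tables: per-condition efficacy, cross-condition rescaled correlation,
#' weights, weighted gene fitness, and (when control guides are present)
#' Wilcoxon p-values of each target's guide scores against the non-targeting
#' controls with Benjamini-Hochberg adjustment per condition, plus the
#' combined score `S = |F_wmean| * -log10(p_adj)`.
#'
#' @param F_mat Fitness matrix (guides x conditions) from
#'   [fitness_scores()].
#' @param lib Guide table with `sgrna_id`, `target_id` and (for control
#'   detection) optional `target_type`.
#' @param efficacy_pooling `"max_condition"`: weights use each guide's
#'   efficacy in the condition where the target's max |F| occurs (default);
#'   `"per_condition"`: weights vary by condition.
#' @param weight_mode Passed to [gene_fitness()].
#' @param threshold Combined-score significance threshold (default 4).
#' @param n_controls Number of control guides used per Wilcoxon test
#'   (default 10; if more controls exist, the first 10 by id sort are used).
#' @return A [fitness_table()] whose `target` table also carries a
#'   `significant` column (`S >= threshold`).
#' @export
compute_fitness_table <- function(F_mat, lib,
                                  efficacy_pooling = c("max_condition",
                                                       "per_condition"),
                                  weight_mode = "printed",
                                  threshold = 4, n_controls = 10L) {
  efficacy_pooling <- match.arg(efficacy_pooling)
  lib <- lib[match(rownames(F_mat), lib$sgrna_id), , drop = FALSE]
  is_ctrl <- if ("target_type" %in% names(lib)) {
    lib$target_type == "control"
  } else rep(FALSE, nrow(lib))
  conds <- colnames(F_mat)

  gene_rows <- which(!is_ctrl)
  gene_ids <- lib$target_id[gene_rows]
  Fg <- F_mat[gene_rows, , drop = FALSE]

  # per-condition efficacy within each target
  E_mat <- Fg * NA_real_
  for (idx in split(seq_along(gene_rows), gene_ids)) {
    for (cond in conds) {
      E_mat[idx, cond] <- repression_efficacy(Fg[idx, cond])
    }
  }
  R_scaled <- sgrna_correlation(Fg, gene_ids)

  # pooled efficacy: value from the condition holding the target's max |F|
  E_pooled <- rep(NA_real_, length(gene_rows))
  for (idx in split(seq_along(gene_rows), gene_ids)) {
    best <- which.max(apply(abs(Fg[idx, , drop = FALSE]), 2L, max))
    E_pooled[idx] <- E_mat[idx, best]
  }

  sg_list <- list(); tg_list <- list()
  ctrl_ids <- sort(lib$sgrna_id[is_ctrl])
  if (length(ctrl_ids) > n_controls) ctrl_ids <- ctrl_ids[seq_len(n_controls)]
  for (cond in conds) {
    w <- if (efficacy_pooling == "max_condition") {
      R_scaled * E_pooled
    } else {
      R_scaled * E_mat[, cond]
    }
    sg_list[[cond]] <- data.frame(
      sgrna_id = lib$sgrna_id[gene_rows], target_id = gene_ids,
      condition_id = cond, F = Fg[, cond], E = E_mat[, cond],
      R_scaled = unname(R_scaled), w = unname(w), stringsAsFactors = FALSE)
    ctrl_F <- F_mat[ctrl_ids, cond]
    per_tg <- lapply(split(seq_along(gene_rows), gene_ids), function(idx) {
      Fw <- gene_fitness(Fg[idx, cond], w[idx], mode = weight_mode)
      p <- if (length(ctrl_F) > 0L) {
        wilcoxon_vs_controls(Fg[idx, cond], ctrl_F)
      } else NA_real_
      data.frame(target_id = gene_ids[idx[1L]], condition_id = cond,
                 F_wmean = Fw, p = as.numeric(p), stringsAsFactors = FALSE)
    })
    tg <- do.call(rbind, per_tg)
    tg$p_adj <- if (all(is.na(tg$p))) NA_real_ else bh_adjust(tg$p)
    tg$S <- ifelse(is.na(tg$p_adj), NA_real_,
                   combined_score(tg$F_wmean, tg$p_adj))
    tg_list[[cond]] <- tg
  }
  sgrna <- do.call(rbind, sg_list); rownames(sgrna) <- NULL
  target <- do.call(rbind, tg_list); rownames(target) <- NULL
  target$significant <- !is.na(target$S) & target$S >= threshold
  fitness_table(sgrna, target)
}
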