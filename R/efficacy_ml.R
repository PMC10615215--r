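# Guide-efficacy sequence features and classifier harness: fixed 40-nt
# windows around the spacer, one-hot encoding (4 x 40 = 160 features),
# binary efficacy labels at E = 0.5, a seeded 75/25 split, four pluggable
# classifiers, position-wise feature importance and enrichment logos.
#
# Window positions are PAM-relative: the spacer's PAM-proximal base is -1,
# counting left (5'-ward) through the spacer into the 5' flank; the 3'
# flank (which begins with the PAM) gets +1, +2, ...

BASES <- c("A", "C", "G", "T")

#' Build the fixed 40-nt feature window around a spacer
#'
#' The spacer is centered and the genomic flanks are trimmed so 5' and 3'
#' context lengths differ by at most 1 nt and the total window is exactly
#' `width` nt: a 20-nt spacer gets 10 nt each side, a 23-nt spacer (9, 8),
#' an 18-nt spacer (11, 11). The 5' side receives the extra base when the
#' remainder is odd.
#'
#' @param spacer Spacer sequence (5'->3', PAM-proximal end last).
#' @param flank5,flank3 Genomic context on each side of the protospacer (the
#'   3' flank starts with the PAM).
#' @param width Total window width (default 40).
#' @return The window string of length `width`.
#' @export
build_window <- function(spacer, flank5, flank3, width = 40L) {
  L <- nchar(spacer)
  rem <- width - L
  if (rem < 0L) stop("spacer longer than the window")
  n5 <- ceiling(rem / 2)
  n3 <- rem - n5
  if (nchar(flank5) < n5 || nchar(flank3) < n3) {
    stop("insufficient genomic context: need ", n5, " nt 5' and ", n3,
         " nt 3' of the spacer")
  }
  paste0(substr(flank5, nchar(flank5) - n5 + 1L, nchar(flank5)),
         spacer,
         substr(flank3, 1L, n3))
}

#' PAM-relative position labels of a window
#'
#' @param spacer_len Spacer length in nt.
#' @param width Window width (default 40).
#' @return Integer vector of length `width`: 5' flank and spacer positions
#'   are negative (spacer PAM-proximal base = -1), PAM-side context is
#'   +1, +2, ...
#' @export
window_positions <- function(spacer_len, width = 40L) {
  rem <- width - spacer_len
  n5 <- ceiling(rem / 2)
  n3 <- rem - n5
  c(seq(-(spacer_len + n5), -1L), seq_len(n3))
}

#' One-hot encode a window
#'
#' Each position becomes a 4-slot indicator in fixed base order A, C, G, T,
#' giving a `4 * width` binary vector (160 for the default 40-nt window).
#' Feature names are `p<position>_<base>` with PAM-relative positions.
#'
#' @param window Window string (ACGT only).
#' @param positions Position labels (default [window_positions()] for a
#'   20-nt spacer).
#' @return Named binary integer vector of length `4 * nchar(window)`.
#' @export
onehot_encode <- function(window,
                          positions = window_positions(20L, nchar(window))) {
  chars <- strsplit(window, "", fixed = TRUE)[[1L]]
  if (any(!chars %in% BASES)) {
    stop("window contains a non-ACGT character")
  }
  stopifnot(length(positions) == length(chars))
  v <- as.integer(as.vector(vapply(chars, function(b) BASES == b,
                                   logical(4L))))
  names(v) <- paste0("p", rep(positions, each = 4L), "_",
                     rep(BASES, length(chars)))
  v
}

#' Decode a one-hot vector back to its window
#'
#' @param v One-hot vector from [onehot_encode()].
#' @return The window string.
#' @export
onehot_decode <- function(v) {
  m <- matrix(v, nrow = 4L)
  paste(BASES[apply(m, 2L, which.max)], collapse = "")
}

#' One-hot encode many windows into a feature matrix
#'
#' @param windows Character vector of equal-length windows.
#' @param positions Shared position labels.
#' @return Binary matrix, one row per window, `4 * width` named columns.
#' @export
encode_windows <- function(windows,
                           positions = window_positions(20L,
                                                        nchar(windows[1L]))) {
  out <- t(vapply(windows, onehot_encode, integer(4L * nchar(windows[1L])),
                  positions = positions, USE.NAMES = FALSE))
  colnames(out) <- names(onehot_encode(windows[1L], positions))
  rownames(out) <- names(windows)
  out
}

#' Whole-guide extra features
#'
#' GC content, melting temperature (Wallace rule, `2(A+T) + 4(G+C)` degrees
#' C), spacer length, distance to the promoter/start, and the optional
#' precomputed hybridization-energy score (`crisproff` column, accepted but
#' never computed here; missing values are imputed with the supplied or
#' training-set mean).
#'
#' @param lib Guide table with `spacer`, `distance_to_start` and optional
#'   `crisproff`.
#' @param crisproff_impute Mean used to impute missing `crisproff` values
#'   (default: mean of the non-missing values; ignored if the column is
#'   absent).
#' @return Numeric matrix with columns `gc`, `tm`, `length`,
#'   `distance_to_promoter` (and `crisproff` when supplied).
#' @export
guide_extras <- function(lib, crisproff_impute = NULL) {
  gc <- vapply(lib$spacer, gc_fraction, numeric(1L), USE.NAMES = FALSE)
  at <- nchar(lib$spacer) * (1 - gc)
  tm <- 2 * at + 4 * nchar(lib$spacer) * gc
  out <- cbind(gc = gc, tm = tm, length = nchar(lib$spacer),
               distance_to_promoter = lib$distance_to_start)
  if ("crisproff" %in% names(lib)) {
    co <- lib$crisproff
    if (anyNA(co)) {
      fill <- if (is.null(crisproff_impute)) mean(co, na.rm = TRUE) else
        crisproff_impute
      co[is.na(co)] <- fill
    }
    out <- cbind(out, crisproff = co)
  }
  rownames(out) <- lib$sgrna_id
  out
}

#' Binary efficacy label
#'
#' Bins repression efficacy at 0.5: `E < 0.5` is `"low"`, `E >= 0.5` is
#' `"high"` (the boundary maps to high).
#'
#' @param E Efficacy values in \[0, 1\].
#' @return Factor with levels `low`, `high`.
#' @export
label_efficacy <- function(E) {
  if (any(is.na(E)) || any(E < 0 | E > 1)) {
    stop("E must lie in [0, 1]")
  }
  factor(ifelse(E >= 0.5, "high", "low"), levels = c("low", "high"))
}

#' Select the guides eligible for efficacy modeling
#'
#' Keeps guides whose target reaches an absolute weighted gene fitness of at
#' least `min_abs_F` in at least one condition — a deliberately permissive
#' cutoff so that enough guides remain for training.
#'
#' @param fit A [fitness_table()].
#' @param min_abs_F Threshold on `max_cond |F_wmean|` (default 1).
#' @return Character vector of eligible sgRNA ids.
#' @export
select_modeling_set <- function(fit, min_abs_F = 1) {
  stopifnot(inherits(fit, "fitness_table"))
  mx <- vapply(split(abs(fit$target$F_wmean), fit$target$target_id),
               max, numeric(1L), na.rm = TRUE)
  keep_targets <- names(mx)[mx >= min_abs_F]
  unique(fit$sgrna$sgrna_id[fit$sgrna$target_id %in% keep_targets])
}

#' Seeded train/validation split
#'
#' Sizes are `round(n * fraction)` and the remainder; the split is uniform
#' at random (no stratification) and fully determined by the seed. A
#' 6,306-row set at the default 0.75 yields 4,730 training and 1,576
#' validation rows.
#'
#' @param n Number of observations (or a data.frame, whose row count is
#'   used).
#' @param fraction Training fraction (default 0.75).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `validation`.
#' @export
split_train_validation <- function(n, fraction = 0.75, seed = 1L) {
  if (is.data.frame(n) || is.matrix(n)) n <- nrow(n)
  if (n < 2L) stop("need at least 2 observations")
  n_train <- round(n * fraction)
  set.seed(seed)
  train <- sort(sample.int(n, n_train))
  list(train = train, validation = setdiff(seq_len(n), train))
}

fit_one_model <- function(model, x_train, y_train, params) {
  switch(model,
    random_forest = randomForest::randomForest(
      x = x_train, y = y_train,
      ntree = params$rf_ntree %||% 200L,
      importance = TRUE),
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(x_train,
                                     label = as.integer(y_train == "high"))
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$gb_max_depth %||% 1L,
                      eta = params$gb_eta %||% 0.1),
        data = dtrain, nrounds = params$gb_nrounds %||% 200L,
        verbose = 0)
    },
    svm = e1071::svm(x = x_train, y = y_train, kernel = "radial",
                     cost = params$svm_cost %||% 1,
                     gamma = params$svm_gamma %||% (1 / ncol(x_train))),
    mlp = {
      nnet::nnet(x = x_train, y = stats::model.matrix(~ y_train - 1),
                 size = params$mlp_size %||% 16L,
                 decay = params$mlp_decay %||% 1e-3,
                 maxit = params$mlp_maxit %||% 200L,
                 MaxNWts = 100000L, trace = FALSE, softmax = TRUE)
    },
    stop("unknown model: ", model))
}

predict_one_model <- function(model, fit, x) {
  switch(model,
    random_forest = stats::predict(fit, x),
    gradient_boosting = {
      pr <- stats::predict(fit, xgboost::xgb.DMatrix(x))
      factor(ifelse(pr >= 0.5, "high", "low"), levels = c("low", "high"))
    },
    svm = stats::predict(fit, x),
    mlp = {
      pr <- stats::predict(fit, x)
      lev <- sub("^y_train", "", colnames(pr))
      factor(lev[apply(pr, 1L, which.max)], levels = c("low", "high"))
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train an ensemble of efficacy classifiers and evaluate on validation
#'
#' Fits any subset of the four harness models — a bagged tree ensemble
#' (random forest), a boosted tree ensemble (depth-1 gradient boosting), an
#' RBF-kernel max-margin classifier, and a small single-hidden-layer neural
#' network — on the training features, predicts the validation set, and
#' reports per-model, per-class recall and precision plus the number of
#' high-efficacy validation guides recovered by at least one model.
#'
#' @param x_train,y_train Training feature matrix and label factor
#'   (`low`/`high`).
#' @param x_val,y_val Validation feature matrix and labels.
#' @param models Models to fit (default all four).
#' @param params Named list of hyperparameter overrides (`rf_ntree`,
#'   `gb_max_depth`, `gb_eta`, `gb_nrounds`, `svm_cost`, `svm_gamma`,
#'   `mlp_size`, `mlp_decay`, `mlp_maxit`).
#' @param seed Integer seed for the stochastic fitters.
#' @return List with `fits`, `predictions` (validation guides x models),
#'   `metrics` (per model and class: recall, precision), `union_high`
#'   (count of high-efficacy validation guides labeled correctly by >= 1
#'   model) and `n_high_val`.
#' @export
train_and_evaluate <- function(x_train, y_train, x_val, y_val,
                               models = c("random_forest",
                                          "gradient_boosting",
                                          "svm", "mlp"),
                               params = list(), seed = 1L) {
  y_train <- factor(y_train, levels = c("low", "high"))
  y_val <- factor(y_val, levels = c("low", "high"))
  if (length(unique(y_train)) < 2L) {
    stop("training labels are single-class; nothing to learn")
  }
  set.seed(seed)
  fits <- lapply(stats::setNames(models, models), function(mdl) {
    fit_one_model(mdl, x_train, y_train, params)
  })
  preds <- vapply(models, function(mdl) {
    as.character(predict_one_model(mdl, fits[[mdl]], x_val))
  }, character(nrow(x_val)))
  preds <- matrix(preds, nrow = nrow(x_val),
                  dimnames = list(rownames(x_val), models))
  metrics <- do.call(rbind, lapply(models, function(mdl) {
    pr <- factor(preds[, mdl], levels = c("low", "high"))
    do.call(rbind, lapply(c("low", "high"), function(cl) {
      tp <- sum(pr == cl & y_val == cl)
      data.frame(model = mdl, class = cl,
                 recall = tp / max(1L, sum(y_val == cl)),
                 precision = if (sum(pr == cl) == 0L) NA_real_ else
                   tp / sum(pr == cl),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(metrics) <- NULL
  high_idx <- which(y_val == "high")
  union_high <- sum(apply(preds[high_idx, , drop = FALSE] == "high", 1L, any))
  list(fits = fits, predictions = preds, metrics = metrics,
       union_high = union_high, n_high_val = length(high_idx))
}

#' Position-wise feature importance from a tree ensemble
#'
#' Maps a fitted tree ensemble's per-feature importances back to the
#' (PAM-relative position, base) grid of the one-hot window; sequence
#' importances are normalized to sum to 1. Extra (non-sequence) features are
#' reported separately.
#'
#' @param fit A fitted `randomForest` or `xgboost` model from the harness.
#' @param feature_names Column names of the training matrix.
#' @return List with `sequence` (`data.frame`: `position`, `base`,
#'   `importance`) and `extras` (named vector, possibly empty).
#' @export
position_importance <- function(fit, feature_names) {
  if (inherits(fit, "randomForest")) {
    imp <- fit$importance[, "MeanDecreaseGini"]
    names(imp) <- rownames(fit$importance)
  } else if (inherits(fit, "xgb.Booster")) {
    tab <- xgboost::xgb.importance(model = fit)
    imp <- stats::setNames(rep(0, length(feature_names)), feature_names)
    imp[tab$Feature] <- tab$Gain
  } else {
    stop("model exposes no per-feature importances; ",
         "use logo_weights() for sequence analysis instead")
  }
  imp <- imp[feature_names]
  is_seq <- grepl("^p-?\\d+_[ACGT]$", feature_names)
  seq_imp <- imp[is_seq]
  if (sum(seq_imp) > 0) seq_imp <- seq_imp / sum(seq_imp)
  pos <- as.integer(sub("^p(-?\\d+)_[ACGT]$", "\\1", names(seq_imp)))
  base <- sub("^p-?\\d+_([ACGT])$", "\\1", names(seq_imp))
  list(sequence = data.frame(position = pos, base = base,
                             importance = unname(seq_imp),
                             stringsAsFactors = FALSE),
       extras = imp[!is_seq])
}

base_freqs <- function(windows) {
  chars <- do.call(rbind, strsplit(windows, "", fixed = TRUE))
  apply(chars, 2L, function(col) {
    vapply(BASES, function(b) mean(col == b), numeric(1L))
  })
}

#' Signed per-position enrichment logo weights
#'
#' For each window position and base, `log2` of the (pseudocount-smoothed)
#' base frequency in the foreground class over the background frequency:
#' positive values mean enrichment, negative depletion. With a base fixed in
#' the class and a uniform background the weight approaches 2 bits.
#'
#' @param class_windows Windows of the foreground class (>= 2).
#' @param background_windows Background windows (>= 2), e.g. the other
#'   class or the whole library.
#' @param positions PAM-relative position labels.
#' @param pseudocount Frequency smoothing constant epsilon; smoothed
#'   frequency is `(f + eps) / (1 + 4 eps)` (default 0.01).
#' @return `data.frame` with `position`, `base`, `weight` (bits).
#' @export
logo_weights <- function(class_windows, background_windows,
                         positions = window_positions(20L,
                                                      nchar(class_windows[1L])),
                         pseudocount = 0.01) {
  if (length(class_windows) < 2L || length(background_windows) < 2L) {
    stop("need at least 2 sequences per class")
  }
  smooth <- function(f) (f + pseudocount) / (1 + 4 * pseudocount)
  fc <- smooth(base_freqs(class_windows))
  fb <- smooth(base_freqs(background_windows))
  w <- log2(fc / fb)
  data.frame(position = rep(positions, each = 4L),
             base = rep(BASES, ncol(w)),
             weight = as.vector(w), stringsAsFactors = FALSE)
}
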