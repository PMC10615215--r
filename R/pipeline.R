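# Orchestration: one configured, logged run of
# design -> simulate -> quantify -> fitness -> stats -> efficacy ML,
# with per-stage seeds derived from a single global seed and a JSON
# manifest recording parameters, seeds, input hashes and outputs.

#' Derive a per-stage seed from the global seed
#'
#' Fixed derivation (global seed plus a stage-name hash, modulo 2^31 - 1)
#' so that adding or toggling one stage never shifts another stage's random
#' stream.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + 97561 * h) %% 2147483647)
}

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Global seed.
#' @param stages Stages to run, in dependency order.
#' @param sim Arguments forwarded to [sim_config()].
#' @param quantify List: `pseudocount`, `normalize` (`"quantile"` or
#'   `"none"`), `ref` (`"matched"`/`"pooled"`).
#' @param fitness List: `efficacy_pooling`, `weight_mode`, `threshold`.
#' @param ml List: `min_abs_F`, `fraction`, `models`, `window_width`.
#' @param counts,meta Optional paths to pre-existing counts/metadata TSVs
#'   (used instead of simulation when the simulate stage is disabled).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "pipeline_out", seed = 1L,
                            stages = c("simulate", "quantify", "fitness",
                                       "stats", "efficacy_ml"),
                            sim = list(), quantify = list(),
                            fitness = list(), ml = list(),
                            counts = NULL, meta = NULL) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 sim = sim, quantify = quantify, fitness = fitness, ml = ml,
                 counts = counts, meta = meta),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the screen analysis pipeline
#'
#' Executes the enabled stages in dependency order, writes each stage's
#' tables under the output directory, and returns (and writes) a manifest
#' recording the configuration, derived per-stage seeds, md5 hashes of
#' inputs and the output paths. Re-running with the same configuration
#' reproduces identical outputs. Referenced input files are checked before
#' any stage runs; a missing file aborts the run with nothing executed.
#'
#' @param cfg A [pipeline_config()] (or YAML path).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  # pre-flight: every referenced input must exist before anything runs
  for (p in c(cfg$counts, cfg$meta)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("pre-flight: input file does not exist: ", p)
    }
  }
  if (!"simulate" %in% cfg$stages &&
      any(c("quantify", "fitness", "stats") %in% cfg$stages) &&
      (is.null(cfg$counts) || is.null(cfg$meta))) {
    stop("pre-flight: quantify needs either the simulate stage or ",
         "'counts' and 'meta' paths")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, stages = list())
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")

  sim <- NULL; cm <- NULL; l2fc_mat <- NULL; fit <- NULL
  for (stage in cfg$stages) {
    rec <- list(seed = stage_seed(cfg$seed, stage), params = cfg[[c(
      simulate = "sim", quantify = "quantify", fitness = "fitness",
      stats = "fitness", efficacy_ml = "ml")[[stage]]]] %||% list())
    if (stage == "simulate") {
      sc <- do.call(sim_config, c(cfg$sim, list(seed = rec$seed)))
      sim <- simulate_library(sc)
      cm <- simulate_counts(sim$library, sim$truth, sc)
      rec$outputs <- as.character(
        write_simulation(sim, cm, file.path(cfg$out_dir, "sim")))
    } else if (stage == "quantify") {
      if (is.null(cm)) {
        rec$inputs <- as.list(tools::md5sum(c(cfg$counts, cfg$meta)))
        cm <- read_counts(cfg$counts, cfg$meta)
      }
      q <- cfg$quantify
      l2fc_mat <- log2fc(cm, pseudocount = q$pseudocount %||% 0.5,
                         ref = q$ref %||% "matched")
      if ((q$normalize %||% "quantile") == "quantile" &&
          ncol(l2fc_mat) >= 2L) {
        l2fc_mat <- quantile_normalize(l2fc_mat)
      }
      out <- file.path(cfg$out_dir, "l2fc.tsv")
      utils::write.table(
        data.frame(sgrna_id = rownames(l2fc_mat), l2fc_mat,
                   check.names = FALSE),
        out, sep = "\t", quote = FALSE, row.names = FALSE)
      rec$outputs <- out
    } else if (stage == "fitness") {
      if (is.null(l2fc_mat)) stop("stage 'fitness' needs 'quantify' first")
      F_mat <- fitness_scores(l2fc_mat)
      lib <- if (!is.null(sim)) sim$library else
        data.frame(sgrna_id = rownames(F_mat),
                   target_id = rownames(F_mat),
                   target_type = "gene", stringsAsFactors = FALSE)
      f <- cfg$fitness
      fit <- compute_fitness_table(
        F_mat, lib,
        efficacy_pooling = f$efficacy_pooling %||% "max_condition",
        weight_mode = f$weight_mode %||% "printed",
        threshold = f$threshold %||% 4)
      rec$outputs <- as.character(
        write_fitness(fit, file.path(cfg$out_dir, "fitness.tsv")))
    } else if (stage == "stats") {
      if (is.null(fit)) stop("stage 'stats' needs 'fitness' first")
      hits <- fit$target[order(-ifelse(is.na(fit$target$S), -Inf,
                                       fit$target$S)), ]
      out <- file.path(cfg$out_dir, "hits.tsv")
      utils::write.table(hits, out, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      rec$outputs <- out
    } else if (stage == "efficacy_ml") {
      if (is.null(fit) || is.null(sim)) {
        stop("stage 'efficacy_ml' needs 'fitness' (and a library) first")
      }
      m <- cfg$ml
      rec$outputs <- run_ml_stage(fit, sim$library, m, rec$seed, cfg$out_dir)
    } else {
      stop("unknown stage: ", stage)
    }
    manifest$stages[[stage]] <- rec
  }
  manifest$started <- started
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

run_ml_stage <- function(fit, lib, m, seed, out_dir) {
  ids <- select_modeling_set(fit, min_abs_F = m$min_abs_F %||% 1)
  sub <- lib[lib$sgrna_id %in% ids, , drop = FALSE]
  if (nrow(sub) < 8L) {
    warning("too few guides pass the modeling filter; skipping ML stage")
    return(character())
  }
  # efficacy label from the pooled (max-|F| condition) efficacy already in
  # the fitness table: take each guide's max E across conditions
  E <- vapply(split(fit$sgrna$E, fit$sgrna$sgrna_id), max, numeric(1L))
  E <- E[sub$sgrna_id]
  width <- m$window_width %||% 40L
  windows <- mapply(build_window, sub$spacer, sub$flank5, sub$flank3,
                    MoreArgs = list(width = width))
  pos <- window_positions(nchar(sub$spacer[1L]), width)
  x <- encode_windows(unname(windows), pos)
  rownames(x) <- sub$sgrna_id
  y <- label_efficacy(E)
  sp <- split_train_validation(nrow(x), fraction = m$fraction %||% 0.75,
                               seed = seed)
  res <- train_and_evaluate(x[sp$train, ], y[sp$train],
                            x[sp$validation, ], y[sp$validation],
                            models = m$models %||% c("random_forest",
                                                     "gradient_boosting"),
                            seed = seed)
  imp <- position_importance(res$fits[[1L]], colnames(x))
  lw <- logo_weights(windows[y == "high"], windows, positions = pos)
  dir.create(file.path(out_dir, "ml"), showWarnings = FALSE)
  paths <- file.path(out_dir, "ml",
                     c("metrics.tsv", "importance.tsv", "logo_weights.tsv"))
  utils::write.table(res$metrics, paths[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(imp$sequence, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(lw, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
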