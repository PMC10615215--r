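#' @keywords internal
"_PACKAGE"

TARGET_TYPES <- c("gene", "asRNA", "iTSS", "sRNA", "control")

#' Read a target annotation table
#'
#' Parses a tab-separated table of screen targets (ORFs, antisense RNAs,
#' internal TSS, small RNAs, plus optional non-targeting control entries).
#' Coordinates are 1-based and inclusive, the convention used by common
#' bacterial genome annotation. Control entries carry no coordinates.
#'
#' @param path Path to a TSV file with header columns
#'   `target_id`, `type`, `seqid`, `strand`, `start`, `end`.
#' @return A `data.frame` with one row per target and columns
#'   `target_id`, `target_type`, `seqid`, `strand`, `start`, `end`.
#' @export
read_targets <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  required <- c("target_id", "type", "seqid", "strand", "start", "end")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("target table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    return(data.frame(target_id = character(), target_type = character(),
                      seqid = character(), strand = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    target_id = df$target_id,
    target_type = df$type,
    seqid = df$seqid,
    strand = df$strand,
    start = suppressWarnings(as.integer(df$start)),
    end = suppressWarnings(as.integer(df$end)),
    stringsAsFactors = FALSE
  )
  # line numbers reported are file lines (header = line 1)
  for (i in seq_len(nrow(out))) {
    line <- i + 1L
    rec <- out[i, ]
    if (!rec$target_type %in% TARGET_TYPES) {
      stop(sprintf("line %d: unknown target type '%s'", line, rec$target_type))
    }
    if (rec$target_type == "control") {
      out$start[i] <- NA_integer_
      out$end[i] <- NA_integer_
      next
    }
    if (is.na(rec$start) || is.na(rec$end)) {
      stop(sprintf("line %d: non-integer coordinates for '%s'", line, rec$target_id))
    }
    if (!rec$strand %in% c("+", "-")) {
      stop(sprintf("line %d: strand must be '+' or '-', got '%s'", line, rec$strand))
    }
    if (rec$start > rec$end) {
      stop(sprintf("line %d: start (%d) > end (%d) for '%s'",
                   line, rec$start, rec$end, rec$target_id))
    }
  }
  if (anyDuplicated(out$target_id)) {
    dup <- out$target_id[duplicated(out$target_id)][1L]
    stop("duplicate target_id: ", dup)
  }
  out
}

#' Construct a count matrix container
#'
#' Bundles an sgRNA-by-sample matrix of sequencing read counts with its sample
#' metadata (condition, generation, replicate). This is the common currency of
#' the quantification stage.
#'
#' @param counts Numeric matrix, sgRNAs in rows (rownames = sgRNA ids),
#'   samples in columns (colnames = sample ids). Values must be non-negative.
#' @param meta `data.frame` with columns `sample_id`, `condition_id`,
#'   `generation`, `replicate`; one row per column of `counts`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, meta) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have sgRNA rownames and sample colnames")
  }
  if (any(is.na(counts)) ) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  required <- c("sample_id", "condition_id", "generation", "replicate")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0L) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  }
  absent <- setdiff(colnames(counts), meta$sample_id)
  if (length(absent) > 0L) {
    stop("sample(s) in counts missing from metadata: ",
         paste(absent, collapse = ", "))
  }
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  # conditions without a generation-0 reference are unusable downstream
  bad <- vapply(split(meta$generation, meta$condition_id),
                function(g) !any(g == 0), logical(1L))
  unusable <- names(bad)[bad]
  if (length(unusable) > 0L) {
    warning("condition(s) without a generation-0 reference: ",
            paste(unusable, collapse = ", "))
  }
  structure(list(counts = counts, meta = meta, unusable = unusable),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d sgRNAs x %d samples (%d condition(s))\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$meta$condition_id))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read sgRNA counts and sample metadata
#'
#' Reads an sgRNA-by-sample counts TSV (first column `sgrna_id`) and a sample
#' metadata TSV keyed by `sample_id`, and returns a validated
#' [count_matrix()]. Counts must be non-negative integers; every counts column
#' must be described in the metadata. A condition lacking a generation-0
#' sample is kept but flagged unusable (with a warning).
#'
#' @param path Counts TSV path.
#' @param meta_path Metadata TSV path with columns `sample_id`,
#'   `condition_id`, `generation`, `replicate`.
#' @return A `count_matrix`.
#' @export
read_counts <- function(path, meta_path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (names(tab)[1L] != "sgrna_id") {
    stop("counts table must have 'sgrna_id' as its first column")
  }
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(is.na(m))) stop("counts contain missing or non-numeric cells")
  if (any(m < 0)) stop("negative count found")
  if (any(m != floor(m))) stop("non-integer count found")
  rownames(m) <- ids
  meta <- utils::read.delim(meta_path, sep = "\t", header = TRUE,
                            check.names = FALSE)
  count_matrix(m, meta)
}

#' Assemble a fitness table container
#'
#' @param sgrna `data.frame` with per-(sgRNA, condition) columns `sgrna_id`,
#'   `target_id`, `condition_id`, `F` (fitness), `E` (repression efficacy in
#'   \[0,1\]), `R_scaled` (rescaled sgRNA correlation in \[0,1\]), `w`
#'   (aggregation weight).
#' @param target `data.frame` with per-(target, condition) columns
#'   `target_id`, `condition_id`, `F_wmean`, `p`, `p_adj`, `S`.
#' @return An object of class `fitness_table`.
#' @export
fitness_table <- function(sgrna, target) {
  need_sg <- c("sgrna_id", "target_id", "condition_id", "F", "E", "R_scaled", "w")
  need_tg <- c("target_id", "condition_id", "F_wmean", "p", "p_adj", "S")
  if (!all(need_sg %in% names(sgrna))) {
    stop("sgrna table needs columns: ", paste(need_sg, collapse = ", "))
  }
  if (!all(need_tg %in% names(target))) {
    stop("target table needs columns: ", paste(need_tg, collapse = ", "))
  }
  structure(list(sgrna = sgrna, target = target), class = "fitness_table")
}

#' @export
print.fitness_table <- function(x, ...) {
  cat(sprintf("fitness_table: %d sgRNA rows, %d target rows, %d condition(s)\n",
              nrow(x$sgrna), nrow(x$target),
              length(unique(x$target$condition_id))))
  invisible(x)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.15g", v)
  }, character(1L))
  out
}

#' Write a fitness table to TSV
#'
#' Writes the per-target table to `path` and the per-sgRNA table to a
#' companion file (`*_sgrna.tsv`). Numeric values are serialized with 15
#' significant digits so that a read round-trip reproduces them to at least
#' 12 significant digits; missing p-values (untestable targets) are written
#' as `NA`.
#'
#' @param table A [fitness_table()].
#' @param path Output path for the per-target TSV.
#' @return Invisibly, the two file paths written.
#' @export
write_fitness <- function(table, path) {
  stopifnot(inherits(table, "fitness_table"))
  sg_path <- sub("\\.tsv$", "_sgrna.tsv", path)
  if (sg_path == path) sg_path <- paste0(path, "_sgrna.tsv")
  tg <- table$target
  for (col in c("F_wmean", "p", "p_adj", "S")) tg[[col]] <- fmt_num(tg[[col]])
  sg <- table$sgrna
  for (col in c("F", "E", "R_scaled", "w")) sg[[col]] <- fmt_num(sg[[col]])
  utils::write.table(tg, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  utils::write.table(sg, sg_path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(c(path, sg_path))
}

#' Read a fitness table written by [write_fitness()]
#'
#' @param path The per-target TSV path (the companion `*_sgrna.tsv` is read
#'   from the same directory).
#' @return A `fitness_table`.
#' @export
read_fitness <- function(path) {
  sg_path <- sub("\\.tsv$", "_sgrna.tsv", path)
  if (sg_path == path) sg_path <- paste0(path, "_sgrna.tsv")
  tg <- utils::read.delim(path, sep = "\t", header = TRUE,
                          na.strings = "NA", check.names = FALSE)
  sg <- utils::read.delim(sg_path, sep = "\t", header = TRUE,
                          na.strings = "NA", check.names = FALSE)
  if (nrow(tg) == 0L) {
    tg <- data.frame(target_id = character(), condition_id = character(),
                     F_wmean = numeric(), p = numeric(), p_adj = numeric(),
                     S = numeric(), stringsAsFactors = FALSE)
  }
  if (nrow(sg) == 0L) {
    sg <- data.frame(sgrna_id = character(), target_id = character(),
                     condition_id = character(), F = numeric(), E = numeric(),
                     R_scaled = numeric(), w = numeric(),
                     stringsAsFactors = FALSE)
  }
  fitness_table(sg, tg)
}

#' Read condition design descriptors
#'
#' Reads the cultivation design table (one row per condition: CO2 level,
#' light intensity, treatment flags, generation time) used to build the
#' design matrix for condition-effect regression.
#'
#' @param path TSV with columns `condition_id`, `co2` (`high`/`low`),
#'   `light` (photon flux, numeric), and 0/1 flag columns
#'   `fluctuating_light`, `glucose`, `DCMU`, `N_limitation`, plus
#'   `generation_time_h`.
#' @return A `data.frame`.
#' @export
read_condition_design <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  need <- c("condition_id", "co2", "light", "fluctuating_light", "glucose",
            "DCMU", "N_limitation", "generation_time_h")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("condition design is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!all(df$co2 %in% c("high", "low"))) stop("co2 must be 'high' or 'low'")
  df
}
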