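# Quantification: spacer counting from reads, median-of-ratios size
# factors, pseudocount log2 fold changes versus generation 0, and
# between-sample quantile normalization.

#' Count exact spacer matches in a FASTQ file
#'
#' Counts, for each guide, the reads containing its spacer as an exact
#' substring. Reads matching more than one spacer (e.g. one spacer a
#' substring of another) are discarded and tallied in the `ambiguous`
#' attribute; reads matching none are tallied in `unassigned`.
#'
#' @param path FASTQ file path (uncompressed or gzipped).
#' @param lib Guide table with columns `sgrna_id`, `spacer`.
#' @return Named integer vector of counts per sgRNA with attributes
#'   `ambiguous` and `unassigned`.
#' @export
count_spacers <- function(path, lib) {
  reads <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) stop("could not read FASTQ '", path, "': ",
                             conditionMessage(e)))
  counts <- stats::setNames(integer(nrow(lib)), lib$sgrna_id)
  nhit <- integer(length(reads))
  hit_id <- integer(length(reads))
  for (k in seq_len(nrow(lib))) {
    hits <- Biostrings::vcountPattern(lib$spacer[k], reads) > 0L
    nhit[hits] <- nhit[hits] + 1L
    hit_id[hits] <- k
  }
  ok <- nhit == 1L
  tab <- tabulate(hit_id[ok], nbins = nrow(lib))
  counts[] <- tab
  attr(counts, "ambiguous") <- sum(nhit > 1L)
  attr(counts, "unassigned") <- sum(nhit == 0L)
  counts
}

#' Write reads for a counts column as FASTQ
#'
#' Emits `count` copies of each spacer embedded between its flanks, a
#' zero-error read simulator used to exercise the exact-match counter.
#'
#' @param counts Named integer vector (names = sgRNA ids).
#' @param lib Guide table with `sgrna_id`, `spacer` and optional flanks.
#' @param path Output FASTQ path.
#' @return Invisibly, `path`.
#' @export
write_reads_fastq <- function(counts, lib, path) {
  idx <- match(names(counts), lib$sgrna_id)
  if (anyNA(idx)) stop("counts contain sgRNAs absent from the library")
  f5 <- if ("flank5" %in% names(lib)) lib$flank5[idx] else ""
  f3 <- if ("flank3" %in% names(lib)) lib$flank3[idx] else ""
  seqs <- rep(paste0(f5, lib$spacer[idx], f3), counts)
  ids <- sprintf("read%07d", seq_along(seqs))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(
                                strrep("I", nchar(seqs))))
  invisible(path)
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over guides (restricted to
#' guides with positive counts in every sample) of the ratio of the guide's
#' count to its geometric mean across samples. If no guide is positive in
#' every sample, the median falls back to the guide subset positive in the
#' sample pair being ratioed, with a warning.
#'
#' @param m Count matrix (guides x samples) or a [count_matrix()].
#' @return Named numeric vector of positive size factors.
#' @export
size_factors <- function(m) {
  if (inherits(m, "count_matrix")) m <- m$counts
  all_pos <- rowSums(m <= 0) == 0L
  if (!any(all_pos)) {
    warning("no guide has positive counts in all samples; ",
            "using per-sample positive subsets")
    logg <- log(m)
    logg[!is.finite(logg)] <- NA
    geo <- exp(rowMeans(logg, na.rm = TRUE))
    sf <- apply(m, 2L, function(col) {
      ok <- col > 0 & geo > 0
      stats::median(col[ok] / geo[ok])
    })
    return(sf)
  }
  sub <- m[all_pos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  apply(sub, 2L, function(col) stats::median(col / geo))
}

#' Normalized log2 fold changes versus generation 0
#'
#' Computes `log2((c_ij/sf_j + pc) / (c_i0/sf_0 + pc))` per guide and
#' post-reference sample, where the generation-0 reference of a condition is
#' replicate-matched when replicate labels align (`ref = "matched"`) or the
#' mean of the normalized generation-0 samples (`ref = "pooled"`).
#'
#' @param cm A [count_matrix()].
#' @param sf Size factors (defaults to [size_factors()] of `cm`).
#' @param pseudocount Pseudocount added to normalized counts (default 0.5).
#' @param ref `"matched"` or `"pooled"` generation-0 reference.
#' @return Matrix of log2 fold changes (guides x samples with generation >
#'   0) with the matching sample metadata in attribute `meta`.
#' @export
log2fc <- function(cm, sf = size_factors(cm), pseudocount = 0.5,
                   ref = c("matched", "pooled")) {
  ref <- match.arg(ref)
  stopifnot(inherits(cm, "count_matrix"))
  meta <- cm$meta
  norm <- sweep(cm$counts, 2L, sf[meta$sample_id], "/")
  out_cols <- which(meta$generation > 0)
  vals <- matrix(NA_real_, nrow = nrow(norm), ncol = length(out_cols),
                 dimnames = list(rownames(norm),
                                 meta$sample_id[out_cols]))
  for (k in seq_along(out_cols)) {
    j <- out_cols[k]
    cond <- meta$condition_id[j]
    ref_idx <- which(meta$condition_id == cond & meta$generation == 0)
    if (length(ref_idx) == 0L) {
      stop("condition '", cond, "' has no generation-0 reference")
    }
    if (ref == "matched") {
      match_idx <- ref_idx[meta$replicate[ref_idx] == meta$replicate[j]]
      ref_col <- if (length(match_idx) == 1L) norm[, match_idx] else
        rowMeans(norm[, ref_idx, drop = FALSE])
    } else {
      ref_col <- rowMeans(norm[, ref_idx, drop = FALSE])
    }
    vals[, k] <- log2((norm[, j] + pseudocount) / (ref_col + pseudocount))
  }
  attr(vals, "meta") <- meta[out_cols, , drop = FALSE]
  vals
}

#' Quantile normalization of log2 fold changes
#'
#' Classic quantile normalization (as in limma's
#' `normalizeBetweenArrays(method = "quantile")`): each column's sorted
#' values are replaced by the across-column mean of sorted values, so all
#' columns end up with an identical value distribution while within-column
#' ranks are preserved. Used between conditions to make fitness scores
#' comparable when conditions differ in effective generations. Ties share
#' the mean of the quantiles they span.
#'
#' @param x Numeric matrix (e.g. from [log2fc()]).
#' @param columns Columns to normalize jointly (default all).
#' @return The matrix with the selected columns normalized; attributes are
#'   preserved.
#' @export
quantile_normalize <- function(x, columns = seq_len(ncol(x))) {
  meta <- attr(x, "meta")
  if (length(columns) < 2L) {
    warning("quantile normalization needs >= 2 columns; returning input")
    return(x)
  }
  x[, columns] <- limma::normalizeBetweenArrays(x[, columns, drop = FALSE],
                                                method = "quantile")
  attr(x, "meta") <- meta
  x
}
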