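#' nCounter-style probe count matrix
#'
#' @param counts non-negative integer matrix, probes in rows (rownames =
#'   probe/gene ids), samples in columns (colnames = sample ids).
#' @param probe_class character vector (length = rows) with values
#'   `"endogenous"`, `"positive"` or `"negative"`.
#' @param samples data.frame with columns `sample`, `cell_line`, `replicate`;
#'   one row per column of `counts`.
#' @return list of class `count_matrix`.
#' @export
count_matrix <- function(counts, probe_class, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' needs probe rownames and sample colnames")
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be non-negative integers")
  probe_class <- as.character(probe_class)
  if (length(probe_class) != nrow(counts))
    stop("probe_class length must match the number of probes")
  bad <- !probe_class %in% c("endogenous", "positive", "negative")
  if (any(bad))
    stop("unknown probe class(es): ", paste(unique(probe_class[bad]),
                                            collapse = ", "))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample", "cell_line", "replicate")
  if (!all(req %in% names(samples)))
    stop("samples needs columns: ", paste(req, collapse = ", "))
  if (!setequal(samples$sample, colnames(counts)))
    stop("sample metadata and count columns disagree")
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, probe_class = probe_class,
                 samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d probes (%d endogenous) x %d samples\n",
              nrow(x$counts), sum(x$probe_class == "endogenous"),
              ncol(x$counts)))
  invisible(x)
}

#' Negative-control background threshold for one sample
#'
#' `mean + k * SD` of the sample's negative-control probe counts (sample
#' standard deviation, n-1 denominator; k defaults to 2, the platform's usual
#' convention).
#'
#' @param cm a [count_matrix()].
#' @param sample sample id.
#' @param k_sd number of standard deviations above the mean.
#' @return A single numeric threshold (raw count scale).
#' @export
background_threshold <- function(cm, sample, k_sd = 2) {
  stopifnot(inherits(cm, "count_matrix"))
  neg <- cm$counts[cm$probe_class == "negative", sample]
  if (length(neg) < 2L)
    stop("need at least 2 negative-control probes to estimate background")
  mean(neg) + k_sd * stats::sd(neg)
}

#' Sample quality control
#'
#' A sample is excluded when the fraction of endogenous probes whose raw
#' count exceeds the sample's negative-control background threshold falls
#' below `min_fraction_above_background` (reason `low_binding_density`), or
#' when it appears in the manual exclusion list (reason `manual` unless the
#' list carries named reasons, e.g. `hybridization_error`).
#'
#' @param cm a [count_matrix()].
#' @param min_fraction_above_background proportion in `[0, 1]`; default 0.5.
#' @param k_sd background threshold multiplier, see [background_threshold()].
#' @param manual_exclude character vector of sample ids to exclude by hand;
#'   if named, names are sample ids and values are the reasons.
#' @return data.frame of class `qc_report`: `sample`, `cell_line`,
#'   `replicate`, `background`, `fraction_above_background`, `status`
#'   (`pass`/`excluded`), `reason`.
#' @export
qc_samples <- function(cm, min_fraction_above_background = 0.5, k_sd = 2,
                       manual_exclude = character()) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!sum(cm$probe_class == "negative"))
    stop("QC requires negative-control probes")
  if (min_fraction_above_background < 0 || min_fraction_above_background > 1)
    stop("min_fraction_above_background must be in [0, 1]")
  if (is.null(names(manual_exclude)) && length(manual_exclude))
    manual_exclude <- stats::setNames(rep("manual", length(manual_exclude)),
                                      manual_exclude)
  endo <- cm$counts[cm$probe_class == "endogenous", , drop = FALSE]
  out <- cm$samples
  out$background <- vapply(out$sample, function(s)
    background_threshold(cm, s, k_sd), numeric(1))
  out$fraction_above_background <- vapply(seq_len(ncol(endo)), function(j)
    mean(endo[, j] > out$background[[j]]), numeric(1))
  out$status <- "pass"
  out$reason <- "none"
  low <- out$fraction_above_background < min_fraction_above_background
  out$status[low] <- "excluded"
  out$reason[low] <- "low_binding_density"
  man <- out$sample %in% names(manual_exclude)
  out$status[man] <- "excluded"
  out$reason[man] <- unname(manual_exclude[out$sample[man]])
  class(out) <- c("qc_report", "data.frame")
  out
}

.geomean <- function(x) exp(mean(log(x)))

#' Positive-control and global-median normalization
#'
#' For every QC-passing sample, in order: (1) a positive-control factor —
#' the across-sample mean of per-sample geometric means of positive-control
#' probes divided by this sample's geometric mean — applied multiplicatively;
#' (2) a global median-scaling factor — the across-sample mean of per-sample
#' medians of (positive-control-normalized) endogenous counts divided by this
#' sample's median — applied multiplicatively. The negative-control
#' background threshold is carried through both factors so presence calls can
#' compare normalized counts against it; background is never subtracted.
#'
#' @param cm a [count_matrix()].
#' @param qc a `qc_report` from [qc_samples()]; excluded samples are dropped.
#' @return list of class `normalized_counts`: `values` (endogenous probe x
#'   passing-sample matrix), `samples`, `pos_factor`, `median_factor`,
#'   `background` (per-sample threshold on the normalized scale), `qc`.
#' @export
normalize_counts <- function(cm, qc = qc_samples(cm)) {
  stopifnot(inherits(cm, "count_matrix"), inherits(qc, "qc_report"))
  keep <- qc$sample[qc$status == "pass"]
  if (!length(keep)) stop("no samples passed QC")
  if (!sum(cm$probe_class == "positive"))
    stop("normalization requires positive-control probes")

  pos <- cm$counts[cm$probe_class == "positive", keep, drop = FALSE]
  endo <- cm$counts[cm$probe_class == "endogenous", keep, drop = FALSE]
  g <- apply(pos, 2L, .geomean)
  if (any(g == 0))
    stop("zero geometric mean of positive controls in sample(s): ",
         paste(keep[g == 0], collapse = ", "))
  pos_factor <- mean(g) / g

  endo_pos <- sweep(endo, 2L, pos_factor, `*`)
  med <- apply(endo_pos, 2L, stats::median)
  if (any(med == 0))
    stop("zero median of endogenous counts in sample(s): ",
         paste(keep[med == 0], collapse = ", "))
  median_factor <- mean(med) / med
  values <- sweep(endo_pos, 2L, median_factor, `*`)

  bg_raw <- qc$background[match(keep, qc$sample)]
  background <- bg_raw * pos_factor * median_factor
  names(background) <- keep

  structure(list(values = values,
                 samples = cm$samples[match(keep, cm$samples$sample), ,
                                      drop = FALSE],
                 pos_factor = pos_factor, median_factor = median_factor,
                 background = background, qc = qc),
            class = "normalized_counts")
}

#' @export
print.normalized_counts <- function(x, ...) {
  cat(sprintf("normalized_counts: %d genes x %d samples (%d excluded by QC)\n",
              nrow(x$values), ncol(x$values),
              sum(x$qc$status == "excluded")))
  invisible(x)
}
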