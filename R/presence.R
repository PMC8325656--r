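#' Replicate and cell-line presence-calling rules
#'
#' An mRNA is called present in a cell line when it is detected above the
#' background threshold in a majority of that line's passing replicates:
#' 2 of 3, or 2 of 2 when a replicate was lost to QC. A transcript is present
#' in a histological type when it is present in every cell line of the type,
#' and a type-level (consensus) call is only made when at least
#' `min_lines_per_type` lines of the type survive QC.
#'
#' @param min_detected_replicates named integer vector mapping the number of
#'   passing replicates to the required number of detections (default
#'   `c("2" = 2, "3" = 2)`); replicate counts not listed fall back to a
#'   strict majority, `floor(n/2) + 1`.
#' @param min_lines_per_type minimum cell lines per histology for a
#'   type-level consensus call (default 2).
#' @return list of class `presence_rules`.
#' @export
presence_rules <- function(min_detected_replicates = c("2" = 2, "3" = 2),
                           min_lines_per_type = 2) {
  if (any(min_detected_replicates < 1))
    stop("required detection counts must be >= 1")
  n <- as.integer(names(min_detected_replicates))
  if (any(is.na(n)) || any(min_detected_replicates > n))
    stop("required count must not exceed the replicate count it is keyed on")
  structure(list(min_detected_replicates = min_detected_replicates,
                 min_lines_per_type = min_lines_per_type),
            class = "presence_rules")
}

.required_detections <- function(rules, n_replicates) {
  key <- as.character(n_replicates)
  if (key %in% names(rules$min_detected_replicates))
    as.integer(rules$min_detected_replicates[[key]])
  else
    floor(n_replicates / 2) + 1L
}

#' Per-sample detection above background
#'
#' A gene is detected in a sample when its normalized count strictly exceeds
#' the sample's background threshold (negative-control mean + k SD, carried
#' through normalization).
#'
#' @param norm a `normalized_counts` from [normalize_counts()].
#' @return Logical gene x sample matrix.
#' @export
detect_replicates <- function(norm) {
  stopifnot(inherits(norm, "normalized_counts"))
  sweep(norm$values, 2L, norm$background, `>`)
}

#' Cell-line and histology-level presence calls
#'
#' @param detection logical gene x sample matrix from [detect_replicates()].
#' @param samples data.frame (`sample`, `cell_line`, `replicate`) describing
#'   the detection columns; defaults to `norm$samples` when `detection` is
#'   built from a `normalized_counts` passed as `norm`.
#' @param rules a [presence_rules()].
#' @param histology a [histology_map()].
#' @return list of class `presence_matrix`: `by_line` (logical gene x
#'   cell-line matrix), `by_type` (logical gene x histology matrix, only
#'   types with a consensus call), `non_consensus_types` (types with too few
#'   lines for a type-level call), `n_replicates` (named integer per line),
#'   `detection` (the input, as provenance).
#' @export
call_presence <- function(detection, samples, rules = presence_rules(),
                          histology = histology_map()) {
  stopifnot(is.matrix(detection), is.logical(detection))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!setequal(samples$sample, colnames(detection)))
    stop("sample metadata and detection columns disagree")
  samples <- samples[match(colnames(detection), samples$sample), ,
                     drop = FALSE]
  unmapped <- setdiff(samples$cell_line, names(histology))
  if (length(unmapped))
    stop("cell line(s) missing from histology map: ",
         paste(unmapped, collapse = ", "))

  lines <- unique(samples$cell_line)
  n_rep <- vapply(lines, function(l) sum(samples$cell_line == l), integer(1))
  zero <- lines[n_rep == 0L]
  if (length(zero)) {
    warning("dropping cell line(s) with no passing replicates: ",
            paste(zero, collapse = ", "))
    lines <- setdiff(lines, zero)
  }
  by_line <- vapply(lines, function(l) {
    det <- detection[, samples$sample[samples$cell_line == l], drop = FALSE]
    rowSums(det) >= .required_detections(rules, ncol(det))
  }, logical(nrow(detection)))
  by_line <- matrix(by_line, nrow = nrow(detection),
                    dimnames = list(rownames(detection), lines))

  types <- unique(unname(histology[lines]))
  lines_of <- lapply(types, function(h) lines[histology[lines] == h])
  names(lines_of) <- types
  consensus <- types[lengths(lines_of) >= rules$min_lines_per_type]
  by_type <- vapply(consensus, function(h) {
    rowSums(by_line[, lines_of[[h]], drop = FALSE]) ==
      length(lines_of[[h]])
  }, logical(nrow(detection)))
  by_type <- matrix(by_type, nrow = nrow(detection),
                    dimnames = list(rownames(detection), consensus))

  structure(list(by_line = by_line, by_type = by_type,
                 non_consensus_types = setdiff(types, consensus),
                 n_replicates = stats::setNames(
                   vapply(lines, function(l) sum(samples$cell_line == l),
                          integer(1)), lines),
                 detection = detection),
            class = "presence_matrix")
}

#' Venn selection of candidate mRNA biomarkers
#'
#' Compares type-level presence between two histologies regardless of
#' abundance: transcripts present only in the first type, only in the
#' second, and shared by both.
#'
#' @param presence a `presence_matrix` from [call_presence()].
#' @param types two histologies with consensus calls (default benign vs
#'   ccRCC).
#' @return list of class `biomarker_report` with `type_sets`, disjoint
#'   `regions`, `sizes` and `kind = "mrna"`.
#' @export
venn_mrna <- function(presence, types = c("benign", "ccRCC")) {
  stopifnot(inherits(presence, "presence_matrix"), length(types) == 2L)
  miss <- setdiff(types, colnames(presence$by_type))
  if (length(miss))
    stop("no consensus presence calls for type(s): ",
         paste(miss, collapse = ", "))
  type_sets <- lapply(types, function(h)
    rownames(presence$by_type)[presence$by_type[, h]])
  names(type_sets) <- types
  regions <- venn_regions(type_sets)
  structure(list(type_sets = type_sets, regions = regions,
                 sizes = stats::setNames(lengths(regions), names(regions)),
                 kind = "mrna"),
            class = "biomarker_report")
}

#' Transcripts detected anywhere, and present in every cell line
#'
#' @param presence a `presence_matrix` from [call_presence()].
#' @return list: `any_sample` (genes detected above background in at least
#'   one sample) and `all_lines` (genes with a cell-line-level presence call
#'   in every line). The latter is always a subset of the former.
#' @export
detected_anywhere <- function(presence) {
  stopifnot(inherits(presence, "presence_matrix"))
  det <- presence$detection
  list(any_sample = rownames(det)[rowSums(det) > 0],
       all_lines = rownames(presence$by_line)[
         rowSums(presence$by_line) == ncol(presence$by_line)])
}
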