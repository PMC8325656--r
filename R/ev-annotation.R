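#' Fold-change thresholds for EV association and differential abundance
#'
#' The pipeline's single fold-change cutoff: 1.5-fold, i.e. 0.58 on the log2
#' scale as printed, or exactly `log2(1.5) = 0.58496` when `exact_log2 = TRUE`.
#' Comparisons against the cutoff are strict (`>`) by default.
#'
#' @param fc_linear linear fold-change threshold, must be > 1.
#' @param exact_log2 use `log2(fc_linear)` instead of the rounded printed
#'   value.
#' @param fc_log2 log2 threshold; defaults to `round(log2(fc_linear), 2)`
#'   (0.58 for 1.5-fold) or the exact log2 under `exact_log2`. Must agree with
#'   `log2(fc_linear)` to within 0.01.
#' @param strict logical; `TRUE` means values equal to the threshold do not
#'   pass.
#' @param branch2_lower_inclusive logical; whether the second annotation
#'   branch's lower bound (`EV - CL >= 0`) is inclusive.
#' @return A list of class `analysis_thresholds`.
#' @export
analysis_thresholds <- function(fc_linear = 1.5, exact_log2 = FALSE,
                                fc_log2 = NULL, strict = TRUE,
                                branch2_lower_inclusive = TRUE) {
  if (fc_linear <= 1) stop("fc_linear must exceed 1")
  if (is.null(fc_log2))
    fc_log2 <- if (exact_log2) log2(fc_linear) else round(log2(fc_linear), 2)
  if (abs(fc_log2 - log2(fc_linear)) > 0.01)
    stop("fc_log2 must be within 0.01 of log2(fc_linear)")
  structure(list(fc_linear = fc_linear, fc_log2 = fc_log2, strict = strict,
                 branch2_lower_inclusive = branch2_lower_inclusive),
            class = "analysis_thresholds")
}

.exceeds <- function(x, cut, strict) if (strict) x > cut else x >= cut

#' Annotate proteins as EV-associated with the two-branch fold-change rule
#'
#' A protein is EV-associated in a cell line if either (1) its EV-vs-CL
#' (cell lysate) log2 fold change exceeds the threshold (default 0.58, i.e.
#' 1.5-fold), or (2) that fold change lies between 0 and the threshold while
#' the EV-vs-2K (debris pellet) log2 fold change exceeds the threshold. A
#' protein whose required fold change is missing (not quantified) is
#' `unevaluable`, never guessed.
#'
#' @param rm a `ratio_matrix` (merged, or mergeable).
#' @param thresholds an [analysis_thresholds()].
#' @param cell_lines cell lines to annotate; default every line with an EV and
#'   CL column.
#' @return Object of class `ev_annotation`: data.frame with one row per
#'   (protein, cell_line) and columns `protein`, `cell_line`, `ev_cl_logfc`,
#'   `ev_2k_logfc`, `status` (`ev_associated`, `not_ev_associated`,
#'   `unevaluable`) and `branch` (`evcl`, `evcl_ev2k`, `none`).
#' @export
annotate_ev <- function(rm, thresholds = analysis_thresholds(),
                        cell_lines = NULL) {
  stopifnot(inherits(rm, "ratio_matrix"))
  rm <- merge_plexes(rm)
  if (is.null(cell_lines)) {
    cl <- unique(rm$columns$cell_line)
    has <- vapply(cl, function(l)
      !is.null(.ratio_col(rm, l, "EV")) && !is.null(.ratio_col(rm, l, "CL")),
      logical(1))
    cell_lines <- cl[has]
  }
  if (!length(cell_lines)) stop("no cell line has both EV and CL columns")
  out <- lapply(cell_lines, function(line) {
    ev <- .ratio_col(rm, line, "EV"); cl <- .ratio_col(rm, line, "CL")
    if (is.null(ev) || is.null(cl))
      stop("cell line ", line, " lacks an EV or CL column")
    k2 <- .ratio_col(rm, line, "2K")
    ev_cl <- ev - cl
    ev_2k <- if (is.null(k2)) rep(NA_real_, length(ev)) else ev - k2
    ann <- classify_ev(ev_cl, ev_2k, thresholds)
    data.frame(protein = rownames(rm$ratios), cell_line = line,
               ev_cl_logfc = ev_cl, ev_2k_logfc = ev_2k,
               status = ann$status, branch = ann$branch,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, out)
  class(out) <- c("ev_annotation", "data.frame")
  out
}

#' Classify (EV-vs-CL, EV-vs-2K) fold-change pairs
#'
#' Vectorised core of [annotate_ev()]; exposed so the rule can be checked
#' directly against a truth table.
#'
#' @param ev_cl_logfc,ev_2k_logfc numeric vectors of log2 fold changes
#'   (`NA` = not quantified).
#' @param thresholds an [analysis_thresholds()].
#' @return list with character vectors `status` and `branch`.
#' @export
classify_ev <- function(ev_cl_logfc, ev_2k_logfc,
                        thresholds = analysis_thresholds()) {
  t <- thresholds
  n <- length(ev_cl_logfc)
  stopifnot(length(ev_2k_logfc) == n)
  status <- rep("not_ev_associated", n)
  branch <- rep("none", n)

  b1 <- !is.na(ev_cl_logfc) & .exceeds(ev_cl_logfc, t$fc_log2, t$strict)
  in_band <- !is.na(ev_cl_logfc) & !b1 &
    (if (t$branch2_lower_inclusive) ev_cl_logfc >= 0 else ev_cl_logfc > 0) &
    (if (t$strict) ev_cl_logfc <= t$fc_log2 else ev_cl_logfc < t$fc_log2)
  b2 <- in_band & !is.na(ev_2k_logfc) &
    .exceeds(ev_2k_logfc, t$fc_log2, t$strict)

  status[b1] <- "ev_associated"; branch[b1] <- "evcl"
  status[b2] <- "ev_associated"; branch[b2] <- "evcl_ev2k"
  status[is.na(ev_cl_logfc)] <- "unevaluable"
  status[in_band & is.na(ev_2k_logfc)] <- "unevaluable"
  list(status = status, branch = branch)
}

#' Positive and negative EV marker panel
#'
#' Default positive markers are the classic EV proteins FLOT1, CD81, CD63,
#' CD9, ALIX (PDCD6IP) and TSG101; default negative (non-EV) markers are the
#' ER/mitochondrial contaminant indicators CANX, HSP90B1 and CYC1.
#'
#' @param positive,negative character vectors of marker ids; must be disjoint.
#' @return list of class `marker_panel`.
#' @export
marker_panel <- function(positive = c("FLOT1", "CD81", "CD63", "CD9",
                                      "PDCD6IP", "TSG101"),
                         negative = c("CANX", "HSP90B1", "CYC1")) {
  if (length(intersect(positive, negative)))
    stop("positive and negative marker panels must be disjoint")
  structure(list(positive = positive, negative = negative),
            class = "marker_panel")
}

#' EV marker quality-control summary
#'
#' Classifies each panel marker in each cell line by its EV-vs-CL fold
#' change: `elevated_in_ev` when the log2 FC exceeds the threshold,
#' `depleted_in_ev` when it falls below minus the threshold, `neither`
#' otherwise, `not_detected` when the marker is absent from the matrix or has
#' no quantified fold change.
#'
#' @param rm a `ratio_matrix`.
#' @param panel a [marker_panel()].
#' @param thresholds an [analysis_thresholds()].
#' @return data.frame with columns `marker`, `role`, `cell_line`,
#'   `ev_cl_logfc`, `class`.
#' @export
marker_qc <- function(rm, panel = marker_panel(),
                      thresholds = analysis_thresholds()) {
  stopifnot(inherits(rm, "ratio_matrix"), inherits(panel, "marker_panel"))
  rm <- merge_plexes(rm)
  lines <- unique(rm$columns$cell_line[rm$columns$fraction == "EV"])
  markers <- c(panel$positive, panel$negative)
  role <- rep(c("positive", "negative"),
              c(length(panel$positive), length(panel$negative)))
  grid <- expand.grid(i = seq_along(markers), cell_line = lines,
                      stringsAsFactors = FALSE)
  res <- mapply(function(i, line) {
    m <- markers[[i]]
    if (!m %in% rownames(rm$ratios)) return(c(NA_real_, "not_detected"))
    fc <- fraction_logfc(rm, line, "EV", "CL")[[m]]
    cls <- if (is.na(fc)) "not_detected"
      else if (.exceeds(fc, thresholds$fc_log2, thresholds$strict))
        "elevated_in_ev"
      else if (.exceeds(-fc, thresholds$fc_log2, thresholds$strict))
        "depleted_in_ev"
      else "neither"
    c(fc, cls)
  }, grid$i, grid$cell_line)
  data.frame(marker = markers[grid$i], role = role[grid$i],
             cell_line = grid$cell_line,
             ev_cl_logfc = as.numeric(res[1L, ]), class = res[2L, ],
             stringsAsFactors = FALSE)
}

#' Consensus EV-association counts across cell lines
#'
#' For each k, the number (and identity) of proteins annotated EV-associated
#' in at least k cell lines. Sets are nested (k+1 within k) and counts
#' non-increasing by construction.
#'
#' @param annot an `ev_annotation` from [annotate_ev()].
#' @return list of class `ev_consensus`: `counts` (data.frame `k`,
#'   `n_proteins`), `sets` (list, `sets[[k]]` = proteins EV-associated in >= k
#'   lines), `per_protein` (named integer: lines in which each protein is
#'   EV-associated) and `n_cell_lines`.
#' @export
consensus_ev_counts <- function(annot) {
  stopifnot(inherits(annot, "ev_annotation"))
  lines <- unique(annot$cell_line)
  ev <- annot[annot$status == "ev_associated", , drop = FALSE]
  per_protein <- table(factor(ev$protein, levels = unique(annot$protein)))
  per_protein <- stats::setNames(as.integer(per_protein),
                                 names(per_protein))
  ks <- seq_len(length(lines))
  sets <- lapply(ks, function(k) names(per_protein)[per_protein >= k])
  structure(list(
    counts = data.frame(k = ks, n_proteins = lengths(sets)),
    sets = sets, per_protein = per_protein, n_cell_lines = length(lines)),
    class = "ev_consensus")
}

#' Proteins detected in the EV preparation of each cell line
#'
#' "Detected in the EV preparation" means: the protein has a quantified
#' EV-fraction ratio for that cell line. These per-line detection sets feed
#' the detection-based Venn biomarker selection ([venn_proteins()]).
#'
#' @param rm a `ratio_matrix`.
#' @return Named list: cell line -> character vector of detected proteins.
#' @export
ev_detection_sets <- function(rm) {
  stopifnot(inherits(rm, "ratio_matrix"))
  rm <- merge_plexes(rm)
  lines <- unique(rm$columns$cell_line[rm$columns$fraction == "EV"])
  out <- lapply(lines, function(line) {
    ev <- .ratio_col(rm, line, "EV")
    rownames(rm$ratios)[!is.na(ev)]
  })
  stats::setNames(out, lines)
}
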