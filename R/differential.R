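#' Map cell lines to renal histology groups
#'
#' @param map named character vector or list, cell line -> histology. The
#'   defaults mirror the study design: ccRCC = 786-O, 769-P, Caki1; pRCC =
#'   ACHN, Caki2; benign = HK2 (plus RPTEC for the transcript arm).
#' @param histologies allowed histology labels.
#' @return Named character vector of class `histology_map`.
#' @export
histology_map <- function(map = c("HK2" = "benign", "RPTEC" = "benign",
                                  "786-O" = "ccRCC", "769-P" = "ccRCC",
                                  "Caki1" = "ccRCC", "ACHN" = "pRCC",
                                  "Caki2" = "pRCC"),
                          histologies = c("benign", "ccRCC", "pRCC")) {
  map <- unlist(map)
  bad <- !map %in% histologies
  if (any(bad))
    stop("unknown histology label(s): ", paste(unique(map[bad]), collapse = ", "))
  if (is.null(names(map)) || any(!nzchar(names(map))))
    stop("every entry must be named by a cell line")
  class(map) <- "histology_map"
  map
}

.direction <- function(delta, t) {
  d <- rep("neither", length(delta))
  d[!is.na(delta) & .exceeds(delta, t$fc_log2, t$strict)] <- "increased"
  d[!is.na(delta) & .exceeds(-delta, t$fc_log2, t$strict)] <- "decreased"
  d
}

#' Pairwise differential abundance between two cell lines
#'
#' Pure fold-change rule: a protein is `increased` in `line_a` relative to
#' `line_b` when the log2 difference of their reference ratios exceeds the
#' threshold, `decreased` below minus the threshold, otherwise `neither`.
#' Proteins with a missing value in either line are `neither` and flagged.
#'
#' @param rm a `ratio_matrix`.
#' @param line_a,line_b cell lines to compare (a vs b).
#' @param fraction fraction to compare within (default `"EV"`).
#' @param thresholds an [analysis_thresholds()].
#' @return data.frame of class `differential_result`: `protein`, `logfc`,
#'   `direction`, `missing`, with attribute `comparison`.
#' @export
differential_pairwise <- function(rm, line_a, line_b, fraction = "EV",
                                  thresholds = analysis_thresholds()) {
  stopifnot(inherits(rm, "ratio_matrix"))
  rm <- merge_plexes(rm)
  a <- .ratio_col(rm, line_a, fraction)
  b <- .ratio_col(rm, line_b, fraction)
  if (is.null(a)) stop("unknown cell line or missing fraction: ", line_a)
  if (is.null(b)) stop("unknown cell line or missing fraction: ", line_b)
  delta <- a - b
  out <- data.frame(protein = rownames(rm$ratios), logfc = delta,
                    direction = .direction(delta, thresholds),
                    missing = is.na(delta), stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "comparison") <- sprintf("%s_vs_%s_%s", line_a, line_b, fraction)
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Group-consensus differential abundance
#'
#' A protein is `increased` in group A relative to group B only when it is
#' increased in *every* pairwise comparison of a line of A against a line of
#' B (all-pairs conjunction); `decreased` symmetrically. Any missing pairwise
#' value makes the protein `neither`. A group-mean alternative (log2
#' difference of group means against the same threshold) is available via
#' `method = "mean"` but is not the default.
#'
#' @param rm a `ratio_matrix`.
#' @param group_a,group_b disjoint, non-empty character vectors of cell lines.
#' @param fraction fraction to compare within (default `"EV"`).
#' @param thresholds an [analysis_thresholds()].
#' @param method `"all_pairs"` (default) or `"mean"`.
#' @return data.frame of class `differential_result`: `protein`, `direction`,
#'   `missing`, plus per-pair log2 fold-change columns (all-pairs method) or
#'   `logfc` (mean method).
#' @export
differential_group <- function(rm, group_a, group_b, fraction = "EV",
                               thresholds = analysis_thresholds(),
                               method = c("all_pairs", "mean")) {
  method <- match.arg(method)
  if (!length(group_a) || !length(group_b))
    stop("groups must be non-empty")
  if (length(intersect(group_a, group_b)))
    stop("groups overlap: ", paste(intersect(group_a, group_b), collapse = ", "))
  rm <- merge_plexes(rm)

  if (method == "mean") {
    np <- nrow(rm$ratios)
    cols_a <- matrix(vapply(group_a, function(l) .ratio_col(rm, l, fraction),
                            numeric(np)), nrow = np)
    cols_b <- matrix(vapply(group_b, function(l) .ratio_col(rm, l, fraction),
                            numeric(np)), nrow = np)
    delta <- rowMeans(cols_a) - rowMeans(cols_b)
    out <- data.frame(protein = rownames(rm$ratios), logfc = delta,
                      direction = .direction(delta, thresholds),
                      missing = is.na(delta), stringsAsFactors = FALSE)
  } else {
    pairs <- expand.grid(a = group_a, b = group_b, stringsAsFactors = FALSE)
    dirs <- matrix("neither", nrow(rm$ratios), nrow(pairs))
    fcs <- matrix(NA_real_, nrow(rm$ratios), nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      pw <- differential_pairwise(rm, pairs$a[[i]], pairs$b[[i]], fraction,
                                  thresholds)
      dirs[, i] <- pw$direction
      fcs[, i] <- pw$logfc
    }
    any_missing <- rowSums(is.na(fcs)) > 0
    direction <- rep("neither", nrow(rm$ratios))
    all_inc <- rowSums(dirs == "increased") == ncol(dirs) & !any_missing
    all_dec <- rowSums(dirs == "decreased") == ncol(dirs) & !any_missing
    direction[all_inc] <- "increased"
    direction[all_dec] <- "decreased"
    colnames(fcs) <- sprintf("logfc_%s_vs_%s", pairs$a, pairs$b)
    out <- data.frame(protein = rownames(rm$ratios), direction = direction,
                      missing = any_missing, fcs, stringsAsFactors = FALSE,
                      check.names = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "comparison") <- sprintf("{%s}_vs_{%s}_%s",
                                     paste(group_a, collapse = ","),
                                     paste(group_b, collapse = ","), fraction)
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Cell/EV concordant differential proteins
#'
#' Proteins whose differential direction against a reference cell line is the
#' same in the cell lysate (CL) fraction and the EV fraction — i.e. whose EV
#' cargo change mirrors the parental cell change. `neither` in either
#' fraction is not concordant.
#'
#' @param rm a `ratio_matrix`.
#' @param line cell line compared against the reference.
#' @param reference_line reference (default `"HK2"`, the benign line).
#' @param thresholds an [analysis_thresholds()].
#' @return list: `proteins` (character vector of concordant proteins) and
#'   `detail` (data.frame with per-fraction directions).
#' @export
concordance <- function(rm, line, reference_line = "HK2",
                        thresholds = analysis_thresholds()) {
  cl <- differential_pairwise(rm, line, reference_line, "CL", thresholds)
  ev <- differential_pairwise(rm, line, reference_line, "EV", thresholds)
  detail <- data.frame(protein = cl$protein, cl_direction = cl$direction,
                       ev_direction = ev$direction, stringsAsFactors = FALSE)
  hit <- detail$cl_direction != "neither" &
    detail$cl_direction == detail$ev_direction
  list(proteins = detail$protein[hit], detail = detail)
}

# Disjoint region partition of 2 or 3 named sets; regions keyed by the
# "+"-joined sorted names of the sets containing each element.
venn_regions <- function(sets) {
  stopifnot(length(sets) >= 2L, !is.null(names(sets)))
  universe <- unique(unlist(sets, use.names = FALSE))
  nm <- names(sets)
  combos <- unlist(lapply(seq_along(nm), function(k)
    utils::combn(nm, k, paste, collapse = "+")))
  if (!length(universe)) {
    regions <- lapply(combos, function(cb) character(0))
    names(regions) <- combos
    return(regions)
  }
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(NULL, names(sets)))
  key <- apply(member, 1L, function(r) paste(names(sets)[r], collapse = "+"))
  regions <- lapply(combos, function(cb) universe[key == cb])
  names(regions) <- combos
  regions
}

#' Detection-based Venn selection of candidate protein biomarkers
#'
#' A protein counts as detected for a histology only when it is detected in
#' the EV preparation of *every* cell line of that histology. The three
#' histology detection sets are then partitioned into the 7 disjoint Venn
#' regions; proteins unique to one histology are its candidate EV biomarkers,
#' the triple intersection is the consensus renal EV proteome.
#'
#' @param detection named list, cell line -> character vector of proteins
#'   detected in that line's EV preparation (see [ev_detection_sets()]).
#' @param histology a [histology_map()] covering every detection cell line.
#' @return list of class `biomarker_report`: `type_sets` (histology ->
#'   detected proteins), `regions` (disjoint Venn regions), `sizes` (named
#'   integer region sizes), `kind = "protein"`.
#' @export
venn_proteins <- function(detection, histology) {
  stopifnot(is.list(detection), !is.null(names(detection)))
  unmapped <- setdiff(names(detection), names(histology))
  if (length(unmapped))
    stop("cell line(s) missing from histology map: ",
         paste(unmapped, collapse = ", "))
  types <- unique(unname(histology[names(detection)]))
  type_sets <- lapply(types, function(h) {
    lines <- names(detection)[histology[names(detection)] == h]
    Reduce(intersect, detection[lines])
  })
  names(type_sets) <- types
  if (length(type_sets) < 2L)
    stop("need detection sets from at least two histologies")
  regions <- venn_regions(type_sets)
  structure(list(type_sets = type_sets, regions = regions,
                 sizes = stats::setNames(lengths(regions), names(regions)),
                 kind = "protein"),
            class = "biomarker_report")
}

#' @export
print.biomarker_report <- function(x, ...) {
  cat(sprintf("biomarker_report (%s): %d region(s)\n", x$kind,
              length(x$regions)))
  for (nm in names(x$sizes))
    cat(sprintf("  %-24s %d\n", nm, x$sizes[[nm]]))
  invisible(x)
}
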