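#' TMT quantification table
#'
#' Container for protein-level TMT reporter abundances (log2 scale) together
#' with the channel design: which cell line, sub-cellular fraction and plex
#' each channel belongs to, and which channel is the pooled reference that
#' links plexes.
#'
#' @param values numeric matrix, proteins in rows (rownames = protein ids),
#'   channels in columns (colnames = channel ids). `NA` marks a protein not
#'   quantified in a channel. Values are log2 abundances unless
#'   `log2_transform = TRUE`.
#' @param design data.frame with columns `channel`, `cell_line`, `fraction`
#'   (one of `"EV"`, `"CL"`, `"2K"`; `NA` for the reference channel), `plex`,
#'   and logical `is_reference`. Exactly one reference channel per plex.
#' @param log2_transform if `TRUE`, `values` are linear intensities and are
#'   log2-transformed on construction (non-positive values become `NA`).
#'
#' @return An object of class `quant_table`: a list with elements `values`
#'   and `design`.
#' @export
quant_table <- function(values, design, log2_transform = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("'values' must have protein ids as rownames")
  if (is.null(colnames(values)))
    stop("'values' must have channel ids as colnames")
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  req <- c("channel", "cell_line", "fraction", "plex", "is_reference")
  miss <- setdiff(req, names(design))
  if (length(miss))
    stop("design is missing required column(s): ", paste(miss, collapse = ", "))
  design$is_reference <- as.logical(design$is_reference)
  if (!setequal(design$channel, colnames(values)))
    stop("design channels and value columns disagree")
  design <- design[match(colnames(values), design$channel), , drop = FALSE]
  rownames(design) <- NULL

  bad_frac <- !design$is_reference & !design$fraction %in% c("EV", "CL", "2K")
  if (any(bad_frac))
    stop("unknown fraction label(s): ",
         paste(unique(design$fraction[bad_frac]), collapse = ", "),
         " (must be EV, CL or 2K)")
  n_ref <- tapply(design$is_reference, design$plex, sum)
  if (any(n_ref != 1L))
    stop("each plex must have exactly one reference channel; plex(es) ",
         paste(names(n_ref)[n_ref != 1L], collapse = ", "), " violate this")
  smp <- design[!design$is_reference, , drop = FALSE]
  key <- paste(smp$cell_line, smp$fraction, smp$plex, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (cell_line, fraction, plex) channel(s) in design")

  if (log2_transform) {
    values[!is.na(values) & values <= 0] <- NA
    values <- log2(values)
  }
  if (any(is.infinite(values)))
    stop("log2 abundances must be finite (or NA)")
  structure(list(values = values, design = design), class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("quant_table: %d proteins x %d channels, %d plex(es)\n",
              nrow(x$values), ncol(x$values), length(unique(x$design$plex))))
  invisible(x)
}

#' Log2 ratios to the pooled reference channel
#'
#' For every non-reference channel, subtracts the log2 abundance of its plex's
#' pooled reference channel, protein by protein. The reference channel links
#' the plexes: ratios from different plexes share a common denominator and are
#' comparable after [merge_plexes()]. A ratio is present only where both the
#' sample channel and the reference channel were quantified.
#'
#' @param quant a [quant_table()].
#' @return An object of class `ratio_matrix`: list with `ratios` (protein x
#'   column matrix of log2 ratios), `columns` (data.frame `column`,
#'   `cell_line`, `fraction`, `plex`), `n_plexes_quantified` (named integer:
#'   plexes in which each protein has at least one quantified ratio),
#'   `n_plexes` (total plexes in the design) and `merged` (`FALSE`).
#' @export
compute_reference_ratios <- function(quant) {
  stopifnot(inherits(quant, "quant_table"))
  des <- quant$design
  smp <- des[!des$is_reference, , drop = FALSE]
  ref_of <- des$channel[des$is_reference]
  names(ref_of) <- des$plex[des$is_reference]

  ratios <- quant$values[, smp$channel, drop = FALSE] -
    quant$values[, ref_of[as.character(smp$plex)], drop = FALSE]
  cols <- data.frame(column = paste(smp$cell_line, smp$fraction, smp$plex,
                                    sep = "|"),
                     cell_line = smp$cell_line, fraction = smp$fraction,
                     plex = smp$plex, stringsAsFactors = FALSE)
  colnames(ratios) <- cols$column

  plexes <- sort(unique(smp$plex))
  quant_in_plex <- vapply(plexes, function(p) {
    rowSums(!is.na(ratios[, cols$plex == p, drop = FALSE])) > 0
  }, logical(nrow(ratios)))
  n_plexes_quantified <- as.integer(rowSums(as.matrix(quant_in_plex)))
  names(n_plexes_quantified) <- rownames(ratios)

  structure(list(ratios = ratios, columns = cols,
                 n_plexes_quantified = n_plexes_quantified,
                 n_plexes = length(plexes), merged = FALSE),
            class = "ratio_matrix")
}

#' Merge per-plex ratio columns into one column per (cell line, fraction)
#'
#' Aligns ratios from all plexes onto a single column per (cell line,
#' fraction) pair. Values are never altered, only coalesced: a protein's value
#' comes from whichever plex quantified it. If the same (cell line, fraction)
#' was measured in more than one plex and a protein carries two different
#' values, that is a design conflict and an error. Already-merged input is
#' returned unchanged (the operation is idempotent).
#'
#' @param rm a `ratio_matrix` from [compute_reference_ratios()].
#' @return A merged `ratio_matrix` (`merged = TRUE`), columns named
#'   `"<cell_line>|<fraction>"`.
#' @export
merge_plexes <- function(rm) {
  stopifnot(inherits(rm, "ratio_matrix"))
  if (isTRUE(rm$merged)) return(rm)
  cols <- rm$columns
  key <- paste(cols$cell_line, cols$fraction, sep = "|")
  ukey <- unique(key)
  merged <- matrix(NA_real_, nrow(rm$ratios), length(ukey),
                   dimnames = list(rownames(rm$ratios), ukey))
  for (k in ukey) {
    sub <- rm$ratios[, key == k, drop = FALSE]
    if (ncol(sub) > 1L) {
      conflict <- apply(sub, 1L, function(v) {
        v <- v[!is.na(v)]
        length(v) > 1L && max(v) - min(v) > 1e-9
      })
      if (any(conflict))
        stop("conflicting duplicate values for column ", k, " (",
             sum(conflict), " protein(s)); plexes disagree")
    }
    merged[, k] <- apply(sub, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) v[[1L]] else NA_real_
    })
  }
  first <- !duplicated(key)
  out_cols <- data.frame(column = ukey,
                         cell_line = cols$cell_line[first],
                         fraction = cols$fraction[first],
                         plex = NA, stringsAsFactors = FALSE)
  structure(list(ratios = merged, columns = out_cols,
                 n_plexes_quantified = rm$n_plexes_quantified,
                 n_plexes = rm$n_plexes, merged = TRUE),
            class = "ratio_matrix")
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat(sprintf("ratio_matrix: %d proteins x %d columns (%s)\n",
              nrow(x$ratios), ncol(x$ratios),
              if (isTRUE(x$merged)) "merged" else "per-plex"))
  invisible(x)
}

#' Restrict a ratio matrix to proteins quantified in every plex
#'
#' The subset "quantified across all TMT plexes" is an explicit filter, not a
#' silent drop: proteins seen in only some plexes stay in the full matrix with
#' their per-plex provenance in `n_plexes_quantified`.
#'
#' @param rm a `ratio_matrix`.
#' @return The `ratio_matrix` restricted to proteins with
#'   `n_plexes_quantified == n_plexes`.
#' @export
subset_all_plexes <- function(rm) {
  stopifnot(inherits(rm, "ratio_matrix"))
  keep <- rm$n_plexes_quantified == rm$n_plexes
  rm$ratios <- rm$ratios[keep, , drop = FALSE]
  rm$n_plexes_quantified <- rm$n_plexes_quantified[keep]
  rm
}

.ratio_col <- function(rm, cell_line, fraction) {
  hit <- rm$columns$cell_line == cell_line & rm$columns$fraction == fraction
  if (!any(hit)) return(NULL)
  rm$ratios[, rm$columns$column[hit][[1L]]]
}

#' Per-protein log2 fold change between two fractions of one cell line
#'
#' `log2 FC = ratio(fraction_a) - ratio(fraction_b)`; because both ratios
#' share the pooled-reference denominator this equals the direct log2
#' difference between the two fractions. Missing in either fraction
#' propagates to missing.
#'
#' @param rm a merged `ratio_matrix`.
#' @param cell_line cell line name.
#' @param fraction_a,fraction_b fraction labels (`"EV"`, `"CL"` or `"2K"`).
#' @return Named numeric vector of per-protein log2 fold changes.
#' @export
fraction_logfc <- function(rm, cell_line, fraction_a, fraction_b) {
  stopifnot(inherits(rm, "ratio_matrix"))
  rm <- merge_plexes(rm)
  for (f in c(fraction_a, fraction_b))
    if (!f %in% c("EV", "CL", "2K"))
      stop("unknown fraction label: ", f)
  a <- .ratio_col(rm, cell_line, fraction_a)
  b <- .ratio_col(rm, cell_line, fraction_b)
  if (is.null(a) || is.null(b))
    stop("cell line ", cell_line, " lacks fraction ",
         if (is.null(a)) fraction_a else fraction_b)
  a - b
}
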