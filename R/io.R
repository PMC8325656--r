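#' Typed TSV input and output
#'
#' All tabular exchange uses tab-separated text with a one-line header.
#' Identifiers are opaque, case-sensitive strings. Each writer's output
#' round-trips through the matching reader without loss.
#'
#' @param quant a [quant_table()].
#' @param path matrix file path; the design travels in a sidecar
#'   `<path>.design.tsv` (writer) or is read from `design_path`.
#' @param design_path design TSV path.
#' @return Readers return the corresponding object; writers return `path`
#'   invisibly.
#' @name evcargo_io
NULL

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

.read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  df
}

.matrix_to_df <- function(m, id_col) {
  cbind(stats::setNames(data.frame(rownames(m), stringsAsFactors = FALSE),
                        id_col),
        as.data.frame(m, check.names = FALSE))
}

.df_to_matrix <- function(df, id_col) {
  m <- as.matrix(df[setdiff(names(df), id_col)])
  rownames(m) <- df[[id_col]]
  m
}

#' @rdname evcargo_io
#' @export
write_quant_table <- function(quant, path) {
  stopifnot(inherits(quant, "quant_table"))
  .write_tsv(.matrix_to_df(quant$values, "protein"), path)
  .write_tsv(quant$design, paste0(path, ".design.tsv"))
  invisible(path)
}

#' @rdname evcargo_io
#' @export
read_quant_table <- function(path, design_path = paste0(path, ".design.tsv")) {
  df <- .read_tsv(path, "protein")
  design <- .read_tsv(design_path,
                      c("channel", "cell_line", "fraction", "plex",
                        "is_reference"))
  quant_table(.df_to_matrix(df, "protein"), design)
}

#' @rdname evcargo_io
#' @param rm a `ratio_matrix`.
#' @export
write_ratio_matrix <- function(rm, path) {
  stopifnot(inherits(rm, "ratio_matrix"))
  df <- .matrix_to_df(rm$ratios, "protein")
  df$n_plexes_quantified <- rm$n_plexes_quantified
  .write_tsv(df, path)
  .write_tsv(rm$columns, paste0(path, ".columns.tsv"))
  invisible(path)
}

#' @rdname evcargo_io
#' @param columns_path column-metadata TSV path.
#' @export
read_ratio_matrix <- function(path,
                              columns_path = paste0(path, ".columns.tsv")) {
  df <- .read_tsv(path, c("protein", "n_plexes_quantified"))
  cols <- .read_tsv(columns_path,
                    c("column", "cell_line", "fraction", "plex"))
  n_plex <- stats::setNames(as.integer(df$n_plexes_quantified), df$protein)
  m <- .df_to_matrix(df[setdiff(names(df), "n_plexes_quantified")],
                     "protein")
  merged <- all(is.na(cols$plex))
  structure(list(ratios = m[, cols$column, drop = FALSE], columns = cols,
                 n_plexes_quantified = n_plex,
                 n_plexes = if (merged) max(n_plex, 1L)
                            else length(unique(cols$plex)),
                 merged = merged),
            class = "ratio_matrix")
}

#' @rdname evcargo_io
#' @param cm a [count_matrix()].
#' @export
write_count_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- .matrix_to_df(cm$counts, "probe")
  df <- cbind(df[1L], probe_class = cm$probe_class, df[-1L])
  .write_tsv(df, path)
  .write_tsv(cm$samples, paste0(path, ".samples.tsv"))
  invisible(path)
}

#' @rdname evcargo_io
#' @param samples_path sample-metadata TSV path.
#' @export
read_count_matrix <- function(path,
                              samples_path = paste0(path, ".samples.tsv")) {
  df <- .read_tsv(path, c("probe", "probe_class"))
  samples <- .read_tsv(samples_path, c("sample", "cell_line", "replicate"))
  count_matrix(.df_to_matrix(df[setdiff(names(df), "probe_class")], "probe"),
               df$probe_class, samples)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line — name, description, then member
#' ids, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fgsea::gmtPathways(path)
}

#' Read or write a ranked list in RNK dialect
#'
#' Two tab-separated columns — gene id and ranking metric — no header.
#'
#' @param ranked a [ranked_list()].
#' @param path RNK file path.
#' @return `read_rnk` returns a `ranked_list`; `write_rnk` returns `path`
#'   invisibly.
#' @export
write_rnk <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_list"))
  utils::write.table(data.frame(names(ranked), as.numeric(ranked)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_rnk
#' @export
read_rnk <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) != 2L) stop("RNK files carry exactly two columns")
  ranked_list(stats::setNames(as.numeric(df[[2L]]), df[[1L]]))
}
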