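#' Run the full EV-cargo biomarker discovery pipeline
#'
#' Executes every stage in order on a proteomics quantification table and an
#' nCounter-style count matrix: reference ratios -> plex merging -> EV
#' annotation -> consensus counts -> marker QC -> group differential
#' abundance -> detection-based protein Venn selection -> transcript QC ->
#' normalization -> presence calling -> mRNA Venn selection -> (optionally)
#' GSEA on the ccRCC-vs-benign ranking. All intermediates are returned, and
#' written as TSV when `out_dir` is given. The run is deterministic given
#' `seed`.
#'
#' @param quant a [quant_table()].
#' @param counts a [count_matrix()], or `NULL` to skip the transcript arm.
#' @param histology a [histology_map()] covering every cell line in either
#'   input (the run fails fast naming any unmapped line).
#' @param thresholds an [analysis_thresholds()].
#' @param rules a [presence_rules()].
#' @param gene_sets named list of gene sets for GSEA, or `NULL` to skip.
#' @param gsea_groups length-2 character vector of histologies ranked
#'   against each other for GSEA (first vs second).
#' @param manual_exclude manual QC exclusions, as in [qc_samples()].
#' @param min_fraction_above_background QC rule, see [qc_samples()].
#' @param n_permutations GSEA permutation draws.
#' @param seed integer seed for every stochastic stage.
#' @param out_dir directory for TSV outputs, or `NULL`.
#' @return list of class `ev_pipeline_result` with elements `ratios`,
#'   `annotation`, `consensus`, `marker_qc`, `differential` (one
#'   `differential_result` per histology pair), `protein_report`, `qc`,
#'   `normalized`, `presence`, `mrna_report`, `ranked`, `gsea`, and
#'   `manifest` (per-stage row counts, seed, package version).
#' @export
run_ev_pipeline <- function(quant, counts = NULL,
                            histology = histology_map(),
                            thresholds = analysis_thresholds(),
                            rules = presence_rules(),
                            gene_sets = NULL,
                            gsea_groups = c("ccRCC", "benign"),
                            manual_exclude = character(),
                            min_fraction_above_background = 0.5,
                            n_permutations = 1000,
                            seed = 1, out_dir = NULL) {
  stopifnot(inherits(quant, "quant_table"))
  in_lines <- unique(quant$design$cell_line[!quant$design$is_reference])
  if (!is.null(counts)) in_lines <- union(in_lines, counts$samples$cell_line)
  unmapped <- setdiff(in_lines, names(histology))
  if (length(unmapped))
    stop("stage histology_map: cell line(s) not mapped: ",
         paste(unmapped, collapse = ", "))

  res <- list()
  res$ratios <- merge_plexes(compute_reference_ratios(quant))
  res$annotation <- annotate_ev(res$ratios, thresholds)
  res$consensus <- consensus_ev_counts(res$annotation)
  res$marker_qc <- marker_qc(res$ratios, thresholds = thresholds)

  prot_lines <- unique(res$ratios$columns$cell_line)
  types <- unique(unname(histology[prot_lines]))
  pairs <- if (length(types) >= 2L) utils::combn(types, 2L, simplify = FALSE)
           else list()
  res$differential <- lapply(pairs, function(tp) {
    differential_group(res$ratios,
                       prot_lines[histology[prot_lines] == tp[[1L]]],
                       prot_lines[histology[prot_lines] == tp[[2L]]],
                       "EV", thresholds)
  })
  names(res$differential) <- vapply(pairs, paste, "", collapse = "_vs_")
  res$protein_report <- venn_proteins(ev_detection_sets(res$ratios),
                                      histology)

  if (!is.null(counts)) {
    res$qc <- qc_samples(counts, min_fraction_above_background,
                         manual_exclude = manual_exclude)
    res$normalized <- normalize_counts(counts, res$qc)
    detection <- detect_replicates(res$normalized)
    res$presence <- call_presence(detection, res$normalized$samples, rules,
                                  histology)
    both <- intersect(c("benign", "ccRCC"), colnames(res$presence$by_type))
    if (length(both) == 2L)
      res$mrna_report <- venn_mrna(res$presence, both)
    norm_types <- unique(unname(
      histology[unique(res$normalized$samples$cell_line)]))
    have <- intersect(gsea_groups, norm_types)
    if (length(have) == 2L) {
      lines_of <- function(h) {
        l <- unique(res$normalized$samples$cell_line)
        l[histology[l] == h]
      }
      res$ranked <- rank_genes(res$normalized, lines_of(gsea_groups[[1L]]),
                               lines_of(gsea_groups[[2L]]))
      if (!is.null(gene_sets))
        res$gsea <- gsea(res$ranked, gene_sets,
                         n_permutations = n_permutations, seed = seed)
    }
  }

  res$manifest <- pipeline_manifest(res, seed)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  class(res) <- "ev_pipeline_result"
  res
}

#' Per-stage row counts and provenance of a pipeline run
#'
#' @param res partial or complete pipeline result list.
#' @param seed the seed the run used.
#' @return list: `package_version`, `seed`, `stages` (named integer row
#'   counts). Identical inputs and seed reproduce an identical manifest.
#' @export
pipeline_manifest <- function(res, seed) {
  n_of <- function(x) {
    if (is.null(x)) return(NA_integer_)
    if (is.matrix(x)) return(nrow(x))
    if (is.data.frame(x)) return(nrow(x))
    if (inherits(x, "ratio_matrix")) return(nrow(x$ratios))
    if (inherits(x, "normalized_counts")) return(nrow(x$values))
    if (inherits(x, "presence_matrix")) return(nrow(x$by_line))
    if (inherits(x, "biomarker_report")) return(length(unlist(x$regions)))
    if (inherits(x, "ev_consensus")) return(nrow(x$counts))
    length(x)
  }
  stages <- vapply(res[setdiff(names(res), "manifest")], n_of, integer(1))
  list(package_version = as.character(utils::packageVersion("evcargo")),
       seed = seed, stages = stages)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_ratio_matrix(res$ratios, p("ratios.tsv"))
  .write_tsv(as.data.frame(res$annotation), p("ev_annotation.tsv"))
  .write_tsv(res$consensus$counts, p("consensus_counts.tsv"))
  .write_tsv(res$marker_qc, p("marker_qc.tsv"))
  for (nm in names(res$differential))
    .write_tsv(as.data.frame(res$differential[[nm]]),
               p(sprintf("differential_%s.tsv", gsub("[^A-Za-z0-9_.-]", "_",
                                                     nm))))
  write_biomarker_report(res$protein_report, p("protein_biomarkers"))
  if (!is.null(res$qc)) .write_tsv(as.data.frame(res$qc), p("qc.tsv"))
  if (!is.null(res$normalized))
    .write_tsv(.matrix_to_df(res$normalized$values, "gene"),
               p("normalized_counts.tsv"))
  if (!is.null(res$presence)) {
    .write_tsv(.matrix_to_df(res$presence$by_line, "gene"),
               p("presence_by_line.tsv"))
    .write_tsv(.matrix_to_df(res$presence$by_type, "gene"),
               p("presence_by_type.tsv"))
  }
  if (!is.null(res$mrna_report))
    write_biomarker_report(res$mrna_report, p("mrna_biomarkers"))
  if (!is.null(res$ranked)) write_rnk(res$ranked, p("ranked.rnk"))
  if (!is.null(res$gsea)) .write_tsv(as.data.frame(res$gsea), p("gsea.tsv"))
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}

#' Write a biomarker report as TSV plus a JSON region-size summary
#'
#' @param report a `biomarker_report`.
#' @param stem output path stem; writes `<stem>.tsv` (one row per gene or
#'   protein with its Venn region) and `<stem>.json` (region sizes).
#' @return `stem`, invisibly.
#' @export
write_biomarker_report <- function(report, stem) {
  stopifnot(inherits(report, "biomarker_report"))
  rows <- do.call(rbind, lapply(names(report$regions), function(nm) {
    ids <- report$regions[[nm]]
    if (!length(ids)) return(NULL)
    data.frame(id = ids, region = nm, stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(id = character(), region = character())
  .write_tsv(rows, paste0(stem, ".tsv"))
  jsonlite::write_json(as.list(report$sizes), paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
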