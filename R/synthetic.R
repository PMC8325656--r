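#' Configuration for the synthetic EV-cargo study generator
#'
#' Describes a simulated study shaped like the real one: a panel of renal
#' cell lines with benign/ccRCC/pRCC histology, TMT proteomics of EV, cell
#' lysate (CL) and debris (2K) fractions split over two plexes linked by a
#' pooled reference channel, and nCounter-style triplicate transcript counts.
#'
#' @param n_proteins,n_genes numbers of simulated proteins and endogenous
#'   probes (defaults 2000 and 770).
#' @param cell_lines named character vector: cell line -> histology. Default
#'   is the study panel (HK2/RPTEC benign, 786-O/769-P/Caki1 ccRCC,
#'   ACHN/Caki2 pRCC).
#' @param n_replicates_per_line transcript replicates per line (>= 2).
#' @param frac_ev_associated fraction of proteins planted as EV-enriched in
#'   every cell line.
#' @param frac_subtype_markers fraction of proteins (and of genes) planted as
#'   histology-specific cargo, per histology; marker sets are disjoint.
#' @param ev_logfc_mean mean planted EV-vs-CL log2 enrichment; must exceed
#'   0.58 so planted proteins clear the annotation threshold at zero noise.
#' @param noise_sd Gaussian channel noise, log2 units.
#' @param nb_dispersion negative-binomial dispersion of endogenous counts
#'   (0 = Poisson).
#' @param background_mean,background_sd background count distribution
#'   (truncated Gaussian, rounded) for negative controls and absent genes.
#' @param seed integer seed; identical (seed, config) gives bit-identical
#'   output.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 2000, n_genes = 770,
                             cell_lines = c("HK2" = "benign",
                                            "RPTEC" = "benign",
                                            "786-O" = "ccRCC",
                                            "769-P" = "ccRCC",
                                            "Caki1" = "ccRCC",
                                            "ACHN" = "pRCC",
                                            "Caki2" = "pRCC"),
                             n_replicates_per_line = 3,
                             frac_ev_associated = 0.10,
                             frac_subtype_markers = 0.015,
                             ev_logfc_mean = 2, noise_sd = 0.4,
                             nb_dispersion = 0.1,
                             background_mean = 12, background_sd = 4,
                             seed = 1) {
  for (pp in c(frac_ev_associated, frac_subtype_markers))
    if (pp < 0 || pp > 1) stop("proportions must lie in [0, 1]")
  if (n_replicates_per_line < 2)
    stop("n_replicates_per_line must be >= 2")
  if (ev_logfc_mean <= 0.58)
    stop("ev_logfc_mean must exceed 0.58 so planted proteins are separable")
  if (noise_sd < 0 || nb_dispersion < 0 || background_mean < 0 ||
      background_sd < 0)
    stop("noise, dispersion and background parameters must be non-negative")
  cell_lines <- unlist(cell_lines)
  bad <- !cell_lines %in% c("benign", "ccRCC", "pRCC")
  if (any(bad)) stop("histologies must be benign, ccRCC or pRCC")
  structure(list(n_proteins = n_proteins, n_genes = n_genes,
                 cell_lines = cell_lines,
                 n_replicates_per_line = n_replicates_per_line,
                 frac_ev_associated = frac_ev_associated,
                 frac_subtype_markers = frac_subtype_markers,
                 ev_logfc_mean = ev_logfc_mean, noise_sd = noise_sd,
                 nb_dispersion = nb_dispersion,
                 background_mean = background_mean,
                 background_sd = background_sd, seed = seed),
            class = "synthetic_config")
}

#' Read or write a synthetic configuration as YAML
#'
#' @param config a [synthetic_config()].
#' @param path file path.
#' @return `read_synthetic_config` returns a `synthetic_config`;
#'   `write_synthetic_config` returns `path` invisibly.
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  x <- unclass(config)
  x$cell_lines <- as.list(x$cell_lines)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$cell_lines <- unlist(x$cell_lines)
  do.call(synthetic_config, x)
}

.trunc_norm_counts <- function(n, mean, sd) {
  as.integer(round(pmax(0, stats::rnorm(n, mean, sd))))
}

#' Generate a synthetic TMT proteomics experiment with known truth
#'
#' Simulates log2 reporter abundances for EV, CL and 2K fractions of each
#' cell line, split across two plexes that share a pooled reference channel
#' and carry different global offsets (removed by reference normalization).
#' Planted EV-associated proteins get an EV-vs-CL (and EV-vs-2K) log2
#' enrichment of at least `ev_logfc_mean`; all other proteins are centred at
#' or below zero. Histology-marker proteins are quantified only in the lines
#' of their histology (and EV-enriched there), so detection-based selection
#' can recover them.
#'
#' @param config a [synthetic_config()].
#' @return list: `quant` (a [quant_table()]) and `truth` (list with
#'   `ev_associated` — cell line -> protein ids; `subtype_markers` —
#'   histology -> protein ids; `ev_logfc` — per-protein planted EV-vs-CL
#'   effect).
#' @export
generate_proteomics <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  np <- config$n_proteins
  lines <- names(config$cell_lines)
  proteins <- sprintf("P%04d", seq_len(np))

  n_ev <- round(config$frac_ev_associated * np)
  n_mark <- round(config$frac_subtype_markers * np)
  types <- unique(unname(config$cell_lines))
  ids <- sample(proteins)
  ev_set <- ids[seq_len(n_ev)]
  markers <- list()
  off <- n_ev
  for (h in types) {
    markers[[h]] <- if (n_mark) ids[off + seq_len(n_mark)] else character()
    off <- off + n_mark
  }

  delta <- numeric(np); names(delta) <- proteins
  delta[] <- -abs(stats::rnorm(np, 0, 0.3))
  planted <- c(ev_set, unlist(markers))
  delta[planted] <- config$ev_logfc_mean *
    (1 + abs(stats::rnorm(length(planted), 0, 0.15)))

  base <- stats::rnorm(np, 6, 1.5); names(base) <- proteins
  plex_of <- stats::setNames(rep_len(1:2, length(lines)), lines)
  plex_offset <- c(`1` = 0, `2` = 0.5)

  design <- list(); values <- list()
  for (p in 1:2) {
    ref_id <- sprintf("ref_plex%d", p)
    design[[ref_id]] <- data.frame(channel = ref_id, cell_line = "pooled",
                                   fraction = NA_character_, plex = p,
                                   is_reference = TRUE,
                                   stringsAsFactors = FALSE)
    values[[ref_id]] <- base + plex_offset[[p]] +
      stats::rnorm(np, 0, config$noise_sd)
  }
  for (line in lines) {
    p <- plex_of[[line]]
    h <- config$cell_lines[[line]]
    absent <- unlist(markers[setdiff(types, h)])
    for (frac in c("EV", "CL", "2K")) {
      ch <- sprintf("%s_%s", line, frac)
      design[[ch]] <- data.frame(channel = ch, cell_line = line,
                                 fraction = frac, plex = p,
                                 is_reference = FALSE,
                                 stringsAsFactors = FALSE)
      eff <- if (frac == "EV") delta else rep(0, np)
      v <- base + eff + plex_offset[[p]] + stats::rnorm(np, 0, config$noise_sd)
      v[match(absent, proteins)] <- NA_real_
      values[[ch]] <- v
    }
  }
  mat <- do.call(cbind, values)
  rownames(mat) <- proteins
  quant <- quant_table(mat, do.call(rbind, design))

  ev_by_line <- lapply(lines, function(line)
    sort(c(ev_set, markers[[config$cell_lines[[line]]]])))
  names(ev_by_line) <- lines
  truth <- list(ev_associated = ev_by_line,
                subtype_markers = lapply(markers, sort),
                ev_logfc = delta)
  list(quant = quant, truth = truth)
}

#' Generate synthetic nCounter-style transcript counts with known truth
#'
#' Endogenous probes: negative-binomial counts around line-specific means for
#' planted-present genes, background counts (truncated Gaussian) for absent
#' genes; a 6-probe positive-control ladder at geometric concentrations,
#' identical in expectation across samples up to a per-sample scale factor
#' that also multiplies endogenous counts; 8 negative-control probes from
#' the background distribution. Histology-marker genes are present only in
#' the lines of their histology. Presence truth is recorded per
#' (gene, cell line).
#'
#' @param config a [synthetic_config()].
#' @param present_mean_log2 mean of the per-gene log2 expression level for
#'   present genes (default 7, i.e. ~128 counts).
#' @param present_sd_log2 between-gene SD of that level (default 1.5).
#' @param qc_fail_samples sample ids whose endogenous probes are forced to
#'   background (simulated hybridization failure), for exercising QC.
#' @param positive_ladder expected counts of the positive-control ladder.
#' @return list: `counts` (a [count_matrix()]) and `truth` (list with
#'   `present` — logical gene x cell-line matrix; `subtype_markers` —
#'   histology -> gene ids; `expression` — per-gene mean level).
#' @export
generate_nanostring <- function(config, present_mean_log2 = 7,
                                present_sd_log2 = 1.5,
                                qc_fail_samples = character(),
                                positive_ladder = c(7680, 1920, 480, 120,
                                                    30, 8)) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  ng <- config$n_genes
  lines <- names(config$cell_lines)
  types <- unique(unname(config$cell_lines))
  genes <- sprintf("G%04d", seq_len(ng))

  n_mark <- round(config$frac_subtype_markers * ng)
  ids <- sample(genes)
  markers <- list(); off <- 0
  for (h in types) {
    markers[[h]] <- if (n_mark) ids[off + seq_len(n_mark)] else character()
    off <- off + n_mark
  }
  rest <- ids[-seq_len(off)]
  n_rest <- length(rest)
  grp <- sample(c("all", "none", "random"), n_rest, replace = TRUE,
                prob = c(0.45, 0.20, 0.35))

  present <- matrix(FALSE, ng, length(lines),
                    dimnames = list(genes, lines))
  present[rest[grp == "all"], ] <- TRUE
  rnd <- rest[grp == "random"]
  present[rnd, ] <- matrix(stats::runif(length(rnd) * length(lines)) < 0.5,
                           length(rnd), length(lines))
  for (h in types)
    present[markers[[h]], lines[config$cell_lines == h]] <- TRUE

  mu <- 2^stats::rnorm(ng, present_mean_log2, present_sd_log2)
  names(mu) <- genes
  line_shift <- matrix(2^stats::rnorm(ng * length(lines), 0, 0.25), ng,
                       dimnames = list(genes, lines))

  nrep <- config$n_replicates_per_line
  sample_ids <- as.vector(vapply(lines, function(l)
    sprintf("%s_r%d", l, seq_len(nrep)), character(nrep)))
  samples <- data.frame(sample = sample_ids,
                        cell_line = rep(lines, each = nrep),
                        replicate = rep(seq_len(nrep), length(lines)),
                        stringsAsFactors = FALSE)
  scale_fac <- 2^stats::rnorm(length(sample_ids), 0, 0.15)
  names(scale_fac) <- sample_ids

  draw_counts <- function(mu_vec) {
    if (config$nb_dispersion == 0) stats::rpois(length(mu_vec), mu_vec)
    else stats::rnbinom(length(mu_vec), mu = mu_vec,
                        size = 1 / config$nb_dispersion)
  }
  endo <- matrix(0L, ng, length(sample_ids),
                 dimnames = list(genes, sample_ids))
  for (j in seq_along(sample_ids)) {
    line <- samples$cell_line[[j]]
    forced_bg <- sample_ids[[j]] %in% qc_fail_samples
    on <- present[, line] & !forced_bg
    cnt <- .trunc_norm_counts(ng, config$background_mean,
                              config$background_sd)
    if (any(on))
      cnt[on] <- as.integer(draw_counts(mu[on] * line_shift[on, line] *
                                          scale_fac[[j]]))
    endo[, j] <- cnt
  }

  pos <- t(vapply(positive_ladder, function(lv)
    as.integer(stats::rpois(length(sample_ids), lv * scale_fac)),
    integer(length(sample_ids))))
  rownames(pos) <- sprintf("POS_%s", LETTERS[seq_along(positive_ladder)])
  colnames(pos) <- sample_ids
  neg <- matrix(.trunc_norm_counts(8L * length(sample_ids),
                                   config$background_mean,
                                   config$background_sd),
                8L, length(sample_ids),
                dimnames = list(sprintf("NEG_%d", 1:8), sample_ids))

  counts <- rbind(endo, pos, neg)
  probe_class <- rep(c("endogenous", "positive", "negative"),
                     c(ng, nrow(pos), nrow(neg)))
  cm <- count_matrix(counts, probe_class, samples)
  truth <- list(present = present, subtype_markers = lapply(markers, sort),
                expression = mu)
  list(counts = cm, truth = truth)
}
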