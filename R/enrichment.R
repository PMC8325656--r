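#' Rank genes by group fold change on normalized counts
#'
#' Ranking metric: `log2((mean_A + pseudocount) / (mean_B + pseudocount))`
#' over median-normalized counts, genes in descending order, ties broken
#' alphabetically by gene id so the order is deterministic.
#'
#' @param norm a `normalized_counts`.
#' @param group_a,group_b cell-line names (expanded to their samples) or
#'   sample ids; both non-empty.
#' @param pseudocount added to both means before the ratio (default 1).
#' @return Named numeric vector of class `ranked_list`, sorted decreasing.
#' @export
rank_genes <- function(norm, group_a, group_b, pseudocount = 1) {
  stopifnot(inherits(norm, "normalized_counts"))
  expand <- function(g) {
    s <- unlist(lapply(g, function(x) {
      if (x %in% norm$samples$sample) return(x)
      norm$samples$sample[norm$samples$cell_line == x]
    }))
    unique(s)
  }
  sa <- expand(group_a); sb <- expand(group_b)
  if (!length(sa) || !length(sb))
    stop("both groups must resolve to at least one sample")
  ma <- rowMeans(norm$values[, sa, drop = FALSE])
  mb <- rowMeans(norm$values[, sb, drop = FALSE])
  metric <- log2((ma + pseudocount) / (mb + pseudocount))
  ranked_list(metric)
}

#' Construct a ranked gene list
#'
#' @param metric named numeric vector of finite ranking-metric values; no
#'   duplicated names.
#' @return The vector sorted in decreasing metric order (ties by gene id),
#'   class `ranked_list`.
#' @export
ranked_list <- function(metric) {
  if (is.null(names(metric)) || anyDuplicated(names(metric)))
    stop("metric must be named with unique gene ids")
  if (any(!is.finite(metric))) stop("ranking metric must be finite")
  metric <- metric[order(-metric, names(metric), method = "radix")]
  class(metric) <- c("ranked_list", "numeric")
  metric
}

#' Weighted running-sum enrichment score
#'
#' The classic GSEA statistic: walking down the ranked list, the running sum
#' gains `|metric|^p / sum(|metric|^p over hits)` at each gene of the set
#' (a hit) and loses `1 / (N - N_hits)` at each miss; the enrichment score
#' is the running-sum value of maximal absolute deviation from zero. The
#' leading edge is the set members at or before the extremum (after it for a
#' negative score).
#'
#' @param ranked a [ranked_list()].
#' @param gene_set character vector of gene ids; must intersect the list and,
#'   unless it covers the whole list, be a proper subset.
#' @param p weight exponent (default 1, the "weighted" statistic; 0 gives
#'   the unweighted Kolmogorov-Smirnov form).
#' @return list: `es`, `running_sum` (numeric, one value per ranked gene),
#'   `leading_edge` (character), `hits` (logical vector over the list).
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  stopifnot(inherits(ranked, "ranked_list"), p >= 0)
  hits <- names(ranked) %in% gene_set
  nh <- sum(hits)
  if (nh == 0L) stop("gene set is disjoint from the ranked list")
  n <- length(ranked)
  step <- numeric(n)
  if (nh == n) {
    step[hits] <- .hit_increments(abs(ranked)[hits], p)
  } else {
    step[hits] <- .hit_increments(abs(ranked)[hits], p)
    step[!hits] <- -1 / (n - nh)
  }
  running <- cumsum(step)
  i_ext <- which.max(abs(running))
  es <- running[[i_ext]]
  leading <- if (es >= 0) names(ranked)[hits & seq_len(n) <= i_ext]
             else names(ranked)[hits & seq_len(n) >= i_ext]
  list(es = es, running_sum = running, leading_edge = leading, hits = hits)
}

.hit_increments <- function(w, p) {
  w <- w^p
  tot <- sum(w)
  if (tot == 0) rep(1 / length(w), length(w)) else w / tot
}

# ES for hit positions only (sorted), avoiding the full running sum; the
# extremum is always at a hit (top candidate) or just before one (bottom
# candidate). Used in the permutation loop.
.es_at_positions <- function(abs_metric_p, pos, n, csum = NULL) {
  pos <- sort.int(pos)
  k <- length(pos)
  w <- abs_metric_p[pos]
  tot <- sum(w)
  hit_cum <- if (tot == 0) seq_len(k) / k else cumsum(w) / tot
  dec <- 1 / (n - k)
  miss_before <- (pos - seq_len(k)) * dec
  tops <- hit_cum - miss_before
  bottoms <- c(0, hit_cum[-k]) - miss_before
  hi <- max(tops); lo <- min(bottoms)
  if (hi >= -lo) hi else lo
}

#' Gene set enrichment analysis with a permutation null
#'
#' For each gene set: observed enrichment score ([enrichment_score()]);
#' a gene-label permutation null (random sets of the same size drawn from
#' the ranked list, `n_permutations` times, seeded); nominal p with the
#' same-sign convention and add-one smoothing,
#' `p = (1 + #same-sign permuted |ES| >= |ES|) / (1 + #permutations of that
#' sign)`; NES = ES divided by the mean |permuted ES| of the same sign; and
#' an FDR q from the standard pooled-NES ratio. A set is flagged significant
#' when nominal p and q both pass their cutoffs.
#'
#' @param ranked a [ranked_list()].
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]); sets are intersected with the ranked list and must stay
#'   non-empty.
#' @param weight_p weight exponent (default 1).
#' @param n_permutations permutation draws per set (default 1000).
#' @param nominal_p_cutoff,fdr_q_cutoff significance cutoffs (defaults 0.05
#'   and 0.25).
#' @param seed integer seed for the permutation stream.
#' @param min_size drop sets with fewer than this many genes in the list.
#' @return data.frame of class `gsea_result`: `set`, `size`, `es`, `nes`,
#'   `p`, `q`, `significant`, `degenerate_null`, `leading_edge`
#'   (comma-separated).
#' @export
gsea <- function(ranked, gene_sets, weight_p = 1, n_permutations = 1000,
                 nominal_p_cutoff = 0.05, fdr_q_cutoff = 0.25, seed = 1,
                 min_size = 2) {
  stopifnot(inherits(ranked, "ranked_list"), n_permutations >= 1)
  if (is.null(names(gene_sets))) stop("gene_sets must be named")
  sets <- lapply(gene_sets, intersect, x = names(ranked))
  keep <- lengths(sets) >= min_size & lengths(sets) < length(ranked)
  if (!any(keep)) stop("no gene set overlaps the ranked list adequately")
  sets <- sets[keep]

  n <- length(ranked)
  absw <- abs(unclass(ranked))^weight_p
  set.seed(seed)

  rows <- vector("list", length(sets))
  perm_nes_pool <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    sc <- enrichment_score(ranked, sets[[i]], weight_p)
    k <- length(sets[[i]])
    perm_es <- vapply(seq_len(n_permutations), function(j)
      .es_at_positions(absw, sample.int(n, k), n), numeric(1))
    pos <- perm_es[perm_es >= 0]; neg <- perm_es[perm_es < 0]
    same <- if (sc$es >= 0) pos else neg
    degenerate <- length(same) == 0L
    # tolerance keeps permutations that tie the observed ES (up to
    # floating-point path differences) in the tail count
    p <- if (degenerate) 1 / (n_permutations + 1)
         else (1 + sum(abs(same) >= abs(sc$es) - 1e-10)) /
              (1 + length(same))
    nes <- if (degenerate) NA_real_ else sc$es / mean(abs(same))
    perm_nes <- rep(NA_real_, n_permutations)
    if (length(pos)) perm_nes[perm_es >= 0] <- pos / mean(pos)
    if (length(neg)) perm_nes[perm_es < 0] <- neg / mean(abs(neg))
    perm_nes_pool[[i]] <- perm_nes[!is.na(perm_nes)]
    rows[[i]] <- data.frame(
      set = names(sets)[[i]], size = k, es = sc$es, nes = nes, p = p,
      q = NA_real_, significant = NA, degenerate_null = degenerate,
      leading_edge = paste(sc$leading_edge, collapse = ","),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  pool <- unlist(perm_nes_pool)
  res$q <- vapply(res$nes, .gsea_fdr, numeric(1),
                  obs = res$nes, pool = pool)
  res$significant <- !is.na(res$q) & res$p < nominal_p_cutoff &
    res$q < fdr_q_cutoff
  rownames(res) <- NULL
  class(res) <- c("gsea_result", "data.frame")
  res
}

# Standard GSEA FDR: fraction of pooled permuted NES at least as extreme
# (same sign) over fraction of observed NES at least as extreme, capped at 1.
.gsea_fdr <- function(nes, obs, pool) {
  if (is.na(nes)) return(NA_real_)
  obs <- obs[!is.na(obs)]
  if (nes >= 0) {
    denom_pool <- sum(pool >= 0); denom_obs <- sum(obs >= 0)
    if (!denom_pool || !denom_obs) return(NA_real_)
    num <- sum(pool >= nes) / denom_pool
    den <- sum(obs >= nes) / denom_obs
  } else {
    denom_pool <- sum(pool < 0); denom_obs <- sum(obs < 0)
    if (!denom_pool || !denom_obs) return(NA_real_)
    num <- sum(pool <= nes) / denom_pool
    den <- sum(obs <= nes) / denom_obs
  }
  min(1, num / max(den, .Machine$double.eps))
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of drawing at
#' least the observed overlap between the selected genes and the set when
#' sampling `|selected|` genes from the universe without replacement;
#' Benjamini-Hochberg adjustment across sets. The universe defaults to the
#' genes quantified in the experiment, so inference is conditioned on
#' detection.
#'
#' @param selected character vector of selected genes; must be a subset of
#'   `universe`.
#' @param universe character vector, the background gene population.
#' @param gene_sets named list of character vectors; each is intersected
#'   with the universe (sets that vanish are dropped with a warning).
#' @return data.frame of class `ora_result`: `set`, `set_size`, `overlap`,
#'   `selected_size`, `universe_size`, `p`, `q`, `genes` (overlap ids,
#'   comma-separated).
#' @export
ora <- function(selected, universe, gene_sets) {
  selected <- unique(selected); universe <- unique(universe)
  if (length(setdiff(selected, universe)))
    stop("selected genes must be a subset of the universe")
  if (is.null(names(gene_sets))) stop("gene_sets must be named")
  sets <- lapply(gene_sets, intersect, x = universe)
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("dropping set(s) with no universe overlap: ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  if (!length(sets)) stop("no gene set overlaps the universe")
  nU <- length(universe); nS <- length(selected)
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    ov <- intersect(s, selected)
    p <- stats::phyper(length(ov) - 1L, length(s), nU - length(s), nS,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = length(ov),
               selected_size = nS, universe_size = nU, p = p, q = NA_real_,
               genes = paste(ov, collapse = ","), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  rownames(res) <- NULL
  class(res) <- c("ora_result", "data.frame")
  res
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up procedure with monotonicity enforcement.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
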