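# Shared toy-data builders. Everything is constructed in code; no files.

# Two-plex quant table with hand-pickable channel values. `channels` is a
# named list: channel id -> c(cell_line, fraction, plex) ("REF" fraction
# marks the reference). Values default to zero and can be overridden per
# channel with a numeric vector over proteins.
make_quant <- function(proteins, channels, values = list()) {
  mat <- matrix(0, length(proteins), length(channels),
                dimnames = list(proteins, names(channels)))
  for (ch in names(values)) mat[, ch] <- values[[ch]]
  design <- do.call(rbind, lapply(names(channels), function(ch) {
    x <- channels[[ch]]
    data.frame(channel = ch, cell_line = x[[1]],
               fraction = if (x[[2]] == "REF") NA_character_ else x[[2]],
               plex = as.integer(x[[3]]), is_reference = x[[2]] == "REF",
               stringsAsFactors = FALSE)
  }))
  quant_table(mat, design)
}

# Single-plex quant table giving exact EV/CL/2K reference ratios per line:
# ratios is a list cell_line -> list(EV=, CL=, `2K`=) of per-protein vectors
# (NA allowed). Reference channel is zero so channel value == ratio.
make_ratio_quant <- function(proteins, ratios) {
  channels <- list(ref = c("pooled", "REF", 1))
  values <- list()
  for (line in names(ratios)) {
    for (frac in names(ratios[[line]])) {
      ch <- paste0(line, "_", frac)
      channels[[ch]] <- c(line, frac, 1)
      values[[ch]] <- ratios[[line]][[frac]]
    }
  }
  make_quant(proteins, channels, values)
}

make_ratios <- function(proteins, ratios) {
  merge_plexes(compute_reference_ratios(make_ratio_quant(proteins, ratios)))
}

# Count matrix from an endogenous block plus explicit control probes.
make_counts <- function(endo, pos, neg, cell_line = NULL, replicate = NULL) {
  counts <- rbind(endo, pos, neg)
  rownames(counts) <- c(rownames(endo),
                        sprintf("POS_%d", seq_len(nrow(pos))),
                        sprintf("NEG_%d", seq_len(nrow(neg))))
  if (is.null(cell_line)) cell_line <- rep("A", ncol(endo))
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(cell_line), cell_line,
                            FUN = seq_along)
  }
  samples <- data.frame(sample = colnames(endo), cell_line = cell_line,
                        replicate = replicate, stringsAsFactors = FALSE)
  count_matrix(counts, rep(c("endogenous", "positive", "negative"),
                           c(nrow(endo), nrow(pos), nrow(neg))),
               samples)
}

# Independent brute-force running-sum ES: literal loop over the ranked list.
brute_force_es <- function(metric_sorted, set, p = 1) {
  hits <- names(metric_sorted) %in% set
  nh <- sum(hits)
  n <- length(metric_sorted)
  denom <- sum(abs(metric_sorted[hits])^p)
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    if (hits[[i]]) {
      run <- run + if (denom == 0) 1 / nh else abs(metric_sorted[[i]])^p / denom
    } else {
      run <- run - 1 / (n - nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}
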