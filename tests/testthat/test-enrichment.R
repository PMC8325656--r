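test_that("ranking metric is the log2 ratio of pseudocounted group means", {
  endo <- matrix(c(100L, 50L, 200L, 100L, 50L, 100L,
                   100L, 50L, 200L, 100L, 25L, 400L), 6,
                 dimnames = list(sprintf("g%d", 1:6), c("a1", "b1")))
  pos <- matrix(rep(c(100L, 400L), 2), 2,
                dimnames = list(NULL, c("a1", "b1")))
  neg <- matrix(rep(10L, 4), 2)
  cm <- make_counts(endo, pos, neg, cell_line = c("A", "B"))
  norm <- normalize_counts(cm, qc_samples(cm,
                                          min_fraction_above_background = 0))
  r <- rank_genes(norm, "A", "B", pseudocount = 0)
  # medians equal -> unit factors; hand metric log2(colA/colB)
  want <- log2(endo[, 1] / endo[, 2])
  expect_equal(unname(r[names(want)[order(-want, names(want))]]),
               unname(sort(want, decreasing = TRUE)))
  expect_equal(r[["g5"]], 1)          # 50 vs 25
  expect_equal(r[["g1"]], 0)          # equal means
  expect_error(rank_genes(norm, "A", "missing"), "at least one sample")
})

test_that("ranked lists are deterministic, finite, duplicate-free", {
  expect_error(ranked_list(c(a = 1, a = 2)), "unique")
  expect_error(ranked_list(setNames(Inf, "a")), "finite")
  r <- ranked_list(c(b = 1, a = 1, c = 2))
  expect_equal(names(r), c("c", "a", "b"))   # ties broken by id
})

test_that("enrichment score equals the brute-force running sum", {
  set.seed(41)
  for (i in 1:50) {
    metric <- ranked_list(setNames(rnorm(10), paste0("g", 1:10)))
    set <- sample(names(metric), 3)
    sc <- enrichment_score(metric, set)
    expect_equal(sc$es, brute_force_es(metric, set))
    expect_lte(abs(sc$es), 1)
    expect_equal(sc$running_sum[10], 0, tolerance = 1e-12)
  }
})

test_that("degenerate sets produce the expected extreme scores", {
  metric <- ranked_list(setNames(c(3, 2, 1, -1, -2), paste0("g", 1:5)))
  expect_equal(enrichment_score(metric, names(metric))$es, 1)
  expect_equal(enrichment_score(metric, "g1", p = 0)$es, 1)
  expect_error(enrichment_score(metric, "zz"), "disjoint")
  # leading edge: members before the positive extremum
  sc <- enrichment_score(metric, c("g1", "g2", "g5"))
  expect_true(all(sc$leading_edge %in% c("g1", "g2")))
})

test_that("enrichment scores match the fgsea reference on random instances", {
  skip_if_not_installed("fgsea")
  set.seed(43)
  for (i in 1:20) {
    metric <- ranked_list(setNames(rnorm(30), sprintf("g%02d", 1:30)))
    set <- sample(names(metric), 5)
    ours <- enrichment_score(metric, set)$es
    ref <- fgsea::calcGseaStat(unclass(metric),
                               which(names(metric) %in% set),
                               gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-8)
  }
})

test_that("permutation p converges to exhaustive enumeration on 8 genes", {
  metric <- ranked_list(setNames(c(2.5, 1.8, 1.2, 0.6, -0.4, -0.9, -1.5,
                                   -2.2), paste0("g", 1:8)))
  set <- c("g1", "g2", "g4")
  obs <- enrichment_score(metric, set)$es
  # exhaustive: all C(8,3) = 56 placements of a size-3 set
  all_es <- apply(combn(8, 3), 2, function(idx)
    brute_force_es(metric, names(metric)[idx]))
  same_sign <- all_es[sign(all_es) == sign(obs) | all_es == 0]
  exact_tail <- mean(abs(same_sign) >= abs(obs))
  res <- gsea(metric, list(s = set), n_permutations = 4000, seed = 2)
  # MC tolerance: 3 binomial SEs around the exhaustive tail probability
  se <- sqrt(exact_tail * (1 - exact_tail) / 4000)
  expect_lt(abs(res$p - exact_tail), max(3 * se, 0.02))
  expect_equal(res$es, obs)
  expect_lte(abs(res$es), 1)
})

test_that("strong planted enrichment is significant; permutations reproduce", {
  set.seed(47)
  metric <- ranked_list(setNames(c(sort(runif(20, 2, 3), decreasing = TRUE),
                                   rnorm(80, 0, 0.3)),
                                 sprintf("g%03d", 1:100)))
  sets <- list(top = names(metric)[1:10],
               random = sample(names(metric), 10))
  r1 <- gsea(metric, sets, n_permutations = 500, seed = 5)
  r2 <- gsea(metric, sets, n_permutations = 500, seed = 5)
  expect_identical(r1, r2)
  expect_true(r1$significant[r1$set == "top"])
  expect_lt(r1$p[r1$set == "top"], 0.05)
})

test_that("hypergeometric ORA equals exhaustive draw enumeration", {
  # universe 10, set of 5, select 5, all 5 in the set: p = 1/C(10,5)
  universe <- paste0("u", 1:10)
  gs <- list(s = universe[1:5])
  res <- ora(universe[1:5], universe, gs)
  expect_equal(res$p, 1 / choose(10, 5))
  # enumeration oracle: P(overlap >= k) over all C(10,5) selections
  sel_all <- combn(10, 5)
  for (k_obs in c(2, 3)) {
    selected <- c(universe[seq_len(k_obs)],
                  universe[6:(6 + 4 - k_obs)])   # 5 picks, k_obs in the set
    obs <- length(intersect(selected, gs$s))
    tail_p <- mean(apply(sel_all, 2, function(ix) sum(ix <= 5) >= obs))
    expect_equal(ora(selected, universe, gs)$p, tail_p)
  }
  # set equal to the universe: p = 1 whatever is selected
  expect_equal(ora(universe[c(1, 7)], universe, list(all = universe))$p, 1)
  expect_error(ora(c("u1", "zz"), universe, gs), "subset")
})

test_that("BH adjustment matches independent step-up arithmetic", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # independent step-up oracle on random vectors
  set.seed(53)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    m <- length(p)
    ord <- order(p)
    q_sorted <- p[ord] * m / seq_len(m)
    for (j in (m - 1):1) q_sorted[j] <- min(q_sorted[j], q_sorted[j + 1])
    q <- numeric(m); q[ord] <- pmin(q_sorted, 1)
    expect_equal(bh_adjust(p), q)
  }
})

test_that("GSEA nominal p is calibrated under a null metric", {
  set.seed(59)
  metric <- ranked_list(setNames(rnorm(200), sprintf("g%03d", 1:200)))
  sets <- lapply(1:120, function(i) sample(names(metric), 15))
  names(sets) <- paste0("s", 1:120)
  res <- gsea(metric, sets, n_permutations = 400, seed = 3)
  frac <- mean(res$p < 0.05)
  se <- sqrt(0.05 * 0.95 / 120)
  expect_lt(frac, 0.05 + 3 * se)
})
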