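# Builds a normalized_counts whose detection outcome is fully controlled:
# negatives are constant (threshold = background_mean exactly) and all
# samples share identical controls so both normalization factors are 1.
make_norm <- function(endo, cell_line, bg = 10L) {
  pos <- matrix(rep(c(100L, 400L), ncol(endo)), 2,
                dimnames = list(NULL, colnames(endo)))
  neg <- matrix(rep(bg, 2 * ncol(endo)), 2,
                dimnames = list(NULL, colnames(endo)))
  cm <- make_counts(endo, pos, neg, cell_line = cell_line)
  normalize_counts(cm, qc_samples(cm, min_fraction_above_background = 0))
}

test_that("detection is strictly above the per-sample threshold", {
  endo <- matrix(c(10L, 11L, 9L, 10L), 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  norm <- make_norm(endo, c("A", "A"))
  det <- detect_replicates(norm)
  expect_identical(unname(det),
                   matrix(c(FALSE, TRUE, FALSE, FALSE), 2))
  # elementwise comparison oracle on random counts
  set.seed(23)
  endo2 <- matrix(rpois(60, 10), 20,
                  dimnames = list(sprintf("g%02d", 1:20),
                                  c("s1", "s2", "s3")))
  norm2 <- make_norm(endo2, c("A", "A", "A"))
  expect_identical(unname(detect_replicates(norm2)), unname(endo2 > 10))
})

test_that("replicate-majority rule calls cell-line presence", {
  # g1: 2/3 detected -> present; g2: 1/3 -> absent; g3: 3/3 -> present
  endo <- matrix(c(20L, 20L, 5L,   20L, 5L, 5L,   5L, 20L, 20L), 3,
                 byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"),
                                 c("A_r1", "A_r2", "A_r3")))
  norm <- make_norm(endo, rep("A", 3))
  pres <- call_presence(detect_replicates(norm), norm$samples,
                        histology = histology_map(c(A = "benign")))
  expect_identical(unname(pres$by_line[, "A"]), c(TRUE, FALSE, TRUE))
  # 2/2 rule after losing a replicate
  norm2 <- make_norm(endo[, 1:2], rep("A", 2))
  pres2 <- call_presence(detect_replicates(norm2), norm2$samples,
                         histology = histology_map(c(A = "benign")))
  expect_identical(unname(pres2$by_line[, "A"]), c(TRUE, FALSE, FALSE))
})

test_that("presence is invariant to replicate order", {
  set.seed(29)
  endo <- matrix(rpois(30, 12), 10,
                 dimnames = list(sprintf("g%02d", 1:10),
                                 c("A_r1", "A_r2", "A_r3")))
  norm <- make_norm(endo, rep("A", 3))
  det <- detect_replicates(norm)
  base <- call_presence(det, norm$samples,
                        histology = histology_map(c(A = "benign")))
  perm <- c(3, 1, 2)
  shuffled <- call_presence(det[, perm], norm$samples[perm, ],
                            histology = histology_map(c(A = "benign")))
  expect_identical(base$by_line, shuffled$by_line)
})

test_that("type presence needs every line of the type (2/2 rule)", {
  endo <- matrix(c(20L, 20L, 20L, 5L), 1,
                 dimnames = list("g1", c("HK2_r1", "HK2_r2",
                                         "RPTEC_r1", "RPTEC_r2")))
  norm <- make_norm(endo, c("HK2", "HK2", "RPTEC", "RPTEC"))
  pres <- call_presence(detect_replicates(norm), norm$samples)
  expect_true(pres$by_line["g1", "HK2"])
  expect_false(pres$by_line["g1", "RPTEC"])
  expect_false(pres$by_type["g1", "benign"])   # HK2 present, RPTEC absent
})

test_that("single-line histologies yield no consensus type call", {
  endo <- matrix(20L, 1, 4,
                 dimnames = list("g1", c("HK2_r1", "RPTEC_r1",
                                         "ACHN_r1", "ACHN_r2")))
  norm <- make_norm(endo, c("HK2", "RPTEC", "ACHN", "ACHN"))
  pres <- call_presence(detect_replicates(norm), norm$samples)
  expect_true("benign" %in% colnames(pres$by_type))
  expect_true("pRCC" %in% pres$non_consensus_types)
  expect_false("pRCC" %in% colnames(pres$by_type))
  expect_error(venn_mrna(pres, c("benign", "pRCC")), "no consensus")
})

test_that("mRNA Venn selection follows set arithmetic on type presence", {
  # a: benign only; b: both; c: ccRCC only
  endo <- matrix(5L, 3, 8,
                 dimnames = list(c("a", "b", "c"),
                                 sprintf("s%d", 1:8)))
  lines <- rep(c("HK2", "RPTEC", "786-O", "769-P"), each = 2)
  colnames(endo) <- paste0(lines, "_r", rep(1:2, 4))
  endo["a", 1:4] <- 20L
  endo["b", ] <- 20L
  endo["c", 5:8] <- 20L
  norm <- make_norm(endo, lines)
  pres <- call_presence(detect_replicates(norm), norm$samples)
  v <- venn_mrna(pres)
  expect_equal(v$regions[["benign"]], "a")
  expect_equal(v$regions[["ccRCC"]], "c")
  expect_equal(v$regions[["benign+ccRCC"]], "b")
  # identical / disjoint degenerate cases
  endo2 <- endo; endo2["a", ] <- 20L; endo2["c", ] <- 20L
  v2 <- venn_mrna(call_presence(detect_replicates(make_norm(endo2, lines)),
                                norm$samples))
  expect_equal(lengths(v2$regions)[["benign"]], 0L)
  expect_equal(lengths(v2$regions)[["ccRCC"]], 0L)
})

test_that("detected-anywhere and present-everywhere sets nest correctly", {
  endo <- matrix(c(20L, rep(5L, 5),    # g1: one replicate of one line
                   rep(20L, 6),        # g2: everywhere
                   rep(5L, 6)), 3,     # g3: nowhere
                 byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"), sprintf("s%d", 1:6)))
  lines <- rep(c("HK2", "RPTEC", "786-O"), each = 2)
  norm <- make_norm(endo, lines)
  pres <- call_presence(detect_replicates(norm), norm$samples,
                        histology = histology_map())
  got <- detected_anywhere(pres)
  expect_setequal(got$any_sample, c("g1", "g2"))
  expect_equal(got$all_lines, "g2")
  expect_true(all(got$all_lines %in% got$any_sample))
  # brute-force scan oracle on random detection
  set.seed(37)
  endo2 <- matrix(rpois(60, 10L), 10,
                  dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:6)))
  norm2 <- make_norm(endo2, lines)
  det2 <- detect_replicates(norm2)
  pres2 <- call_presence(det2, norm2$samples)
  got2 <- detected_anywhere(pres2)
  expect_setequal(got2$any_sample,
                  rownames(det2)[apply(det2, 1, any)])
  expect_setequal(got2$all_lines,
                  rownames(det2)[apply(pres2$by_line, 1, all)])
})

test_that("presence rules validate and fall back to strict majority", {
  expect_error(presence_rules(c("3" = 4)), "must not exceed")
  expect_error(presence_rules(c("3" = 0)), ">= 1")
  r <- presence_rules()
  expect_equal(evcargo:::.required_detections(r, 3), 2L)
  expect_equal(evcargo:::.required_detections(r, 2), 2L)
  expect_equal(evcargo:::.required_detections(r, 5), 3L)
})
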