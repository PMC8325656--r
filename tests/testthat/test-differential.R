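test_that("pairwise differential applies the strict +/-0.58 rule", {
  rm <- make_ratios(c("p1", "p2", "p3", "p4", "p5"),
    list(A = list(EV = c(1.2, -0.58, 0, 2, NA)),
         B = list(EV = c(0, 0, 0.5, 3, 1))))
  d <- differential_pairwise(rm, "A", "B")
  expect_equal(d$direction, c("increased", "neither", "neither",
                              "decreased", "neither"))
  expect_true(d$missing[5])
  expect_error(differential_pairwise(rm, "Z", "B"), "unknown cell line")
  # elementwise sign/threshold oracle on random values
  set.seed(5)
  a <- rnorm(30); b <- rnorm(30)
  rm2 <- make_ratios(sprintf("p%02d", 1:30),
                     list(A = list(EV = a), B = list(EV = b)))
  d2 <- differential_pairwise(rm2, "A", "B")
  oracle <- ifelse(a - b > 0.58, "increased",
                   ifelse(a - b < -0.58, "decreased", "neither"))
  expect_equal(d2$direction, unname(oracle))
})

test_that("group consensus equals the brute-force all-pairs conjunction", {
  set.seed(11)
  ga <- c("A1", "A2"); gb <- c("B1", "B2", "B3")
  for (rep in 1:20) {
    vals <- lapply(setNames(nm = c(ga, gb)),
                   function(...) list(EV = rnorm(12, sd = 1.5)))
    vals$A1$EV[sample(12, 2)] <- NA
    rm <- make_ratios(sprintf("p%02d", 1:12), vals)
    got <- differential_group(rm, ga, gb)
    # brute force: literal loop over proteins and line pairs
    for (i in 1:12) {
      dirs <- c(); miss <- FALSE
      for (a in ga) for (b in gb) {
        delta <- vals[[a]]$EV[i] - vals[[b]]$EV[i]
        if (is.na(delta)) miss <- TRUE
        else dirs <- c(dirs, if (delta > 0.58) "increased"
                       else if (delta < -0.58) "decreased" else "neither")
      }
      want <- if (miss) "neither"
        else if (all(dirs == "increased")) "increased"
        else if (all(dirs == "decreased")) "decreased" else "neither"
      expect_equal(got$direction[i], want)
    }
  }
})

test_that("one failing pair blocks group consensus; groups must not overlap", {
  # 5 of 6 pairs clear the threshold, one sits at 0.1
  vals <- list(A1 = list(EV = 2), A2 = list(EV = 0.1 + 0),
               B1 = list(EV = 0), B2 = list(EV = -1), B3 = list(EV = -2))
  vals$A2$EV <- 0.1   # A2 vs B1 delta = 0.1 fails
  rm <- make_ratios("p1", vals)
  d <- differential_group(rm, c("A1", "A2"), c("B1", "B2", "B3"))
  expect_equal(d$direction, "neither")
  expect_error(differential_group(rm, c("A1", "B1"), c("B1", "B2")),
               "overlap")
  expect_error(differential_group(rm, character(), "B1"), "non-empty")
})

test_that("group differential is antisymmetric and nested in pairwise sets", {
  set.seed(21)
  lines <- c("A1", "A2", "B1", "B2")
  vals <- lapply(setNames(nm = lines),
                 function(...) list(EV = rnorm(40, sd = 2)))
  rm <- make_ratios(sprintf("p%02d", 1:40), vals)
  ab <- differential_group(rm, c("A1", "A2"), c("B1", "B2"))
  ba <- differential_group(rm, c("B1", "B2"), c("A1", "A2"))
  expect_equal(ab$protein[ab$direction == "increased"],
               ba$protein[ba$direction == "decreased"])
  expect_equal(ab$protein[ab$direction == "decreased"],
               ba$protein[ba$direction == "increased"])
  inc <- ab$protein[ab$direction == "increased"]
  for (a in c("A1", "A2")) for (b in c("B1", "B2")) {
    pw <- differential_pairwise(rm, a, b)
    expect_true(all(inc %in% pw$protein[pw$direction == "increased"]))
  }
})

test_that("group-mean alternative thresholds the difference of group means", {
  vals <- list(A1 = list(EV = 1), A2 = list(EV = 0.4),
               B1 = list(EV = 0), B2 = list(EV = 0))
  rm <- make_ratios("p1", vals)
  # all-pairs: A2 vs B* delta 0.4 fails; mean delta 0.7 passes
  expect_equal(differential_group(rm, c("A1", "A2"),
                                  c("B1", "B2"))$direction, "neither")
  expect_equal(differential_group(rm, c("A1", "A2"), c("B1", "B2"),
                                  method = "mean")$direction, "increased")
})

test_that("concordance keeps proteins with matching CL and EV direction", {
  rm <- make_ratios(c("p1", "p2", "p3", "p4"),
    list(A = list(EV = c(1, 1, -1, 0), CL = c(1, 0, -1, 0)),
         HK2 = list(EV = c(0, 0, 0, 0), CL = c(0, 0, 0, 0))))
  got <- concordance(rm, "A")
  # p1: CL up + EV up; p2: CL neither; p3: both down; p4: both neither
  expect_setequal(got$proteins, c("p1", "p3"))
  # equals intersection of direction-matched calls
  ev <- differential_pairwise(rm, "A", "HK2", "EV")
  cl <- differential_pairwise(rm, "A", "HK2", "CL")
  manual <- intersect(
    ev$protein[ev$direction != "neither"],
    cl$protein[cl$direction == ev$direction])
  expect_setequal(got$proteins, manual)
})

test_that("protein Venn regions follow hand set arithmetic", {
  detection <- list(HK2 = c("a", "b", "c"), C1 = c("b", "c", "d"),
                    C2 = c("b", "c", "d"), P1 = c("c", "e"))
  hist <- histology_map(c(HK2 = "benign", C1 = "ccRCC", C2 = "ccRCC",
                          P1 = "pRCC"))
  rep <- venn_proteins(detection, hist)
  expect_equal(rep$regions[["benign"]], "a")
  expect_equal(rep$regions[["ccRCC"]], "d")
  expect_equal(rep$regions[["pRCC"]], "e")
  expect_equal(rep$regions[["benign+ccRCC+pRCC"]], "c")
  expect_equal(rep$regions[["benign+ccRCC"]], "b")
  expect_error(venn_proteins(list(X = "a"), hist), "missing from histology")
})

test_that("degenerate Venn inputs: identical and disjoint type sets", {
  hist <- histology_map(c(A = "benign", B = "ccRCC", C = "pRCC"))
  same <- venn_proteins(list(A = c("x", "y"), B = c("x", "y"),
                             C = c("x", "y")), hist)
  expect_setequal(same$regions[["benign+ccRCC+pRCC"]], c("x", "y"))
  expect_equal(sum(lengths(same$regions)), 2L)
  disj <- venn_proteins(list(A = "x", B = "y", C = "z"), hist)
  expect_equal(disj$regions[["benign"]], "x")
  expect_equal(disj$regions[["ccRCC"]], "y")
  expect_equal(disj$regions[["pRCC"]], "z")
})

test_that("Venn regions always partition the union of type sets", {
  set.seed(31)
  hist <- histology_map(c(A = "benign", B = "ccRCC", C = "pRCC"))
  pool <- sprintf("g%02d", 1:40)
  for (i in 1:25) {
    detection <- list(A = sample(pool, sample(0:30, 1)),
                      B = sample(pool, sample(0:30, 1)),
                      C = sample(pool, sample(0:30, 1)))
    rep <- venn_proteins(detection, hist)
    all_ids <- unlist(rep$regions)
    expect_equal(anyDuplicated(all_ids), 0L)        # disjoint
    expect_setequal(all_ids, unique(unlist(rep$type_sets)))  # coverage
  }
})
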