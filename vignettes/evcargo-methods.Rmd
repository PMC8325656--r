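---
title: "Methods: EV-cargo biomarker discovery with evcargo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EV-cargo biomarker discovery with evcargo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Extracellular vesicles (EVs) released by cultured renal cells carry protein
and mRNA cargo that reflects the cell of origin. Comparing EV cargo between
benign kidney epithelial lines and clear-cell (ccRCC) or papillary (pRCC)
renal cell carcinoma lines yields candidate diagnostic and prognostic
biomarkers. `evcargo` implements the full discovery analysis as a tested
pipeline over two data types:

* **Spatial TMT proteomics.** For each cell line, three fractions are
  quantified in one isobaric-labeling experiment: the EV pellet (EV), the
  parental cell lysate (CL), and the 2,000×g debris pellet (2K). A pooled
  reference channel, built from a mix of all cell lysates, is included in
  each plex so that the two plexes can be linked.
* **nCounter-style transcript counts.** A targeted hybridization panel
  measures hundreds of mRNAs per EV sample in replicate, with a
  positive-control ladder and negative-control probes on every cartridge.

## Proteomic model

All proteomic reasoning happens on **log2 ratios to the pooled reference**:
for channel $c$ in plex $p$, $r_{gc} = x_{gc} - x_{g,\mathrm{ref}(p)}$ per
protein $g$. Because every ratio shares the reference denominator, a
within-line fraction contrast reduces to a difference of ratios, and any
plex-wide additive offset cancels exactly (a property the test suite checks).
Missing values propagate; nothing is imputed, because every downstream filter
is defined on observed ratios only.

A protein is annotated **EV-associated** in a cell line by a two-branch rule
on fold changes, with threshold $t = 0.58$ (log2 of a 1.5-fold change, as
printed; a flag switches to exact $\log_2 1.5 = 0.58496$):

1. $\mathrm{EV} - \mathrm{CL} > t$, or
2. $0 \le \mathrm{EV} - \mathrm{CL} \le t$ and $\mathrm{EV} - \mathrm{2K} > t$.

Decisions made where the rule's wording left room, each configurable:

* the comparison at the boundary is **strict** (`0.58` itself does not pass);
* the second branch's lower bound is **inclusive** ("between 0 and 0.58" read
  as $[0, t]$);
* a protein whose required fold change is missing is **unevaluable** — in
  particular, a protein inside the branch-2 band with no 2K measurement is
  never guessed either way.

Consensus across lines is pure counting: the set of proteins EV-associated in
at least $k$ of the annotated lines, which is nested and non-increasing in
$k$ by construction. Differential abundance between lines or histology groups
uses the same $\pm t$ fold-change rule with no p-values (mirroring the
original design, where group comparisons are consensus statements).
**Group-vs-group semantics are the all-pairs conjunction**: a protein is
increased in group A over group B only when it is increased in every
pairwise line-vs-line comparison. A group-mean alternative exists behind
`method = "mean"` but is not the default, because consensus claims like
"increased in all pRCC EVs relative to all ccRCC EVs" quantify over lines,
not over a group average.

Candidate protein biomarkers come from **detection-based set logic**,
deliberately independent of abundance: "detected in the EV preparation"
means the protein has a quantified EV-fraction ratio in that line (a
definition this package fixes explicitly, since detection is otherwise
ambiguous in ratio data). A histology's detection set is the intersection
over its member lines, and the three sets are partitioned into the 7 disjoint
Venn regions; the regions provably partition the union for any input.

## Transcript model

Normalization follows the platform convention, in order, per QC-passing
sample:

1. **QC**: a sample is excluded when fewer than half of its endogenous
   probes (default `min_fraction_above_background = 0.5`) exceed its
   background threshold — the mean + 2 SD of its negative-control counts
   (sample SD; both the multiplier and the fraction are configurable, since
   the vendor software's exact cutoffs are not published). A manual exclusion
   list reproduces study-specific removals such as hybridization failures.
2. **Positive-control factor**: across-sample mean of per-sample geometric
   means of the positive-control ladder, divided by this sample's geometric
   mean, applied multiplicatively.
3. **Global median scaling**: across-sample mean of per-sample medians of
   (positive-normalized) endogenous counts, divided by this sample's median.

The background threshold is *carried through both factors* rather than
subtracted, so presence calls compare normalized counts against a
consistently scaled floor. One consequence worth stating precisely: because
both factors are anchored to across-sample means, rescaling one sample's
counts (an RNA-input difference) shifts *all* normalized values by a single
shared constant — the anchor level — while leaving between-sample structure,
ranks, and every detection call exactly unchanged. The tests assert this
equivariant form; exact invariance of absolute values is impossible under
mean-anchored factors, and absolute normalized units carry no meaning in
this design anyway.

**Presence calling** is replicate-consensus: a gene is detected in a sample
when its normalized count strictly exceeds the carried threshold; present in
a cell line when detected in a strict majority of passing replicates (2/3,
or 2/2 when a replicate was lost to QC); and present in a histology when
present in every member line. A histology represented by fewer than two
passing lines gets no type-level call at all (it is reported as
non-consensus), matching the study's exclusion of pRCC from the mRNA
presence analysis after QC left it a single line. Candidate mRNA biomarkers
are the presence-Venn regions between benign and ccRCC, regardless of
abundance.

## Enrichment statistics

Genes are ranked by $\log_2((\bar{x}_A + c)/(\bar{x}_B + c))$ on normalized
counts (pseudocount $c = 1$ by default), descending, ties broken by gene id
so the ranking is deterministic.

The **GSEA enrichment score** is the classic weighted running sum: walking
down the list, hits gain $|m_i|^p / \sum_{\mathrm{hits}} |m_j|^p$ and misses
lose $1/(N - N_h)$; the ES is the extremum of largest absolute deviation,
and the leading edge is the set members at or before it (after it, for
negative ES). Choices where the original tooling's settings are unstated,
each a package default rather than an inference:

* weight exponent $p = 1$ (the common "weighted" statistic);
* **gene-label permutation** for the null (random same-size sets), because
  two or three samples per class cannot support phenotype permutation;
* nominal $p = (1 + \#\{|ES_\pi| \ge |ES|,\ \text{same sign}\}) /
  (1 + \#\{\text{same-sign permutations}\})$, with a $10^{-10}$ tie
  tolerance so permutations that reproduce the observed score exactly are
  counted in the tail (on small lists the observed placement *is* reachable
  by permutation, and the fast permutation routine computes the identical
  value along a different floating-point path);
* $NES = ES / \mathrm{mean}\,|ES_\pi|$ over same-sign permutations, and FDR
  $q$ from the standard pooled-NES ratio;
* significance requires both nominal $p < 0.05$ and $q < 0.25$.

On an 8-gene list the permutation $p$ is checked against exhaustive
enumeration of all $\binom{8}{3}$ placements, and under a null metric the
fraction of sets with $p < \alpha$ is checked to stay within 3 Monte-Carlo
standard errors of $\alpha$. The enrichment score itself is cross-checked
against `fgsea` on random instances.

**ORA** is the upper-tail hypergeometric probability of the observed overlap
between a selected set and each gene set, with Benjamini–Hochberg correction
across sets. The universe defaults to the genes or proteins quantified in
the experiment — not a genome — so inference is conditioned on detection.

## The synthetic study

`generate_proteomics()` and `generate_nanostring()` emulate the study design
so every stage is testable with known truth and no external data. The
defaults are the package's declared study conditions, set once:

* 2,000 proteins and 770 endogenous probes; seven lines (HK2, RPTEC benign;
  786-O, 769-P, Caki1 ccRCC; ACHN, Caki2 pRCC); three replicates; two
  simulated plexes with distinct global offsets sharing a pooled reference,
  so plex merging and reference normalization are genuinely exercised.
* Gaussian noise on the log2 scale for reporter abundances (`noise_sd`
  0.4 by default) — the standard model for log-intensity data; planted
  EV-associated proteins (10% of proteins, EV-enriched in every line) get a
  per-protein EV-vs-CL effect of `ev_logfc_mean` $\times (1 + |N(0,
  0.15)|)$, so at zero noise every planted protein strictly clears the 0.58
  threshold and every unplanted protein (centred at or below zero) fails it;
  the configuration refuses `ev_logfc_mean` $\le 0.58$ for this reason.
* Histology-marker proteins and genes (1.5% per histology, disjoint sets)
  are *detected only in their histology's lines*, which is what makes
  detection/presence Venn logic able to recover them exactly.
* Negative-binomial endogenous counts (dispersion 0.1; 0 selects Poisson),
  a 6-probe positive ladder at geometric concentrations scaled by a
  per-sample lognormal factor, 8 negative controls and absent-gene counts
  from a truncated-Gaussian background. Non-marker genes are present in all
  lines (45%), absent everywhere (20%), or present per line at random
  (35%) — proportions chosen so a healthy sample's fraction of
  above-background probes sits several binomial SDs above the 0.5 QC floor,
  while a failed (all-background) sample sits near zero; `qc_fail_samples`
  forces such failures for testing.

What the generator does *not* emulate — and what green tests therefore do
not establish about real data: reporter-ion interference and ratio
compression in TMT, peptide-to-protein rollup artifacts, probe-specific
hybridization efficiency, correlated replicate failures, and any biological
correlation structure between proteins or genes. Recovery results on
synthetic data validate the *logic*, not instrument behavior.

Two regimes appear in the tests, both fixed a priori: the default conditions
above, and a separated strong-signal regime (`ev_logfc_mean = 3`,
`noise_sd = 0.1`, `background_sd = 0`, near-Poisson counts, high expression
for present genes) under which recovery of planted truth is exact by
construction and asserted exactly.

## Reproducing a run

```{r}
library(evcargo)

cfg <- synthetic_config(seed = 1)
prot <- generate_proteomics(cfg)
rna <- generate_nanostring(cfg)

res <- run_ev_pipeline(prot$quant, rna$counts, seed = 1)
res$consensus$counts          # k-of-n EV-association counts
res$protein_report$sizes      # 7-region protein detection Venn
res$mrna_report$sizes         # benign/ccRCC presence Venn
```

`scripts/acceptance.R` runs exactly this at study scale (plus the study's
manual QC exclusions: all Caki1 and Caki2 replicates and one HK2 replicate)
and writes every headline quantity as JSON; problem sizes there — 2,000
proteins, 770 genes, 1,000 permutations, 150 null sets — are the package's
standard demonstration sizes.

## Known limitations

* The printed counts of the original study are only reproducible from its
  deposited supplementary tables, which are not redistributed here; the
  acceptance suite encodes that recomputation and reports it as unavailable
  rather than approximating it.
* Fold-change-only differential calls have no error control; they are
  consensus filters, not hypothesis tests, and should be read as such.
* GSEA significance depends on permutation settings (mode, weight, count)
  that published analyses often leave unstated; qualitative agreement is the
  most that recomputed ranks can establish.
* The single-pooled-sample design of the proteomic arm means line-level
  fold changes carry no replicate variance; the pipeline faithfully
  reproduces that limitation rather than inventing one.
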