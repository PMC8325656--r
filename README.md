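# evcargo

Multi-omic discovery of candidate extracellular-vesicle (EV) cargo
biomarkers from cultured renal cell lines, for proteomics/transcriptomics
analysts who want the full decision logic — not just the instrument-vendor
plumbing — as tested, reusable R functions.

EVs secreted by kidney cells carry protein and mRNA whose composition
depends on the cell of origin. Comparing EV cargo across benign epithelial
lines (HK2, RPTEC), clear-cell RCC lines (786-O, 769-P, Caki1) and
papillary RCC lines (ACHN, Caki2) yields candidate markers that separate
cancer from benign and ccRCC from pRCC. `evcargo` implements that analysis
end to end:

* **TMT reference ratios** — protein-level log2 reporter abundances are
  converted to ratios against a pooled reference channel,
  $r_{gc} = x_{gc} - x_{g,\mathrm{ref}(p)}$, which links the two plexes and
  cancels plex-level offsets; plexes are then merged into one column per
  (cell line, fraction ∈ {EV, CL, 2K}).
* **Two-branch EV annotation** — a protein is EV-associated in a line when
  $\mathrm{EV}-\mathrm{CL} > 0.58$ (log2 of 1.5-fold), or when
  $0 \le \mathrm{EV}-\mathrm{CL} \le 0.58$ and
  $\mathrm{EV}-\mathrm{2K} > 0.58$; missing inputs make a protein
  unevaluable, never guessed.
* **Consensus and differential signatures** — nested k-of-n EV-association
  counts; pairwise and all-pairs group differential calls at ±0.58;
  cell/EV concordance against a reference line.
* **Detection-based Venn biomarker selection** — per-histology detection
  sets (intersection over member lines) partitioned into disjoint Venn
  regions; unique regions are the candidate biomarkers.
* **nCounter-style normalization and presence calls** — negative-control
  background (mean + 2 SD), positive-control geometric-mean factor, global
  median scaling; presence = detection in a majority of replicates, in
  every line of a histology.
* **Enrichment statistics** — weighted running-sum GSEA with a seeded
  gene-permutation null, NES and pooled-NES FDR; hypergeometric ORA with
  Benjamini–Hochberg correction.
* **A synthetic study generator** with planted truth (EV-enriched proteins,
  histology-specific cargo, negative-binomial counts, control ladders) so
  every stage is testable without any download.

## Worked example

```r
library(evcargo)

cfg  <- synthetic_config(seed = 1)      # 2000 proteins, 770 genes, 7 lines
prot <- generate_proteomics(cfg)
rna  <- generate_nanostring(cfg)

res <- run_ev_pipeline(prot$quant, rna$counts, seed = 1)

res$consensus$counts
#>   k n_proteins
#> 1 1       1210
#> 2 2        639
#> 3 3        330
#> 4 4        217
#> 5 5        200
#> 6 6        200
#> 7 7        200

res$protein_report$sizes
#>            benign             ccRCC              pRCC      benign+ccRCC
#>                30                30                30                 0
#>       benign+pRCC        ccRCC+pRCC benign+ccRCC+pRCC
#>                 0                 0              1910

res$mrna_report$sizes
#>       benign        ccRCC benign+ccRCC
#>           67           32          315
```

Reading the output: 1,210 of 2,000 proteins pass the two-branch EV rule in
at least one cell line and 200 in all seven — exactly the planted
EV-enriched set, since the counts flatten once noise-driven calls thin out.
The protein Venn recovers the 30 planted markers per histology as unique
regions (candidate subtype biomarkers), with 1,910 proteins detected in
EVs of all three histologies. The mRNA Venn separates transcripts present
only in benign or only in ccRCC EVs from the shared cargo.

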