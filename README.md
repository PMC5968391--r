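# rdhfp — rdhA fingerprinting and strain inference for dechlorinating communities

`rdhfp` is an R package for resolving *Dehalococcoides mccartyi* strains in
mixed dechlorinating cultures and contaminated groundwater. *D. mccartyi*
strains carry a single 16S rRNA gene copy per genome and are nearly
indistinguishable by 16S sequence; what differs between strains is their
complement of reductive dehalogenase catalytic subunit genes (*rdhA*), the
enzymes that strip chlorines from solvents such as TCE, cDCE and vinyl
chloride. The package is aimed at environmental microbiologists and
bioremediation practitioners who monitor these genes by qPCR and want to
turn the raw plate data into strain-level conclusions.

It covers the full workflow:

1. **Sequence handling & ortholog grouping** — FASTA I/O, pairwise global
   alignment (affine gaps, Gotoh), percent identity (PID), and
   classification of RdhA sequences into ortholog groups (OGs) as
   connected components of the graph linking pairs with PID > 0.90.
2. **Distance trees** — neighbor joining from `1 − PID` distances
   (Q-criterion, deterministic tie-breaks), midpoint rooting, Newick
   export.
3. **Primer screening** — in-silico specificity of qPCR primer pairs
   (IUPAC-aware ungapped mismatch counting on both strands, amplicon
   length prediction).
4. **qPCR quantification** — log-linear standard curves
   `Cq = b + m·log10(copies)`, efficiency `E = 10^(−1/m) − 1`,
   replicate/dilution QC, conversion to copies per mL culture or per L
   groundwater, and method detection limits (MDLs) propagated from the
   filtered/elution/template volumes. "No amplification" is censored,
   never zero.
5. **Ratio fingerprints & clustering** — per-sample *rdhA*/16S gene-copy
   ratios (≈ the fraction of genomes carrying each gene), decade bins from
   "> 0.6" down to "< 0.001", and two-way Pearson/UPGMA clustering of
   genes and samples.
6. **Strain inference** — the minimum number of co-existing strains that
   explains a ratio vector, by exact search over binary gene-content
   matrices: observed ratios `r ≈ C a` with `C ∈ {0,1}^(genes×k)` and
   abundances `a` on the unit simplex; plus the closed-form lower bound
   `k ≥ ⌈log2(L+1)⌉` from `L` distinct ratio levels, and co-localization
   candidates from genes that co-vary at equal magnitude.
7. **Synthetic communities** — a generator with known ground truth
   (strain contents, acceptor-driven selection dynamics, plate simulation
   with Gaussian Cq noise and censoring) so that every stage is testable
   without lab data.

## Worked example

Simulate a 12-sample community panel (three enrichment samples on each of
TCE, cDCE, VC and 1,2-DCA), push it through the full pipeline, and cluster
the fingerprints:

```r
library(rdhfp)

truth <- demo_truth(seed = 1)          # 8 strains, 12 samples, Cq noise 0.15
out   <- run_pipeline(truth)           # simulate -> quantify -> ratios

out$curves[["Dhc16S"]]
#> Standard curve [Dhc16S]: slope -3.3085, intercept 36.95, R2 0.9997,
#>   eff 100.6%, range 10-1e+07 copies/rxn

ps <- pearson_similarity(out$profiles, "samples")
cl <- stats::cutree(upgma(ps$distance), k = 4)
split(names(cl), cl)
#> $`1` "TCE_1"  "TCE_2"  "TCE_3"
#> $`2` "cDCE_1" "cDCE_2" "cDCE_3"
#> $`3` "VC_1"   "VC_2"   "VC_3"
#> $`4` "DCA_1"  "DCA_2"  "DCA_3"
```

The samples cluster perfectly by electron acceptor (adjusted Rand index 1.0
against the generating labels). Strain inference on the eight most abundant
genes of one VC sample:

```r
p  <- out$profiles[["VC_1"]]
r  <- setNames(p$ratios$ratio, p$ratios$gene)
p8 <- ratio_profile("VC_1", sort(r[!is.na(r)], decreasing = TRUE)[1:8])
min_strain_decomposition(p8)
#> Model-based minimum strain count: 4 (lower bound 2, residual 0.0500)
#> Abundances: 0.557, 0.266, 0.132, 0.045
#> Assumptions: one 16S copy per genome, one copy per rdhA per genome,
#>   panel completeness.
```

At least four strains are needed to explain this fingerprint within an
absolute ratio tolerance of 0.05 — echoing the headline observation that
ratio fingerprints reveal far more co-existing strains than 16S analysis
(which sees at most two).

A small command-line front end wraps the same functions:

```sh
Rscript inst/cli/rdhfp.R og-assign --fasta rdhA.faa --threshold 0.90 --out og.tsv
Rscript inst/cli/rdhfp.R tree      --fasta rdhA.faa --out tree.nwk
Rscript inst/cli/rdhfp.R qpcr-quant --plate plate.csv --meta meta.csv --out meas.tsv
Rscript inst/cli/rdhfp.R fingerprint --measurements meas.tsv --out fp.tsv
Rscript inst/cli/rdhfp.R infer-strains --fingerprint fp.tsv --epsilon 0.05 --out strains.json
```

## Documentation

The methods vignette (`vignettes/rdha-fingerprinting.Rmd`) describes the
model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and the
numerical conventions (tie-breaks, censoring, tolerances).
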