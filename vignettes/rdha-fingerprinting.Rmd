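---
title: "Methods: rdhA fingerprinting and model-based strain counting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rdhA fingerprinting and model-based strain counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdhfp)
```

# The problem and the model

*Dehalococcoides mccartyi* strains respire chlorinated ethenes and ethanes
but are nearly identical in their 16S rRNA gene; strains differ mainly in
which reductive dehalogenase (*rdhA*) genes they carry. Because each genome
holds exactly one 16S copy, the ratio

$$\rho_g = \frac{\text{copies of } rdhA \text{ gene } g}{\text{copies of 16S}}$$

estimates the fraction of *D. mccartyi* genomes in a sample carrying gene
$g$. A vector of such ratios over a gene panel is a community fingerprint.
This package implements the computational chain from sequences and qPCR
plates to fingerprints, their clustering, and a formal minimum-strain
count.

The strain model is deliberately simple: a sample contains $k$ strains with
binary gene contents $C \in \{0,1\}^{G \times k}$ and abundances $a$ on the
unit simplex, so the expected fingerprint is $\rho = C a$. The model-based
minimum strain count is the smallest $k$ for which some $(C, a)$ reproduces
the observed ratios within an absolute tolerance $\varepsilon$. Assumptions,
always printed with results: one 16S copy per genome, at most one copy of
each panel gene per genome, and panel completeness (cross-amplification
within an ortholog group is tolerated but flagged when it pushes a ratio
above one). The subset-sum lower bound complements the exact search: $k$
strains generate at most $2^k - 1$ distinct positive abundance sums, so $L$
distinct ratio levels force $k \ge \lceil \log_2(L+1) \rceil$.

# Sequence comparison and ortholog groups

Pairwise global alignment uses the Gotoh affine-gap algorithm with a gap of
length $L$ costing $\text{open} + L\cdot\text{ext}$ (defaults 10 and 0.1,
matching the classic pairwise settings for this gene family); terminal gaps
are penalized like internal ones. Three substitution schemes are provided:
`identity_nt` (1.9 for compatible bases), `iub_nt` (additionally scoring
transitions at $1.9 \times 0.5$, the DNA transition weight) and
`protein_default` (BLOSUM62). Exact emulation of any particular alignment
GUI is not promised; the scheme and penalties are stated so group counts
can be audited.

Percent identity is defined as matches over columns where both rows carry a
residue — gap columns are excluded from the denominator, the common
convention for "pairwise identity" and robust to length differences. A
degenerate nucleotide code counts as *compatible* (no mismatch) whenever
its expansion intersects the partner's, but never as an *identity*, a
deliberately conservative choice.

Ortholog groups are the connected components of the graph joining pairs
with PID strictly above 0.90 ("\>90%" is read literally: PID exactly 0.90
does not link). Single linkage is used because identity-based
classifications of this family admit chains; the minimum within-group PID
is recorded per group so a complete-linkage audit is possible. New groups
continue numbering past the largest reference label, ordered by the
alphabetically smallest member, which makes labels independent of input
order. Sequences shorter than 850 nt are set aside before tree building.

Neighbor joining follows Saitou–Nei with the $Q$-criterion; ties break to
the lowest (row, column) pair, and negative branch lengths are clamped to
zero with the deficit moved to the sibling so the joined pair's distance is
preserved. The tree distance is the p-distance $1 - \text{PID}$ with no
multiple-hit correction, since none is implied by guide-tree distances.
Midpoint rooting places the root halfway along the longest leaf-to-leaf
path (delegated to a well-tested library implementation for $n \ge 3$ and
property-checked against an independent path-length computation).

# Primer screening

Primer matching is ungapped Hamming counting over every offset on both
strands, IUPAC-aware on both sides (expansions intersecting count as a
match — conservative for a specificity screen). There is no thermodynamic
model; the annealing temperature travels as metadata. An amplicon is
called when the forward primer's best site is on the plus strand upstream
of the reverse primer's best site on the minus strand *and* both sites
have at most `max_mismatches` (default 2) mismatches — a best match exists
at every offset by definition, so amplicon calling needs a plausibility
cut-off; the raw mismatch minima are always reported regardless.

# qPCR quantification

The calibration model is $Cq = b + m \log_{10}(\text{copies})$, fitted by
ordinary least squares on standards spanning seven decades; amplification
efficiency is $10^{-1/m} - 1$ (100 % at $m = -1/\log_{10} 2 \approx
-3.3219$) and an $R^2 \ge 0.990$ is the accepted QC floor. Inversion is
$\text{copies} = d \cdot 10^{(Cq - b)/m}$ for dilution factor $d$; a
non-amplifying well is a *censored* observation, never zero — this matters
because a censored gene must propagate to an "nd" heatmap cell and to an
upper-bound constraint in strain inference, not to a spurious ratio of 0.

Replicates are combined by geometric mean, since Cq noise is log-domain.
Each template is read undiluted and ten-fold diluted (in duplicate); when
the two dilution levels disagree by more than `agreement_fold` (default 2),
the diluted estimate wins — the purpose of the dilution series is to detect
matrix inhibition, which biases the undiluted reaction low. The published
protocol does not state how disagreements were resolved, so the two-fold
rule is this package's own and is configurable.

Concentrations scale as
$\text{copies/unit} = \text{copies/rxn} \times (V_\text{elution} /
V_\text{template}) / V_\text{filtered}$, per mL of culture or per L of
groundwater. The method detection limit is the per-reaction quantification
floor (default 10 copies, the lowest routinely quantifiable calibrator)
pushed through the same volume scaling, which is why MDLs differ between
sites that filter 0.2 L versus 1 L, or elute in 50 µL versus 920 µL.

# Fingerprints and clustering

Ratios are censored per the rules above ("below detection" when the gene
is under its MDL while 16S is quantifiable; the whole profile "undefined"
when 16S itself is censored) and binned lower-edge-inclusive into the
heatmap classes $[0.6,\infty)$, $[0.1,0.6)$, $[0.01,0.1)$,
$[0.001,0.01)$, $(0,0.001)$, plus "nd". Pearson correlations for
clustering are computed on $\log_{10}$ ratios — the heatmap's decade bins
indicate the analysis lives in log space — with censored entries imputed at
$10^{-4}$, one decade below the lowest bin edge; undefined entries are
dropped pairwise, and a pair sharing fewer than two defined entries is a
hard error rather than a silent NA. Distance is $1 - r$. UPGMA uses
size-weighted (classical) averaging with lowest-active-index tie-breaks,
and the per-merge "percentage similarity" exported for dendrogram branches
is $100 (1 - h)$ at merge height $h$. Heatmap tables are emitted in
dendrogram leaf order after canonicalizing the input order, so the output
depends only on the data.

# Strain inference: numerical choices

**Level formation.** Ratio levels group the defined ratios greedily in
descending order, starting a new level when the level's max/min span would
exceed $10^{\tau}$ ($\tau = 0.3$ log10 units $\approx$ 2-fold). A
single-linkage rule on consecutive gaps was rejected because chained merges
can violate the very span bound that defines a "level" (e.g. ratios 1.0,
0.95, 0.5 would chain into one level whose extremes differ 2-fold).

**Search.** The exact search enumerates, for $k = 1, 2, \dots, k_{\max}$,
assignments of each gene to a non-empty strain subset. Genes whose ratios
agree within $\varepsilon/2$ are tied to the same subset — a tolerance tied
to the residual bound, *not* to $\tau$: the 2-fold level tolerance is far
coarser than $\varepsilon = 0.05$ and would make even the canonical
$(1.0, 0.6, 0.4) \to k{=}2$ example unsolvable. Strain-relabeling symmetry
is broken by requiring content-matrix columns in strictly decreasing binary
order. Branches are pruned with a sum-of-squares bound: the unconstrained
least-squares SSE of the rows fixed so far lower-bounds any completion, and
a feasible model's SSE cannot exceed $p\,\varepsilon^2$ over $p$ rows.

**Feasibility.** For a candidate assignment, abundances minimize the sum of
squared residuals subject to $\sum a_s = 1$ (solved in closed form via the
Lagrange system); the model is accepted when all $a_s > 0$ and the max-abs
residual over genes is at most $\varepsilon + 10^{-9}$ (the $10^{-9}$
absorbs float noise at the boundary, where residuals of exactly
$\varepsilon$ are common for round inputs). This is a *sufficient*
feasibility test: in principle a minimax-optimal abundance vector could
satisfy the bound where the least-squares one does not, so the reported $k$
is an upper bound on the model-based minimum in such borderline cases. The
exhaustive test oracle applies the same solver, so the dual-route checks
compare search strategies rather than solvers.

**Censoring and clipping.** Censored genes enter as all-zero content rows
(absence trivially satisfies their upper-bound constraint); ratios above 1
are clipped to $1 + \varepsilon$ with a warning, since they most plausibly
reflect cross-amplification within an ortholog group. Ties at the minimal
$k$ resolve to the smallest residual, then the lexicographically smallest
content matrix.

**Co-localization.** Gene pairs qualify when their $\log_{10}$ ratios
correlate at $r \ge 0.9$ *and* sit at the same magnitude (median absolute
log10 difference $\le \tau$) across at least three shared samples — the
magnitude criterion excludes correlated-but-offset trajectories, which
would indicate co-regulated selection, not co-residence on one genome.
Flat, equal trajectories qualify by the magnitude criterion alone since
$r$ is undefined for them. Maximal groups are single-linkage components.

# The synthetic world

The generator emulates exactly the structure the analysis assumes:
strains share one 16S copy per genome and differ in binary complements
over a 15-gene panel named after the tracked assay suite (vcrA, bvcA,
tceA and twelve uncharacterized genes); a core fraction of the panel
(default 0.25) is present in all strains, mirroring the genes observed at
ratios above 0.6 in every culture. Selection is a minimal discrete-transfer
model — abundance times an acceptor-specific fitness factor, renormalized
each transfer — enough to produce acceptor-driven dominance shifts without
pretending to be dechlorination kinetics. Plates carry duplicate reactions
at dilutions 1 and 10, a seven-point ten-fold standard series per target,
Gaussian Cq noise (default sd 0.15 cycles, the error structure of the
instrument; 0.15 cycles $\approx$ 11 % copy error), and censoring below a
10-copies/reaction floor. All randomness derives from a single integer
seed.

Default magnitudes: $10^7$ 16S copies per mL of culture, 10 mL filtered,
50 µL elution, 2 µL template. These were chosen jointly so that undiluted
reactions sit mid-range of the seven-decade calibrators, as in practice —
an earlier draft with $10^8$/mL and 50 mL filtered put reactions above the
top standard, and the resulting extrapolation inflated ratio errors; the
quantification-range flags exist precisely to catch that regime.

What the generator does **not** emulate: multi-copy rdhA genes, primer
cross-reaction between ortholog groups, matrix inhibition (dilution
disagreement never fires on clean synthetic data), plate-to-plate
calibration drift, and real phylogenetic sequence structure. A green
pipeline test therefore establishes the correctness of the computational
chain under the stated model, not robustness to those effects.

# Known limitations

* The 43-groups / 37-ungrouped reproduction on the published 249-sequence
  RdhA panel requires downloading the deposited sequences and is sensitive
  to alignment conventions; it is not part of the offline test suite.
* Progressive multiple alignment, bootstrap support and likelihood trees
  are out of scope; trees here serve ortholog grouping and ordering.
* The strain count is a *model-based minimum*: panel incompleteness,
  multi-copy genes or cross-amplification all bias it, and the
  least-squares feasibility test can overestimate $k$ in boundary cases.
* Exact decomposition is desk-scale (at most 12 defined genes, $k \le
  k_{\max}$); larger panels need the lower bound or external solvers.
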