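---
title: "GC-normalized codon usage and HGT candidate detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GC-normalized codon usage and HGT candidate detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonHGT)
```

## The model

Synonymous codon usage differs more between genomes than within them, so a
gene whose codon usage is atypical for its genome — and typical for another
lineage — is a candidate for horizontal acquisition. The confounder is GC
content: in nematodes especially, much of the gene-to-gene variation in
relative synonymous codon usage (RSCU) simply tracks third-position GC
(GC3). This package's core statistic removes that confounder by building
the GC dependence into the null expectation.

For codon $x$ with $k$ G/C nucleotides, the per-nucleotide GC model gives
$p(x \mid GC3) = GC3^k (1-GC3)^{3-k}$, the expected within-family frequency
is $f_{exp}(x) = p(x \mid GC3) / \sum_{y \in syn(x)} p(y \mid GC3)$, and

$$RSCU_{GC}(x) = f_{ob}(x) / f_{exp}(x).$$

At $GC3 = 0.5$ the expectation is uniform within every family and the
statistic reduces exactly to classic RSCU (on the observed/expected scale).
For a two-fold family whose members differ only at the third position, the
G/C-ending codon's expectation equals GC3 — the algebra the closed-form
tests pin to $10^{-12}$.

Modelling assumptions worth stating:

- The exponent $k$ counts G/C over **all three** codon positions. This only
  matters for the six-fold families (Leu, Ser, Arg) whose members differ
  outside position 3; a per-nucleotide constant that a full positional
  model would carry cancels in the family normalization.
- A gene's GC3 enters as a point estimate from its own codons. For short
  genes this estimate is noisy, and because $1/f_{exp}$ is convex the
  noise adds a small positive/negative bias to individual profile
  components (largest for six-fold families, shrinking roughly with the
  inverse codon count). Genomewide averages over genes of 100–500 codons
  inherit a visible residue of this bias; above ~1000 codons it is
  immaterial. Deviation *rankings*, which compare genes of similar length
  against one common reference, are essentially unaffected.

## Profile space and conventions

Profiles live on the 59 codons of degenerate families: ATG and TGG are
excluded because their RSCU is identically 1, and stop codons are excluded
everywhere. Families absent from a gene are imputed to the neutral value 1
so a missing amino acid contributes nothing to Euclidean distances. GC3 is
clamped to $[0.01, 0.99]$ before the expectation so no codon ever has zero
expected frequency; GC3 itself is computed over all codons of the CDS
(terminal stop removed), including Met and Trp. Genes enter any profile
computation only with $\ge 100$ codons (inclusive). The genomewide
reference is the unweighted mean of per-gene profiles, and the reference
GC3 is the mean of per-gene GC3 values (not pooled third positions) —
both choices keep every gene equally weighted regardless of length.
Internally all coordinates are 0-based half-open; GFF3 I/O converts to and
from the 1-based inclusive convention.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_codons` | 100 | minimum gene length (codons, inclusive) for profiles |
| `threshold` (orphan) | 1e-3 | nematode e-value below which a gene has a homolog (strict `<`) |
| `insect_threshold` | 1e-3 | insect e-value for class I membership (strict `<`) |
| `fold` (class II) | 1000 | required nematode/insect e-value ratio (inclusive `<=`) |
| e-value floor | 1e-180 | replaces exact zeros before ratios (common report precision floor) |
| `flank` | 30 kb | half-width of retrotransposon neighborhoods |
| `max_span` | 40 kb | maximal endonuclease/reverse-transcriptase locus span |
| `n_iter` | 1000 | permutation iterations; smallest reachable p is 1/(n_iter+1) |
| `n_val`, `reps` | 333, 10 | validation draw per species and replicate count in cross-validation |

Boundary semantics are deliberate and pinned by tests: orphan and class I
thresholds are strict, the class II ratio is inclusive at exactly
1000-fold (with a $1+10^{-9}$ relative guard so the inclusive boundary
survives floating point). Cross-validation holds each validation gene out
of its own species' reference profile; without the hold-out, accuracy
would be optimistically biased. The $\pm$ reported with accuracies and
confusion rows is the sample standard deviation over replicates.

## Statistical tests

**Orphan rank enrichment.** Genes are sorted by decreasing deviation
(ties broken by gene id, so results are order-invariant), and orphan
positions are converted to normalized ranks in $(0,1]$. Under the null the
ranks are (up to lattice discreteness and a finite-population correction)
uniform, and a one-sample Kolmogorov–Smirnov test against Uniform(0,1)
measures enrichment; the two-sided p is reported with the direction read
off the signed D components. The lattice and without-replacement effects
make the test slightly conservative when orphans are a large fraction of
the genes; calibration (type-I error within $0.05 \pm 0.02$ at
$\alpha = 0.05$) is verified at a 1.5% sampling fraction (60 orphans among
4000 genes), where both corrections are negligible.

**Fisher's exact test.** Two-sided p as the sum of hypergeometric point
probabilities not exceeding the observed one (with the conventional
$1+10^{-7}$ relative tolerance); fold enrichment is the in-set success
fraction over the overall fraction. An independent log-factorial
enumeration oracle checks every table with positive margins and total
$\le 60$.

**Rank-sum comparison.** Two-sample Wilcoxon via `stats::wilcox.test`:
exact for small tie-free samples, normal approximation with tie correction
otherwise. (The exact branch engages whenever `wilcox.test` can afford it,
not only at $n+m \le 12$; complete separation at $n=m=10$ therefore yields
the exact minimum $2/\binom{20}{10}$.)

**Domain enrichment.** Hypergeometric upper tail for each domain with
Benjamini–Hochberg q-values reported alongside the raw p-values.

**Colocalization permutation test.** The observed statistic counts target
genes whose *start* lies inside the merged flank regions (starts avoid
double counting genes straddling a boundary). Each iteration re-places the
identical multiset of region lengths uniformly over the contigs, mutually
non-overlapping, by rejection sampling; the empirical p uses the add-one
correction $(1 + \#\{count \ge observed\})/(1 + N)$ and can never be zero.
Sampled regions may overlap the observed ones by default (excluding them
would bias p conservatively; a switch is provided). The fold dispersion is
the standard deviation of per-iteration ratios observed/sampled,
matching the "fold $\pm$ sd" reporting style; iterations with a zero
sampled count are dropped from the dispersion only. The genome-wide
bounded-locus scan requires both boundary genes on the same strand — the
orientation the one published example locus shows; relaxing strand
matching would only add loci, so the stricter reading is used and flagged.

## The synthetic-data generators

The generators are first-class, tested code: they define the study
conditions under which every statistical claim in the test suite is made.

**Species generators.** A species is the profile $1 + s\,u$ with
separation $s$ the exact Euclidean distance from the neutral profile and
$u$ a seed-derived unit direction. Within every synonymous family $u$ is
projected orthogonal to (a) the expected frequencies at the species' mean
GC3 — so the target is a valid profile — and (b) their GC3-ending
component — so a species' codon preference carries **no net third-position
GC signal**. Constraint (b) is what makes the construction behave like the
biology the GC normalization assumes: without it, preferring the G-ending
codon of a two-fold family shifts realized GC3, which feeds back through
$f_{exp}(\widehat{GC3})$ and displaces the realized profile from the
target by a length-independent offset (observed at $\approx 0.08$ in
$L_\infty$ before the constraint was added). The price is that two-fold
families carry no species signal — their only degree of freedom *is* the
third base — leaving 23 informative dimensions, which is ample for the
classification studies. Genes sample codons with within-family
probabilities $\propto$ weight $\times$ $f_{exp}(GC3_{gene})$, family
choice proportional to family size, lengths uniform over `len_range`, and
per-gene GC3 normal around the species mean (clamped to $[0.05, 0.95]$).

**Planted genomes.** Retro genes are placed first; their merged 30-kb
flanks cover a fraction $f$ of the genome, and each orphan/class I/class
II gene starts inside the flanks with probability $\min(1, e \cdot f)$,
making the expected permutation fold equal the enrichment factor $e$.
Homology e-values are drawn on log10 scales chosen so each category
satisfies its defining rule exactly: natives have nematode hits in
$[10^{-100}, 10^{-10}]$; class I genes have only insect hits in
$[10^{-50}, 10^{-4}]$; class II genes have insect hits 3–30 decades below
their nematode hits; retro genes have insect hits 1–2.9 decades below
their nematode hits — insect-closer (so they anchor the reference set) but
below the 1000-fold ratio, so they are not themselves class II and never
sit in the colocalization target set they define. Plain orphans receive,
with probability 0.5, an insect hit *above* $10^{-3}$.

**Planted ESTs.** Each EST embeds one stop-free run of known frame and
coordinates, bounded by in-frame stops. The run's interior is salted with
a rotating set of five two-codon motifs that place a stop in every other
reading frame (both strands) at least once per ~90 bp, flanks are
stop-rich codon soup, and an optional decoy run of 153–279 bp in another
frame makes the six-frame rule reject the EST. Every construction is
certified by an internal codon-by-codon scan (runs outside the planted
features capped at 120 bp) and redrawn on the rare violation, so
accept/reject truth is exact by construction.

What the generators do **not** emulate: amino-acid composition differences
between species, sequence-level evolution (indels, substitution models),
introns, overlapping or nested gene models, and EST sequencing error.
Passing tests therefore demonstrate correctness of the statistics and
recovery under the stated model, not robustness to real-data artifacts.

## Numerical choices and degenerate inputs

- Nearest-neighbor ties break lexicographically by species name;
  assignment is deterministic and independent of reference order.
- Constant deviation vectors trigger a warning and fall back to the stable
  id ordering.
- Frames tied for the longest ORF are flagged ambiguous and rejected
  rather than resolved arbitrarily.
- Zero e-values are floored, not dropped; negative e-values are rejected.
- Rejection sampling in the permutation test aborts with a diagnostic
  after 1000 consecutive failures (region set too dense); region sets
  covering more than half the genome are refused up front.
- All generator randomness flows through explicit integer seeds, and the
  ambient RNG state is restored afterwards, so library calls never perturb
  a user's session.

## Problem sizes used in the checks

The test suite and acceptance script run at desk scale, chosen so each
statistical check operates where its guarantees hold: classification uses
4 species × 500 genes (150–500 codons) at profile separation 1.6
(pairwise analytic distances ≥ 2.0); KS calibration uses 60 orphans among
4000 genes over 1000 label permutations; the null colocalization study
uses ~960 target genes with flanks covering ~27% of a 16-Mb genome so the
fold estimate's relative error stays below ~5%; the factor-3 recovery uses
410 targets at ~14% coverage; ORF recovery uses 1000 planted ESTs; the
profile-convergence check uses 1000–2000-codon genes where the
finite-length bias of the ratio statistic is negligible.

## Known limitations

- The GC model treats positions independently; real dinucleotide and
  context effects (e.g. CpG avoidance) are outside the model.
- Headline genome-scale results for *P. pacificus* (34.4%/71.7%
  cross-validated accuracy over 71 real species, the $P < 10^{-54}$
  insect enrichment, the 1.15-fold colocalization) require the real
  genome and the downloaded species panel and are not reproducible here;
  the published summary counts ship as `ppacificus_counts` for the
  arithmetic that *is* reproducible.
- Homology searches themselves (BLAST/HMMer execution), transcript
  clustering, alignment and tree estimation are out of scope: tabular
  results are consumed, not produced.
- `run_all()` recomputes all stages on every invocation rather than
  resuming from cached stage outputs; runs are cheap at the scales the
  package targets and determinism makes caching unnecessary.
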