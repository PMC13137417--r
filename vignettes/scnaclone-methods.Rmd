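---
title: "Models and methods behind scnaclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scnaclone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnaclone)
```

`scnaclone` turns per-cell integer copy-number (CN) calls from droplet
single-cell WGS of tumors into a cleaned, clustered, allele-annotated
clonal decomposition with a phylogeny. This vignette documents the models
each stage assumes, the tunable parameters and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, and
the numerical decisions made where the design was genuinely open.

## Data model

Everything is anchored to a `bin_genome`: ordered, non-overlapping 0-based
half-open bins (BED convention, 20 kb base resolution) with a per-bin
mappability fraction. A `cn_matrix` holds cells × bins integer CN with
per-call quality at raw resolution, or fractional mean-ploidy values after
aggregation. Missing calls are carried explicitly as `NA` and never
imputed at the data layer: the upstream caller's bad calls are removed per
cell, while bins are only dropped genome-wide by the mappability filter.
Cells are never deleted either — a `cell_table` records a forward-only
status label per barcode (`unlabeled → diploid/tumor →
noisy/apoptotic/doublet/artifact/pseudodiploid`), so every decision is
auditable after the run.

## Cell and call filtering

DIMAPD (depth-independent median absolute deviation of pairwise
differences) measures bin-to-bin noisiness per cell; DNA-replicating
(S-phase) cells inflate it. A Gaussian is fit to all per-cell scores by
sample mean and SD and the threshold set at the upper tail probability
`dimapd_p = 0.1`:

$$ t = \hat\mu + z_{0.9}\,\hat\sigma \approx \hat\mu + 1.2816\,\hat\sigma $$

A cell is *noisy* if its ploidy confidence is low **or** DIMAPD exceeds
`t`. Fitting uses all scores including outliers; an optional upper-trimmed
fit exists (`trim`) but is off by default, since a plain fit to "the data"
is the reproducible reading and, with contamination shifted +5 SD, the
threshold inflates only mildly (the planted S-phase sensitivity stays
≥ 0.99 in the test suite). The fit is done before any other cell removal;
whether to fit before or after dropping low-confidence cells is
underdetermined, and fitting on everything is the choice made here.

Call-level: quality `< 15` (strict) sets a call missing; mappability
`< 0.90` (strict) drops the bin for all cells. Aggregation then averages
runs of `factor = 500` consecutive same-chromosome bins (20 kb → 10 Mb)
over the non-missing calls; chromosome-end remainders become a final short
bin, so aggregated bins never straddle chromosomes (downstream
per-chromosome logic depends on this).

## Clustering and model selection

Aggregated profiles are centered and scaled, reduced by PCA (components up
to 95% cumulative variance, capped at 50 and n−1; missing aggregated
values are imputed to the cell's own mean ploidy first, since PCA needs
complete data, and carry no signal), and k-means is run for every
k ≤ `k_max = 20`. Each solution is scored by

$$ \mathrm{AIC}(k) = n\ln(\mathrm{WSS}(k)/n) + 2k,\qquad
   \mathrm{BIC}(k) = n\ln(\mathrm{WSS}(k)/n) + k\ln n . $$

Two numerical choices matter here:

* **Monotone WSS.** Independent random restarts make WSS(k) non-monotone
  (a lucky restart at k = 12 can beat k = 11 badly and crater the
  criterion curve). Each k is therefore also seeded with the best
  (k−1)-solution's centers plus the point farthest from its center; the
  better of cascade and random starts is kept, which makes WSS(k)
  non-increasing and finds rare-cell clusters reliably.
* **Elbow selection, not arg-min.** When within-cluster spread is small
  relative to between-cluster distances — exactly the regime of clean CN
  profiles — `n ln WSS` rewards splitting pure noise by more than the +2
  penalty for any feasible k, so a literal arg-min slides to `k_max` and
  shreds real clones. The selected k is instead: the smallest k whose WSS
  is numerically zero (the data are exactly k point clusters); otherwise
  the elbow of the AIC curve, computed as the smallest k within 95% of the
  maximal distance below the chord joining the curve's endpoints (the
  automatic version of reading the bend off a criterion plot, which is how
  this clustering strategy is used in practice); a raw arg-min only if the
  curve has no bend. BIC is evaluated on the same WSS and reported — it
  tends to undercluster heterogeneous tumor populations, which is why AIC
  drives the choice.

Each cluster is re-clustered once by the same method (`subcluster`),
labeled `"<cluster>.<sub>"`; clusters under 3 cells stay whole. DAPC
computes linear discriminant functions on the retained PCs by the
generalized between/within eigenproblem, ridge-regularized
(`lambda = 1e-6` of the mean within-scatter diagonal, with a warning) when
the within-scatter is singular; loadings are back-projected to bins
through the PCA rotation. The diploid cluster is the one minimizing mean
|CN − 2|, required to be ≤ `diploid_max_dev = 0.25` copies — beyond a
quarter copy of average deviation a "diploid" population is not credible.

Pseudodiploid cells — near-diploid cells carrying sparse low-level gains
at sites recurrently amplified in the tumor, candidate premalignant
cells — are flagged within the diploid cluster when ≥ 3 aggregated bins
deviate from CN 2 by more than 0.5 copies; each flagged cell's gains are
scored by Jaccard overlap with the tumor consensus gains. The ≥ 3-bin rule
is this package's formalization of a descriptive observation; both
threshold and deviation are exposed in `pipeline_config()`.

## Doublets and artifacts

Baselines are per-bin median consensus profiles of pre-WGD tumor clusters
(medians resist outlier cells; pre-WGD because doubling every expected
profile is wrong when a pre-WGD representative exists). Expected
diploid–tumor doublets add 2 to a baseline; expected tumor–tumor doublets
sum two baselines. Cells are matched to the nearest reference by mean
per-bin Manhattan distance and called doublets only when the nearest
reference is a doublet profile **and** the margin to the best singlet
reference exceeds `doublet_margin = 0.3` mean copies/bin (ties favor the
singlet; the default margin leaves flip-noise singlets unflagged in the
default simulation).

The reference set needs care. A post-WGD clone satisfies
$|2A - (A+2)| = |A-2| \le \min(|2A-A|, |2A-2|)$: it is *always* nearer the
founder-plus-diploid doublet profile than any singlet reference, so
matching alone would discard entire WGD clones. Non-baseline tumor
clusters therefore enter as additional singlet references, unless their
own consensus matches a doublet profile — and a doublet-like cluster is
rescued as a genuine clone only when it is population-sized
(`min_clone_cells = 10`) and shows consensus LOH, because a doublet
containing a diploid genome has both alleles ≥ 1 everywhere and can show
no LOH at all. Known limitation: tumor–tumor doublet clusters *do* retain
LOH and can evade this screen; with realistic doublet rates they rarely
form coherent clusters, and the per-cell margin rule still catches
dispersed ones.

The artifact filter removes cells whose aggregated profile has no bin
rounding to an odd CN — the signature of CN overfitting, where a scaled
diploid genome is called at even multiples. The diploid cluster is exempt
(all-even is its normal state), as are clusters whose cells are
majority-WGD (legitimately all-even genomes); a strictly literal reading
would discard every normal cell.

## Allele-specific statistics

Haplotype CN is estimated per bin by rounding:
`b = round(BAF * total)`, `a = total − b` (half-up rounding, so BAF 0.5 at
odd totals resolves deterministically toward B). This deliberately
replaces a joint evolutionary-link inference across cells: the analysis
content here is the derived statistics, which are computed exactly —

* **LOH**: `min(a,b) = 0` with `a+b > 0`; covers hemizygous loss (1,0),
  copy-neutral LOH (2,0), and LOH with gain of the remaining allele
  (3,0)+, and excludes homozygous deletion. Segments are maximal runs of
  ≥ `min_loh_run = 3` bins; cluster consensus requires the bin to be LOH
  in ≥ 80% of informative cells.
* **WGD**: fraction of the assessed genome (length-weighted, bins with
  defined allele CN; undefined if under half the genome is assessed) with
  major allele CN ≥ 2; strictly greater than 0.5 calls WGD, so a cell at
  exactly 0.5 is not doubled. Autosomes and X are treated uniformly (the
  emulated study samples are all female); per-cluster labels are the
  majority of per-cell calls.
* **Mirrored allelic imbalance**: maximal runs (≥ 3 bins) where two
  clusters' consensus totals agree, both are imbalanced, and the major
  haplotype differs — the (2,1)/(1,2) signature of convergent gains.
  Shared LOH or same-haplotype imbalance is never reported, and the call
  is invariant to the global phase convention.
* **BAF smoothing**: cluster-pooled SNP counts binned into 100 kb blocks
  (`sum b / sum total`); RDR is the cell's bin fraction of reads over the
  diploid reference's.

## Phylogeny and diversity

Distances are Manhattan (trees) or Euclidean (intracluster diversity),
computed over bins defined in both profiles and normalized per shared bin
by default so cells with different missing-call loads are comparable
(raw-sum mode exists for strict replication). Trees use balanced minimum
evolution — the `fastme`-style heuristic with NNI and SPR rearrangements
on the balanced (Pauplin) tree-length objective — and are rooted by
inserting the root at the midpoint of the diploid outgroup's pendant edge.
Negative branch lengths are clamped to zero after the topology is fixed;
displayed "negative evolutionary space" for outgroups is a plotting
convention that stored trees never carry. The test suite verifies the
heuristic against exhaustive enumeration of all topologies (≤ 6 taxa)
scored by an independently implemented Pauplin length. Cell-level trees
use integer-rounded 1 Mb profiles; subcluster trees use mean 20 kb
profiles.

Intracluster diversity is the complete set of n(n−1)/2 pairwise distances
per cluster, and the mean–SD regression fits per-bin SD on per-bin mean
CN across a cluster's cells by OLS; under CN-proportional noise the slope
is positive, i.e. variability concentrates in gained regions.

## The synthetic-data generator

`clone_spec()` defines a clone tree rooted at a diploid ancestor with
ordered event lists (gain, loss, focal amplification, copy-neutral LOH,
hemizygous deletion, WGD) applied cumulatively along the root path —
so copy-neutral LOH of chr17 followed by WGD yields (4,0), the absolute-CN
2-then-4 pattern that dates LOH before doubling. Cells are sampled with
independent per-bin flip noise ε (a ±1 copy flip on one haplotype, so
total = A + B holds exactly), optionally scaled by CN/2
(`cn_noise_scaling`) to emulate read-sampling noise. Contaminant classes
follow their construction rules: diploid–tumor doublets add 2 to a clone
profile, tumor–tumor doublets sum two clone profiles, pseudodiploids take
each truncal gain region independently with probability 0.5 at +1,
apoptotic cells degrade a uniform 30–70% of bins to CN 0/1, S-phase cells
draw DIMAPD from the clean Gaussian shifted +5 SD (the real metric's
distribution is unpublished; only the Gaussian-fit filter is defined, so
any well-separated shift serves). SNP counts are Poisson(λ) totals with
Binomial B-allele draws at `b/(a+b)`; zero-CN bins emit no reads.

The default spec (`default_clone_spec()`) fixes the study conditions used
throughout: a heavily aneuploid founder (eight truncal events including
chr17 copy-neutral LOH and chr13 hemizygous loss), a post-WGD descendant,
two pre-WGD siblings with a mirrored chr10 imbalance, and
60/12/10/8/6/10 diploid/S-phase/apoptotic/diploid–tumor/tumor–tumor/
pseudodiploid contaminants at ε = 0.01. Founder-level aneuploidy is not
cosmetic: with a near-diploid founder, WGD(A) ≈ A + 2 and the
clone-versus-doublet question becomes ill-posed for any profile-based
method. The genome is the 22 autosomes + X at 1/30 of the GRCh38 lengths,
20 kb bins (~5,000 bins, ~23 aggregated bins), chosen so a full pipeline
run takes seconds while whole-chromosome and arm-scale events remain
expressible; tests that need finer aggregated structure scale the genome,
not the method.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: segmentation errors are spatially
independent here but correlated along the genome in real HMM output; real
coverage (0.07–0.14×) produces heavier-tailed, cell-quality-dependent
noise than iid flips (ε = 0.01 is a stand-in, exposed in the spec); there
is no read- or fragment-level simulation, no replication timing, and BAF
noise ignores reference bias and phasing switch errors. Conclusions about
absolute error rates on real samples should not be drawn from the
simulation results; the simulations establish correctness of the rules
and calibration of the thresholds under their stated models.

## Pipeline orchestration

`run_pipeline()` fixes the stage order: noisy/call filters → aggregation →
first clustering → apoptotic-cluster removal (clusters whose median
per-cell fraction of bins at CN ≤ 1 exceeds 0.3 — degraded DNA is
identified descriptively in practice, and this is the operational rule) →
diploid-cluster identification → WGD calls → doublet/artifact removal →
final clustering and subclustering with pseudodiploid flagging →
allele statistics → subcluster phylogeny rooted at the diploid subcluster.
All randomness flows from `pipeline_config(seed = )`; identical config and
seed reproduce the report byte for byte. Re-clustering after contaminant
removal can legitimately *raise* the selected k: once dominant
contaminants stop dominating the criterion curve, small residual
populations (surviving doublets, pseudodiploids) resolve into their own
clusters. What it must never do — and what the suite asserts — is
fragment the recovered clones: clone-level agreement with truth never
decreases between rounds.
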