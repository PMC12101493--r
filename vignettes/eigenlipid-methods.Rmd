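---
title: "Eigenlipid analysis of ocean lipidomes: models and methods"
author: "eigenlipid package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eigenlipid analysis of ocean lipidomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eigenlipid)
```

## The scientific problem

Planktonic communities restructure their lipidomes along ocean gradients:
membrane fluidity is maintained under temperature change by remodelling
acyl chain length and unsaturation (homeoviscous adaptation), phosphorus
scarcity favours non-phosphorus betaine lipids over phospholipids, and
photosynthetic (thylakoid) lipids — SQDG, MGDG, DGDG and PG — track the
light environment and the deep chlorophyll maximum (DCM). A depth-resolved,
multi-region lipidomics survey therefore contains groups of lipid species
whose intensities rise and fall together because they respond to the same
environmental driver or originate from the same organisms.

This package recovers those groups as **eigenlipids (ELs)**: clusters of
lipid species with correlated intensity profiles across samples, each
summarised by the first principal component of its members' transformed
intensities. The workflow runs from a raw feature table to cluster-level
ecology: contaminant filtering, compositional transformation, weighted
correlation network clustering, regional projection and reproducibility
testing, vertical/biogeographic characterisation, meta-clustering,
structural comparison, and environmental attribution.

## Preprocessing

**Blank filtering.** A feature is kept iff its median intensity across
samples is at least 20-fold its median across blank runs ("less than
20-fold above blank" is excluded; exactly 20-fold is kept). A blank median
of zero always keeps the feature. Medians are computed globally across all
samples and blanks; a practitioner with per-cruise blanks can apply the
filter per batch by calling `blank_subtract()` on subsets.

**Compositional transform.** Peak intensities are relative quantities, so
each sample is first normalised to its total annotated intensity and then
centred-log-ratio (CLR) transformed: $\mathrm{clr}_i = \ln(x_i/g(x))$ with
$g$ the per-sample geometric mean. Zeros are replaced multiplicatively
before the log: zeros become half the sample's smallest nonzero proportion
and the remaining proportions are rescaled — the standard minimal-distortion
convention in compositional data analysis. CLR output columns sum to 0 by
construction and are invariant to per-sample rescaling of the raw data.

## Network clustering

The network is built on Pearson correlations of CLR values (CLR already
removes per-sample scale; Spearman is reserved for the membership scores,
below). The default adjacency is *signed*,
$a_{ij} = ((1 + r_{ij})/2)^\beta$, so that anti-correlated lipids are
treated as unconnected rather than as neighbours — anti-correlation between
lipid pools is ecologically meaningful and should separate clusters, not
join them. An unsigned option ($|r|^\beta$) is available.

The soft power $\beta$ is chosen as the smallest candidate whose signed
scale-free fit $R^2$ (regression of $\log_{10} p(k)$ on $\log_{10} k$ over
connectivity bins, sign-flipped when the slope is positive) reaches 0.8;
when no candidate reaches it — which is the norm for data with a few large
planted blocks, whose degree distribution is bimodal rather than
scale-free — the best-fitting power is used with a warning. On the
synthetic benchmark the detected modules are insensitive to $\beta$ over
the whole candidate range, because block separation, not topology shaping,
does the work.

Topological overlap is the classic
$TOM_{ij} = (\ell_{ij} + a_{ij})/(\min(k_i,k_j) + 1 - a_{ij})$ with
$\ell_{ij} = \sum_{u \ne i,j} a_{iu}a_{uj}$, and $1 - TOM$ is the
clustering dissimilarity (average linkage).

**Adaptive branch cut.** A fixed cut at 99% of the root height proved
structurally unable to separate modules: with realistic noise,
between-module merges occur at 75–93% of the root height, so a 0.99 cut
returns only the two root branches. The cut used here is adaptive and
fully deterministic: every candidate cut height (midpoints between
consecutive merge heights, restricted below a coherence ceiling of 0.9
times the root height so that incoherent near-root branches never count)
is scored by the number of branches of at least `min_module_size` leaves;
the branch count with the greatest total height-persistence wins, and the
cut is placed at the middle of its longest stable run. Branches below the
size threshold become EL0 (unassigned), and modules are renamed
EL1..ELn by decreasing size. Choosing the *persistent* configuration
rather than the first height that maximises the count avoids both
fragmentation (transient counts at low heights) and absorption of loosely
attached background lipids (high cuts). The hybrid PAM-like relabelling
stage of dynamic tree cutting is deliberately out of scope; lipids outside
a stable branch stay in EL0.

**Eigenlipids, membership, projection.** Each module's eigenlipid is the
first left singular vector (over samples) of the member-standardised CLR
submatrix, unit-norm, sign-oriented to correlate positively with the
module's mean profile; the explained-variance fraction is reported.
Membership scores are Spearman correlations between each lipid's profile
and each eigenlipid. Held-out regions are *projected*: the reference
first-PC loadings (renormalised over the lipids present) are applied to
the new samples' CLR values standardised with the reference scaling and
divided by the reference singular value, so projecting the training region
reproduces the training eigenlipids exactly.

**Reproducibility (IGP).** In validation data, each member lipid is
assigned to the nearest module centroid (mean member profile) by Pearson
correlation distance, leaving the lipid out of its own centroid — without
the leave-one-out, a lipid's own contribution biases the in-group
proportion upward. A module's in-group proportion (IGP) is the fraction of
members assigned home. The null distribution relabels lipids at random
with module sizes preserved and recomputes centroids and IGP;
$p = (1 + \#\{IGP_{null} \ge IGP_{obs}\})/(n_{perm}+1)$.

## Spatial statistics

Module abundance per sample is the members' summed raw intensity over the
total annotated intensity, so EL shares plus the EL0/unassigned share
partition 1. Per station, the EL maximum depth is the sampled depth of
highest share (ties resolve shallowest — conservative toward the surface);
the DCM is the fluorescence argmax with the same tie rule and an optional
3-point median smoother. Depth contrasts (all EL pairs and EL vs DCM) use
the two-sided Mann-Whitney U with Cliff's Delta (positive = the second
entity reaches deeper); province enrichment uses the one-sided test
(province greater than the rest) on mixed-layer samples, where "mixed
layer" means depth at most the station's recorded mixed-layer depth.
Headgroup enrichment is a chi-square goodness-of-fit of each headgroup's
member counts across ELs against a uniform spread. Each analysis family
(depth, province, headgroup, pigment) is Benjamini-Hochberg adjusted as
one family — family boundaries follow the figure-analogue each table
mirrors.

The Mann-Whitney p-value is exact (full enumeration of group assignments,
valid under ties) up to $n+m \le 12$. Beyond that, tie-free data use a
continuity-corrected normal approximation with an Edgeworth kurtosis term
based on the exact fourth moment of the null statistic,
$\mu_4 = nm(N{+}1)\,[5mnN + 3mn - 2(m^2{+}n^2{+}m{+}n)]/240$, which keeps
two-sided p-values within ~0.003 of exact already at $n+m=12$; tied data
fall back to the tie-corrected normal.

## Meta-clustering

Three EL-level views — distributional (1 − Pearson correlation of
eigenlipid profiles), geographic (correlation distance between
per-province mixed-layer mean shares) and vertical (Euclidean distance
between standardised per-depth-bin mean profiles, bins 0–25–50–100–200–400
m chosen to align stations with different sampling depths) — are each
min-max normalised to [0,1] and averaged with equal weights (configurable)
into one integrated distance, clustered by average linkage.

Node significance is a Monte Carlo test in the spirit of significance-of-
hierarchical-clustering methods, simplified and stated in full rather than
mimicking any external implementation: per node (root first, descending
only through significant nodes), a single Gaussian is fit to the node's
EL feature vectors — mean plus a covariance whose eigenvalues are floored
at a background level (squared MAD of the centred entries) so the fit is
full-rank — and `n_sim` simulated datasets are scored by the same
two-group cluster index used on the observed data (within-group sum of
squares after an average-linkage 2-split, as a fraction of total SS).
Using the identical clustering procedure on observed and simulated data is
what keeps the null calibrated; the suite verifies a rejection rate of at
most 7% at $\alpha = 0.05$ over 200 single-Gaussian replicates. The
number of meta-clusters defaults to 1 + the number of significant nodes
found by this descent; a fixed $k$ (e.g. 3) is a configuration preset.
Cophenetic correlation (Pearson, original vs merge-height distances)
reports how faithfully each dendrogram represents its distances.

## Structural comparison

Per EL, structural profiles are intensity-weighted (weights = mean
relative intensity across samples): headgroup composition, mean carbons
per fatty acid, mean double bonds per chain, PUFA-containing fraction,
phosphorus-free fraction and odd-chain fraction. ELs with fewer than 5
species carrying a recognised headgroup are excluded (reported), mirroring
the practice of dropping clusters dominated by structurally unannotated
features. The structural distance is Gower-type: ranged differences for
numeric fields plus the total-variation distance between headgroup
compositions, averaged over non-constant fields; constant fields are
dropped with a note.

The structural and distributional dendrograms are compared as a
tanglegram: entanglement is
$\sum_i |r_L(i) - r_R(i)|^L / \sum_i |i - (n{+}1{-}i)|^L$ (the denominator
is the fully reversed configuration), after a two-sided stepwise
untangling heuristic that flips one branch at a time on alternating sides
while the score improves. $L = 1.5$ follows the common tanglegram default.
Both the raw and untangled scores are reported; untangling can only lower
the score.

Structural differences between modules are tested with a random-intercept
model, `property ~ EL + (1 | sample)` fit by REML — the reading of
"sample-specific variation as a random effect" in which the per-sample,
per-EL intensity-weighted property is the response and samples contribute
exchangeable intercepts. Coefficients are tested by z statistics with BH
adjustment across EL contrasts. If the mixed fit fails, a fixed-effects
model with sample-clustered (CR0 sandwich) standard errors is used and
flagged.

## Environmental responses

*Chain length vs temperature*: ordinary least squares of the per-sample
intensity-weighted mean carbons per FA (membrane glycerolipids of one
saturation class — PC, PG, PE, PI/PS, SQDG, MGDG, DGDG, GADG, DGTS/A,
DGCC — in mixed-layer samples) on in situ temperature, with the 95%
confidence interval on the slope.

*PCA*: modules' standardised shares are decomposed; environmental
covariates enter as supplementary vectors (correlations with the score
axes), and each EL's loading is projected onto each covariate direction —
the EL with the longest projection onto temperature is the strongest
temperature tracker.

*Random-forest attribution*: regression of a response (e.g. a class share
among SFA/MUFA lipids) on temperature and phosphate with a 70:30
train-test split; impurity importances are normalised to sum to 1 and
scaled by $\max(R^2_{test}, 0)$, so an unpredictable response contributes
no attribution. `mtry` uses all predictors (with two predictors,
subsampling them would force uninformative splits). ICE curves evaluate
the fitted forest per test sample over a 50-point grid of one predictor
with the other held at its observed value. Forests use 500 trees and a
fixed seed.

*Layer contrasts*: samples are "mixed" (depth within the station MLD) or
"DCM" (sampled depth nearest the station DCM, below the MLD). The
EL-ratio analysis bins station SST (2 °C default), bootstraps the 95% CI
of the per-layer mean ratio $a/(a{+}b)$ (1000 seeded resamples) and tests
per-bin layer differences with Welch's t (BH over bins). Per-class PUFA
layer contrasts use Welch's t with Cohen's d (DCM minus mixed). The EPA
analysis locates the per-station depth of peak summed intensity of
20:5-carrying species and compares it to the DCM with a Wilcoxon
signed-rank test.

Welch's correction is applied wherever a plain two-sided t test is called
for, since layer and bin subsamples have no reason to share variances.

## The synthetic ocean

Real survey data are not shipped; a seeded generator builds a transparent
stand-in with recoverable ground truth.

**Design.** Regions x provinces x stations x depths (defaults: 3 regions,
3 provinces each, 5 stations per province, depths 5–400 m; region 1 is
the network reference region). Province surface temperatures are fixed on
a 28..−1 °C gradient and interleaved across regions so each region spans
the gradient; stations jitter ±3 °C. Temperature decays with depth;
phosphate mirrors surface temperature, grows with depth and carries
independent station-level "patchiness" — without that independent
variation, temperature and phosphate would be deterministic functions of
each other and driver attribution would be ill-posed. Fluorescence is a
single Gaussian peak per station whose centre (the planted DCM) deepens
with surface temperature; the mixed layer deepens toward cold provinces.

**Lipidome.** Five module archetypes cycle: a 50 m storage-lipid peak
(TAG/DAG), a mid-gradient province bloom (MGDG/SQDG), a temperature
tracker (betaine lipids + TAG), a DCM-tracking chloroplast PUFA module
(SQDG/MGDG/DGDG/PG with an EPA 20:5 chain), and a cold-province
phospholipid module (PG/PE). Province-indicator modules deliberately use a
*mid-gradient* and a *cold* province of the reference region: an
extreme-warm indicator is nearly collinear with the temperature latent and
would confound the planted responses by construction. Each latent is
standardised to unit variance, so `noise_sd` reads as relative noise;
member log-intensity = base + loading x latent + noise, and intensities
are log-normal (multiplicative error matches mass-spectrometric intensity
behaviour). Unassigned lipids are pure noise with their own larger
idiosyncratic scatter (`unassigned_sd` = 0.6 > `noise_sd` = 0.15): with
only measurement-level noise they would appear as an artificially tight
"background cluster" through the CLR common term.

**Structural signatures.** Module members share an exact
carbons-per-fatty-acid value (the chain *split* varies; the sum is fixed)
and modules sit ~3 C/FA apart. The planted chain-length-temperature slope
(0.04 C/FA per °C, base 14.5 C/FA at 0 °C) is imposed by an exponential
tilt of module-member SFA/MUFA membrane intensities whose per-sample
coefficient is solved (by `uniroot`, on expected noisy weights, excluding
the planted contaminants that the blank filter later removes) so the
intensity-weighted mean C/FA of the analysis-grade SFA/MUFA membrane set
equals base + slope x T exactly before noise. Keeping members' C/FA
constant within a module is what keeps this tilt a module-level shift
rather than a within-module confounder; spreading the modules ~3 C/FA
apart keeps the tilt coefficient small so the province module is not
contaminated with a temperature response. No PUFA chain-length slope is
planted. Contaminants (drawn from the unassigned set) receive blank
medians placing them on the failing side of the 20-fold rule by a
configurable margin, with the middle blank run carrying the median
exactly so planted kept/removed sets are deterministic.

**What the generator does not emulate.** Annotation error, censoring/
missingness at the detection limit, within-module loading heterogeneity,
cruise batch effects, covariance between modules beyond what the latents
share, and seasonal or diel variability. Passing the planted-recovery
suites therefore shows the pipeline's correctness and calibration under a
clean, favourable regime — not that real-ocean modules are this crisp.

## Problem sizes, determinism and numerical conventions

The test and benchmark runs use desk-scale problems — 340 lipids x 90–270
samples, 99–499 permutation/Monte-Carlo draws, 100-replicate simulation
suites — chosen so the complete suite exercises every claim in minutes
while leaving all estimators in their asymptotically honest regimes.
Every stochastic step (generator, permutation tests, Monte Carlo,
bootstrap, forests) takes an explicit seed, and seeded runs are
byte-identical end to end; the generator derives independent streams per
stage so that, e.g., metadata are identical whether or not a lipidome is
generated afterwards. Ties in argmax-type statistics resolve shallowest;
the blank-rule boundary keeps exactly-20-fold features; permutation
p-values use the add-one convention with lower bound $1/(n_{perm}+1)$;
CLR columns sum to 0 within 1e-9.

## Known limitations

- The adaptive branch cut assumes modules form coherent branches below
  0.9 of the root height; extremely weak modules merging near the root are
  returned as EL0 rather than guessed at.
- The node-significance test is a declared, simplified analogue of
  hierarchical Monte-Carlo significance testing, not a re-implementation
  of any published package's internals; with very few leaves per node its
  Gaussian fit is coarse and nodes under 3 leaves are not tested.
- Sum-composition species without chain annotations use a minimal-
  assumption PUFA heuristic (PUFA-containing iff double bonds exceed chain
  count) and are flagged as heuristic calls.
- The headline numbers of any real survey (thousands of species, hundreds
  of samples, 16 clusters) are outside the synthetic defaults; nothing in
  the package is calibrated to reproduce a specific study's printed
  values.
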