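---
title: "Quantifying and mapping heat tolerance in sheep: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and mapping heat tolerance in sheep: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovitherm)
```

`ovitherm` implements the computational chain of a heat-adaptation
study in sheep: heat-load and heat-tolerance phenotyping, SNP quality
control, multilocus diversity statistics, population-structure
inference, mixed-model association, and positional gene annotation,
together with a ground-truth synthetic-data generator. This vignette
explains the models, the conventions, and the design decisions that were
genuinely open, in enough detail that a user can judge what the package
computes and what its tests do and do not demonstrate.

## Heat-load and heat-tolerance phenotypes

### The temperature–humidity index

`thi()` combines dry-bulb temperature (°C) and relative humidity (%) as

$$\mathrm{THI} = F - 0.55\,\frac{RH}{100}\,(F - 58),
\qquad F = 1.8\,\mathrm{DBT} + 32 .$$

$F$ is the temperature in Fahrenheit; the humidity term vanishes at
$F = 58$ (14.44 °C), below which humidity no longer adds heat load. The
index is often printed without parentheses in the livestock literature;
the grouping above is the one that reproduces standard published tables
of morning readings for hot arid zones (71.9–75.8 at 27–29 °C) and
afternoon readings near 110 at 48 °C. THI is dimensionless; values above
about 72 indicate heat stress for sheep and above about 90, severe
stress. Internally the computation is full precision; reports round to
one decimal (`thi_table()` leaves rounding to the caller).

One caveat a user should know: published climate tables are not always
self-consistent. For instance a morning reading of 33.0 °C at 40% RH
gives 84.05 under every plausible bracketing of the formula; a printed
value of 81.1 for that cell cannot be reproduced and the package makes
no attempt to match it.

### Derived respiratory and metabolic parameters

Tidal volume is the minute gas volume per breath,
$\mathrm{TV} = \mathrm{GV}/\mathrm{RR}$ (L/breath, `tidal_volume()`),
requiring $\mathrm{RR} > 0$. Metabolic rate converts open-circuit gas
exchange to energy with the abbreviated Weir equation and normalizes by
metabolic body size:

$$\mathrm{MR} = 1440\,(3.941\,\dot V_{O_2} + 1.106\,\dot V_{CO_2})
  \,/\, BW^{0.75}
\quad [\mathrm{kcal\,kg^{-0.75}\,day^{-1}}].$$

The Weir coefficients are the natural choice when exactly VO2 and VCO2
are measured; they are exposed as an argument (`coef`) for labs that
prefer Brouwer-style constants.

### The animal heat-tolerance index (AHTI)

`ahti_score()` takes one rest (07:00) and one stress (14:00) row per
animal and flags, for each of RT, ET, RR, TV and MR, whether the change
exceeds twice the parameter's at-rest standard deviation. The AHTI is
the number of flags: 0 is the most tolerant animal, 5 the least.

Three conventions had to be fixed where the procedure is
under-determined, and all three are exposed as arguments:

- **Which SD?** With a single rest measurement per animal, a per-animal
  SD is not estimable; the package uses the cross-animal SD of rest
  values per parameter (whole cohort). A pre-computed per-parameter SD
  can be supplied via `sd_baseline` (e.g. per-breed baselines).
- **Signed or absolute change?** The default compares the absolute
  change, so parameters that fall under stress (tidal volume typically
  does, as panting trades depth for rate) can still flag;
  `signed = TRUE` restricts to increases.
- **Zero-SD degenerate case.** If a parameter has zero rest SD the flag
  falls back to "any nonzero change", with a warning.

The score is invariant under any affine rescaling applied jointly to a
parameter's rest and stress values (units cancel through the SD), and
under permutation of animals.

## SNP quality control

`filter_snps()` applies the three chip-QC filters — minor allele
frequency below 0.01, call rate below 90%, exact Hardy–Weinberg p below
1e-6 (all thresholds arguments). All three criteria are computed on the
*input* matrix, so the retained set does not depend on any filter order;
the order MAF → call rate → HWE is used only to attribute each removed
marker to a single criterion in the report. This makes `filter_snps()`
idempotent and monotone in its thresholds, which the test suite checks
on random fixtures.

The HWE test (`hwe_exact_test()`) is the conditional exact test: given
the observed allele counts, the two-sided p-value sums the probabilities
of all heterozygote counts no more probable than the observed one. An
exact test rather than χ² matters because the filter operates at the
10⁻⁶ tail, where the χ² approximation is unreliable at cohort sizes of a
few hundred. The probabilities are evaluated in log space and normalized
within the support, so tables with thousands of genotypes are safe; a
mid-p variant is available (`midp = TRUE`, off by default). HWE is
computed on the whole cohort, mirroring single-pass chip QC; subsetting
the `geno_matrix` by group gives per-group QC when wanted.

## Diversity and differentiation

- **Hexp** (`nei_gene_diversity()`): per marker
  $h = \frac{N}{N-1}\left(1 - \sum_a p_a^2\right)$ with $N$ the observed
  allele copies; reported as the mean over markers. The $N/(N-1)$ factor
  is the small-sample (unbiasedness) correction.
- **Ia and rbarD** (`index_of_association()`): per locus $j$ and sample
  pair $(a,b)$, $d_j = |g_a - g_b|/2 \in \{0, \tfrac12, 1\}$
  (codominant diploid convention); the multilocus pair distance is
  $D = \sum_j d_j$. With $V_O$ the variance of $D$ over pairs and
  $V_E = \sum_j v_j$ the sum of single-locus distance variances,
  $$I_a = V_O/V_E - 1, \qquad
  \bar r_d = \frac{V_O - V_E}{2\sum_{j<k}\sqrt{v_j v_k}} .$$
  Both have expectation zero under random mating; significant positive
  values indicate multilocus association (linkage, inbreeding,
  clonality). All variances use the divide-by-N convention —
  consistently in $V_O$, $V_E$ and the denominator — which makes the
  duplicated-locus identity ($I_a = \bar r_d = 1$ for two identical
  loci) exact, a property the tests assert to 1e-12. Pairs missing a
  genotype at a locus are dropped from that locus only
  (pairwise-complete); listwise deletion would discard most chip data.
  With a single locus $\bar r_d$ is undefined and the function raises a
  validation error. No permutation test is run; the statistics are
  descriptive here.
- **Fst** (`weir_cockerham_fst()`): the Weir–Cockerham (1984) θ for
  each pair of groups, from per-marker variance components $a$ (among
  populations), $b$ (among individuals within populations) and $c$
  (within individuals), with unequal sample sizes and the observed
  heterozygosity terms; multilocus
  $\theta = \sum_m a_m / \sum_m (a_m + b_m + c_m)$. Small negative
  estimates are a known property of the estimator and are kept. More
  than two groups are reported pairwise (a matrix), which is what the
  downstream tree wants. The implementation is verified against an
  independently coded ANOVA sums-of-squares formulation to 1e-10 on
  random instances.
- **Trees** (`nj_tree()`): Saitou–Nei neighbor joining via `ape::nj()`
  on the (negative-clamped) distance matrix, with negative branch
  lengths clamped to zero; Newick output via `ape::write.tree()`.

`diversity_table()` assembles the per-group (breed or location) rows
plus a `Total` row — sample count, Hexp, Ia, rbarD — the layout of a
standard diversity summary table.

## Population structure

**PCA** (`pca_genotypes()`): dosages are centered by $2\hat p$ and
scaled by $\sqrt{2\hat p(1-\hat p)}$ (Patterson scaling), missing values
mean-imputed, monomorphic markers dropped; scores and percent variance
come from the SVD.

**Cluster number by BIC** (`find_clusters_bic()`): seeded multi-start
k-means on retained PCs, scored by
$\mathrm{BIC}(K) = n\ln(\mathrm{WSS}_K/n) + K\ln n$. A practical note:
this criterion behaves sensibly when many PC axes are retained (the
DAPC-style setting, where k-means cannot reduce high-dimensional noise
WSS enough to beat the penalty). On very low-dimensional score matrices
it can over-split; retain a few dozen axes.

**DAPC** (`dapc_genotypes()`): linear discriminant axes on the retained
PCs for supplied or k-means-derived groups, maximizing the
between/within scatter ratio; at most $K-1$ axes, percent of
discriminable variance per axis summing to 100. The number of PCs
defaults to the count explaining 90% of variance (capped at
$n - K$), and the within-scatter is ridge-regularized (trace-scaled
1e-6) when numerically singular — both situations that real chip data
with $n \approx 200$ regularly produces.

**Admixture** (`admixture_lsq()`): the sNMF-style least-squares model.
With $M$ the observed half-dosage matrix ($g/2$), minimize
$\|M - QF\|^2$ over the observed entries subject to each row of $Q$ on
the probability simplex and $F \in [0,1]^{K \times m}$. Missing
genotypes are excluded from the objective rather than imputed, which is
also what makes the masked cross-entropy machinery coherent.

The optimizer is block coordinate descent. Each $Q$ row is solved
*exactly* by a small active-set quadratic program on the simplex — this
matters, because projecting the unconstrained least-squares solution
onto the simplex systematically stalls short of the simplex faces
(errors-in-variables attenuation of ancestry estimates for unadmixed
individuals). The $F$ block takes an unconstrained least-squares jump
(kept only when it lowers the objective) followed by fixed-step
projected-gradient refinement; $1/L$ steps on a convex quadratic block
are guaranteed descent steps, so the sweep objective is non-increasing —
an invariant the tests check on every fit. Convergence stops when the
relative objective change drops below `tol` (default 1e-8; the SSE
surface is very flat near the optimum, and a looser 1e-6 demonstrably
stops before the ancestry coefficients finish moving to the faces).
$K = 1$ has the closed form $Q = \mathbf 1$, $F_{1j}$ = mean
half-dosage. The paper-scale tooling for this model runs $10^5$
iterations of stochastic updates; a deterministic block solver needs
only tens of sweeps at these problem sizes, so `max_iter` defaults
to 500.

**Choosing K** (`cross_entropy_select()`): a seeded 5% of observed
entries is masked, the factorization fit on the rest for each K, and
each fit scored by the cross-entropy of held-out half-dosages against
$\pi = \mathrm{clip}(QF, \varepsilon, 1-\varepsilon)$:
$$\mathrm{CE} = -\operatorname{mean}\big[\tfrac g2\ln\pi +
 (1 - \tfrac g2)\ln(1-\pi)\big].$$
The best K minimizes the criterion. Clipping guarantees finiteness. On
three-population simulations at chip density the criterion selects
K = 3, matching the BIC route.

## Mixed-model association

**Kinship** (`vanraden_kinship()`): $W$ = dosages column-centered by
$2\hat p$ (mean-imputed missing), $K = WW^\top / 2\sum_j \hat
p_j(1-\hat p_j)$. On Hardy–Weinberg data the diagonal averages near 1.

**Variance components** (`reml_null()`): the null polygenic model
$y = X\beta + u + e$, $\operatorname{Var}(u) = \sigma_g^2 K$,
$\operatorname{Var}(e) = \sigma_e^2 I$, fit by REML with the EMMA
spectral trick: eigendecompose $SKS$ (with $S$ the projection off $X$),
rotate, and profile the restricted likelihood over
$\delta = \sigma_e^2/\sigma_g^2$ on a 100-point log grid spanning
$10^{-5}$–$10^5$, refined with Brent optimization around the best grid
bracket. With $K = I$ the split $\sigma_g^2$ vs $\sigma_e^2$ is
unidentifiable, but the total matches the OLS residual variance — the
degenerate case the tests pin down. Users should know that $h^2$
estimates from a few hundred animals with chip-derived kinship have
large sampling variance; single-cohort estimates of heritability are
indicative, not definitive.

**Scan** (`marker_scan()`): P3D/EMMAX — the variance components are
estimated once on the null model and reused for every marker, reducing
each test to generalized least squares through a cached rotation
$V^{-1/2} = \mathrm{diag}(\sigma_g^2\lambda_i + \sigma_e^2)^{-1/2}
U^\top$. Per marker: allele-substitution effect $\hat\alpha$ (phenotype
units per Alt allele), its SE, a two-sided t test with
$n - \operatorname{rank}(X) - 1$ df, lod $= -\log_{10}p$, and
Benjamini–Hochberg q-values. Covariates default to intercept-only;
breed/location factors can be passed via `X`. Monomorphic markers are
emitted flagged with effect 0 and p 1 rather than dropped, so record
counts match the input panel. With $K = I$ the scan reproduces textbook
OLS to 1e-8, which the tests verify against `lm()`.

**Status** (`significance_status()`): `Sig` at raw $p \le 10^{-3}$ —
the operational threshold used with FDR reporting alongside, since
candidate tables in this literature list raw p-values against that
cutoff. `SigLD` marks markers that miss the cutoff but are at
$p \le 2\times10^{-3}$ and in strong LD (composite-dosage
$r^2 \ge 0.8$) with a `Sig` marker on the same chromosome within 1 Mb —
capturing the "significant through linkage" annotation; all three knobs
are arguments. Markers without chromosome or position skip the LD step
but are still tested and can be `Sig` (unplaced chip markers are real
and worth reporting).

**Plots** (`manhattan_qq_data()`): plot-ready tables — cumulative
genome coordinates with alternating color indices, expected vs observed
$-\log_{10}p$, and the genomic inflation factor
$\lambda_{GC}$ (median χ² ratio).

## Annotation

`map_snps_to_genes()` assigns each placed SNP to a gene: inside the
body ([start, end], 1-based inclusive) unstarred; otherwise the nearest
gene strictly closer than 10 kbp, starred (`GENE*`); when two genes
flank the SNP within range, the two nearest joined (`DSC2-DSC3*`); else
`-`. Ties break by distance then lexicographic id, so the mapping is
deterministic and order-independent. Internally every coordinate in the
package is 1-based inclusive; BED's 0-based half-open intervals are
converted at the read/write boundary (`read_gene_table()`), which keeps
the 10-kbp rule free of off-by-one ambiguity.

`hypergeom_enrichment()` is a generic over-representation test:
one-sided hypergeometric tail $P(X \ge k)$ for each user-supplied gene
set against a finite universe, BH-corrected across sets. No pathway
database ships with the package; curated databases version quickly and
belong to the user.

## The synthetic-data generator

`simulate_admixed_genotypes()` draws, per marker, an ancestral Alt
frequency $p_0 \sim U(0.05, 0.95)$ and K population frequencies from
the Balding–Nichols Beta distribution
$\mathrm{Beta}\!\big(p_0\frac{1-F}{F},\,(1-p_0)\frac{1-F}{F}\big)$ with
drift $F$ = `fst_target`; ancestry rows are Dirichlet(`alpha`);
individual dosages are Binomial(2, $q_i = \sum_k Q_{ik}F_{kj}$);
missingness is independent Bernoulli. Balding–Nichols was chosen
because it makes the drift parameter directly checkable by the
package's own Fst estimator: at `fst_target = 0.1` the realized
pairwise Weir–Cockerham θ between unadmixed populations is within
±0.02 at $n = 200$, $m = 5000$. Markers are laid out on 5 chromosomes
at 25-kb spacing so positional logic (LD windows, gene flanks) is
exercised. Markers are independent given ancestry — the generator does
*not* simulate linkage disequilibrium, pedigrees or selection, so tests
passing on it say nothing about LD-driven confounding in real data.

`simulate_physiology()` builds a latent heat-response score per animal,
$$s_i = \sqrt{h^2}\,g_i + \sqrt{1-h^2}\,z_i,$$
scaled to SD 0.5, where $g_i$ combines declared causal-marker effects
with a polygenic term drawn with covariance proportional to the
*realized* vanRaden kinship — so the GWAS model assumptions hold
exactly under simulation, giving clean type-I-error tests — and
$z_i$ is independent noise. Each scored parameter then changes by
$\delta_p(1 + s_i)$ plus measurement noise with SD
$0.25\,|\delta_p|$; noise proportional to the stress delta means
setting all deltas to zero gives exactly zero change and AHTI 0.

Two deliberate design choices in the defaults:

- **Staggered flag thresholds.** The default baselines (RT 39.0 ± 0.35
  °C, ET 36.0 ± 0.6 °C, RR 40 ± 8 /min, TV 0.25 ± 0.03 L, MR 140 ± 10
  kcal kg⁻⁰·⁷⁵ d⁻¹, with stress deltas +1.12 °C, +1.2 °C, +64 /min,
  −0.044 L, +11.4 units) put the five $2\sigma$ flag thresholds at
  evenly spread latent-score values ($s \approx -0.75, -0.375, 0,
  0.375, 0.75$). The 0–5 staircase is then close to linear in $s$, so
  simulated effect sizes transmit interpretably to AHTI and the
  generator's $h^2$ survives the discretization (REML on AHTI recovers
  $h^2 = 0.5$ within ±0.15 averaged over seeds at $n = 300$,
  $m = 5000$). The values themselves are realistic resting and
  post-exercise heat-stress physiology for desert sheep.
- **Causal effects in AHTI units.** Declared effects (AHTI units per
  Alt allele) are converted to latent shifts through the nominal
  AHTI-per-latent-unit slope 2.5 implied by that threshold spacing. The
  mapping is nominal — the realized allele-substitution effect on the
  discrete score varies with the cohort — but it is accurate enough
  that a 1.0-unit causal SNP at MAF ≥ 0.2 is the genome-wide top hit at
  $p \le 10^{-3}$ in ≥ 90% of seeded replicates at $n = 200$.

Tidal volume and metabolic rate are simulated directly and the raw
measurements back-computed (GV = TV·RR; VO2 from MR at respiratory
quotient 0.85, VCO2 = 0.85·VO2), so the panel's derivations hold
exactly. Body weight is constant within animal. All randomness flows
from one integer seed through `withr::with_seed()`, leaving global RNG
state untouched; identical seeds give bit-identical output.

`simulate_meteo()` just assembles a site × (07:00, 14:00) table of DBT
and RH for `thi_table()`, validating ranges (RH in [0,100], DBT in
−20–60 °C) and label uniqueness.

## Problem sizes, tolerances and limitations

The test suite runs the statistical checks at reduced but
representative sizes, chosen once: null and power GWAS simulations at
$n = 200$, $m = 2000$ (20 replicates for power); structure selection at
$n = 150$, $m = 5000$; ancestry recovery at $m = 3000$ (least-squares
ancestry noise scales as $1/\sqrt{m\cdot F_{st}}$, so chip-density
marker counts are the regime the MAE < 0.05 claim belongs to);
heritability transmission at $n = 300$, $m = 5000$ over 10 seeds. Exact
algebraic identities (duplicated-locus Ia/rbarD, HWE vs enumeration,
Weir–Cockerham vs its oracle, P3D-vs-OLS) are held to 1e-8–1e-12.

Known limitations: no LD-aware simulation; no sample-level QC
(relatedness pruning, sex checks); admixture standard errors are not
computed; the enrichment test ships no databases; `read_plink_text()`
re-orients Alt to the minor allele, so round-trips are exact only for
minor-allele-coded panels; and PLINK binary BED, phased or imputed
formats are out of scope.
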