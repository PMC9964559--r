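---
title: "Methods: expression-constrained flux modeling and flux-based survival subtyping"
author: "fluxprog developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-constrained flux modeling and flux-based survival subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxprog)
```

# The problem

Metabolite abundance correlates poorly with gene expression, so pathway
activity cannot be read off a transcriptome directly. Constraint-based
metabolic modeling offers a bridge: expression fixes per-sample enzyme
capacities, mass balance and an objective restrict the feasible flux
space, and sampling that space yields a per-sample flux profile for
every reaction in a genome-scale network. `fluxprog` implements this
bridge end to end for a prognosis question: which metabolic reactions'
fluxes are associated with patient survival, which correlated groups
(modules) of such reactions are robust, and whether a combination of two
module markers defines a clinically meaningful metabolic subtype (the
motivating application is IDH1-wild-type glioblastoma, where high
nucleotide-interconversion and low purine-recycling activity mark a
good-prognosis subgroup).

# The modeling chain

## Expression to enzyme capacity

Relative protein abundance is a pluggable model of FPKM; the default is
the power family $E_g = \mathrm{FPKM}_g^{\alpha}$ with $\alpha = 1$.
Gene-protein-reaction (GPR) rules are evaluated numerically with the
standard convention: AND (an enzyme complex) takes the minimum of its
children, OR (isozymes) the sum. The source study does not state its
rule; this convention is the field default and is monotone in every
gene, which the test-suite asserts as a property. Genes present in a
rule but absent from the expression table contribute the median of the
supplied abundances (configurable to zero or skip-rule); zero would
spuriously shut reactions on identifier-mapping gaps.

## Michaelis-Menten bounds

For a reaction with enzyme level $E_r$ and turnover numbers
$k^{f}_{cat}, k^{b}_{cat}$ (per minute), capacity bounds are

$$ub_r = s\,k^{f}_{cat}\,E_r, \qquad
  lb_r = \begin{cases}-s\,k^{b}_{cat}\,E_r & \text{reversible}\\
  0 & \text{otherwise}\end{cases}$$

intersected with the model's default bounds (enzyme data can only
tighten a model, never widen it). The dimensionless `scale` $s$ absorbs
the units bridge between relative abundance times kcat and
µmol/min/L. Reactions missing from the kinetics table use the table's
median kcat (configurable constant) rather than being shut. Empty GPRs
leave model bounds untouched.

## FBA and near-optimal sampling

Flux balance analysis maximizes $w^\top v$ over
$\{S v = 0,\; lb \le v \le ub\}$ with $w$ supported on the biomass and
ATP-demand reactions. The LP is solved by a dense two-phase primal
simplex written for this package (no LP solver is assumed in the
environment); an independently coded brute-force vertex enumerator
provides the oracle route in the tests, and the two must agree to
1e-6 on batteries of random toy networks.

Because the flux vector at an LP optimum is not unique, per-sample
profiles come from sampling, not from the optimizer: an
artificial-centering hit-and-run (ACHR) chain explores
$\{S v = 0,\; lb \le v \le ub,\; w^\top v \ge \gamma\,\mathrm{opt}\}$
in null-space coordinates (so steady state holds exactly), and the
reported per-sample flux is the mean of the retained points. The
optimum fraction $\gamma$ defaults to 0.9; $\gamma = 1$ degenerates to
the optimal face and is supported for tests.

### Chain length

Defaults are 1000 retained points, warmup 500, thinning 40. The warmup
and thinning are larger than the literature-typical 200/10 because we
measured the quality of the mean estimator directly: on the bundled
synthetic world, two chains with different seeds agree on per-sample
means with rank correlation ~0.92 at 200/10 (i.e. roughly a third of
the apparent between-sample variance was Monte-Carlo noise) and ~0.99
at 500/40. Since the flux matrix is the substrate for every downstream
statistic, the longer chain is the default; all three settings remain
configurable.

# Survival statistics

All survival machinery is implemented from first principles (the CRAN
`survival` package appears only as a test oracle):

* **Median split**: a sample is "high" iff its value is strictly larger
  than the cohort median; ties at the median go to "low". Constant
  vectors are an error.
* **Log-rank**: at each distinct event time, observed minus expected
  events in the index group accumulate with the hypergeometric
  variance; $\chi^2_1$, two-sided, no continuity correction. Zero
  events overall returns p = 1 with a flag. The test-suite compares the
  statistic against `survival::survdiff` and the p-value against an
  exhaustive permutation oracle on cohorts of n <= 10.
* **Kaplan-Meier**: product-limit estimate; the median is the earliest
  event time with $\hat S(t) \le 0.5$ (so for uncensored times 2,4,6,8
  the median is 4); "not reached" is reported as NA.
* **Cox**: Newton-Raphson partial likelihood for one binary covariate,
  Efron tie handling by default (Breslow available), CI from observed
  information. Monotone likelihoods (complete separation) are flagged
  divergent rather than silently iterated.

The prognosis screen applies the median split and log-rank to every
reaction's flux and keeps strict p < 0.01 (the threshold the source
analysis states); direction (+1 = high flux, longer survival) comes
from the sign of the Cox coefficient on the same split. No multiplicity
correction is applied at this stage, matching the original procedure; a
Benjamini-Hochberg column is emitted for the reader in the differential
stage.

# Modules, differential flux, WDA

**Modules.** Prognostic reactions become nodes of a graph with an edge
when |Spearman rho| > 0.8 across samples (the source writes both "R"
and "rho"; rank correlation is the safer reading and Pearson remains
available). Nodes with degree below `min_neighbors` (default 1, i.e.
"correlated with at least one other significant reaction") are singular
and dropped; modules are the connected components of the rest. A
module's direction is its members' majority; components mixing
directions are flagged rather than resolved — with absolute
correlation, a pathway's uptake exchange is anti-correlated with its
chain yet belongs to the same physical module, which is why mixing is
legitimate.

**Differential flux.** Two-group contrasts on log2 flux with
empirical-Bayes variance moderation: residual variances are modeled as
scaled-F, the prior degrees of freedom and prior variance are recovered
by moment matching on log-variances (digamma/trigamma identities), and
the moderated t has $d_0 + d_g$ degrees of freedom. With prior df 0 the
statistic reduces exactly to the ordinary t (asserted to 1e-12);
estimates agree with `limma::eBayes` (oracle) to 1e-6. Signed fluxes
make log2 ill-defined, so only reactions whose sampled means share one
sign across samples are log-transformed (with the sign factored out);
the remainder are analyzed on the raw scale and flagged.

**WDA.** For a pathway (subsystem) with $n$ fluxes, $k_\uparrow$
significantly increased and $k_\downarrow$ significantly decreased, and
$T$ significant fluxes network-wide:

$$\mathrm{Weight} = \frac{k_\uparrow + k_\downarrow}{T}, \qquad
  \mathrm{WDA} = 100 \cdot \mathrm{Weight} \cdot
  \frac{k_\uparrow - k_\downarrow}{n}.$$

Pathways with no significant fluxes score 0; $|\mathrm{WDA}| \le 100$;
weights sum to 1 when every significant flux has exactly one pathway.
Reactions without a subsystem are excluded with a warning.

# Subtyping

Each module is summarized by a representative: the member with the
smallest log-rank p, ties broken lexicographically. Because a tight
module's members share one median split (up to label swap), their
p-values tie to floating-point noise; ties are therefore detected with
a relative tolerance, otherwise the representative would be chosen by
ulp accidents.

For a pair of modules the two representative fluxes are median-split
independently; `concordant_good` is high in the positive
(protective) representative and low in the negative one,
`concordant_bad` the exact complement, everything else `other`.
Two conventions required decisions the source does not spell out:

* **Orientation follows the representative's own direction**, not the
  module majority. If the uptake exchange of a protective pathway is
  selected (its flux is the negative of the chain's), using the module
  majority would invert the high/low axis and the subtype comparison
  would silently test low-vs-low against high-vs-high — a null
  comparison. With orientation taken from the representative's own Cox
  sign this cannot happen.
* **Same-direction pairs** use the negated flux of one member, which by
  rank-equivariance of the median split yields the analogous
  high/high-vs-low/low concordance.

`scan_pairs` evaluates every unordered module pair this way, skips
pairs whose concordant classes fall below `min_group_size` (default 5;
the log-rank test is unstable below that), and ranks by log-rank p with
deterministic tie-breaking. `summarize_subtype` reports the Cox HR and
CI between the concordant classes, Kaplan-Meier medians per class and
for the rest of the cohort, and percentage median-survival gains (NA
when a median is not reached).

# The synthetic world

Every stage is exercised on generated cohorts with planted structure;
no external data are needed. The generator builds:

* a connected toy network of `n_pathways` linear enzymatic chains, each
  fed by an uptake exchange (lb = -50 µmol/min/L) and drained by a
  terminal export, plus a biomass sink drawing 0.01 of every terminal
  metabolite and an ATP branch (0.02 of pathway 1's terminal) with its
  own demand, both capped at 2; the objective is biomass + ATP demand.
  The draw coefficients are deliberately small: if the objective branch
  competes for pathway mass, biomass flux inherits the planted survival
  signal and leaks it into non-planted reactions, violating the stated
  hazard model. A pathway's exchanges carry the pathway's subsystem
  label and belong to its ground-truth module — mass balance makes
  their fluxes (anti-)correlated with the chain exactly as a transport
  or exchange reaction sits inside a real pathway module.
* log-normal expression: per-gene means $\mu_g \sim N(3, 1)$ on
  log-FPKM; genes of a planted module add $\lambda z_m$ (module
  activity $z_m \sim N(0,1)$ per sample, loading $\lambda = 0.95$) plus
  noise $\sigma = 0.1$;
* kinetics: kcat_f log-normal around 25/min (sdlog 0.3); the synthetic
  modeling scale is 0.01, sized so enzyme bounds — not the medium —
  are the binding constraints (chain capacities of a few µmol/min/L);
* survival: exponential with rate
  $\lambda_0 \exp(\sum_m \beta_m z_{mi})$, $\lambda_0 = 0.05$/month
  (median ~14 months, typical of IDH1-wild-type glioblastoma), planted
  effects $\beta = \mp 0.7$ (one protective, one harmful pathway, a
  third pathway null), censoring uniform on (0, 75] months (~30%
  censored). $\lambda_0$ and the censoring window were fixed once from
  a latent-level power analysis before any end-to-end test existed.

What a green test establishes: that planted co-expression survives the
bounds -> FBA -> sampling chain (|rho| > 0.5 between mean flux and
activity; in practice ~0.95), that the screen is calibrated under the
null, and that module membership, the top-ranked pair, and the subtype
separation are recovered in >= 90% of seeded replicates. What it does
not establish: realism of transcriptome-wide covariance (only planted
genes are correlated), batch effects, IDH1-mutation biology (the flag
column is constant), non-exponential hazards, or anything about real
genome-scale networks — the toy chains have none of Recon3D's loops,
cofactor coupling or compartment structure.

# Numerical choices

* Feasibility tolerance 1e-6 (steady state and bounds), LP optimality
  1e-9 relative; infinite bounds clamped at 1e6 inside the LP.
* Simplex uses Bland's rule (no cycling); the oracle enumerates basic
  solutions and is exponential — toy networks only.
* The ACHR chain runs in null-space coordinates, so $S v = 0$ holds to
  machine precision by construction; chord endpoints guard against
  zero-length directions (degenerate polytopes simply stay put, which
  makes $\gamma = 1$ on a unique optimum exact).
* Median-split ties go to "low" ("strictly larger than the median");
  KM median uses the $\le 0.5$ convention; Cox Newton steps are damped
  at |step| <= 2 and |beta| > 15 is declared divergent.
* Representative ties: relative tolerance 1e-9 on p, then
  lexicographic.

# Limitations

Single binary covariate Cox only (no multivariable adjustment); no
loopless/thermodynamic constraints; vmax-only kinetics (no Km
saturation); raw p thresholds by design, so screens on thousands of
reactions will contain ~alpha-level false discoveries (the calibration
test quantifies exactly this); the brute-force LP oracle and the
permutation log-rank oracle are exponential and restricted to toy
sizes; real SBML models are supported at the parsing level (L3 + FBC,
groups subsystems) but genome-scale sampling performance is out of
scope for the bundled pure-R/Rcpp solver.
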