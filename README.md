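# fluxprog

Expression-constrained metabolic flux modeling and flux-based survival
subtyping, as a tested R pipeline.

## Who this is for

Computational biologists who want to ask a prognosis question at the
level of metabolic *fluxes* rather than transcripts: given a
genome-scale metabolic network, a gene × sample expression table
(FPKM), enzyme turnover numbers and per-sample survival follow-up,
which reactions' fluxes are associated with survival, which correlated
reaction modules are robust markers, and does a two-module combination
define a metabolic subtype with a distinct outcome? The motivating
setting is IDH1-wild-type glioblastoma, where high
nucleotide-interconversion combined with low purine-recycling activity
marks a good-prognosis subgroup, but every stage is generic.

## The method in brief

Per sample:

1. protein abundance `E_g = FPKM_g^α` (pluggable model),
2. enzyme level per reaction through its gene–protein–reaction rule
   (AND → min, OR → sum),
3. Michaelis–Menten capacity bounds `ub = s·kcat_f·E_r`
   (`lb = −s·kcat_b·E_r` if reversible), intersected with model bounds,
4. flux balance analysis maximizing biomass + ATP demand over
   `{S·v = 0, lb ≤ v ≤ ub}` (own dense two-phase simplex, checked
   against an independent brute-force vertex oracle),
5. artificial-centering hit-and-run sampling of
   `{S·v = 0, lb ≤ v ≤ ub, wᵀv ≥ γ·opt}` (Rcpp kernel, γ = 0.9); the
   sample's flux profile is the mean of the retained points
   (µmol/min/L).

Across samples: each reaction's flux is median-split ("high" = strictly
above the median) and tested by a first-principles log-rank test
(strict p < 0.01); direction comes from the sign of a univariate Cox
fit (Efron ties). Prognostic reactions with |Spearman ρ| > 0.8 to at
least one other form modules (connected components); each module's best
member represents it; every positive/negative module pair yields a
subtype assignment (`concordant_good` = high protective flux ∧ low
harmful flux, `concordant_bad` the complement) compared by log-rank and
Cox. Differential flux between the concordant classes uses a moderated
t (empirical-Bayes variance shrinkage, moment matching on
log-variances), and pathway scores follow the weighted
differential-abundance formula

    Weight = (n_up + n_down) / T,
    WDA    = 100 · Weight · (n_up − n_down) / n_pathway

with `T` the network-wide significant-flux count.

A synthetic-cohort generator plants co-expressed flux modules with
known survival effects (exponential hazard, log-hazard linear in module
activities, ~30% uniform censoring) so the entire pipeline is testable
offline; see the methods vignette (`vignettes/flux-prognosis-methods.Rmd`)
for every modeling assumption and numerical choice.

## Worked example

```r
library(fluxprog)
co <- simulate_cohort(synthetic_spec(random_seed = 1))   # 150 samples, 2 planted modules
fm <- flux_matrix(co$network, co$expression, co$kinetics, cohort_gpmm_config(co))
pr <- find_prognostic_reactions(fm, co$survival)
mods <- extract_modules(fm, pr)
ps <- scan_pairs(mods, fm, co$survival, pr)
ps[1, ]
#>   module_pos module_neg rep_pos rep_neg sign_pos sign_neg n_good n_bad    hr logrank_p
#> 1         M2         M1   EX_M2   EX_M1        1        1     36    36 0.101  1.84e-11
asg <- assign_subtype(ps$sign_pos[1] * fm[ps$rep_pos[1], ],
                      ps$sign_neg[1] * fm[ps$rep_neg[1], ])
summarize_subtype(asg, co$survival)
```

The screen finds exactly the ten reactions of the two planted pathways
(all at log-rank p ≈ 1e-05), groups them into two modules, and the
top-ranked pair separates the cohort into concordant classes of 36
samples each (24% of the cohort per class): hazard ratio 0.101
(95% CI 0.047–0.216), log-rank p = 1.8e-11, median survival 52.5
months in `concordant_good` vs 2.5 in `concordant_bad` and 10.6 in the
rest of the cohort. The uptake exchange `EX_M2` representing the
harmful module carries direction +1 because its flux is the negative of
the chain flux — high `EX_M2` means low pathway activity; the pair scan
orients every representative by its own Cox direction so such members
cannot flip the subtype axis.

A command-line interface wraps the same stages
(`simulate fluxes prognosis modules subtype diff wda all`):

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "fluxprog.R", package = "fluxprog"))') \
    simulate --seed 7 --outdir cohort/
```

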