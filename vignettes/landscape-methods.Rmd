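---
title: "Methods: combinatorial genotype-phenotype analysis of hemoglobin function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinatorial genotype-phenotype analysis of hemoglobin function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbcube)
```

## The problem this package addresses

When a protein adapts — here, the high-altitude oxygen affinity of bar-headed
goose hemoglobin relative to its lowland *Anser* relatives — the derived
genotype differs from the ancestor at a handful of amino-acid sites. Which
substitution did the work? Did the others compensate for side-effects? The
answer requires measuring every mutational intermediate: with $k$ biallelic
sites there are $2^k$ genotypes (the hypercube), $2^k - 2$ intermediates, and
$k!$ forward pathways along which the derived states can be acquired. hbcube
takes per-genotype functional assays (or their summaries) and computes the
combinatorial statistics this study design calls for, plus the phylogenetic
polarization that defines which state is ancestral in the first place.

## Models fitted to the raw assays

**Oxygen equilibria.** Fractional saturation is modelled by the Hill
equation,
$$Y = \frac{P\mathrm{O}_2^{\,n}}{P_{50}^{\,n} + P\mathrm{O}_2^{\,n}},$$
fitted by unweighted nonlinear least squares on the saturation residuals
(`fit_hill()`). $P_{50}$ (torr) indexes affinity — lower is tighter binding —
and $n_{50}$ is the cooperativity coefficient. The optimizer is `stats::nls`
with a relative tolerance of 1e-8 and `scaleOffset = 1`, the latter so that
noise-free synthetic curves (zero residual at the optimum) converge instead
of erroring; initialization is a deterministic Hill-plot linearization
(logit $Y$ on $\log P\mathrm{O}_2$ over points with $0.05 < Y < 0.95$).
Weighted least squares is available (`weights =`) but off by default: with
5-8 equilibration steps per curve there is little information to estimate
weights from, and the unweighted fit is the reproducible reference. A fit is
flagged non-converged unless the optimizer succeeds *and* the fitted
$P_{50}$ lies within the observed pressure range extended one decade either
side. Replicate summaries (`summarize_replicates()`) report the SEM as
between-replicate scatter ($s/\sqrt{n}$); the asymptotic per-fit standard
error is reported separately (`mean_fit_se`) rather than mixed in, because
published tables do not say which of the two their errors are.

**Anion sensitivity.** The effect of allosteric anions (Cl$^-$, inositol
hexaphosphate) is indexed as $\Delta \log P_{50} = \log_{10} P_{50}^{\text{effector}}
- \log_{10} P_{50}^{\text{stripped}}$ (`anion_sensitivity()`), dimensionless
and antisymmetric by construction.

**Kinetics.** Stopped-flow deoxygenation traces and autoxidation
$A_{541}/A_{630}$ ratio series are both fitted with
$y(t) = c + A e^{-kt}$ (`fit_monoexponential()`), with half-life
$t_{1/2} = \ln 2 / k$. Rates follow the trace's time unit: s$^{-1}$ for
dissociation, h$^{-1}$ for autoxidation. Two documented interpretations are
baked in as package policy: (i) instrument-software phrasing of rates "per
half-life" is not reproducible as written, so the rate is defined directly
as the fitted exponential constant; (ii) apparent O$_2$ dissociation rates
are sometimes printed in M$^{-1}$s$^{-1}$, but a monoexponential time
constant is dimensionally s$^{-1}$, which is what the fit reports — the
discrepancy is recorded in the fit's `unit_note`. Fits with $r^2 < 0.99$
(the conventional bar for clean traces) carry a `low_quality` flag; a trace
that fits best with a negative rate carries `sign_error`. Neither flag ever
silently drops a result.

## Landscape statistics

Effects are defined on the $\log_{10}$ scale:
$\Delta = \log_{10}(\bar{x}_{\text{derived}}) - \log_{10}(\bar{x}_{\text{background}})$
(`mutation_effect()`). Log effects are the primary scale because the anion
indices are already logs and because log effects telescope: along any
pathway the step effects sum *exactly* to the endpoint difference, which the
tests assert to 1e-12. The signed raw-scale companion is
$100(10^{\Delta} - 1)$ percent; when comparing to published integer
percentages the package rounds half away from zero (an 18% reduction is
$\Delta = -0.0857$, percent $= -17.9$).

Significance per effect is a Welch two-sample $t$-test reconstructed from
(mean, SEM, $n$), with Welch-Satterthwaite degrees of freedom, two-tailed at
$\alpha = 0.05$ and no multiple-testing correction — the source tables
report per-comparison significance without naming a procedure, so this
choice is recorded here and in output metadata rather than hidden.

`rank_largest_effect()` identifies, per pathway, the step with the largest
effect in a declared direction (affinity gains are $P_{50}$ *decreases*;
the direction is an explicit argument, never guessed). Ties within 1e-12
are reported as ties — both sites listed, the pathway marked — because
silently breaking a tie would fabricate a claim. A verified property of the
shipped panel is that the winner is the same whether "largest" is measured
as $|\Delta|$ or as raw percent change; the two framings agree on these
data, so neither needs to be privileged.

Double-mutant-cycle epistasis between sites $a, b$ at a fixed background is
$$\varepsilon = [\log_{10} AB - \log_{10} aB] - [\log_{10} Ab - \log_{10} ab],$$
with the compensation ratio $AB/ab$ ($\approx 1$ means the double mutant
restored the ancestral value). On the shipped autoxidation panel this
quantifies the canonical compensatory story: the valine substitution at
site alpha63 raises the autoxidation rate more than 2-fold on glycine-alpha18
backgrounds, and the serine substitution at alpha18 returns the double
mutant to within 10% of the ancestral corner (one of the two cycles
over-compensates, so the assertion is one-sided:
$AB \le 1.10 \times ab$).

Missing hypercube corners always fail loudly, naming the genotype; nothing
is imputed.

## Parsimony polarization

Which state is "ancestral" comes from a rooted species tree plus a taxon x
site state matrix (`fitch_parsimony()`). Change counts and per-node sets of
equally parsimonious states are computed by unit-cost dynamic programming
(Sankoff with 0/1 costs, up and down passes). On binary trees this is
identical to the classic Fitch intersection/union algorithm; on polytomies
the naive Fitch generalization can over-count, whereas the DP remains exact
— and exactness against a brute-force enumeration oracle on all small trees
is an acceptance requirement, which decided the design. A substitution is
assigned to a branch (`assign_branches()`) only when the parent's and
child's state sets are disjoint, i.e. every maximally parsimonious
reconstruction changes state there; it is reported as `from -> to` only
when both sets are singletons, and flagged ambiguous otherwise. Ambiguity is
never resolved by an arbitrary pick.

The shipped waterfowl fixture (`anserinae_fixture()`) is a **synthetic
emulation**, clearly labelled as such in its filenames: the per-species
matrix behind the published figure is not machine-readable, so the fixture
is constructed so that the documented summary facts — ancestral genotype
GAP at the alpha sites and TD at the beta sites, three substitutions on the
bar-headed goose terminal branch, two on the stem of the remaining *Anser*
clade — are the unique parsimonious solution. Green tests on it establish
that the algorithms recover a history with those properties, not that the
emulated species states are the true ones.

## Pleiotropy screen

Trade-offs are screened by correlating per-mutation changes in one trait
against another (`edge_deltas()` + `pearson()`). Published screens of this
kind rarely state the pairing rule, and the rule changes both $n$ and $r$;
hbcube therefore implements three conventions — every hypercube edge
($k \cdot 2^{k-1}$ pairs), first steps from the ancestor ($k$ pairs), and
genotype-level pairing of the trait values themselves — and records the
convention in every result row. The package deliberately asserts no match
to any published $r$: on the shipped panel the genotype-level raw-scale
convention gives $r \approx -0.29$ over the 11 proteins, and the tests pin
that number against a direct `cor()` computation, not against a published
value measured under an unknown convention.

## The synthetic-data generators

Generators (`gen_saturation_curves()`, `gen_kinetic_traces()`,
`gen_autoxidation_series()`, `gen_landscape()`, `gen_site_state_matrix()`)
exist so the full pipeline is testable with no laboratory data. Their
defaults are the stated assay world, chosen once and not tuned: 8
equilibration steps (protocols use 5-8; 8 is the information-richest case),
triplicate replicates, Gaussian saturation noise with sd 0.01 (the scale at
which published triplicate SEs of a few hundredths of a torr arise),
log-spaced PO$_2$ over $[P_{50}/8,\; 8 P_{50}]$ (step placement is
unspecified in the protocol; log spacing covers both asymptotes of a Hill
curve evenly), 90-hour autoxidation series sampled hourly with the shipped
11-genotype rate panel as default truth, and landscape replicate noise of
0.02 on the $\log_{10}$ scale. Noise is Gaussian and independent across
points — no instrument model is attempted — and saturation noise is clipped
to $[0,1]$ with clipping events counted. Every generator requires a seed
and is bit-reproducible; every generator records its planted truth so
recovery tests close the loop.

Two generator design points worth knowing: interaction terms in
`gen_landscape()` may be of any order, not just pairwise, which lets the
test suite plant the *exact* interaction decomposition of the shipped
affinity panel and verify that the landscape statistics reproduce its
pathway-winner split (4 of 6 pathways won by the alpha119 substitution, 2
by alpha63, exactly the pathways where it occurs first). And
`gen_site_state_matrix()` plants substitutions only on branches that are
not children of the root: a change on a root-child branch cannot be
polarized by parsimony (the single change can be placed on either side of
the root), so planting there would make the stated recovered-exactly
property false for a reason that has nothing to do with the algorithm.

## What a green suite does and does not establish

It establishes: the combinatorial statistics reproduce the published
summary numbers from the transcribed panel tables; the fitters recover
planted parameters at the stated noise (P$_{50}$ within 2%, rates within
5%, noiseless to 1e-6 relative); parsimony equals brute-force enumeration
on small trees; epistasis estimates equal an exhaustive interaction solve
on synthetic landscapes. It does not establish anything about real
instrument noise (drift, heteroscedasticity, saturation-dependent error),
about the true waterfowl character matrix (emulated), or about which
pairing convention produced any published correlation.

## Numerical choices in one place

* `nls` relative tolerance 1e-8, max 10000 iterations, `scaleOffset = 1`.
* Hill fit convergence additionally requires $P_{50}$ within the observed
  pressure decade-extended range.
* Tie tolerance in winner ranking: 1e-12 on $\Delta$.
* Telescoping asserted to 1e-12; noiseless recovery to 1e-6 relative.
* Percent comparisons to integer published values: round half away from
  zero.
* Welch df from summary statistics; $p$ two-tailed; $\alpha = 0.05$.
* PO$_2$ is torr everywhere internally; kPa accepted at the CSV boundary
  (1 kPa = 7.50062 torr).

## Known limitations

Only biallelic sites; no allosteric two-state (MWC) model — the Hill fit is
descriptive; no likelihood-based ancestral reconstruction (the tree is an
input, never inferred); no population-genetic accessibility modelling of
pathways; autoxidation is strictly monoexponential (no autocatalytic
phase); correlations come with no multiple-testing control beyond the raw
per-row $p$.
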