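---
title: "Descriptor-based toxicity modeling of carbamates: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptor-based toxicity modeling of carbamates: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qstr)
```

## The problem

Carbamate pesticides inhibit acetylcholinesterase by carbamylating its
catalytic serine; their acute toxicity is conventionally summarized by the
oral rat LD50.  A quantitative structure–toxicity relationship (QSTR)
links that endpoint to quantities computable from the molecular structure,
so that the toxicity of untested carbamates can be estimated and the
structural features driving it can be read off the model.  This package
implements one such analysis end to end: the response transform, the ten
molecular descriptors of a published multi-linear model, model fitting and
internal validation, genetic-algorithm descriptor selection, the
leverage-based applicability domain, and a seeded synthetic-data generator
that makes the whole pipeline testable without any external downloads.

The response is the negative decadic logarithm of the molar lethal dose,

$$\log(1/C), \qquad C = \mathrm{LD}_{50}\,[\mathrm{mg/kg}] \; / \; M_w\,[\mathrm{g/mol}] \;\; (\text{numerically mmol/kg}),$$

so larger values mean higher toxicity (`log_inv_c()`).

## The model

The frozen published model (`PUBLISHED_MODEL`) is a ten-descriptor linear
form

$$\widehat{\log(1/C)} = 18.7033 + 0.3231\,EA - 34.0837\,q_C - 0.6319\,LOC
- 22.6053\,SpPosA\_RG - 1.5012\,H4m + 0.2275\,nCt - 0.6919\,nROCON
+ 0.6524\,B05_{[C\text{-}N]} + 0.3996\,B05_{[N\text{-}O]} + 0.6244\,DLS_{05}.$$

Two descriptors are electronic and are *ingested as data*: the electron
affinity $EA$ (eV) and the Hirshfeld charge $q_C$ of the carbamate
carbonyl carbon (elementary charges).  Both come from quantum-chemistry
calculations that are outside this package's scope; `conceptual_dft()`
derives $I$, $A$, $\mu$, $\eta$, $\omega$ and the gap from supplied
frontier-orbital energies by the Koopmans finite-difference convention,
but never computes orbital energies itself.  The remaining eight are
structural, topological or geometric and are computed here from the
molecular graph and 3D coordinates.

## Descriptor conventions

Descriptor software differs in small conventions the original sources do
not always pin down.  Every such choice is a documented default with a
configuration flag, chosen once at design time:

* **Aromaticity and rings.** Structures are parsed with OpenBabel
  (kekulized bond orders); ring perception and the aromaticity of each
  ring follow ChemmineR's ring analysis.  Ring counts (`NRG567`) use the
  smallest set of smallest rings, selected from the perceived rings by
  GF(2)-independent greedy accumulation up to the cyclomatic number.
* **Unsaturation.** $Unsat = NRG_{567} + nDB + 2\,nTB + (nAB+1)/2$.  Read
  literally, the last term assigns 0.5 to molecules with *no* aromatic
  bonds; a nonzero unsaturation for ethane is chemically meaningless, so
  the default takes the term as 0 when $nAB = 0$, and
  `unsat_literal = TRUE` restores the printed form.  $Unsat\text{-}p$
  divides by the number of heavy atoms that are not halogens (F, Cl, Br,
  I, At) and carry no bonded hydrogen; when that denominator is zero the
  ratio is undefined and the corresponding drug-likeness rule counts as
  unsatisfied.
* **Drug-like score.** $DLS_{05}$ is the fraction of two rules satisfied:
  $nNO/nC3 \in [0.10, 1.80]$ (inclusive) and $Unsat\text{-}p \le 0.43$;
  an undefined ratio ($nC3 = 0$) fails its rule.
* **nROCON.** 1 when a C–O–C(=O)–N fragment exists whose ester-oxygen
  substituent is a non-aromatic carbon; O-aryl carbamates, carbamic acids
  and O–N (oxime) carbamates score 0.
* **B05 flags.** Presence of a C,N (resp. N,O) heavy-atom pair at
  shortest-path distance exactly five bonds.
* **Geometric descriptors.** $SpPosA\_RG$ is the sum of strictly positive
  eigenvalues (threshold $10^{-10}\max|\lambda|$, to avoid counting
  numerical zeros) of the inverse-squared-distance matrix over heavy
  atoms, divided by the heavy-atom count.  $H4m$ centers the heavy-atom
  coordinates, forms the molecular influence matrix
  $H = M(M^\top M)^{-1}M^\top$ (Moore–Penrose pseudo-inverse for planar or
  linear geometries), and sums $H_{ij} w_i w_j$ over unordered pairs at
  topological distance 4 with $H_{ij} > 0$, with carbon-scaled masses
  $w_i = m_i/m_C$.  Both default to heavy atoms only
  (`getaway_include_h` / `include_h` flags add hydrogens); distances are
  measured on the same atom set.  Fewer than five atoms in the set means
  no lag-4 pairs and a value of exactly 0.
* **Geometries are inputs.** 3D coordinates are never generated
  internally; geometric descriptors of molecules without coordinates are
  flagged `NA`, never silent zeros.  The bundled toy-set geometries are
  idealized force-field conformers (frozen literals), which is why the
  package promises invariances and oracle agreement for the geometric
  descriptors, not bit-parity with any particular descriptor program.
* **Fragments.** Multi-fragment inputs (salts) are reduced to the largest
  heavy-atom fragment with a warning before descriptor computation, since
  these descriptors assume a connected graph.

## Fitting and validation

`qstr_fit()` solves the least-squares problem through the QR
factorization (`stats::lm`), and reports
$R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$, $\mathrm{RMSE} = \sqrt{SSE/n}$,
MAE, two-sided $t$ p-values, 95% confidence half-widths, and standardized
coefficients $b_j\,\mathrm{sd}(x_j)/\mathrm{sd}(y)$ using population
(n-denominator) standard deviations (switchable to sample ones).  A
constant response is defined to have $R^2 = 0$.  Rank-deficient designs
are an error naming the collinear columns, never a silent drop.

$Q^2_{\mathrm{LOO}}$ uses the hat-matrix shortcut
$e_i/(1-h_{ii})$ by default and an explicit leave-one-out refit loop as an
independent second route (`q2_loo(..., method = "refit")`); both use the
full-sample mean in the denominator, which guarantees
$Q^2 \le R^2$.  A model is flagged internally predictive when
$Q^2_{\mathrm{LOO}} > 0.5$.

Five-fold cross-validation shuffles rows by seed into near-equal folds;
out-of-fold $R^2$ uses the held-out fold's own mean.  Because the original
description of the splitting procedure is ambiguous (a random split in one
place, fold selection "by the median of $R^2$" in another), both are
implemented: plain seeded folds by default, and a `median_r2` mode that
draws 25 candidate fold assignments and keeps the one with the median mean
CV $R^2$.

The train/test split holds out $\lfloor 0.15\,n \rfloor$ compounds.  The
floor (rather than round-half-up) is deliberate: for 178 compounds it
yields 26 test and 152 training rows, the only split consistent with the
published critical leverage $h^* = 3(p+1)/n = 33/152 = 0.217$.

The applicability domain uses leverages $h_i = x_i^\top(X^\top X)^{-1}x_i$
from the thin QR (their sum is exactly $p+1$); new compounds are projected
with the training $(X^\top X)^{-1}$.  `williams_data()` /
`plot.qstr_fit()` tabulate and draw leverage against standardized
residuals (residual / training RMSE) with the $\pm 3\sigma$ band and
$h^*$ cutoff; points beyond $h^*$ are extrapolations, points beyond
$3\sigma$ response outliers.

## Genetic-algorithm descriptor selection

`ga_select()` searches fixed-size descriptor subsets with tournament
selection (size 3), uniform crossover repaired to the fixed subset size,
single-member swap mutation and elitism of 1.  Defaults (population 100,
generations 200, crossover 0.8, mutation 0.1) are conventional values —
the original report gives none — and every one is exposed in
`ga_config()`.  The default fitness is $Q^2_{\mathrm{LOO}}$; $R^2$ is
available.  Duplicate-column fitness ties resolve by first-seen order.
Before selection, `prefilter()` removes constant columns and, for every
pair with $|r| > 0.90$, the member less correlated with the response
(ties: the later column).  Note that on the printed reference rows the
$B05_{[C\text{-}N]}$ column equals 1 for every compound and is therefore
removed by the constant-column rule — pre-filtering is meant for the full
descriptor pool, not for a table restricted to an already-selected model.

## The synthetic generator

`gen_linear_dataset()` emulates what the analysis statistically assumes: a
weakly inter-correlated descriptor matrix (latent Gaussian copula; the
correlation matrix is a *fixed* function of the configuration, since a
study has one chemical space, and its largest off-diagonal entry is capped
at 0.45, the largest entry of the published descriptor correlation
matrix), a few near-degenerate binary columns produced by quantile
thresholding (mimicking the almost-constant lag-5 flags and the
concentrated drug-like score), and a response
$y = \beta_0 + X\beta + \varepsilon$, $\varepsilon \sim N(0, \sigma^2)$.
The `"study-regime"` preset fixes the study conditions: 178 compounds, 10
active descriptors, two binary columns (rates 0.95 and 0.70), and
$\sigma = 0.9856$ (`STUDY_REGIME_NOISE_SD`), calibrated once by the
included script (`inst/scripts/calibrate-noise.R`) so the mean full-data
$R^2$ centers on 0.6584.  With honest Gaussian noise at $n = 178$ the
sampling standard deviation of $R^2$ is about 0.04, so individual draws
scatter around that center — the distribution is summarized by its mean
and by the fact that draws fall on both sides of the published value.

What the generator does *not* emulate: real descriptor marginals (counts,
bounded indices), the discrete dependence between structural descriptors
of actual molecules, measurement structure in LD50 values, or any
chemistry.  Green simulation tests therefore demonstrate the correctness
and calibration of the statistical machinery at the study's size and
signal-to-noise ratio — not predictive validity on real carbamates.

The separate `toy_carbamate_set()` fixture covers the chemistry side: 21
hand-analysed molecules exercising every structural-descriptor branch,
with expected values assigned by hand at authoring time.

## Problem sizes and numerical choices

Test and validation runs use sizes chosen to exercise the study regime
while staying lightweight: 100 random instances for the
leave-one-out/hat-matrix identity (up to 100 × 12), 200 replicates at
152 × 10 for coefficient coverage, 10 seeds × (178 × 30, population 60,
generations 60) for GA recovery, and 50 seeds of the 178 × 10 preset for
the calibration summaries.  Degenerate inputs are defined, not patched
around: empty graphs, disconnected graphs (error directing to
`largest_fragment()`), leverage exactly 1 (LOO undefined — error),
coincident atoms (error), planar geometries (pseudo-inverse with a note),
constant responses ($R^2 = 0$).

## Limitations

* Geometric descriptor values depend on the input conformer; with
  force-field rather than quantum-chemistry geometries they are close but
  not identical to published per-compound values, which is why the
  package validates them by invariance and independent-oracle agreement.
* Only eleven of the twelve printed reference compounds are available in
  the transcribed table; the frozen-model consistency checks run on those
  eleven.
* Reproducing the published fit statistics exactly requires the complete
  178-compound descriptor table, which is not bundled;
  `refit_descriptor_table()` performs that reproduction when such a table
  (canonical CSV layout) is supplied.
* Alternative regressors (ridge, lasso, boosting, SVR) are out of scope:
  the modelling value of this analysis is its interpretability.
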