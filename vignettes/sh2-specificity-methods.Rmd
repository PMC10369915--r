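---
title: "Models and methods: SH2 specificity screens, binding, activation, and coupling energetics"
author: "sh2profiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sh2profiler)
```

# Scope

`sh2profiler` implements the quantitative core of an SH2-domain
phosphopeptide specificity study as a reusable, tested pipeline: enrichment
scoring of bacterial peptide-display selections from sequencing counts,
control-calibrated hit calling, position-specific sequence logos and
scanning-mutagenesis matrices, exact-equilibrium fluorescence-polarization
(FP) binding fits (direct and competition), phosphopeptide-dependent
phosphatase-activation EC50 fits, and double-mutant-cycle coupling
energetics. A synthetic-data module generates screens and titrations with
known ground truth so that every stage is exercised without external data.

# The selection screen and its statistic

A display library of fixed-length peptides — wild-type human phosphosites,
point variants, and tyrosine-free negative controls — is enzymatically
phosphorylated, selected on SH2-coated beads, and deep-sequenced before and
after selection. The per-peptide statistic is a plain frequency ratio:

$$\mathrm{score}_i \;=\; \frac{f_i^{\text{selected}}}{f_i^{\text{input}}},
\qquad
f_i = \frac{c_i + \alpha}{\sum_j (c_j + \alpha)},$$

with pseudocount $\alpha = 1$ read per peptide by default. The pseudocount
exists only to keep selection dropouts finite; at typical depths it perturbs
well-sampled peptides by far less than counting noise, and $\alpha = 0$ is
supported for exactness checks. Three identities pin the arithmetic down and
are enforced in the test suite: scoring a sample against itself gives
exactly 1; at $\alpha = 0$ the scores are invariant to uniformly rescaling
the read depth; and $\sum_i f_i^{\text{input}}\,\mathrm{score}_i = 1$
(frequency conservation).

Counting is exact-match on the translated peptide: each read is sliced at a
configured coding region, translated in frame, and counted only if it
equals a library peptide, so synonymous codons collapse correctly. Reads
with ambiguous bases, stop codons, or no library match are tallied under
explicit discard reasons and reconcile with the read total. No mismatch
tolerance is applied: the library is a defined set, and a one-substitution
read is more plausibly a different library member's sequencing error than a
legitimate observation. The read layout (offset and length of the coding
region) is configuration because display constructs differ; the default
takes the whole read in frame 0.

Replicates are averaged on the score scale (arithmetic mean), matching how
replicate screens are annotated per library; distinct libraries are
concatenated by peptide id, and a peptide screened in one library keeps its
own replicate count. Peptides with more than one tyrosine are dropped
before analysis — with several phosphorylatable positions the enrichment
cannot be attributed to a single site — while tyrosine-free controls are
retained because calibration needs them.

## Hit calling calibrated on tyrosine-free controls

Tyrosine-free peptides cannot be phosphorylated, so their enrichment
distribution measures the non-specific background of the selection. The
calibrated cutoff is the smallest value $c$ (among the sorted control
scores, bounded below by a configurable floor) with
$\Pr(\text{control score} > c) \le$ `max_control_fraction` (default 0.02).
A fixed user cutoff is equally supported, since published screens of this
kind fix 3.2 — a value at which fewer than 2% of controls score as binders.
Hits are single-tyrosine, non-control peptides with mean score **strictly
greater** than the cutoff; strict comparison makes counting unambiguous at
ties and is antitone in the cutoff (raising the cutoff can only shrink the
hit set — a property test). Mean-score calling is the default because one
score per peptide is what the field's scatter plots present; an
all-replicates mode is available behind a flag for the stricter
per-replicate question.

## Logos and scanning matrices

The logo value for amino acid $a$ at position $p$ relative to the
phosphotyrosine (pTyr = 0, excluded; window −5…+5 clipped to the peptide) is

$$\log_2\frac{(n_{\mathrm{enr}}(p,a)+\beta)/(N_{\mathrm{enr}}+20\beta)}
             {(n_{\mathrm{lib}}(p,a)+\beta)/(N_{\mathrm{lib}}+20\beta)},$$

a log-probability enrichment of the hit set against the full
single-tyrosine library, with a shared pseudocount $\beta$ (default one
occurrence). Base 2 is a documented choice (the convention "log-transformed
probabilities" leaves the base open) and is configurable. Two exact
properties hold by construction and are tested: if the hit set is the whole
library the matrix is identically zero for any pseudocount, and per
position $\sum_a f_{\mathrm{lib}}(a)\,2^{\mathrm{value}(a)} = 1$. At
$\beta = 0$ a residue absent from both sets carries no information and its
cell is set to 0 rather than NaN. On synthetic screens whose true weights
follow a position-weight model, the recovered logo reproduces the sign of
every favoured/disfavoured residue with weight ratio ≥ 4 (seeded test).

Scanning-mutagenesis matrices locate each single-substitution variant by
direct sequence comparison against the wild-type peptide and store
$\log_2(\mathrm{score_{variant}}/\mathrm{score_{wildtype}})$; wild-type
residue cells are exactly 0 by construction. Variants that are absent,
multiply substituted, or below an optional input-count floor are flagged
missing rather than imputed — weak wild-type binders differentiate neutral
from loss-of-function substitutions poorly, and imputation would disguise
that.

# Binding models

All concentrations are micromolar; nanomolar inputs are converted on load.

**Direct FP titration.** The probe is not assumed to be in trace: the bound
probe concentration is the exact ligand-depletion root

$$L_b = \tfrac12\Big(R+L+K_d-\sqrt{(R+L+K_d)^2-4RL}\Big),$$

and the signal model is
$s(R) = s_f + (s_b - s_f)\, L_b/L$. At $L \to 0$ this reduces to the
hyperbola $R/(R+K_d)$, which the implementation uses as the exact limit at
$L = 0$.

**Competition FP titration.** Probe and unlabeled competitor compete for
one receptor site. Free receptor $F$ is the unique physical root of

$$F^3 + (K_a+K_b+A+B-R)F^2 + \big(K_aK_b + K_b(A-R) + K_a(B-R)\big)F
  - K_aK_bR = 0,$$

solved by `polyroot` with Newton polishing; root selection asserts
positivity, $F \le R$, and mass balance for all three species to $10^{-9}$
relative. No IC50/Cheng–Prusoff shortcut is used anywhere — those
approximations bias exactly the tight binders the analysis cares about. The
solver is validated against an independent iterative mass-action solver
(bracketing plus Newton on the monotone balance equation
$F + AF/(K_a{+}F) + BF/(K_b{+}F) = R$) on 10,000 random inputs; the two
agree to ~$10^{-14}$ relative. For free-receptor roots below roughly
$10^{-8} R$ both routes are limited by double-precision cancellation
against the totals, which is far below any experimentally meaningful
concentration.

**Activation.** Phosphopeptide binding to the N-SH2 domain relieves SHP2
autoinhibition; initial rates follow
$v(c) = v_0 + (v_{\max}-v_0)\,c^n/(EC_{50}^n + c^n)$ with $n = 1$ by
default, matching the simple saturating curves such activation shows. The
Hill coefficient can be freed as a robustness check. The basal rate is a
fitted parameter rather than being subtracted, so zero-activator points
inform it. EC50 estimates are exactly invariant to affine rescaling of the
rate axis (tested to $10^{-9}$). The affinity–potency relation is
summarized as the Pearson correlation of $\log_{10} EC_{50}$ against
$\log_{10} K_d$ with the log–log regression slope; a zero-variance axis is
reported as undefined rather than NaN.

## How the fits are computed

All three fit types share one structure: the two signal endpoints enter the
model linearly, and a single nonlinear parameter (log-transformed $K_d$,
$K_i$, or $EC_{50}$) does not. The fits therefore use variable projection:
at each candidate value of the log-constant the endpoint pair is solved
exactly by linear least squares, and only the profiled residual sum of
squares is searched — a coarse 80-point log-spaced grid spanning the
titrated concentration range six natural-log units beyond either end,
golden-section refinement, then Newton polishing of the profile minimum via
central differences (golden section alone resolves an argmin only to about
the square root of machine precision). The grid makes the search global, so
no starting value or multi-start heuristic is needed, and noiseless data
are recovered to ~$10^{-10}$ relative. The signal axis is normalized
internally to make tolerances scale-free; endpoints are mapped back
afterwards. In Hill mode the two nonlinear parameters are searched by
Nelder–Mead over the same profiled objective.

Standard errors come from the Gauss–Newton covariance
$\hat\sigma^2 (J^\top J)^{-1}$ of the full parameter Jacobian at the
optimum, with the delta method mapping the log-constant's error to the
constant. Degenerate inputs — a flat titration, or all-zero activator
concentrations — are flagged (`converged = FALSE`, `no_transition`) rather
than raised, since a screening workflow must survive failed wells. These
errors are first-order (the usual nonlinear-regression caveat): across 100
seeded noisy repeats the truth lies within ±2 SE in ≥ 90% of fits for
every mode, which is what the acceptance suite asserts.

**Fold-changes** between domain variants are ratios of geometric means of
replicate dissociation constants (fold > 1 = tighter variant binding), with
a two-sided Welch t-test on log-$K_d$ when at least three replicates per
side exist; the confidence interval is computed on the log scale and
back-transformed, so it always contains the fold.

# Double-mutant-cycle energetics

Binding free-energy differences use
$\Delta\Delta G = -RT\ln(\mathrm{fold})$ with
$R = 1.9872\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ and $T = 298.15$ K by
default (the assay temperature is a parameter; kcal is the default unit
with a kJ option). Equivalently $\Delta\Delta G_X = RT\ln(K_d^X/K_d^{wt})$,
negative for affinity-enhancing mutations. For a four-state cycle
(wild type, single mutants A and B, double mutant AB):

$$\Delta\Delta G_{\mathrm{int}}
  = \Delta\Delta G_{AB} - \Delta\Delta G_A - \Delta\Delta G_B
  = RT\ln\frac{K_d^{AB}K_d^{wt}}{K_d^A K_d^B},$$

which is symmetric under exchanging A and B and identically zero for an
additive cycle (both tested to $10^{-12}$). The sign convention is fixed by
that identity: **negative** $\Delta\Delta G_{\mathrm{int}}$ means the
double mutant binds tighter than additivity predicts; **positive** means
sub-additivity. When only fold-changes are reported, the equivalent route is
$\Delta\Delta G_{\mathrm{int}} = RT\ln(\mathrm{fold}_A^{wt\,bg} /
\mathrm{fold}_A^{B\,bg})$: attenuation of a mutation's fold by the second
mutation is sub-additive and hence positive. For the T42A/K55R pair this
means peptides whose T42A enhancement collapses in a K55R background (the
+2 Glu peptides MILR1 pTyr338, 90→28-fold, and PD-1 pTyr223, 28→4.3-fold)
carry positive interaction energies (+0.69 and +1.11 kcal/mol), while Gab2
pTyr614 (20→43-fold) is super-additive (−0.45 kcal/mol) — either way, a
nonzero value means the two residues are energetically coupled.

# The synthetic-data generator

The generator exists to give every downstream stage data with known truth.

**Screens** are modeled as one round of multiplicative reweighting:
input counts are multinomial at the input depth from the input frequencies
(uniform by default), selected counts are multinomial with probabilities
proportional to input frequency × selection weight. Tyrosine-free controls
carry weight 1 — non-binders ride through at background. One round is
sufficient to give the pipeline the statistical structure it assumes (a
frequency ratio estimates the weight up to normalization: the expected
score of peptide $i$ is $w_i / \sum_j f_j w_j$); the bead-enrichment
kinetics of a real selection are not modeled. Weight recovery is tested at
depth $10^6$, where the regression of scores on normalized weights has
slope $1.00 \pm 0.05$. Position-weight-model weights
(`pwm_screen_weights()`) let tests and the workflow generate screens with
designed position-specific preferences.

**Titrations** add zero-mean Gaussian noise to the exact forward curves.
Gaussian (not Poisson) noise matches plate-reader FP measurements, whose
error is dominated by detector and pipetting scatter, not photon counting.
Defaults chosen once as realistic instrument scales: 2 mP for binding
signals spanning ~150 mP, 2% of the maximal rate for activation. All
randomness flows from one explicit seed per call (`withr::with_seed`), so
identical calls are bitwise-reproducible and no global RNG state leaks.

What the generator does **not** emulate — expression bias, PCR jackpotting,
phosphorylation efficiency, multi-round selection, plate-position effects —
bounds what green tests mean: they certify the statistics conditional on
the sampling model, not robustness to those real-data artifacts.

# Problem sizes and numerical choices

The test and acceptance workloads are sized to be desk-scale while leaving
the asymptotic claims intact: 1,000 random count tables for the score
identities; one screen of 440 peptides at depth $10^6$–$2\times10^6$ for
weight recovery and logo sign recovery; $10^4$ random inputs for the
competitive-solver cross-check; 100 seeded repeats per fit type for SE
coverage. Titration designs are 12 concentrations in technical duplicate
(24 wells) spanning at least four decades around the true constant — the
usual plate layout for FP and activity assays, and enough degrees of
freedom that ±2-SE coverage of the truth is comfortably above 90%.

Other numerical decisions, collected: strictly-greater hit comparison;
cutoff candidates are the observed control scores plus a floor, and the
floor is a lower bound on the result; logo 0/0 cells are 0 at zero
pseudocount; the competition cubic's physical root is the smallest positive
real root ≤ R, Newton-polished, with mass balance asserted; flat or
degenerate titrations are flagged, never raised; replicate pooling requires
identical peptide sets within a library and disjoint ids across libraries.

# Limitations

Enrichment scores are plain frequency ratios — no variance stabilization or
count-model shrinkage — so low-input-count peptides are noisy; the
pseudocount bounds but does not remove that. The hit cutoff treats controls
as exchangeable with non-binders. FP fits assume a single binding site and
no fluorescence-intensity artifacts; anisotropy/polarization unit
conversions are out of scope. EC50 fits are per-curve (no shared maximal
rate across peptides), and the two-state allosteric equilibrium underlying
activation is not itself modeled. Coupling energies inherit the precision
of the underlying $K_d$ ratios and report no enthalpic/entropic
decomposition.
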