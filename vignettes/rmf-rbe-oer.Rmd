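---
title: "From DNA damage yields to RBE and OER: the models behind protonRBE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From DNA damage yields to RBE and OER: the models behind protonRBE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonRBE)
```

## The problem

Proton therapy plans weight physical dose by a relative biological
effectiveness (RBE), conventionally the constant 1.1. Along a 62-MeV proton
track, however, the linear energy transfer (LET) rises from about 1 keV/µm at
the entrance to about 23 keV/µm at the distal edge of the Bragg peak, the DNA
damage it inflicts becomes more clustered, and the biological effect per Gy
rises with it. Tumour hypoxia pulls in the opposite direction: with little
oxygen to "fix" radical damage, fewer lesions form per Gy, but the *relative*
advantage of densely ionising radiation grows. `protonRBE` packages a
transparent, fully inspectable chain from damage-yield tables to RBE and
oxygen enhancement ratio (OER):

1. **Damage spectra.** Clustered lesions on duplex DNA are classified into
   the standard seven categories — BD, SSB, SSB⁺, 2SSB, DSB, DSB⁺, DSB⁺⁺ —
   by proximity rules (`classify_cluster()`), and bookkept as yields per Gy
   per Gbp (`damage_spectrum()`, `aggregate_totals()`).
2. **Enzymatic DSBs.** Excision repair of a non-DSB cluster can incise the
   backbone opposite an existing nick and create a *de novo* DSB
   (`enzymatic_dsb_yield()`, `simulate_repair()`).
3. **RMF → LQ.** The repair–misrepair–fixation (RMF) model maps the DSB
   yield per cell per Gy to linear-quadratic survival coefficients
   (`lq_alpha()`, `lq_beta()`).
4. **Endpoints.** Yield-ratio RBE for DSB induction, survival-level RBE, and
   OER (`rbe_dsb()`, `rbe_survival()`, `oer_survival()`).

The package ships the published yield and repair-outcome tables for six
depths (P1–P6) of a 62-MeV beam and the cobalt-60 reference
(`load_fixture_tables()`), plus seedable Monte Carlo emulators of the
damage-induction and excision-repair simulations, so the complete pipeline
runs and is testable without any external simulation software.

## Damage classification

A cluster is a non-empty set of lesions (strand breaks, damaged bases,
abasic sites) at 1-based coordinates on the two strands of a short duplex
segment. The rules, applied in order:

* no breaks → `BD`;
* breaks confined to one strand → `SSB` (one) or `SSBp` (two or more);
* opposite-strand breaks all separated by ≥ 10 bp → `SSB2`;
* two disjoint opposite-strand break pairs, each within 10 bp and lying
  within 10 bp of one another → `DSBpp`;
* a qualifying pair with at least one extra break within 10 bp of either
  end → `DSBp`;
* otherwise → `DSB`.

"Within 10 base pairs" is implemented as separation strictly below
`rule_distance` (default 10); abasic sites count as base-class (non-break)
damage, since they are excision-repair substrates rather than backbone
discontinuities. The published description does not state whether the DSB⁺⁺
window is measured between DSB centres or between their nearest breaks; we
use nearest-break separation, exposed as `dsb_pair_window` so either reading
can be enforced. The classifier is verified against an independent
brute-force enumerator over all two-lesion geometries in a 30-bp window and
thousands of random 3–5-lesion clusters.

```{r}
classify_cluster(damage_cluster(c(100, 104, 107), strand = c(1, 2, 1)))
```

## The damage-induction emulator

`generate_clusters()` mirrors the two-step structure of damage-spectrum
Monte Carlo codes — scatter damage sites over the genome, then resolve each
site into lesions — with deliberately simple sub-distributions chosen for
testability: the number of sites is Poisson with mean proportional to dose ×
genome size × oxygen factor, each site carries 1 + Poisson(`cluster_density`)
lesions placed uniformly in a 25-bp window, each lesion is an independent
strand break with probability `break_fraction` on a uniformly random strand.
It is an emulator of that class of simulation, not a port of any of them,
and it makes no claim to reproduce their per-category yields exactly.

Default calibration (chosen once, from the packaged entrance-position
spectrum, and not revisited): `lesion_yield` 616 per Gy per Gbp (the P1
total damage yield), `break_fraction` 0.32 (giving the observed ~68 % BD
share), `cluster_density` 0.05 (entrance-like sparseness), and oxygen
scaling factors 1.00 / 0.85 / 0.43 for 21 / 2 / 0.1 % O₂ taken from the
ratios of the packaged DSB yields (e.g. 6.97/8.28 and 3.54/8.28). What the
emulator reproduces, and the tests assert: dose linearity of estimated
yields, monotone yield loss with falling oxygen, growing complex-damage
share (and DSB⁺/DSB ratio) with `cluster_density`, and a total damage yield
within 10 % of the packaged P1 total at ≥ 10⁵ sites. What it does *not*
emulate: track structure, energy spectra, chromatin geometry, or sequence
context — so agreement of downstream endpoints on synthetic spectra
demonstrates internal consistency of the pipeline, not fidelity to real
proton dosimetry.

## Excision repair and enzymatic DSBs

The conversion yield is the multiplicity-weighted sum
\[
\mathrm{DSB}_{\mathrm{enz}} = \sum_i p_i\,Y_i ,
\]
with \(Y_i\) the yield of non-DSB clusters of \(i\) lesions and \(p_i\) the
per-cluster conversion probability. The published outcome tables give only
per-pathway averages, so *table mode* applies a uniform \(p_i\) — a stated
limitation. The "maximum conversion" bookkeeping multiplies the total
non-DSB damage by the long-patch-BER DSB-formation probability; with the
printed inputs at P6 this gives \((511-12.4)\times 0.019 = 9.47\) per Gy per
Gbp against a printed 9.66, which implies an unrounded probability of about
0.0194 — a discrepancy we document rather than resolve. RBE for enzymatic
DSB always uses the printed conversion yields against the 6.00 per Gy per
Gbp cobalt-60 reference.

*Simulation mode* (`simulate_repair()`) samples a per-cluster outcome —
correct repair, mutation, or enzymatic DSB — from an explicit decision tree
using the published simulation inputs: inhibition distance 8 bp, first-strand
choice probability 0.5, polymerase errors 10⁻⁴ (short-patch BER) and 10⁻⁶
(long-patch BER and NER), misinsertion probability 0.75 opposite a damaged
or lost base. The tree itself is this package's design, since the original
simulation's internals are published elsewhere; the frozen choices are:

* base-class lesions are excised before pre-existing nicks are ligated
  (glycosylase/AP-endonuclease action precedes the pathway's final ligation
  step), so a nick opposite a base lesion within the inhibition distance
  *always* converts;
* within each class, the starting strand is Bernoulli(0.5) when both strands
  carry damage, then position order;
* misinsertion applies when the template opposite the resynthesis patch
  carries an unrepaired base-class lesion, with pathway patch windows of
  1 bp (short-patch BER), 8 bp (long-patch BER) and 30 bp (NER, the excised
  oligonucleotide span);
* NER pathways incise at dual sites flanking the lesion, modelled as an
  extra `ner_span` (default 20 bp) of incision reach — this is what makes
  the NER pathways' DSB-formation probability exceed short-patch BER's, as
  the published outcome tables show (0.038–0.072 vs 0.008–0.016).

Each replicate consumes a fixed number of random draws (one order draw plus
one per lesion), so the conversion probability is *pathwise* monotone in the
inhibition distance at a fixed seed — a property the tests assert exactly.
Sampled frequencies are checked against exact enumeration of the decision
tree inside three-sigma binomial bands at 10⁵ replicates per geometry.

## The RMF model

With \(\Sigma\) the DSB yield per cell per Gy (per-Gbp yields × 6 Gbp per
cell), \(f_R\) the fraction of initial DSBs that are potentially rejoinable,
and \(\bar z_F = 0.204\,\mathrm{LET}/d^2\) the frequency-mean specific
energy of a spherical nucleus of diameter \(d = 8\) µm:

\[
\alpha = \bigl[1 - f_R(1-\theta)\bigr]\,\Sigma
       + \kappa\,\bar z_F\,(f_R\Sigma)^2 , \qquad
\beta = \tfrac{\kappa}{2}\,(f_R\Sigma)^2 ,
\]

and \(S = e^{-(\alpha D + \beta D^2)}\). The α expression deserves a note:
its source typography is corrupted, and the form above is adopted because it
(a) reduces to the classic RMF form \(\theta\Sigma + \kappa\bar z_F\Sigma^2\)
at \(f_R = 1\) and (b) makes unrejoinable DSBs lethal at first order, which
is the stated role of the rejoining cutoff. The classic form remains
available via `lq_alpha(..., form = "rmf")`.

\(f_R\) is the fraction of DSBs with lesion multiplicity below the cutoff
\(j\): \(f_R = \Sigma^{-1}\sum_{i=2}^{j-1}\Sigma_i\). The packaged parameter
sets are θ = 5.79×10⁻³, κ = 5.59×10⁻⁵ with j = 9 at 21 % O₂ and j = 8 at
2 % O₂, and θ = 4.1×10⁻³, κ = 3×10⁻⁵ with j = 7 at 0.1 % O₂. The published
tables do not include the multiplicity distributions \(\Sigma_i\), so
\(f_R\) cannot be recomputed from shipped data; we default it to 0.99 at
21 %/2 % O₂ and 0.98 at 0.1 % O₂ — the stated 0.98–0.99 range of rejoined
fractions, with the lower value assigned to the condition with the stricter
cutoff — and every entry point accepts an override
(`pipeline_config(f_R = ...)`, `rmf_lq_coefficients(f_R = ...)`).

## Endpoints

DSB induction is linear in dose, so RBE at that endpoint is the yield ratio
\(\Sigma_P/\Sigma_\gamma\) against the cobalt-60 reference (LET 2.4 keV/µm;
yields 8.14 / 6.85 / 3.48 per Gy per Gbp at 21 / 2 / 0.1 % O₂). Survival RBE
is reported in two labelled modes, because both conventions are in use: at a
fixed test dose of 1 Gy (`rbe_survival()`), and at the isoeffect survival
level of 10 % (`rbe_survival_iso()`). The OER is the dose ratio
\(D_h/D_a\) at matched survival, each dose the unique non-negative root of
\(\alpha D + \beta D^2 = -\ln S\); the other quadratic root is negative
whenever α, β > 0, and the β → 0 linear limit is handled explicitly. The
closed-form survival RBE is verified against a numeric isoeffect
root-finding oracle to 10⁻⁹ relative on 10⁴ random coefficient/dose draws,
plus its analytic dose limits \(\alpha_P/\alpha_\gamma\) (D → 0) and
\(\sqrt{\beta_P/\beta_\gamma}\) (D → ∞).

```{r}
report <- run_report(pipeline_config())
subset(report$oer, select = c(position, let_kev_um, oer_survival, oer_dsb))
```

## Numerical conventions and degenerate inputs

* Printed-table comparisons round the computed value to the table's printed
  precision (3 significant figures; 2 decimals for the enzymatic-RBE
  column) and require agreement within one unit in the last printed digit —
  the closest agreement 3-digit inputs can support.
* The validator (`validate_fixtures()`) re-derives every in-table identity.
  One cell genuinely fails: the entrance-position simple-DSB categories sum
  to 8.297 per Gy per Gbp while the printed total is 8.28, a gap beyond the
  worst-case rounding of the inputs. The printed totals are authoritative
  downstream (they, not the category sums, carry the RBE columns).
* Degenerate synthetic draws with zero DSB yield produce NA survival
  endpoints rather than errors; zero-dose runs return empty cluster lists;
  dose-for-survival at S = 1 is 0.
* All stochastic operations take explicit seeds and are deterministic given
  one; nothing relies on ambient RNG state (`withr::with_seed` scoping).

## Known limitations

* Survival-level RBE and OER magnitudes depend on \(f_R\) inputs that the
  published tables do not contain. With the default \(f_R\), the pipeline's
  survival OER declines along the track (about 1.76 at the entrance to 1.67
  at the distal Bragg peak at 10 % survival) — the *trend* is the validated
  claim, not the published absolute values (3.0 → 2.5), which require the
  unpublished multiplicity distributions. The P1→P2 OER step is flat to
  within rounding of the 3-digit yields (the hypoxic/aerobic yield ratio
  inverts in its fourth digit between those depths), so monotonicity is
  asserted strictly from P2 onward.
* The OER for DSB induction computed from the packaged yields is ≈ 2.19–2.34,
  while the source narrative quotes 2.85–2.64; the narrative figure is not
  derivable from the printed yields (possibly an anoxic rather than 0.1 %
  reference) and we report the yield-ratio value.
* Table mode applies one conversion probability across all cluster
  multiplicities; multiplicity-resolved probabilities can be supplied to
  `enzymatic_dsb_yield()` when available.
* The emulators are calibrated at the entrance position; positions P2–P6
  are represented by their printed yields, not by re-simulation.

## Problem sizes used by the test suite

The suite's Monte Carlo checks use: 10⁵ replicates per two-lesion repair
geometry (about 30 geometries), 10⁴ random draws for the survival-RBE oracle
equivalence, roughly 10⁵ damage sites for the generator calibration and
complexity checks, and exhaustive two-lesion classification over a 30-bp
window plus 2 000 random larger clusters. These sizes give three-sigma
binomial resolution on probabilities down to 10⁻⁴ while keeping the full
suite in the low minutes on one core.
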