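---
title: "Methods: descriptor profiling, CNS scoring and SAR triage for BPA libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptor profiling, CNS scoring and SAR triage for BPA libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpatriage)
```

## The problem this package addresses

Benzylphenoxyacetamide (BPA) compounds are a family of fenofibrate-derived
amides explored as anti-glioblastoma candidates. A glioblastoma drug has to
do two hard things at once: kill tumor cells at low micromolar
concentrations, and reach the tumor across the blood–brain barrier (BBB).
This package implements the computational half of that triage: it computes
physicochemical descriptor panels from structure, scores CNS penetrability,
applies property thresholds, relates structure modifications to measured
cell-viability (CV) data region by region, and characterizes dose–response.
A synthetic-library generator with a planted activity rule makes every stage
testable end to end with known ground truth.

The compound series is organized around four modification regions of the BPA
skeleton: (A) the halogen on the distal benzoyl ring, (B) the linker between
the two aromatic rings (carbonyl, methylene, ether, or a reduced ring), (C)
the alpha-carbon substitution (gem-dimethyl, monomethyl, unsubstituted), and
(D) the amide moiety.

## Structure handling

Structures enter as SMILES. The package carries its own perception layer
(`parse_structure()`): an atom/bond graph with formal charges, aromatic
flags, implicit-hydrogen counts and ring membership, with parse errors that
point at the offending token position. Aromaticity is taken from the input
(aromatic SMILES), not re-perceived from kekulized forms; all packaged and
enumerated structures are written in aromatic form. Canonicalization is
delegated to Open Babel (via ChemmineOB), which the enumerator uses to
deduplicate and to give deterministic output ordering (ties broken by
lexicographic SMILES).

Salts are handled by the parent-fragment convention: descriptors and scores
are computed on the largest fragment with counterions stripped, and formal
charge on the parent is preserved. This matters for the quaternary ammonium
member of the series (HR36): its polar surface area and logBB are those of
the cation, not the neutral salt.

## The descriptor panel

Every descriptor uses an open, published contribution scheme embedded in the
package with per-row citations in the source:

* **TPSA** — Ertl's topological N/O fragment contributions. This is the one
  descriptor the vendor tool used by the original study is known to agree
  with: the packaged PP1 and HR1 structures reproduce the printed 66.84 and
  49.77 square Angstroms exactly, which is also how the structure
  transcription itself is validated.
* **ClogP** — Wildman–Crippen atom contributions, with atom typing
  implemented as graph rules in the published table order and element-default
  fallbacks (with a warning) for untypable atoms.
* **MP** (molecular polarizability) — Miller's additive atomic-hybrid
  components. Strictly additive by construction: swapping a para-Cl for a
  para-F changes the value by exactly the difference of the two atomic
  components.
* **LogS** — the ESOL linear model evaluated in log10(mol/L) and shifted by
  log10(MW) to report log10(mg/mL), matching the unit used in the series'
  property tables.
* **HBD/HBA at pH 7** — donors are N–H/O–H hydrogens, acceptors are N/O
  atoms bearing a lone pair excluding amide N, pyrrole-type aromatic N and
  positively charged N. Counts are taken on a pH-adjusted microspecies: a
  basic center whose lookup pKa exceeds the pH is protonated (one more
  donor, one fewer acceptor). This is the simplest defensible reading of
  "donors/acceptors at pH 7".
* **pKa** — a configurable functional-group lookup (primary/secondary/
  tertiary aliphatic amine 10.6/10.8/9.8, the dialkylaminoethyl-amide side
  chain 9.5, amide-substituted piperazine 7.8, aniline 4.6; amide N
  non-basic). No per-molecule pKa engine is assumed. A quaternary N+ returns
  the permanent-cation sentinel (`Inf` internally, printed as
  `permanent_cation`).
* **ClogD at pH 7.4** — the monoprotic closed form
  `clogd = clogp - log10(1 + 10^(pKa - pH))`; equal to ClogP when no basic
  center exists; a permanent cation takes a capped 4-log-unit penalty, which
  keeps the permanently charged series member scored as strongly
  hydrophilic.

Vendor-computed ClogP/LogS/pKa values printed in the original tables are
**not** expected to be reproduced bit-for-bit (those models are
proprietary); they are packaged as reference inputs
(`reference_values()`) and used as inputs where the original arithmetic is
scheme-independent — notably the logBB worked case below.

## Conformers and minimal projection area

MPA (minimal projection area) needs 3D coordinates. The package builds them
with a deterministic distance-geometry embedding: bonded atoms are pulled to
reference lengths (covalent-radius sums scaled by bond order), geminal pairs
to law-of-cosines distances for ideal angles (109.47/120/180 degrees by
hybridization), and non-bonded pairs are repelled below a fraction of their
van der Waals contact distance; the objective is minimized with L-BFGS-B
from a breadth-first initial layout whose tie-breaks and jitter derive from
the seed. Determinism — identical coordinates for identical (molecule,
seed) — is a hard requirement here, and the resulting geometries satisfy two
checked invariants: bonded distances within 15% of reference, and no
non-bonded pair closer than 0.7 times the sum of van der Waals radii. These
are triage-quality geometries, not force-field-minimized ensembles; MPA is
the only consumer.

MPA itself is the minimum, over viewing directions, of the area of the
union of projected atom discs (Bondi radii). Areas are computed on a 2D
raster with 0.1 Angstrom spacing; the orientation search is a 10-degree
coarse grid over the hemisphere followed by two local refinement levels
(down to 2.5 degrees). In testing, the refined search consistently matches
or beats a 1000-orientation random-sampling oracle, so the reported value is
a slightly tighter minimum than naive sampling would give. The exact MPA
algorithm behind the original tables is unpublished; only the
"MPA over 70 square Angstroms transports poorly" criterion semantics are
reproduced.

## CNS-MPO and logBB

The CNS-MPO score sums six desirability transforms (clogP, clogD, MW, TPSA,
HBD, pKa) on a 0–6 scale. The six properties and the scale are fixed by the
method; the breakpoint values are not printed in the study and therefore
live in a YAML config (`cns_config()`), defaulting to the published CNS-MPO
definition: clogp monotone (3, 5); clogd (2, 4); MW (360, 500); TPSA hump
(20, 40, 90, 120); HBD (0.5, 3.5); pKa (8, 10). "Weighted scoring" is read
as the desirability weighting itself — the components sum unweighted, which
is the cited method's standard form. Two conventions close the gaps the
method leaves open: no basic center scores pKa desirability 1.0, and a
permanent cation scores 0.0.

BBB penetration is estimated by the linear model
`logBB = 0.152 ClogP - 0.0148 PSA + 0.139`, with classes: readily crossing
above 0.3, poor below -1.0, intermediate between. The worked HR36 case uses
the printed ClogP (-0.31) with the module-computed cation PSA (46.61) and
lands on -0.6 at one decimal — the intermediate class, consistent with a
permanently charged, inactive-at-25-uM compound. For display the package
rounds logBB to one decimal and MPO to two, matching the precision of the
original tables.

Triage (`apply_triage()`, `triage_library()`) turns the panel into
pass/fail flags — MPO >= 4, MPA <= 70, LogS >= -4.5, MP in 30–40, ClogP in
2–5 — and ranks by criteria passed, ties broken by MPO, then logBB, then id.
The original study's final lead set mixed these numbers with judgment; the
package exposes the ranked table rather than asserting a selection.

## SAR: flags, matched pairs, rule induction, dose–response

`substructure_flags()` derives the candidate pharmacophore features from
structure alone: the benzophenone carbonyl linker (diaryl ketone), a
chlorine para to the ring attachment point, the alpha-methyl count, the
amide nitrogen class (primary/secondary/tertiary, or ester/acid), and a
permanently charged quaternary nitrogen. `matched_pairs()` lists compound
pairs identical in three regions and differing in the fourth — the region
scheme's unit of evidence — with their viability deltas.

Activity is called at 50% of control at 25 uM. The threshold is a design
choice: the series' described actives sit at CV 0.17–43% and its inactives
at 58–98%, so 50 separates them cleanly. Rule induction is deliberately not
a regression: with ~50–60 compounds and strongly correlated flags, the
package computes per-feature necessity P(flag | active) and sufficiency gap
P(active | flag) − P(active | ¬flag), and requires necessity >= 0.9 with a
positive gap. The amide class is handled ordinally (tertiary > secondary >
primary), reporting the highest qualifying level. A feature with no negative
examples in the data cannot be contradicted and keeps its gap defined as
P(active | flag).

On the packaged fixture (the compounds whose structures and 25-uM CVs are
transcribable from the study's text), induction recovers the carbonyl linker
and the gem-dimethyl requirement. It does **not** recover the 4'-chloro
requirement from this subset: the fluoro analog HR9 (CV 35.55%) is itself
active under the 50% threshold and is the only non-chloro compound with a
transcribed CV, capping para-chloro necessity at 2/3. That is the same
halogen exception the series' own comparison dwells on, and the tests pin
this number rather than forcing the flag.

Dose–response uses a four-parameter logistic with the top fixed at 100%
(vehicle control defines 100) and the bottom at 0 — four printed points
cannot support four free parameters. Fitting is least squares in
(log IC50, log Hill) with multi-start initialization over a geometric IC50
grid and several Hill slopes; exact duplicate records are collapsed first,
which also makes the fit invariant to duplicated rows. The fit is
scale-equivariant in concentration by construction. The printed PP1 series
(98.36 / 70.03 / 43.67 / 1.04 at 1 / 5 / 10 / 25 uM) fits to IC50 ~8.1 uM,
inside the "around 10 uM" band reported for the leads.

## The synthetic-data generator

`generate_virtual_library()` emulates the study's design space: a region
grid around the BPA scaffold, a planted pharmacophore rule (default:
carbonyl linker + para-chloro + gem-dimethyl + tertiary amide), and a
bimodal viability response — active mean 5% of control, inactive mean 92% at
25 uM — with Gaussian noise of SD 4 percentage points, matching the
magnitude of the replicate SDs printed for this assay (roughly 2–8 points).
Viability is clamped to [0, 110] so slightly super-control values remain
possible, as they do in the real data. Sampling is without replacement from
the enumeration, so region tags stay exactly balanced when the whole grid is
taken; the default grid (2 x 2 x 2 x 8 = 64 variants, n = 60) keeps a
handful of rule-satisfying actives in every draw.

What the generator does *not* emulate: correlated noise between
concentrations, plate effects, solubility-driven artifacts, or any coupling
between the descriptor panel and the viability response beyond the planted
rule. Passing the recovery tests therefore shows the induction machinery is
sound under the stated noise model — not that the rule criteria would
survive every pathology of real screening data.

`generate_descriptor_table()` draws panels uniformly from the observed
descriptor ranges of the series (clogp -0.5..5.5, psa 40..120, hbd 0..3, mw
250..500, mp 25..45, logs -6..1, mpa 35..80, pKa absent or 7..10.5) and is
used for the property sweeps (MPO bounded in [0, 6], per-component
monotonicity).

## Numerical choices and problem sizes

* TPSA is reported rounded to two decimals (the precision of the printed
  values it reproduces); all other descriptors are unrounded.
* The embedding retries up to 5 re-jittered starts before raising an error;
  molecules above 200 atoms (with hydrogens) are rejected.
* The MPA raster (0.1 A) contributes under ~1% area error for molecules of
  this size; rotation invariance is tested at a 2% tolerance.
* The 4PL optimizer uses Nelder-Mead with a tight relative tolerance and 25
  starts; `converged` additionally requires a finite IC50 below 100 times
  the top concentration.
* Test problem sizes were chosen to exercise the statistics while keeping
  the default suite a few minutes long: rule-induction checks run 10 seeds
  at n = 60, noise-degradation checks 8 seeds per noise level, the MPA
  oracle 10 conformers x 1000 random orientations, and the MPO sweep 1000
  panels.

## Known limitations

* ClogP/LogS/pKa are open-scheme estimates; agreement with the vendor values
  printed in the original tables is neither expected nor required, and the
  pKa lookup is a coarse functional-group table.
* Aromaticity is trusted from the input SMILES; kekulized input without
  lowercase aromatic atoms will be treated as non-aromatic.
* Conformers are single, deterministic triage geometries, not ensembles;
  MPA inherits that approximation.
* The fixture covers only the compounds nameable from the study's text;
  compounds drawn only in figure artwork are excluded (listed in the fixture
  header), so fixture-level SAR statements rest on a small n.
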