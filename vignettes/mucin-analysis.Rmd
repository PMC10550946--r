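---
title: "Mucin-domain glycoproteomics, polymer metrics and dissociation kinetics with mucintools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mucin-domain glycoproteomics, polymer metrics and dissociation kinetics with mucintools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucintools)
```

# The problem

Mucin domains resist conventional proteomics: trypsin cannot access their
densely O-glycosylated Ser/Thr stretches, search engines struggle with the
combinatorial explosion of glycoforms, and the glycans themselves change the
physical behavior of the polypeptide — a heavily glycosylated mucin domain is
a stiff, extended bottle-brush, a sparsely glycosylated one collapses.
`mucintools` packages three layers of analysis that together characterize a
mucin-domain glycoprotein: (i) validation, localization and quantitation of
O-glycopeptides produced by O-glycoproteases (mucinases) such as SmE, ImpA,
OgpA and StcE; (ii) polymer metrics (persistence length, bending angle,
height per glycan) on coordinate trajectories of the glycosylated domain;
and (iii) dissociation-rate estimation from SPR sensorgrams. A seeded
synthetic-data layer generates every input with planted ground truth, so
every procedure is testable end to end.

# Glycan compositions

Glycans are represented as monosaccharide count vectors over HexNAc (N),
hexose (H), NeuAc (A) and fucose (F) — composition only, no linkage or
topology. Masses are residue (dehydrated) monoisotopic masses computed from
the elemental formulas HexNAc C8H13NO5 (203.0794 Da), Hex C6H10O5
(162.0528 Da), NeuAc C11H17NO8 (291.0954 Da) and dHex C6H10O4 (146.0579 Da),
so composition mass is exactly additive. Sialic-acid linkage ambiguity is
deliberately not modeled.

`enumerateCompositions()` supports de novo assignment: the difference between
a precursor's neutral mass and a naked peptide mass is matched against all
bounded count vectors (defaults N≤6, H≤6, A≤4, F≤3, ±0.02 Da), which covers
every structure in the bundled 12-composition database. The database itself
is a package choice of twelve common Tn/core 1/core 2 species; it is a
plain-text table (`inst/extdata/default_glycans.csv`) and fully replaceable.

Core categories follow a fixed map: Tn is a single HexNAc with no hexose and
at most one NeuAc **or** one fucose (so sialyl-Tn and fucosyl-Tn count as
Tn); core 1 is one HexNAc with hexose; core 2 is two or more HexNAc with
hexose; everything else — notably bare N2 — is "other". The membership of
sialyl-Tn and fucosyl-Tn is not dictated by the underlying biology of the
category names; the map above is the package's choice, is stated in the
`classifyCore()` documentation, and reproduces the category assignments
implied by the multi-site decomposition triples (N2 → two Tn, H2N2 → two
core 1, H2N2A4 → two disialyl core 1).

# Spectra and fragments

b/y ions are generated glycan-free (the HCD convention — O-glycans are
labile), c/z ions glycan-retaining, with z ions modeled as z-dot radicals
(neutral mass = residue sum + 1.9918 Da, i.e. H2O − NH2); the proton mass is
1.007276 Da and fragment charges run 1..(precursor charge − 1). Y0, the
intact peptide stripped of all glycans, is generated at every precursor
charge. Carbamidomethyl Cys is fixed; oxidized Met is variable. Peak matching
is greedy nearest-m/z within a ppm tolerance (20 ppm MS2, 10 ppm MS1
defaults); when several theoretical ions claim one observed peak all matches
are kept and flagged ambiguous rather than arbitrated.

The product-dependent ETD trigger is implemented verbatim: at least 3 of the
8 HexNAc/NeuAc oxonium fingerprints (126.055, 138.055, 144.07, 168.065,
186.076, 204.086, 274.092, 292.103 m/z — the mixed printed precision is kept
as printed) within ±0.1 m/z at more than 5% of the base peak, with precursor
m/z in [300, 1500] and charge 2–6. "Relative intensity" is taken relative to
the most intense peak of the spectrum.

# The validation rulebook

Acceptance requires two necessary rules, in order:

1. **Naked peptide.** A peak at Y0 at any charge up to the precursor charge.
   When the peptide carries oxidized Met, Y0 minus the side-chain loss CH4SO
   (63.9983 Da) also counts.
2. **Backbone coverage.** For peptides of ≤12 residues, at least 80% of
   backbone bonds covered by any matched b/y ion ("nearly full coverage" is
   not quantified by the method description; 80%/12 are package defaults and
   configurable). For longer peptides, every expected-abundant bond — the
   bond N-terminal to each Pro and C-terminal to each Asp — must be covered;
   a C-terminal Pro's final bond is satisfied by b(n−1) alone.

Localization only affects per-site status, never acceptance. All arrangements
of the glycan multiset over candidate Ser/Thr sites are enumerated and tested
against every matched c/z ion (c/z evidence outranks b/y and is the only
evidence used); a site is localized when all surviving arrangements agree on
its glycan, contradicted when no arrangement survives — including the case
where a glycan-free c/z fragment is observed across a site every arrangement
must glycosylate. The enumeration replaces the human judgment of "sufficient
c/z ions" with an exact criterion, and a brute-force arrangement oracle in
the test suite confirms it for peptides of up to 8 residues. When HCD and ETD
evidence conflict, the site is reported "contradicted"; the package does not
guess.

When two or more glycan-bearing sites remain unresolved, the 138/144 oxonium
ratio gates the core-1 decomposition: if the ratio is strictly under 1.2 and
no 407 m/z di-HexNAc oxonium is present, a total composition divisible into
equal core-1-or-smaller parts (N2, H2N2, H2N2A4, ...) is assigned as one part
per unresolved site. The site status stays "unlocalized"; only the working
glycan assignment is updated, and the decision records that the rule fired.

Identification transfer to weaker spectra uses the cosine similarity over the
strong spectrum's matched backbone channels with a default threshold of 0.7
(a package choice; the method description gives no number).

# Quantitation

XIC areas are trapezoidal integrals. Isotopes follow the mass-dependent rule
— only the monoisotopic peak under 1600 Da, two isotopes up to 2400 Da
(inclusive; "under"/"over" are read strictly, "up to" inclusively), three
above — spaced 1.00335/z, summed over all observed charge states. Site tables
sum all peptides carrying a (site, glycan) pair and normalize within the
site; the most abundant glycan per site is chosen category-first (summed area
per category, then the top glycan within the winning category), with exact
ties broken deterministically by the fixed category order Tn < core1 <
core2 < other and then the canonical composition string.

# Cleavage landscape

Coordinates are 1-based; a cleavage event is recorded at its P1' residue
index. Peptide N-terminal boundaries are events unless at the protein
N-terminus; C-terminal boundaries are events when the next residue starts
another observed peptide or is Ser/Thr; boundaries following Lys/Arg are
excluded when trypsin was part of the digestion. Ambiguously mapped peptides
are flagged and excluded from counting. Implied glycosites are Ser/Thr at the
P1' of observed cleavages that were never localized. Mapped structures are
distinct (protein, site, glycan) pairs; unique glycoforms are distinct
(peptide, glycan multiset, localization pattern) triples — unlocalized
variants of one composition collapse to a single glycoform, a definitional
choice recorded here because the counting definitions do not settle it.
Motif windows span ±5 residues around the scissile bond (P5..P1, P1'..P5'),
gap-padded at termini; the position frequency matrix columns each sum to 1
and export cleanly to sequence-logo tools.

# Polymer metrics

The mucin polymer is the ordered N, CA, C backbone chain of a residue range.
The bond autocorrelation C(n) is the average cosine between bond vectors n
steps apart, over positions and frames; the persistence length comes from a
least-squares fit of log C(n) = −n·lb/lp through the origin, over lags from 1
up to the first lag where C(n) < e⁻² (or half the chain), restricted to
C(n) > 0 — the fit range is a package choice since the estimator is usually
delegated to polymer libraries without stating one. A chain with no
measurable decorrelation is flagged infinite rather than given a number.
Replicas are fitted separately and reported as mean ± SD, with the replica
count recorded. The default analysis window is the final 1000 frames.

Centers of mass are mass-weighted, with element masses inferred from atom
names when a topology does not provide them. The normalized end-to-end
distance divides the anchor-to-anchor distance by the number of mucin-domain
residues (Å per residue). The bending angle is measured at the middle anchor
between vectors to the first and last anchors, in [0°, 180°]; frames with a
degenerate zero-length vector yield NA rather than an arbitrary angle.
Height per glycan — "total glycosylation" in the outstretched starting frame,
"effective glycosylation" averaged over the final frame window — divides the
backbone end-to-end length of the mucin residue range by the glycan count.
End-to-end (not contour) length is used; for an outstretched starting
structure the two coincide, and end-to-end is what shrinks upon relaxation,
which is the quantity of interest. All metrics are invariant under rigid
transforms of the coordinates, and the tests verify this with random
rotations and translations.

# Dissociation kinetics

Sensorgram dissociation phases are fit to Y = (Y0 − NS)·exp(−K·X) + NS by
unweighted nonlinear least squares (Levenberg–Marquardt), initialized at
Y0 = first response, NS = last response, K = 3/span, with K bounded positive.
A fit is flagged non-converged when the optimizer fails, the amplitude
Y0 − NS is not positive, or the fitted decay is negligible over the observed
window (K·span ≤ 10⁻³) — constant or rising responses therefore never
produce a rate. Replicates are fit individually and summarized as mean ± SD
(n = 1 is flagged and given SD 0), matching the convention of reporting koff
over independent experiments rather than pooling points.

# Synthetic data: what it emulates and what it does not

Generators are pure functions of (seed, parameters). The glycoprotein
generator plants a Ser/Thr/Pro-rich mucin region (default residues at
T/S/P/A/G/V frequencies 0.25/0.25/0.20/0.15/0.10/0.05, a realistic mucin
composition) and glycosylates each mucin-region Ser/Thr with probability 0.6,
drawing glycans from a default mix of 30% Tn, 30% core 1, 20% sialyl core 1,
10% sialyl-Tn and 10% extended core 2 — chosen once as a plausible
site-specific heterogeneity profile. These densities give adjacent
glycosylated pairs in ~40–55% of glycosites, the substrate feature that
separates SmE from ImpA.

Enzyme rules encode the reported specificities: SmE cleaves N-terminal to any
glycosylated Ser/Thr and tolerates glycosylated P1; ImpA requires
unglycosylated P1; OgpA is blocked by NeuAc on the P1' glycan (sialidase
co-treatment is simulated by stripping A counts); StcE requires T/S*-X-T/S
with the scissile bond placed before X by default (the exact scissile
position within the motif is configurable because it is not pinned down by
the motif notation alone). ImpA's reported P1 amino-acid preferences are
noted but not parameterized beyond the glycan policy.

The run generator emits HCD spectra whose oxonium content follows the glycans
(NeuAc fingerprints only when sialylated; the 407 m/z ion and an elevated
138/144 ratio only when one glycan carries ≥2 HexNAc), b/y ions with
configurable per-ion dropout (default 0.1, a typical fragment-detection
efficiency), Y0 at all charges, and EThcD scans only when the synthetic HCD
actually fires the trigger; MS1 traces are Gaussian elution peaks (σ =
0.2 min) with a geometric isotope envelope. The generator does **not**
emulate chimeric spectra, co-isolation, retention-time drift, realistic
isotope fine structure or decoy-aware FDR — so the planted-truth recovery
rates demonstrate the correctness and determinism of the rulebook under
controlled noise, not search-engine performance on real instrument data.

The worm-like-chain generator draws successive bond deflections with mean
cosine exp(−lb/lp) (deflection density ∝ exp(κ·cosθ) with κ solved from the
Langevin function), making C(n) = exp(−n·lb/lp) exact in expectation — an
analytic oracle for the persistence-length estimator. Frames are independent,
unlike genuine MD frames, which are autocorrelated in time; recovery within
15% on these ensembles therefore validates the estimator, not MD convergence.

# Problem sizes and numerical choices

The shipped tests and the benchmark script use 20 synthetic glycoproteins of
200 residues for the enzyme contrast, ~120 glycopeptides plus as many
shuffled decoys for validation recovery, 1000 random residual masses for the
enumeration oracle, 1575 gate combinations for the trigger truth table,
worm-like chains of 200 monomers × 400 frames at planted persistence lengths
of 20/100/400 Å, and 200 simulated sensorgrams with SNR 20 and rates in
0.01–0.5 s⁻¹ — sizes chosen so the whole suite runs in about a minute on one
CPU while keeping the recovery statistics stable across seeds. Degenerate
inputs are handled explicitly: empty compositions are legal everywhere except
core classification, a composition that does not divide by the site count is
kept single with a warning, spectra with no peaks never trigger, inverted RT
windows and non-positive masses are errors, and missing residues in a
trajectory are reported by name.

# Known limitations

Compositions only — no glycan topology, linkage or N-glycan support beyond
what the generators need. No FDR estimation or search-engine scoring: the
validation engine assumes candidate identifications already exist. No
match-between-runs or cross-run normalization in quantitation. The polymer
metrics assume a constant atom set across frames and do not model periodic
boundary wrapping. The SPR module fits dissociation only — no association
phase, equilibrium affinity or bulk-refractive-index correction.
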