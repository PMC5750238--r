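---
title: "Models and methods behind the apta-FRET pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the apta-FRET pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptafret)
```

This vignette explains the models and procedures the package
implements, the parameters that matter, and the choices made where the
design was genuinely open.

## The system

An apta-FRET construct is a single-stranded RNA origami tile of the
2H-AE family — two parallel double helices joined by two antiparallel
even (AE) crossovers — carrying two fluorogenic aptamers: a donor
(Spinach or its in-vivo-optimized sibling Broccoli, lighting up
DFHBI-1T) and the acceptor Mango (lighting up YO3-biotin). An internal
180° kissing loop (KL) between the crossovers both closes the strand
topology and stabilizes the tile; replacing the KL's bulged adenines
with a toehold hairpin ("branched KL") turns the tile into a
strand-displacement switch, and inserting a SAM riboswitch turns it
into a small-molecule sensor. Because donor and acceptor are placed by
the scaffold with base-pair precision, the ratio of sensitized acceptor
emission to donor emission is a conformational readout.

## Blueprint compilation

The original 2D design files for these tiles were hand-made and are not
published, so the blueprint dialect here is package-defined
(line-oriented `HELIX` / `XOVER` / `MOTIF` / `END5` records), scoped
deliberately to the two-helix, two-crossover family.

**Strand tracing.** Both helices are drawn with their top strand
running 5'→3' left to right. At a crossover at column $x$ the helix-1
bottom strand and the helix-2 top strand exchange between columns $x$
and $x+1$ with a reversal of travel direction — the U-turn
characteristic of an antiparallel crossover. Cap motifs (tetraloops,
aptamer cores) join the two strands at a helix end; a kissing loop cuts
its helix between two columns and closes each arm with a hairpin loop.
With the KL between the two crossovers this connectivity yields a
single closed walk visiting every residue exactly once; remove the KL
motif and the inter-crossover region closes on itself as a second
cycle, which the tracer reports as a disconnected strand. The construct
"without a kissing loop" used as a control is therefore modelled the
way it is built chemically: the hairpins stay, only the loop–loop pairs
are dropped (`kissing = FALSE` in `build_structure()`).

**Secondary structure.** Duplex partners and motif-internal stems go on
the nested tier (round brackets); KL loop–loop pairs go on the
pseudoknot tier (square brackets). The pair table is validated as an
involution and each tier is re-parsed with a stack to guarantee
tier-wise nesting.

**Constraints.** Four rules populate the per-position constraint string
(`A C G U` fixed, `N` designable, `W` a designated GU wobble pair):

1. conserved motif bases verbatim;
2. the first six traced positions fixed to `GGGAGA`, the efficient T7
   initiation sequence, with tier-1 partners forced complementary;
3. a G-C "lock" on the base pair at column $x+1$ of each helix at each
   crossover — one pair per helix per crossover, orientation
   alternating G-C / C-G along the trace to avoid G runs (how many
   pairs "locking" fixes, and in which orientation, is unstated in the
   field's descriptions; one pair with alternating orientation is this
   package's choice);
4. within every maximal continuous duplex segment (bounded by helix
   ends, crossovers and KL cuts), a GU wobble pair is designated every
   eighth pair counting from the segment's low-column end. When the
   eighth slot is already fixed, the designation shifts left to the
   nearest designable pair in the window; a window fixed end to end
   yields a warning record rather than an altered conserved base. The
   net guarantee — no more than eight consecutive canonical pairs —
   is what matters for cotranscriptional refolding kinetics, and is
   what the tests assert.

Conflicts between rules (e.g. an initiation base landing on a lock) are
reported as errors, never silently overridden.

**Motif library.** The kissing loop is the HIV-1 DIS loop
(`AAGCGCGCA`; the self-complementary `GCGCGC` core pairs with its
partner, the flanking purines stay bulged), the terminal loop is UUCG,
and the branched KL swaps the two bulged adenines of one partner for a
5-bp toehold hairpin. The aptamer cores (Spinach, Broccoli, Mango
G-quadruplex, SAM-I riboswitch) are representative conserved cores in
the style of the published minimal aptamers: internally consistent with
their pair lists and footprints, but not authoritative sequences, since
none are packaged with a deposited structure. A "flipped" cap — the
donor attached through its other flanking helix — is realized at
blueprint level by traversing the cap fragment from its other end;
this is a 2D stand-in for the 3D operation, adequate because only
footprints, pairing topology and conserved-base placement feed the
downstream design.

## Coarse-grained geometry

The atomistic 3D models behind the published distance scans are not
rebuilt. Instead both helices are idealized as parallel axes 2.4 nm
apart, with A-form rise 0.281 nm/bp and twist 32.7°/bp. A fluorophore
whose aptamer sits at signed stem offset $k$ bp from the reference
crossover is placed at axial coordinate
$z = (k + \mathrm{sign}(k)\,e)\,\mathrm{rise}$ (positive and negative
offsets on opposite sides of the crossover) and azimuth
$k \cdot \mathrm{twist} + \phi_0$ (+180° for a flipped donor), at
radial distance 0.9 nm from its host axis. The axial extension
$e = 1.5$ bp and the 0.9 nm radial offset are calibrated once so the
model reproduces the ~18 nm fluorophore separation of the
S(-31)-M30 no-FRET control; all other predictions follow. Under this
rule equal positive offsets (the S\*5-M5 flagship) place the
fluorophores side by side across the inter-helix gap — the high-FRET
regime — and a distance scan over one stem length oscillates with the
helical period of ~11 bp superposed on the axial trend, matching the
reported pattern of FRET maxima roughly one turn apart.

The donor dipole points toward the acceptor helix axis in the normal
orientation and away from it when flipped, which is the geometric
content of the flip experiment. The acceptor dipole is genuinely
unknown (the acceptor fluorophore cannot be docked rigidly into the
Mango G-quadruplex), so it is a parameter — tangential by default,
configurable to radial, axial or any unit vector — and no claim
depends on it.

Steric clashes are flagged with the cheapest geometry that reproduces
the qualitative flags of the published scans: the acceptor aptamer as a
1.5 nm sphere at the acceptor fluorophore position versus the
donor-carrying stem as a 1.0 nm cylinder from the crossover to the
donor's axial coordinate.

`kappa_squared()`, `forster_radius()` and `fret_efficiency()` are
standard Förster theory
($\kappa^2 = (\cos\theta_T - 3\cos\theta_D\cos\theta_A)^2 \in [0,4]$,
isotropic mean 2/3; $R_0^6 = 8.79\times10^{-5}\,\kappa^2 n^{-4} Q_D J$
in Å⁶ with $J$ in M⁻¹cm⁻¹nm⁴). The mapping from model efficiency $E$ to
the measured ratiometric FRET output is deliberately not asserted: the
ratio is a proxy, and the package never converts one into the other.

## Quantification

All FRET readouts are the ratio of sensitized emission to the sum of
sensitized and donor emission, in $[0,1]$. The spectrofluorometric
correction subtracts direct acceptor excitation
($A_{dir} = I_Y(ex_D,em_Y)/I_Y(ex_Y,em_Y)$) and donor leak-through
before forming the ratio. One printed form of the donor-leak equation
is dimensionally the reciprocal of its stated few-percent value; the
package implements the leak-fraction orientation
($D_{leak} = I_D(ex_D,em_Y)/I_D(ex_D,em_D)$), which is the one
consistent with those values and with how the factor multiplies the
donor channel in the correction, and keeps the reciprocal behind a
compatibility flag rather than resolving the ambiguity silently.
Correction factors are always estimated from controls; the familiar
numbers 0.015/0.074/0.0915 are fixture defaults, never hard-coded into
the equations. A negative corrected numerator clamps to zero with an
explicit flag — "effectively zero" FRET is reported as zero, not as a
negative ratio.

Flow cytometry uses geometric means of gated events (log-normal
intensities make the geometric mean the natural location estimate;
nonpositive events, a baseline artifact, are excluded and counted),
subtracts the empty-construct background arithmetically, and applies
the same corrected ratio with the leak estimated from a donor-only
sample.

Dose–response curves are the named three-parameter model — Hill slope
fixed at 1 — fitted to background-subtracted replicate means with
equal weights by Levenberg–Marquardt least squares. Constant responses
and EC50s outside the tested span are flagged results, not exceptions.

Spectral overlap is reported both ways because "overlap" is used both
ways in practice: the Förster integral $J$ (with the donor emission
area-normalized) and the dimensionless shaded area
$\int \min(\hat f_D, \hat g_A)\,d\lambda$. Comparisons between dye
pairs use `relative_overlap()` on either metric; no absolute claim is
made about one published percentage whose underlying spectra are not
tabulated.

## Single-cell imaging

Cells are segmented from the donor channel — the channel reliably lit
in every expressing cell — by Gaussian smoothing (σ = 1 px), Otsu
thresholding and connected-component labelling with a 20–2000 px area
filter. The labelling is 4-connected (the EBImage implementation);
after smoothing the masks are solid, so the difference from
8-connectivity is immaterial for rod-shaped cells. Per-cell FRET is the
ratio of channel means, not the mean of per-pixel ratios, per the
stated order of operations; the heatmap is the per-pixel ratio inside
kept cells, `NA` outside. One analysis choice goes beyond the quoted
procedure: a per-channel background (the median intensity outside the
segmentation mask) is subtracted from the per-cell means by default,
because any nonzero camera offset biases a ratio of raw means; it can
be disabled. The bottom-5% acceptor filter discards exactly
`round(0.05 n)` cells ranked by directly excited acceptor mean,
pooled across the analysis batch (whether the original filter pooled
across images or worked per image is unstated; pooling is the default
and configurable by simply calling `select_cells()` per image).

Histograms of per-cell FRET are fitted with one- and two-component
Gaussian mixtures — the two fitted forms used for the high-FRET and
control constructs — with the component count selected by BIC. The EM
fits use mclust's deterministic hierarchical initialization, so results
are reproducible without random restarts.

## Synthetic data

Each generator emulates one instrument regime and returns its ground
truth: multiplicative Gaussian noise for cuvette reads, log-normal
event intensities for flow (with a shared per-event size factor, so
geometric means converge to medians), and Gaussian blur + Poisson
photon noise + Gaussian read noise over a constant offset for images.
Noiseless generator output is exactly inverted by the paired analysis
(corrected FRET, flow FRET, EC50 fit, segmentation means) — the
noiseless image limit therefore stays real-valued, with quantization to
integer counts applied only in the noisy regime. Rod-shaped cells are
non-overlapping capsules with per-cell FRET drawn from a Gaussian
mixture (defaults centered at 0.19, the high-FRET construct's
single-cell regime; the two-population control regime uses 0.12/0.19);
a 7.5% acceptor-dim subpopulation gives the bottom-5% filter realistic
work. What the generators do not emulate — optical point-spread
functions beyond Gaussian blur, cell motion, photobleaching, spectral
cross-talk in the microscope — bounds what passing tests show about
real data: they validate the estimators against their own forward
models, not the instruments.

## Problem sizes and numerical choices

The test suite uses desk-scale sizes chosen to keep every check sharp
but quick: 256×256 px images with 20–50 cells (200-cell batches pooled
over eight images), 50,000 flow events where convergence of geometric
means matters, 200 seeded Monte-Carlo titrations (8 doses spanning
three decades around the EC50, triplicates at 5% CV), 10⁵ orientation
triples for the isotropic κ² average, and mixture fits at n = 500.
Tolerances follow the quantity: machine-precision (≤10⁻⁹) for exact
inverse-model identities, 0.02 for 50,000-event Monte-Carlo recovery,
0.01 for mixture means at n = 500. Ties in the acceptor filter are
broken by cell label for determinism; degenerate inputs (constant
titrations, identical FRET values, zero-variance events) are flagged
results rather than errors throughout.

## Known limitations

The blueprint dialect covers only the 2H-AE family; equivalence with
the original hand-made design files cannot be asserted, only the
published design rules themselves. The geometry is coarse-grained by
construction: distances inherit the calibration to a single control
construct, clash flags are qualitative, and the acceptor dipole is a
free parameter. Aptamer core sequences in the motif library are
representative, not authoritative. The imaging pipeline assumes
co-registered channels and does not correct drift, bleaching or
deconvolution.
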