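---
title: "Minor-groove recognition workflows: AT-tract preference, homologue conservation, and tethered particle motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minor-groove recognition workflows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractpm)
library(dplyr)
```

Nucleoid-associated proteins (NAPs) that recognise the DNA minor groove —
curved-DNA-binding protein A (CbpA) of *E. coli* is the motivating example —
prefer AT-tracts, contiguous runs of A/T bases where the minor groove
narrows. Three computational workflows characterise this recognition mode,
and `tractpm` implements all three as tidy, pipeable functions:

1. **Probe-level AT-feature analysis** — from a table of microarray probes
   (sequence + ChIP binding signal), compute per-probe AT content and
   longest-AT-tract length, bin probes by feature, and locate the tract
   length with the strongest mean binding.
2. **Homologue conservation** — dereplicate a BLAST-derived protein
   alignment, build a consensus, and score conservation of individual
   reference residues (e.g. a DNA-binding arginine).
3. **Tethered particle motion (TPM)** — quality-filter bead trajectories by
   scatter eccentricity, compute windowed RMS excursion, and separate bound
   from unbound tether populations; a Monte-Carlo simulator of the
   DNA–bead tether generates realistic trajectories.

Because the original datasets behind such studies (genome-wide probe maps,
500-homologue alignments, raw bead tracks) are typically not deposited, the
package ships seeded generators that plant known structure, so every
analysis stage is testable end to end.

## Probe AT features and binning

`probe_features()` adds two statistics per probe. The AT fraction is
`(#A + #T) / (#A + #C + #G + #T)`: ambiguity codes (N etc.) are excluded
from numerator *and* denominator, a conservative choice that avoids
counting unknown bases either way. The longest AT run is the longest
substring of A/T only; N breaks a run, since an unknown base cannot be
assumed to continue a tract. Both are case-insensitive and invariant under
reverse complement (A↔T, C↔G), which the test suite asserts.

`bin_signal()` assigns every probe to exactly one bin and averages the
signal. Two schemes are provided, both explicit design choices where the
convention is not standardised:

* `at_fraction`: half-open 5-percentage-point bins `[0, 0.05), …` with the
  final bin closed at 1 — fine enough to resolve composition trends, coarse
  enough that bins stay populated at a few thousand probes. Custom `edges`
  are accepted; values outside them land in an explicit `"out of range"`
  bin rather than being dropped.
* `longest_at_run`: one bin per integer run length with a single
  open-ended bin `>=K` (default `max_run = 12`) pooling the sparse
  long-tract tail, where per-integer means would otherwise rest on a
  handful of probes.

`optimum_bin()` is an argmax over non-empty bins with ties broken toward
the lower label, so repeated runs give one deterministic answer. The grand
mean over bins equals the overall mean signal (a weighted-mean identity the
tests check to 1e-12).

```{r probes}
probes <- generate_probe_set(n_probes = 2000, optimal_tract = 6, seed = 7)
bins <- probes |> probe_features() |> bin_signal()
optimum_bin(bins)
```

### What the probe generator emulates

`generate_probe_set()` draws background sequence from a chosen GC
composition (default 0.5, genome-average-like), writes one A/T tract of
random length (uniform on 2–12 by default) at a random position, and
assigns `signal = baseline + effect_size * exp(-(L - L*)^2 / (2 w^2)) +
N(0, noise_sd)` where `L` is the probe's *realised* longest AT run —
background bases can extend a planted tract, so the realised run is never
shorter than the planted one (asserted per probe in tests). A Gaussian bump
(width `w = 0.75` bins, height 2, noise sd 0.5, i.e. a 4:1 effect-to-noise
ratio) was chosen because the emulated biology exhibits an *optimum* tract
length rather than a plateau; widening `effect_width` emulates plateau-like
behaviour when needed. The generator does not emulate genome tiling,
overlapping probes, microarray normalisation artefacts, or the correlated
base composition of real genomes — so recovery of the planted optimum shows
the feature/binning machinery is correct, not that any particular organism
behaves this way.

## Homologue conservation

`pairwise_identity()` counts matches over columns where at least one
sequence has a residue: columns gapped in both are uninformative and are
ignored, while a one-sided gap counts as a mismatch (the homologue lacks
the residue). `dereplicate()` removes near-identical entries — e.g.
hundreds of same-species database hits that would otherwise dominate a
consensus — by a greedy scan in input order, dropping an entry when its
identity to any retained entry reaches the threshold (default 0.99). The
greedy-in-order rule is the simplest deterministic formulation and is
idempotent; the reference entry is scanned first and therefore always
survives.

`consensus_profile()` reports, per column, the most frequent non-gap
residue (lexicographic tie-break), emitting a gap symbol when more than
half the entries are gapped; conservation is the top residue's share of
*all* entries, so gaps count against conservation and
`conservation <= 1 - gap_fraction` always holds. `residue_conservation()`
answers questions of the form "in what fraction of homologues is this
arginine conserved?": the reference position is mapped through gaps with
`map_position()`, and the fraction is computed over non-reference entries
only — a statement about the homologues of the reference, which is why the
reference itself is excluded from the denominator.

```{r conservation}
msa <- generate_msa(n_sequences = 500, length = 120,
                    planted = tibble::tibble(column = 116, residue = "R",
                                             conservation = 0.81),
                    n_duplicates = 12, seed = 3)
derep <- dereplicate(msa, threshold = 0.99, ref_id = "ref")
nrow(msa) - nrow(derep)            # the 12 planted near-duplicates
residue_conservation(derep, "ref", 116)
```

`generate_msa()` plants conservation by exact count —
`round(fraction * (n - 1))` non-reference rows carry the residue and the
rest are guaranteed not to — so recovery tests are exact rather than
binomially noisy. Note the rounding: a planted fraction of 0.81 over 499
non-reference rows is realised as 404/499 ≈ 0.8096, which still prints as
81%. The generator draws independent residues per cell; it does not emulate
phylogenetic correlation, so it validates the counting machinery, not any
evolutionary model.

## TPM analysis

A bead tethered to a surface by a single DNA molecule explores a disc
whose size reports the effective tether length; protein-induced compaction
restricts the motion. Three operations mirror the standard analysis chain:

* `tpm_qc()` computes, per bead, the anchor (mean position) and the scatter
  **eccentricity** `sqrt(lambda_max / lambda_min)` of the covariance matrix
  of `(x, y)` — the major/minor axis standard-deviation ratio. This
  definition is 1 for an isotropic scatter and is the one compatible with
  the conventional acceptance gate of 1.3 (the classical ellipse
  eccentricity never exceeds 1, so it cannot be what that threshold refers
  to). Multiple tethers, stuck beads and drifting beads all produce
  anisotropic scatters and fail the gate; a perfectly collinear scatter is
  reported as `Inf` rather than an error. No drift correction is applied —
  a drifting bead is expected to fail the gate, a documented limitation
  rather than a silent repair.
* `tpm_rms()` computes `RMS = sqrt(mean((x - xbar)^2 + (y - ybar)^2))` over
  consecutive non-overlapping windows (default 40 s at the default 25 Hz
  frame rate, i.e. 1000 frames), with the anchor re-estimated per window
  and the trailing partial window discarded. The mean over frames is the
  plain 1/n average, matching the formula as conventionally written, not
  the n−1 sample-variance convention. Both per-window values and their
  per-bead mean are easily reported, covering both readings of "RMS over
  40 s".
* `split_populations()` separates bound from unbound tethers by an
  exhaustive search over all thresholds between sorted adjacent values,
  minimising the within-class sum of squares — the exact 1-D two-means
  solution, with no random initialisation, hence fully reproducible. An
  all-identical input returns a single-population marker instead of a
  degenerate split. `tidy()`, `glance()` and `autoplot()` methods expose
  the result.

## The tether simulator

`sample_tether()` samples the equilibrium ensemble of a discrete worm-like
chain: `N = round(L_eff / l)` segments of length `l` (default 10 nm, a
fifth of the persistence length — fine enough that the discrete chain's
bending statistics track the continuous one), bending energy
`(Lp / l) * (1 - cos theta)` per interior joint in units of kT, anchored at
the origin of a hard surface with a free joint. A hard bead of radius R
(default 230 nm) is attached at the distal end, and configurations are
rejected unless every chain vertex has `z >= 0` and the bead centre
`z >= R`. The effective contour `L_eff` is the contour length (default
687 bp × 0.34 nm/bp = 233.58 nm) times a `compaction_factor` in (0, 1]:
protein-induced compaction is modelled as a multiplicative shortening of
the tether, the simplest mechanism-agnostic choice given that the
aggregation mechanism being emulated is unknown. Sampling uses Metropolis
pivot moves (random axis, rotation angle uniform on ±1 rad, ~50%
acceptance) with a 2000-sweep burn-in and 5-sweep thinning; these controls
are exposed as arguments.

Two elements of the observation geometry deserve explicit justification,
because they decide whether the simulated excursion matches experiments:

**Bead attachment.** The default (`attachment = "swivel"`) treats the bead
orientation as a free thermal degree of freedom: the DNA end sits at a
point of the bead surface and the bead pivots about it, each chain state
weighted by the bead's allowed-orientation entropy under the surface
constraint. This matches the physical linkage (a flexible
streptavidin–biotin joint, not a rigid weld). The alternative
(`attachment = "tangent"`) welds the bead centre rigidly along the final
chain tangent; the bead then acts as a 230 nm lever arm correlated with
the end orientation and inflates the in-plane excursion well beyond what
tethered beads show:

```{r attachment}
rms_of <- function(s) sqrt(mean((s$x - mean(s$x))^2 + (s$y - mean(s$y))^2))
swivel <- sample_tether(tether_model(seed = 1), 8000)
tangent <- sample_tether(tether_model(attachment = "tangent", seed = 1), 8000)
c(swivel = rms_of(swivel), tangent = rms_of(tangent))
```

**Camera exposure.** `simulate_trajectory()` threads equilibrium samples
into a time series by renewal resampling — each instant keeps the current
position or, with rate set by `correlation_time_s` (default 0.05 s), takes
a fresh equilibrium draw — giving exponentially decaying autocorrelation
while preserving the equilibrium marginal exactly. With
`exposure = "instant"` the frames are snapshots of that process. The
default `exposure = "integrate"` instead averages the position over each
full 40 ms frame, which is what a 25 Hz camera with full-frame exposure
records. Because the bead's positional correlation time is comparable to
the exposure, this motion blur attenuates the *apparent* excursion by a
predictable factor — a well-known property of camera-based TPM — and it is
the recorded, blurred RMS that experimental histograms report:

```{r exposure}
m <- tether_model(frames = 5000, seed = 2)
recorded <- simulate_trajectory(m, n_equilibrium = 10000)
mean(tpm_rms(recorded)$rms_nm)
```

With every parameter at its physical default (233.58 nm contour, 50 nm
persistence length, 230 nm bead, 25 Hz, 0.05 s correlation time) the
recorded RMS lands in the experimentally observed ~150 nm regime for a
687 bp tether, and halving the effective contour length moves it down
toward the restricted-motion regime — the behaviour the analysis chain is
designed to detect:

```{r compaction}
mc <- tether_model(frames = 5000, compaction_factor = 0.5, seed = 2)
mean(tpm_rms(simulate_trajectory(mc, n_equilibrium = 10000))$rms_nm)
```

The temporal model is a deliberate simplification: renewal resampling
reproduces the stationary distribution and an exponential autocorrelation,
but not true Langevin dynamics with hydrodynamic drag near a wall; RMS and
eccentricity depend only on the marginal distribution (and, through blur,
on the correlation time), which is why this suffices. Also not modelled:
chain–bead excluded volume, bead rotational diffusion, and linker
flexibility beyond the free swivel. The simulator validates the analysis
pipeline and reproduces excursion magnitudes; it is not a calibrated
hydrodynamic model of any particular instrument.

### Problem sizes and numerical controls

The test suite and the acceptance script run the Monte-Carlo at 10⁴–3×10⁴
equilibrium samples and 10³–2.5×10⁴ frames per condition — large enough
that the Monte-Carlo error on a mean RMS is ~1 nm, small enough that the
whole suite completes in well under a minute of sampling. Determinism is
strict throughout: every stochastic function takes a seed (the sampler
uses R's RNG, so `set.seed()` governs it too), and identical model + seed
yields bit-identical output, which the tests assert.

## Reproducibility conventions

Units are nm for space and seconds for time; protein positions are 1-based
on the ungapped reference; numeric bins are half-open. All writers prepend
a `#` provenance comment (package version, seed) that all readers skip.
Degenerate inputs fail loudly with the offending record or row named:
ragged alignments, non-uniform time bases (beyond 1% of the median step),
non-finite coordinates, empty windows, all-empty bins.
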