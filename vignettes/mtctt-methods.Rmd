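---
title: "Methods: lattice construction and tail-accessibility statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lattice construction and tail-accessibility statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtctt)
```

This vignette documents the models and numerical choices behind `mtctt`:
how the helical lattice is constructed, how disordered α-tubulin
C-terminal tails (αCTTs) are built, how tail–body salt bridges are
detected and summarized, and what the synthetic trajectory generator does
and does not emulate.

## The lattice model

A microtubule wall is described here by a `lattice_spec`: a lateral rigid
transform `T` mapping the dimer on protofilament *j* onto protofilament
*j + 1* of the same ring, an axial dimer repeat *d* (Å), the
protofilament count *n* (default 13), the start number *s* (default 3)
and the helix axis (by convention +z, plus end toward increasing z, so
"toward the minus end" is decreasing ring index). The defining identity
of the canonical 13-protofilament, 3-start lattice is **seam closure**:

> composing `T` thirteen times is a pure axial translation by three
> monomer repeats (1.5 dimer repeats).

`seam_closure()` checks this by brute-force matrix composition. Real
cryo-EM lattices close imperfectly, so the residuals are accepted up to
configurable tolerances (defaults 0.5 Å translation, 0.5° rotation).
Seam closure is what lets a stacked fragment be placed in an axially
periodic box (`make_infinite()`, axial length = `n_rings` × dimer
repeat) so protofilaments continue across the boundary: a twisted
lattice whose lateral transform does not close cannot match its own
periodic image, and the builder then refuses and points the user at
`make_padded_box()` (each box face exactly `padding` Å — default 20 —
from the extreme atom coordinate).

The spec is never hard-coded: `infer_lattice_spec()` recovers `T` as the
least-squares (Kabsch, base `svd`) superposition of a seed dimer onto
its lateral neighbor, the dimer repeat from the axial component of the
seed→axial-neighbor transform, and the axis from the screw axis of `T`.
Superposition uses backbone atoms (N, CA, C, O): robust to sidechain
divergence between template entries. Which chains constitute the seed
dimer is a user decision (`chain_roles` on read; dimer indices or chain
vectors on inference) — template files do not reliably encode it.

Two further builder operations mirror common preparation steps.
`convert_nucleotide()` turns GMPCPP ligands at the β (exchangeable) site
into GTP by a template-driven bookkeeping edit: the α,β-bridging
methylene carbon becomes a bridging oxygen at the same position and its
hydrogens are dropped; no chemistry is re-optimized, since downstream
users re-equilibrate anyway. `fit_to_reference()` superposes each dimer
of a mobile lattice onto its partner in a reference lattice. The
per-dimer fit is the default because it alone guarantees the mobile
structure adopts the reference lattice geometry exactly (a single global
fit cannot reconcile two lattices that differ in twist or repeat); the
global variant remains available (`per_dimer = FALSE`).

## Tail construction

`append_tails()` grows one-letter sequences (default: the tyrosinated
TubA1A tail `SVEGEGEEEGEEY`, numbering S439–Y451, seven glutamates with
G448 breaking their contiguity) from the last resolved residue of each
target chain. The backbone is built residue by residue with the
natural-extension reference frame, dihedrals drawn uniformly from the
extended-coil region (φ ∈ (−160°, −60°), ψ ∈ (90°, 180°)), ω = 180°,
sidechains from idealized internal coordinates in the common trans
rotamer. A placement is accepted only if every new heavy atom is at
least `clash_cutoff` (default 2.5 Å) from all previously placed heavy
atoms; the covalently attached preceding residue is exempt, because its
bonded and 1–3 neighbors are necessarily nearer (amide C–N = 1.33 Å).
If a chain grows into a dead end the whole chain is rebuilt with fresh
draws (`max_restarts`); the entire procedure is bitwise-deterministic
per seed. Tails are *not* energy-minimized and carry no Boltzmann
weight — they are starting structures, not an ensemble.

## Salt bridges, sites, and the two statistics

A tail residue and a body residue form a salt bridge when any sidechain
donor nitrogen (Lys NZ; Arg NE/NH1/NH2) is within `cutoff` of any
carboxylate oxygen (Glu OE1/OE2; Asp OD1/OD2; optionally OXT plus the
backbone carbonyl O of a C-terminal residue). The 4.0 Å default is the
common convention; no result in the package depends on it being fixed —
every statistic is recomputable at other cutoffs, and contact sets are
monotone in the cutoff (tested). Distances honor the minimum-image
convention along the box axis when the box is periodic. Detection has
two interchangeable paths — all-pairs and a cutoff-grid neighbor list —
kept oracle-identical by tests.

Contacts are assigned to the four-site registry under host relations:
*cis* sites (3, 4) require the body chain to be the tail's own α chain;
*trans* sites (1, 2) require the β chain of the dimer one ring toward
the minus end on the same protofilament, wrapping across the periodic
boundary. Contacts with basic residues outside the registry are kept as
`"other"`. Tails on the minus-most ring of a non-periodic lattice have
no trans partner; they are excluded from the site-1/2 denominators
(`eligible` matrix on the timeline). The registry ships the four
published residue clusters verbatim; note the source texts disagree on
whether site 3 has four or five residues — the registry follows the
explicit per-site lists (four for site 3, five for site 2) and users can
supply their own registry as a TSV.

Two statistics summarize the occupancy tensor `[tail, residue, site,
frame]`:

* **Interaction rate** `R(r, s)`: fractional frame occupancy — the share
  of (frame, tail) observations with ≥ 1 bridge between glutamate `r`
  and site `s`. An events-per-ns variant is exposed secondarily
  (`units = "events_per_ns"`); occupancy is the default because it is
  reproducible without interpreting time units. One residue contacting
  several sites in one frame counts in each site's cell independently.
  Independent trajectories are averaged with equal weight.
* **Inaccessibility trace** `f(t)`: by default the fraction of tails with
  ≥ 1 bridge between the glutamates within E445–E450 and any site
  (per-tail mode). A residue-counting variant over E445–Y451 — with
  Y451 contributing through its terminal carboxylate
  (`include_cterm = TRUE`) — is available behind flags, since both
  definitions are in circulation. The trace is instantaneous with an
  optional trailing moving average (default window 1 = none), not a
  cumulative running fraction.

## The synthetic generator

`simulate_binding()` exists so that every stage above can be validated
without molecular dynamics. Each planted (tail residue, site) pair on
each tail is an independent two-state Markov chain with per-frame
probabilities `p_on`, `p_off`, stationary occupancy
`q = p_on/(p_on+p_off)`, and autocorrelation `ρ = 1 − p_on − p_off`.
The initial state is drawn from the stationary distribution so short
runs are unbiased; `start = "unbound"` instead starts fully accessible,
producing the rising-occupancy relaxation shape. Geometrically, a bound
pair's carboxylate oxygen is placed at `d_bound` (3.0 Å) ± a uniform
jitter (0.4 Å) from a donor of the target site along a direction chosen
(deterministic 64-point sphere search) so that the target donor remains
the closest donor and all other-site donors stay ≥ `d_unbound` (8.0 Å);
unbound oxygens rest ≥ `d_unbound` from every donor. Consequently the
emitted coordinates realize the planted tensor *exactly* under any
cutoff in (`d_bound`+jitter, `d_unbound`) — the analysis-side tests
assert tensor identity, not merely statistical agreement. A glutamate
has two carboxylate oxygens, so at most two sites may be planted per
residue; a third raises a geometric-infeasibility error rather than
silently coupling the chains.

What the generator emulates: two-state binding kinetics with known
occupancies, periodic-boundary trans contacts, multiple donors per site,
simultaneous multi-site binding. What it does not: tail conformational
mechanics (only the carboxylate oxygens move), excluded volume between
frames, force-field energetics, correlated binding between residues, or
water/ions. Passing tests therefore demonstrate that the *analysis*
recovers what a trajectory contains — not that real tails behave like
the presets.

The `gdp_like`/`gtp_like` presets encode the qualitative contrast
between the compacted and expanded lattice states as documented,
arbitrary occupancies (chosen once): site 1 strongest for E441/E443
(q = 0.50/0.40) in both; site-2 binding of residues 445–450
(q = 0.15–0.20) and site-4 binding of 449/450 (q = 0.15) present in
`gdp_like` but nearly abolished (q ≤ 0.01, site 4 exactly 0) in
`gtp_like`; a small shared site-3 term (q = 0.10 at E445/E446). The
per-frame probabilities keep `p_on + p_off ≥ 0.1` so chains decorrelate
within tens of frames and 20 000-frame runs give tight recovery bands.

## Statistical acceptance bands

For an occupancy estimated from a two-state chain, the variance of the
time average over `n` frames is `q(1−q)/n · (1+ρ)/(1−ρ)`; the test suite
uses 3 standard errors with this autocorrelation correction, pooling
tails as independent chains. The per-tail trace mean is compared with
the independence closed form `1 − Π(1−q)` over the planted cells in
E445–E450, with the most conservative (largest) correction factor among
the involved cells.

## Problem sizes and determinism

The validation topology is a 1-protofilament × 3-ring periodic stack
(3 tails, ≈ 1 200 atoms) — the smallest lattice in which every trans
relation, including the wrap across the periodic face, is exercised —
analyzed over 20 000 frames for the recovery tests and 3 000–5 000
frames for shape/contrast checks; full 13 × 3 lattices (39 dimers,
≈ 11 000 atoms with tails) are used for the construction and I/O tests.
All randomness (toy geometry, tail dihedrals, Markov chains, jitter)
flows through per-call integer seeds with save/restore of the caller's
RNG state; identical seeds give byte-identical text outputs, which the
pipeline's md5 manifest makes checkable.

## Known limitations

* The tail builder produces self-avoiding but otherwise unweighted coil
  conformations; ensemble properties (radius of gyration, contact
  propensities) should not be read off the built structures.
* The toy dimer is a geometry fixture — site residues at real author
  numbers with ideal sidechain geometry on a coarse grid — not a protein
  model; PTM chemistry is out of scope (detyrosination is modeled only
  as sequence truncation, `tuba1a_tail("deY")`).
* Site assignment presumes the builder's labeling (pf/ring/dimer);
  trajectories from other tools must come with a labeled topology.
* `"other"`-labeled contacts are a census aid, not a site-discovery
  method.
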