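---
title: "Designing peptide binders from tertiary structural motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing peptide binders from tertiary structural motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termseed)
```

## The model

`termseed` rests on one structural premise: the local geometries that occur
at peptide–protein interfaces recur, as *tertiary motifs* (TERMs), inside
ordinary single-chain structures. A strand pairing inside a beta sheet, a
helix packed against a sheet face, a loop draped over a strand — each is
simultaneously an intramolecular motif and a template for an intermolecular
one. The pipeline therefore never invents interface geometry; it only
re-uses geometry found by substructure search.

The stages, and the quantities that govern them:

**Binding-site fragments and matches.** Around each binding-site residue a
query fragment is grown greedily — start at 3 residues, extend the flanks
while the database still returns at least `n_min_matches` matches within
`rmsd_cutoff` (default 1.0 Å, over all four backbone atoms N, CA, C, O;
optimal rigid superposition by the Kabsch SVD construction, reflections
excluded). Larger fragments carry more context but recur less often;
`n_min_matches` sets that trade-off, and the minimum 3-residue fragment is
always kept so every site residue yields matches. Multi-segment fragments
(up to two proximal 3-residue segments, added under the same rule) are
available behind `multi_segment`.

**Seeds.** For each match, the source structure is scanned for residues
with the *potential to contact* the match's central residue; each, with ±2
flanking residues (merged when expansions overlap, never crossing a chain
break, minimum 3 residues), is transformed into the target frame by the
match superposition. The match window ±2 residues is excluded so seeds
represent tertiary, not sequence-local, context. Seeds that clash with the
target (below) are discarded.

**Potential contacts.** All contact decisions use backbone-only criteria,
so they apply equally to native peptides and sequence-less designs:

* *contact degree* — the probability-weighted fraction of sidechain rotamer
  pairs, placed on the two backbone frames, with heavy atoms within 4.5 Å;
* *interference* — the weighted fraction of rotamers at one residue whose
  sidechain reaches the other residue's backbone;
* *backbone–backbone* — any of the 16 backbone atom pairs within 3.25 Å
  (sequence-adjacent residues excluded).

The first two are binarised at 0.01 — the single binarisation constant in
the package. Fixed-sequence positions (the target protein) use only their
native amino acid's rotamers. The heavy-atom approach distance of 4.5 Å is
an explicit package constant; the rotamer library shipped in
`inst/extdata/rotamers_synthetic.tsv` is deliberately coarse (≤ 6 conformers
per amino acid, linear pseudo-atom sidechains at common chi angles, built
from ideal geometry by `rotamer_library_synthetic()`). It is synthetic — not
derived from any published rotamer survey — and exists so the contact
definitions are computable offline; `read_rotamer_library()` accepts a
richer replacement in the same text format.

**Overlap graph and path sampling.** Two seeds can be joined where
4-residue windows align: every CA pair within 0.75 Å *and* every aligned
residue-frame rotation (frames built from N, CA, C) within 30°. Candidate
window pairs come from a spatial hash of CA cells of size `max_ca_dist`,
which cannot miss a true overlap (aligned CAs within the bound differ by at
most one cell per axis); every candidate is verified exactly, so hashing is
purely an accelerator. Random walks over seed residues (uniform extension,
both directions, stochastic stopping) become designs if they use more than
one seed or an overlap-bearing seed, reach 15 residues, fuse without a van
der Waals clash against the target (pairwise distance below
0.7 × (r_a + r_b), strict), and are not an exact node-sequence repeat of an
accepted path. Rejections are tallied by cause. Exact node-sequence identity
is deliberately the only redundancy rule at this stage; near-duplicates are
collapsed later by backbone clustering.

**Fusion.** Aligned fragments are averaged per atom, then refined by
L-BFGS on a harmonic distance network: bond lengths directly, bond angles
and trans-omega planarity through their equivalent 1-3 / 1-4 atom distances
(targets computed from ideal backbone geometry), plus a weak restraint
(weight 0.05) to the initial average. Distance-only terms keep every
gradient closed-form; the network reproduces ideal geometry to well under
the 0.05 Å contract of the consistency tests, and junction C–N bonds land
in [1.25, 1.40] Å.

**Scoring and selection.** Designs are ranked by potential contacts per
residue (≥ 2.5 to pass) and by the TERM interface score: for every
contacting (design residue, target residue) pair, the two-segment pair-TERM
(each residue ±1) is searched against the database, and the pair scores
`-log10((m+1)/(m̃+1))` are averaged, where `m̃` is the median match count
of pair-TERMs sampled from the database's own intramolecular contacts
(500 by default, cached per database). Negative means the designed interface
geometry is better supported by known structure than a typical motif. The
formula reproduces the sign convention and database-relative normalisation
of the statistic it emulates, but its absolute values depend on the database
supplied and are not comparable across databases. Designs passing both
filters (score ≤ 0.2) are clustered by complete linkage and up to three are
kept per cluster.

**Backbone clustering distance.** The all-vs-all distance is the best
sliding-window backbone RMSD *in the common target frame* — no
superposition. This was a genuinely open choice; we resolved it by the
semantics of the 5 Å and 20 Å thresholds: designs live around one target,
and a pose-invariant (superposed) distance would merge identical backbones
bound at different sites, making cross-site clusters meaningless.

## Benchmarks

*Coverage*: strip the peptide from a complex, define the binding site
(protein residues with ≥ 1 potential contact to the peptide, native
rotamers), generate seeds, and call a peptide residue covered when it lies
in a k-residue peptide window whose **fixed-frame** backbone RMSD to some
seed k-window is ≤ R_c — no superposition, because a seed only counts if it
sits where the native peptide sat. Coverage is reported over *interface*
residues (contacting peptide residues whose B-factor is within 3 SD of the
complex mean). Full k-windows within the peptide are required; windows
extending past a terminus are not scored.

*Reconstruction*: seeds covering 3-residue windows at 2.0 Å are assigned to
windows greedily in ascending RMSD with seed reuse forbidden (each window
must come from a different seed, so reconstructions are chimeric); the
greedy-global order resolves the conflict that one seed may be best for
several windows. Windows left uncovered are omitted from the fusion
topology and excluded from the reported mean RMSD; conserved potential
contacts are counted position-wise against the native map.

*Decoy control*: each real seed is matched by a decoy of identical residue
count, random orientation, posed so its distance-to-protein reproduces a
draw from the real seeds' empirical distance distribution (bisection along
a random approach direction), and clash-free. Decoys carry no database
provenance, so the real-vs-decoy coverage gap isolates what the motif
search contributes beyond geometry-matched noise.

## Sequence layer

Energy tables are linear: `E(s) = Σ self(i, s_i) + Σ pair(i, j, s_i, s_j)`.
The annealed sampler estimates the table's energy scale `s` as the standard
deviation over ≥ 10,000 uniform-random sequences, computes the exact
minimum `E_min`, targets `E = E_min + s/2`, and for each final temperature
in a geometric grid anneals from a hot start and collects Metropolis
samples (single-position mutations, 10 % burn-in, thinning 10); the
ensemble whose mean energy is closest to `E` is returned. Conservation is
`log2(20)` minus the plug-in entropy of the observed column frequencies;
the consensus takes the most frequent amino acid, ties alphabetical.

Minimum-energy sequences under a charge constraint (exactly `n_charged` of
Arg/Asp/Glu/Lys; His is uncharged at neutral pH; a ≤ mode is available) are
found by exact branch-and-bound rather than an external integer-programming
solver: the admissible lower bound combines per-position minima given
assigned interactions, global pair minima among unassigned positions, and a
sorted-delta bound over the remaining charge budget, so the returned
optimum is certified. The tests verify it against exhaustive enumeration.

## What the fixtures do and do not show

The synthetic generators produce ideal-geometry secondary structure
(helix φ = −57°, ψ = −47°; strand φ = −139°, ψ = 135°; ω = 180°), toy
complexes (a two-strand receptor sheet with a hydrogen-bonded peptide
strand, calibrated by a deterministic grid search over pairing geometry
with a 2.6 Å steric floor; or a helix packed over the sheet face), and
planted databases in which receptor and peptide are concatenated into one
renumbered chain — so the binding mode genuinely exists as an intra-chain
tertiary motif, plus noisy clones and ideal-helix distractors.

Passing the plant-and-recover suite shows the machinery is correct: search
is exhaustive-equivalent, placement is exact, coverage and reconstruction
behave as specified, decoys lose. It does not show that real, redundant,
loop-rich structure databases yield the same coverage levels, nor that the
coarse rotamer library reproduces contact statistics of full rotamer
libraries; those depend on data this package deliberately does not bundle.
One geometric fact surfaced by the fixtures is faithful to real sheets:
with ideal rigid strands only the hydrogen-bonded rungs (alternating
residues) come within the 3.25 Å backbone–backbone cutoff, so the ground
truth flags backbone contacts on that subset while every peptide residue
still registers through the sidechain terms.

## Numerical choices and problem sizes

Degenerate (near-collinear) point sets in superposition are flagged with a
warning; reflections are never returned. Match lists sort ascending by
RMSD with ties resolved by database order, and all samplers (paths, decoys,
annealing) are bit-reproducible from their `rng_seed`. The window-signature
prune in search (CA end-to-end distance, tolerance `2·sqrt(2L)·cutoff`) and
the inter-segment centroid prune (`sqrt(N_tot/n_seg)·cutoff` per segment)
are both provably lossless, and the test suite checks search and overlap
detection against unpruned brute-force scans.

The shipped tests and the acceptance script run on desk-scale problems:
10–16-residue peptides, databases of ~7–10 chains (planted entries, noisy
clones, distractors), a few thousand seed windows, tens of sampled paths,
and sequence problems small enough to enumerate (2 × 20, 4 × 6). These
sizes were chosen so every pipeline stage is exercised against an
exhaustive oracle; the algorithms themselves carry no small-size
assumptions, and scale with database volume roughly linearly in the number
of windows.

## Known limitations

* Secondary-structure labels come from a Kabsch–Sander-style hydrogen-bond
  rule set mapped onto the {H, G, E, B, T, C} alphabet; residues no rule
  classifies inherit the shared label of their flanks, else coil. Ideal
  helix/strand fixtures are unambiguous under these rules, but subtle
  classes (3-10 vs alpha boundaries, isolated bridges) will not match any
  particular external labeller residue-for-residue.
* Solvent accessibility normalises Shrake–Rupley areas by an extended
  Gly-X-Gly reference computed over the same atom complement, so relative
  values are self-consistent for backbone-only structures but not
  comparable to full-atom accessibility scales.
* Fusion is a harmonic idealiser, not a physics refinement: no sidechains,
  no electrostatics, no loop closure beyond the distance network.
* The TERM interface score's absolute range is database-relative by
  construction; only comparisons within one database are meaningful.
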