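---
title: "Screening disordered regions for MoRFs and retro-MoRFs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening disordered regions for MoRFs and retro-MoRFs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retromorf)
```

## The screening problem

Intrinsically disordered regions (IDRs) lack a fixed three-dimensional
structure, yet they are rich in binding activity. Much of that activity is
carried by *molecular recognition features* (MoRFs): short, structure-prone,
hydrophobic-rich segments embedded in an IDR that fold upon binding a
partner. In a per-residue disorder profile a MoRF shows up as a *dip* — a
local run of low scores flanked by high-scoring disordered sequence —
because its elevated hydrophobic content locally favours structure.

A *retro-MoRF* is the same segment read backwards. Sequence reversal
preserves length, amino-acid composition, and the coarse pattern of
hydrophobic and charged residues, so a reversed copy of a known binding
segment occurring in another protein is a plausible candidate for binding
an overlapping partner set. Two binding geometries are especially tolerant
of reversal: one face of an amphipathic α-helix (whose helical hydrophobic
moment is mathematically invariant under reversal, see below), and
polyproline-II (PPII) ligands of SH3 domains, whose class I (`RxxPxxP`)
and class II (`PxxPxR`) consensus motifs bind in opposite orientations.

The package turns this idea into a screening pipeline: profile disorder,
detect dips, align the candidate fragments against a database in normal
and reversed orientation, estimate chance similarity empirically, and
accept a hit only when three criteria hold simultaneously:

1. sequence identity of the local alignment is **strictly above 60%**
   (a hit at exactly 60.0% is rejected);
2. the aligned pair shows a **similar hydrophobic/charge pattern**
   (class-match fraction at or above 0.6, see below);
3. the matched span on the target is **disordered, flanked by disorder, or
   in a disordered tail** — but *not* a short disordered linker wedged
   between ordered domains, and not inside a structured region.

## The disorder profiler is a transparent stand-in

Trained disorder predictors are the field's standard tools, but their
weights are not redistributable and their outputs are not reproducible
from first principles. This package deliberately ships a **transparent
scale-based profiler** instead: the score at position *i* is the mean of a
published per-residue disorder propensity over a window centred at *i*.
Downstream logic — dip calling, context classification — only needs a
disorder score track in [0, 1] with the conventional 0.5 order/disorder
boundary, not any particular predictor. Results on real proteins will
differ in detail from any trained predictor's; the profiler is smooth,
composition-driven, and fully auditable.

Two published scales ship with the package (`list_scales()`): the TOP-IDP
disorder propensity (Campen *et al.* 2008), min–max normalised so P = 1
(most disorder-promoting) and W = 0, used as `default_disorder`; and
Kyte–Doolittle hydropathy in both orientations (`hydropathy`,
hydrophilic-high; `hydrophobicity`, native direction, used by the
hydrophobic moment).

Key choices:

* **Window 21** (default): approximates the smoothness of meta-predictor
  curves; small enough that a 15-residue MoRF still carves a visible dip.
* **Threshold 0.5**: the universal order/disorder convention for
  normalized scores.
* **Clipped (shrinking) windows at the termini**, never padding. This is
  what makes the mirror identity
  `profile(reverse(s)) == reverse(profile(s))` hold *exactly* — the
  computable core of the claim that composition-level properties survive
  reversal — and it is asserted to 1e-12 in the test suite.
* **Minimum segment length 4** when calling disordered segments,
  suppressing single-residue flickers.

## Dip detection

`detect_dips()` reports maximal sub-threshold runs that are 5–30 residues
long, bordered by disordered runs of at least 10 residues (one side
suffices at a terminus when `allow_tail` is on, giving `is_tail`
candidates), and at least 0.2 deeper than the mean of their flanks. The
length bounds reflect that MoRFs are short (one to a few helical turns);
the depth floor separates sharp dips from profile noise. Hydrophobic
enrichment — the *difference* between the hydrophobic fraction inside the
dip and over its flanks, a difference rather than a ratio so that
hydrophobe-free flanks pose no division hazard — is an annotation used
for ranking (depth first, then enrichment), not a gate.

```{r dips}
s <- generate_background(200, seed = 3, id = "demo")
m <- random_motif(15, seed = 9)
planted <- plant_motif(s, m, 100, reversed = TRUE, seed = 4)
detect_dips(disorder_profile(planted$seq))
```

## Alignment and empirical significance

The aligner is a full Smith–Waterman with affine gaps (Gotoh), written as
compiled code with a fixed traceback tie-break (diagonal over up over
left) so that a single deterministic optimal alignment is produced.
Defaults are BLOSUM62 with gap open 11 / extend 1, the classical protein
search parameters; a gap of length L costs `open + extend × L`. Percent
identity counts **gap columns in the denominator** — a conservative
convention that makes the strict 60% criterion unambiguous. The score is
validated two independent ways in the test suite: against a brute-force
enumeration over all aligned-column subsets on small instances, and
against an independently implemented affine-gap local aligner on larger
random pairs.

Significance is empirical rather than analytic. For a hit with score `S`,
the query is shuffled `n` times (composition-preserving), each shuffle is
re-scored, and

```
p_emp = (1 + #{shuffle score >= S}) / (n + 1),    E = p_emp × db_size.
```

The add-one form keeps `p_emp` strictly positive (log-safe), and under
the null the p-value is calibrated: over 1,000 random query/target pairs
the fraction with `p_emp <= 0.05` is asserted to lie in [0.03, 0.07].

A consequence worth understanding: the smallest attainable E-value is
`db_size / (n + 1)`. With the defaults (199 shuffles at the prescan stage,
a database of tens of sequences) that floor is on the order of 0.1–0.5,
so classical analytic cutoffs such as 1e-3 are **not reachable** and would
silently discard every hit, including exact matches. The package therefore
prescreens at `E <= 1` — "fewer than one chance hit expected per query
over the database" — and re-estimates survivors with 999 shuffles. Users
who want stricter cutoffs should raise `prescan_n_shuffles` to at least
`db_size / threshold`; every knob is exposed in `scan_params()` and the
YAML config.

## The three-criterion verdict

* **Criterion 1** is strict: `identity > 60`, so 60.0 fails and
  60.0 + ε passes. Identity is measured over the aligned span (local
  alignment), not the whole fragment.
* **Criterion 2** has no canonical formula in the field; the package
  operationalizes "similar hydrophobic/charge pattern" as the fraction of
  alignment columns whose residues share a biochemical class —
  hydrophobic {A,C,F,I,L,M,V,W}, polar {G,N,Q,S,T,Y,P}, positive {K,R,H},
  negative {D,E} — with gap columns counting as mismatches. Identical
  residues always share a class, so pattern similarity is never below
  identity/100. The default threshold 0.6 mirrors the stringency of the
  identity criterion. Both the partition and the threshold are
  config-overridable.
* **Criterion 3** distinguishes four contexts. A span inside a disordered
  run that touches a terminus is a `disordered_tail`; inside a
  non-terminal run shorter than 50 residues it is a `short_linker`
  (observed linker-like runs of roughly 25 and 40 residues motivate the
  50-residue boundary — such runs connect domains rather than bind);
  inside or bordered by longer disordered runs it is
  `flanked_by_disorder`; and when the span and its flanks all average
  below threshold it is `ordered`. Only the tail and flanked contexts
  pass. Because a windowed-mean profiler depresses scores up to half a
  window beyond a structure-prone span, flank measurements and
  run-adjacency checks allow a margin of `window %/% 2` residues; without
  it, a genuine dip's own smoothing shadow would mask its disordered
  neighbourhood.

Amphipathicity and PPII motifs are deliberately **annotations, not
gates**: they support interpretation (a high helical hydrophobic moment
μH, or a class I/II SH3 motif, marks reversal-tolerant binding
geometries) but never decide the verdict. μH is the classical helical
wheel measure `|Σ H_k e^{ikδ}| / n` at δ = 100°; reversing the window
conjugates the complex sum and leaves the magnitude unchanged, which the
suite asserts to 1e-12.

```{r verdict}
classify_ribs(65, 0.8, "flanked_by_disorder")
classify_ribs(60.0, 0.9, "flanked_by_disorder")$reasons
```

## What the synthetic benchmark emulates — and what it does not

`generate_benchmark()` builds databases of i.i.d. background sequences
drawn from a disorder-promoting composition (90% of the mass spread over
the eight most disorder-promoting residues of the shipped scale, 10% over
the rest — sequences profile disordered by construction), plants
hydrophobic-rich motifs in normal or reversed orientation at interior
positions (≥ 40 residues from either terminus, leaving ample flanks), and
optionally mutates planted copies at a per-position rate. Everything is
seeded: the same spec yields byte-identical FASTA.

This emulates exactly the screening situation the pipeline targets — a
short structure-prone fragment recurring, sometimes backwards, inside the
disordered regions of otherwise unrelated sequences — and nothing more.
It does **not** emulate real proteins: no domain architecture, no
evolutionary relatedness or indel history, no sequence correlations
beyond composition, and decoy similarity only at chance level. Passing
the planted-recovery checks therefore demonstrates that the pipeline's
machinery is correct and calibrated, not that its verdicts are accurate
on real proteomes, where the disorder profiler is also only a stand-in
for trained predictors.

## Problem sizes and numerical conventions

The package's standing checks use sizes chosen to characterize behaviour
well while remaining quick to re-run: 200 random pairs (lengths ≤ 8 over
a 4-letter alphabet) for oracle agreement; 500 random sequences for the
reversal invariances (asserted to 1e-12; the operations are exact in real
arithmetic and differ only by floating-point summation order); 1,000
null trials at 199 shuffles for p-value calibration; and 50-target
benchmarks (lengths 300–600, ten planted reversed 15-mers) at mutation
rates 0, 0.1, 0.2, 0.3 for end-to-end recovery, which is complete at
rate 0 and non-increasing in the rate.

Coordinates are 1-based inclusive everywhere in the API and reports —
the native R and IRanges convention — and converted to 0-based half-open
only on BED export. Sequence ids carry provenance markers (`|rev` for
reversed queries, `:start-end` for extracted fragments) so every hit is
traceable to its orientation and source span. All randomness flows
through explicit integer seeds; package functions restore the caller's
RNG state.

## Known limitations

* The profiler is compositional; it cannot reproduce the sharp,
  context-sensitive features of trained predictors, and real MoRFs whose
  hydrophobicity is subtle may not form detectable dips.
* Empirical E-values cost one alignment per shuffle; genuinely small
  thresholds require large `n_shuffles` and correspondingly more time.
* The scan is a linear all-vs-all pass with no heuristic seeding; it is
  meant for fragment-vs-database screening, not proteome-vs-proteome
  search.
* Binding itself is not modelled: a positive verdict marks a candidate
  for sharing a partner set, to be weighed with the μH and PPII
  annotations and, ultimately, experiment.
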