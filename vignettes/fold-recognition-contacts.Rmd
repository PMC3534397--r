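---
title: "Contact definitions, the fraction of common contacts, and fold retrieval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact definitions, FCC, and fold retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldcontacts)
```

## The question and the model

Residue–residue contact maps are well conserved among proteins of the same
fold, even at low sequence identity, which makes them a candidate scoring
signal for fold recognition and threading. But "contact" is not a single
notion: it depends on which atoms the distance is measured between (the
*contact base*), the distance cutoff, and the minimum sequence separation
below which pairs are considered trivially in contact. This package
implements the machinery to compare such definitions on equal footing.

A **contact definition** is the triple

* base ∈ {Cα, Cβ, heavy atoms},
* cutoff *d* (Å, canonical grid 4.5–100 Å),
* minimum separation *s* (default 3: pairs with |j − i| ≤ 2 are excluded).

For the Cβ base, glycine (which has no Cβ) uses its Cα instead; the same
substitution is applied, with a warning, to any residue with a truncated
side chain, which keeps maps total. For the heavy-atom base the distance is
the minimum over all non-hydrogen atom pairs of the two residues, so a
heavy-atom map always contains the Cβ map at the same cutoff (the Cβ pair
distance is one of the minimized candidates). The distance boundary is
closed (= cutoff counts as a contact) — a measure-zero choice fixed for
determinism.

Two structures are compared through a residue-level alignment. If query
residues (a_i, a_j) are aligned to template residues (b_m, b_n) and both
pairs are in contact within their own structures, (a_i, a_j) is a **common
contact**. The pair score is the **fraction of common contacts**

$$
\mathrm{FCC} = \frac{\#\{\text{query residues in} \ge 1 \text{ common contact}\}}
                    {\#\{\text{aligned residues}\}} \in [0, 1].
$$

FCC is directional (query-denominated). The direction used in retrieval is
the pair's first-listed protein; a symmetric mean of both directions is
available (`symmetric = TRUE`). An optional relaxed matching (`relax = 1`)
accepts a template contact whose endpoints each lie within ±1 residue of
(b_m, b_n) after endpoint ordering; a single template contact may serve
several query contacts under relaxation (the stricter one-use alternative
would make the relaxed score depend on matching order, so reuse is the
deterministic choice).

**Retrieval evaluation.** For each fold with ≥ 2 members, positives are all
within-fold pairs and negatives pair the fold's representative — by default
the lexicographically smallest structure id, a deterministic stand-in for an
unspecified choice — with every foreign structure. Pairs are ranked by FCC;
the ROC curve is computed by a descending threshold sweep with tied scores
processed as one block, making the trapezoidal AUC equal to the normalized
Mann–Whitney statistic with ties weighted ½. Per-fold curves are averaged
pointwise on a common grid of 1001 evenly spaced false-positive rates. At a
vertical ROC segment the "TPR at this FPR" is ambiguous; interpolation takes
the upper TPR at a breakpoint and runs to the next breakpoint's lower TPR,
which preserves the trapezoidal area to grid resolution (≤ 10⁻³). The
superfamily level is the same machinery with superfamily ids substituted for
fold ids (`level = "superfamily_id"`).

## Tunable parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `cutoff` | grid 4.5–100 | Å | the quantity under study; occupancy grows monotonically with it |
| `min_separation` | 3 | residues | excludes obvious backbone-neighbour contacts |
| `relax` | 0 | residues | ±1 blurring of common-contact matching |
| `noise_sigma` | 0.5 | Å | within-fold structural divergence of synthetic families |
| `shift_prob`, `max_shift` | 0.3, 2 | –, residues | threading-like block misalignment rate and amplitude |
| `unaligned_prob` | 0.05 | – | residues dropped from a corrupted alignment |

**Occupancy** (fraction of residue pairs in contact) uses the
separation-eligible denominator: pairs (i, j) with j − i ≥ `min_separation`.
This makes occupancy reach exactly 1 at saturating cutoffs, which is the
natural normalization for the map's actual domain; the all-pairs
denominator, which some summaries may intend, is exposed as
`occupancy(m, denominator = "all")` for sensitivity checks.

Sequence-separation analysis bins contacts inclusively (e.g. 5–10, 11–23,
and > 23 via `filter_by_separation(m, 24)`).

## The synthetic world

`make_benchmark()` emulates the statistical shape of a fold-retrieval
dataset at desk scale:

* **Folds** are distinct topologies assembled from ideal secondary-structure
  elements: three- to five-helix bundles (helix: 1.5 Å rise, 100°/residue,
  2.3 Å radius, Cβ 1.53 Å radially outward), antiparallel β-sheets (3.4 Å
  Cα step, 4.8 Å strand spacing, Cβ alternating 1.53 Å above/below the
  sheet plane), and mixed α/β folds. Loops are glycine stretches routed on
  a Bézier arc bulging away from the fold body, followed by a short
  repulsion relaxation, so no two non-adjacent Cα come within 3.5 Å.
* **Families**: each member is the fold template with isotropic per-atom
  Gaussian noise (default σ = 0.5 Å — small enough that within-fold contact
  conservation dominates, large enough that members differ). Loop indels
  are supported (`indel_prob`) but default to 0 in the benchmark: with
  saturating cutoffs every FCC must tie at exactly 1 for the
  "AUC = 0.5 at 100 Å" degeneracy to be exact, and any alignment gap could
  break a tie. This was fixed before measuring, as part of the stated world.
* **Alignments**: within-fold pairs inherit the exact residue
  correspondence from the template (gold); between-fold pairs get an
  index-wise alignment over the shorter length, a crude stand-in for what a
  structural aligner returns on unrelated proteins. A `CorruptionModel`
  shifts contiguous blocks of the alignment (geometric block lengths) by up
  to `max_shift` residues and drops residues, mimicking threading error;
  outputs always remain monotone one-to-one, with out-of-range pairs
  dropped.

Synthetic structures carry only Cα and Cβ pseudo-atoms, so the heavy-atom
base degenerates to min(Cα, Cβ) distances. That exercises all three code
paths with analytic geometry but does **not** probe real side-chain packing;
likewise the flat-sheet Cα/Cβ cross-strand effect requires the antiparallel
register of odd-length strands (the shipped defaults). A green synthetic
test therefore establishes correctness of the *machinery* — map
construction, FCC, ROC averaging, the qualitative cutoff/corruption
orderings — not the field-scale conclusion about which cutoff is best on
real proteins; that depends on real structural variation the generator does
not model (rotamers, bending, domain motion, real threading error
statistics).

## Numerical choices and degenerate inputs

* ROC ties: one block per distinct score; AUC ties weighted ½ (verified
  against a brute-force Mann–Whitney oracle in the tests).
* Curve averaging grid: 1001 points, upper-value convention at breakpoints
  (above).
* Structures shorter than `min_separation + 1` give an empty map with a
  warning; occupancy on a zero-eligible-pair map is an error rather than
  NaN.
* FCC of an empty alignment is undefined → error; an empty template map
  gives FCC 0.
* Alignment sensitivity uses the gold-pair denominator (the operational
  definition); the query-length denominator is available via
  `denominator = "query"`. The ±k tolerance is applied on the template
  index.
* PDB parsing keeps the first altloc conformer, drops hydrogens and HETATM,
  and renumbers residues 1..L (original numbering kept as metadata); all
  separation math uses the internal contiguous indices. Cα-only traces are
  returned but flagged so dataset builders can discard them.
* Seeded determinism: generator functions take a `seed` and restore the
  caller's RNG state on exit; fixed config + seed yields byte-identical
  reports.

## Known limitations

* Heavy-atom maps on synthetic data are not a test of true all-atom
  contacts (two pseudo-atoms per residue).
* The between-fold "alignments" of the benchmark are index-wise, which is
  harsher than a real structural aligner on partially similar folds; the
  negative FCC distribution is therefore somewhat compressed toward 0.
* TM-scores are consumed as external scalars (`best_tmscore_by_rank()`);
  the package computes no structural superpositions.
* HHpred/SUPRB native outputs are not parsed; convert to aligned FASTA.
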