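---
title: "Deriving RNA secondary structure from 3D coordinates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving RNA secondary structure from 3D coordinates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rss3d)
```

## The problem

Secondary (2°) structures of RNAs — above all the ribosomal RNAs — have
traditionally been inferred from sequence co-variation. Co-variation is
powerful but blind to most non-canonical base pairs: purine–purine and
Hoogsteen- or sugar-edge-mediated pairs barely co-vary, so entire
helices built from them (the classic example being a universally
conserved non-canonical helix in the LSU rRNA) appear as single strands
on traditional maps. When an experimental 3D structure exists, the 2°
structure can instead be *read off the coordinates*: every pairing and
stacking interaction is observable, canonical and non-canonical pairs
can be treated on equal footing, and pseudoknots are facts of geometry
rather than modeling choices.

`rss3d` implements that derivation as a pipeline:

1. **structure reading** — mmCIF/PDB in, ordered RNA residue model out;
2. **geometric annotation** — base reference frames, base pairs, base
   stacks;
3. **topology** — helix assembly, unique membership, secondary/tertiary
   roles, nested/non-nested classification with pseudoknot layers,
   base-triple decomposition, domain labels;
4. **serialization** — CT, extended BPSEQ, layered dot-bracket, and a
   lossless JSON record.

## The model

### Paired or not: geometric base-pair detection

Each base with a complete ring is assigned a reference frame by
least-squares superposition of a standard-frame template (the planar
base geometries of the standard nucleotide reference frame, purine and
pyrimidine ring atoms) onto the observed ring atoms. The frame gives an
origin (ring centroid), a proper rotation, and a unit base normal.

A candidate residue pair within a coarse C1′–C1′ prefilter
(`prefilter_c1p`, 15 Å) is called a base pair when all four hold:

* frame-origin distance ≤ `d_origin` (9 Å),
* inter-plane angle ≤ `a_plane` (65°),
* mean vertical offset along the base normals ≤ `v_offset` (2.5 Å),
* at least `h_min` (1) donor–acceptor heavy-atom contact at
  ≤ `d_hb` (3.5 Å).

These thresholds are conventional geometric-annotation ranges, exposed
in `default_params()` and overridable from a flat config file, so users
can tighten them toward crystal-grade annotation or loosen them for
low-resolution models. The vertical-offset gate is what separates
pairing (coplanar, side by side) from stacking (displaced along the
normal): an ideal A-form step has a rise of ~2.8 Å, safely above the
2.5 Å default.

Each pair is labeled by interacting edge (Watson–Crick, Hoogsteen or
sugar, voted by which edge's donor/acceptor set carries the hydrogen
bond contacts, ties resolved WC > Hoogsteen > Sugar), by glycosidic
orientation (cis/trans, from the side of the pair axis the two
glycosidic bonds point to), and as canonical (cis WC/WC A–U, G–C or
G–U) or non-canonical. Pairs within 10% of any threshold are flagged
`borderline`, a machine-readable substitute for the visual curation an
expert would apply. A residue may take part in several pairs — that is
what base triples are — but a given (i, j) pair is reported once.

Stacking requires ring-centroid distance ≤ `d_stack` (5.5 Å), normals
within `a_stack` (30°) of parallel, and strictly positive overlap of
the ring polygons projected on the mean plane. The overlap test is what
rejects coplanar side-by-side bases whose centroids happen to be close.

### Helices: continuous stacks faithful to strand connectivity

A helix is a maximal chain of base pairs in which consecutive pairs
(i, j), (i′, j′) advance the 5′ strand and retreat the 3′ strand
(i < i′ ≤ i+1+g and j′ < j ≤ j′+1+g, with `bulge_tolerance` g = 3) *and*
remain stacked across the junction: a stacking contact must exist
between i and i′ or between j′ and j. A helix may therefore contain
bulges or other defects as long as they do not break the stack
(`has_defect` records this); it is the geometry, not the sequence gap,
that decides. Non-canonical pairs chain exactly like canonical ones, so
a non-canonical pair that is internal to or extends a helix is part of
it. When no stacking information is supplied (pairing-list-only input),
plain sequence adjacency with g = 0 substitutes — the conservative
reading, since stacking cannot be asserted.

Each nucleotide belongs to at most one helix. When a triple spans two
helices, the pair in the larger helix keeps its membership (ties: the
helix starting earlier on the 5′ strand, then on the 3′ strand) and the
other pair is demoted — it remains a pair and is classified tertiary.
Removal splits a chain exactly at the removed pair.

Pairs inside helices are **secondary** interactions; everything else —
isolated pairs and demoted triple partners — is **tertiary**.

### Nested and non-nested helices

Two helices are *nested* when their pairs (i, q) and (j, p) satisfy
i < j < p < q (or are disjoint); they *cross* when some pairs interleave
as i′ < j′ < q′ < p′. Crossing helices cannot both live on a classical
2° diagram, so the package selects a maximum-weight crossing-free
subset (weight = pair count) as layer 0 by exact search on the crossing
graph — branch-and-bound per connected component, with equal-weight ties
broken toward helices starting earlier, so results are reproducible.
An exhaustive-enumeration oracle in the test suite confirms exactness
on random topologies. The remaining helices are non-nested
(pseudoknots, kissing loops), conventionally tertiary elements; they are
assigned greedily by descending weight to layers 1, 2, … such that no
two helices within a layer cross, which is exactly what a multi-bracket
dot-bracket writer needs.

One convention deserves special treatment: the central pseudoknot of
the SSU rRNA, whose helix 2 links all four SSU domains and is kept a
*secondary* element on every classical map even though it is
non-nested. The package generalizes this into a `forced_secondary` list
of helix labels: forced helices are constrained into layer 0 (class
`forced_secondary`), helices crossing them are excluded from layer 0,
and mutually crossing forced helices are an infeasible-constraint
error. Other pseudoknots stay tertiary unless the user forces them.

### Base triples as pairs of base pairs

A base triple is three residues joined by two pairs through a hub
residue; the SSU central pseudoknot's A915–U15–U20 triple (the hub U15
pairs both A915 and U20) is the canonical case. Flat formats cannot
express two partners, so the per-residue partner table is *layered*:
slot 0 carries the helix (secondary) pair — or, for purely tertiary
residues, the lowest-index partner — and further slots carry remaining
partners in ascending order. No pair is ever dropped: CT and
dot-bracket serialize slot-0 pairs that are mutual and report the count
they omit, extended BPSEQ appends `# TRIPLE i j` trailer lines, and
the JSON record is lossless. A residue with more than three partners is
kept but flagged as a structural anomaly.

## Worked example

```{r example}
fx <- make_ideal_duplex("GCGCGCGC", dir = tempdir())
res <- derive(fx$path, out_dir = tempdir(), overwrite = TRUE)
res$log[c("n_pairs", "n_canonical", "n_helices", "n_layers")]
```

And the central-pseudoknot convention on a pairing-list fixture:

```{r pseudoknot}
cp <- make_topology("central_pseudoknot")
h <- label_helices(assemble_helices(cp$pairs, NULL, cp$n_residues),
                   cp$labels)
classify_nesting(h)$layer                              # free selection
classify_nesting(h, forced_secondary = "Helix 2")$layer  # convention
```

## The synthetic fixtures, and what they do and do not show

Real rRNA crystal structures are hundreds of kilobases of binary data;
the package instead generates its own coordinate fixtures at test time.
`make_ideal_duplex()` builds idealized A-form geometry from the
standard-frame base templates — 32.7° helical twist and 2.81 Å rise per
step, the textbook A-form constants — with the complementary strand
antiparallel, and `make_bulged_hairpin()` adds a mid-stem bulge whose
flanking steps remain stacked, plus an unpaired loop, both positioned
so they neither pair nor stack with the stem. `make_topology()` supplies
pairing-list topologies: the four-helix nesting example, the central
pseudoknot (helix 2 at residues 17–19/916–918 in a 920-residue index
space, so tests read like the source structures), the A915–U15–U20
triple, and seeded random interleaved helix sets for the oracle tests.

Passing on these fixtures demonstrates that the geometric criteria,
chaining rule, exact nested-set selection and writers implement their
definitions correctly. It does *not* demonstrate robustness to the
messiness of real crystallographic models — propeller twist, buckle,
sheared non-canonical geometries, modified nucleotides at unusual
positions, chain breaks, or low-resolution coordinate error. On real
structures the thresholds matter: the defaults are deliberately
permissive mid-range values, and the `borderline` flag exists precisely
because automated geometry cannot fully replace expert inspection.

## Numerical and design choices

* **Tie-breaks are explicit everywhere** (edge votes WC > Hoogsteen >
  Sugar; membership to the larger, then earlier helix; equal-weight
  nested sets to earlier 5′ starts; layer filling by descending
  weight), so identical inputs give byte-identical outputs; repeated
  `derive()` runs produce byte-identical JSON.
* **Bulge tolerance g = 3** nucleotides per strand is a guard rail
  only; the stacking requirement is the real gate on helix continuity.
* **Alternate locations** keep the highest-occupancy conformer (ties:
  first in file); **multi-model files** default to model 1, as
  crystallographic and cryo-EM depositions are single-model per
  assembly.
* **Modified nucleotides** map to their parent base through a packaged
  lookup (pseudouridine → U, 1-methyladenosine → A, …), since pairing
  geometry follows the parent; unrecognized residues are excluded with
  a warning.
* **Helix labels and domain schemes are user configuration** (YAML
  label → range maps; domain name/color/ranges). Canonical *E. coli*
  helix numbering and true rRNA domain boundaries are not computed —
  the packaged LSU/SSU schemes carry the conventional domain colors
  with illustrative ranges only.
* **Exact search scope**: nested-set selection is exact on every
  connected component of the crossing graph. rRNA-scale crossing graphs
  are sparse, so components stay small in practice; the oracle test
  fixes 8-helix instances where exhaustive enumeration is feasible.
* **Degenerate inputs**: empty pair lists, fully unpaired chains and
  empty structures serialize to valid (all-dots / zero-partner) output;
  residues with incomplete base rings are retained in the model but
  excluded from frame fitting and hence from pairing.
* **Problem sizes in the tests** (8-bp duplexes, 22-nt hairpins,
  ≤ 8-helix topologies, 100 oracle instances) were chosen as the
  smallest cases that exercise every rule; all suites complete in
  seconds.

## Known limitations

* Edge assignment stops at edge + orientation; the full 12-family
  classification of pairing geometries, bifurcated pairs and
  water-mediated pairs are out of scope.
* No thermodynamic scoring, co-variation analysis, or 2D map drawing —
  the outputs are pairing tables and layered annotations meant to feed
  such tools.
* DNA/RNA hybrids and crystallographic symmetry expansion are not
  handled; chains are used as deposited.
* The forced-secondary mechanism relies on user-supplied helix labels;
  nothing identifies "the" central pseudoknot automatically.
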