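# rss3d — RNA secondary structure derived from 3D coordinates

`rss3d` derives RNA secondary (2°) structure directly from
three-dimensional atomic coordinates (mmCIF or PDB) instead of from
sequence co-variation. It is aimed at structural bioinformaticians who
work with experimentally determined RNA structures — above all
ribosomal RNAs — and want 2° annotations that are consistent with the
3D model: non-canonical base pairs on parity with Watson–Crick pairs,
helices defined by geometry, and pseudoknots handled explicitly.

## The method

A base is in one of two states, paired or non-paired, and pairing is
decided geometrically. Every complete base gets a reference frame by
least-squares superposition of a standard-frame template onto its ring
atoms; residues *i*, *j* are paired when their frame origins are within
9 Å, their base planes within 65°, their mean vertical offset along the
base normals within 2.5 Å, and at least one donor–acceptor heavy-atom
contact exists at ≤ 3.5 Å (all thresholds configurable). Pairs carry a
Leontis–Westhof-style edge label (WC / Hoogsteen / Sugar), cis/trans
orientation, and a canonical flag (cis WC/WC A–U, G–C, G–U). Stacking
requires centroid distance ≤ 5.5 Å, near-parallel normals (≤ 30°) and
positive projected ring overlap.

**Helices** are base pairs forming a continuous base-paired stack
faithful to strand connectivity: consecutive pairs (i, j), (i′, j′)
must advance one strand and retreat the other (up to a bulge tolerance
*g* = 3) *and* stay stacked across the junction — a helix can contain
bulges or other defects as long as they do not break the stack. Each
nucleotide belongs uniquely to at most one helix; pairs inside helices
are **secondary** interactions, all remaining pairs **tertiary**.

Two helices with pairs (i, q) and (j, p) such that i < j < p < q are
**nested**; pairs interleaving as i′ < j′ < q′ < p′ **cross**. An exact
maximum-weight crossing-free subset of helices (weight = pair count)
becomes layer 0 of the 2° structure; the remaining non-nested helices
(pseudoknots, kissing loops) are layered so that no two helices in one
layer cross. Helix labels listed as *forced secondary* are constrained
into layer 0 regardless of weight — the convention that keeps helix 2
of the SSU central pseudoknot a secondary element. Base triples are
decomposed into pairs of base pairs via layered per-residue partner
lists, so no pairing is ever lost.

Output formats: 6-column CT, extended BPSEQ (`# TRIPLE i j` trailer
lines for partners beyond slot 0), multi-alphabet dot-bracket
(`()`, `[]`, `{}`, `<>`, `Aa`, … by pseudoknot layer), and a lossless
JSON record; rRNA domain schemes (name/color/ranges) label every
residue.

## Worked example

The package generates its own idealized A-form coordinate fixtures, so
the example needs no downloads:

```r
library(rss3d)

fx <- make_ideal_duplex("GCGCGCGC", dir = tempdir())
s <- read_structure(fx$path)
s
#> rna_structure: 16 residues in 2 chain(s)
#>   chain A: 8 nt
#>   chain B: 8 nt

head(detect_base_pairs(s)[, c("i","j","base_i","base_j","edge_i",
                              "edge_j","orientation","canonical")], 3)
#>   i  j base_i base_j edge_i edge_j orientation canonical
#> 1 1 16      G      C     WC     WC         cis      TRUE
#> 2 2 15      C      G     WC     WC         cis      TRUE
#> 3 3 14      G      C     WC     WC         cis      TRUE

res <- derive(fx$path, out_dir = tempdir(), overwrite = TRUE)
res$record
#> ss_record 'duplex_GCGCGCGC': 16 nt, 8 pairs (8 secondary, 0 tertiary), 1 helices, 1 layer(s)
```

All 8 constructed Watson–Crick pairs are recovered as canonical cis
WC/WC pairs, assembled into one helix in layer 0, and written to
CT/BPSEQ/dot-bracket/JSON alongside a run log.

The central-pseudoknot convention, on a pairing-list fixture whose
crossing helices use the SSU residue numbering:

```r
cp <- make_topology("central_pseudoknot")
h <- label_helices(assemble_helices(cp$pairs, NULL, cp$n_residues),
                   cp$labels)
classify_nesting(h)$layer                               # free selection
#> 1 2
#> 0 1
classify_nesting(h, forced_secondary = "Helix 2")$layer # convention
#> 1 2
#> 1 0
```

Unforced, the heavier helix wins layer 0 and "Helix 2" is a tertiary
pseudoknot; forcing it secondary flips the assignment.

A command-line front end is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","rss3d",package="rss3d"))') \
    derive structure.cif --out results --formats ct,dotbracket,json
```

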