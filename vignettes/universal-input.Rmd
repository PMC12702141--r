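---
title: "Universal glycan input: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Universal glycan input: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycanbabel)
```

This vignette is the package's own account of what it computes and why
the open design questions were settled the way they were. It states no
empirical result that the test suite does not itself compute.

## The data model

A glycan is a rooted directed tree. The root is the reducing-end residue
(the rightmost token of an IUPAC-condensed string); every other residue
has exactly one parent, and the child-to-parent edge carries a linkage:
anomeric configuration (`a`/`b`/`?`), donor carbon (1, or 2 for the
ulosonic acids), and one or more acceptor positions. A multi-member
acceptor set such as `{3,4}` encodes *narrow* ambiguity and is rendered
`3/4`; full ignorance is the singleton wildcard `?`. Residues known to
be present but of unknown attachment live outside the tree as floating
parts, serialized first in `{...}` and sorted alphabetically among
themselves (the source formats fix the curly-bracket convention but not
multi-part order; alphabetical is the only order that is stable under
re-parsing).

Monosaccharides carry a base token from a controlled namespace of 47
entries (`monosaccharide_table()`), with the defaults that
IUPAC-condensed leaves unwritten: D-enantiomer for most sugars but L for
Fuc, Rha, Ara and IdoA; pyranose ring; donor carbon 1 except C2 for
Neu5Ac, Neu5Gc, Neu, Kdn, Kdo and Fru. Non-default forms are explicit
(`L-Gal`, `Galf`). Positioned modifications append as
`<carbon><tag>` (`Gal6S`); unknown positions use `O` (`GalOS`) to match
the convention of the downstream ecosystem this format feeds. The
modification-tag table (`modification_tags()`) is an extensible
superset — S, P, Me, Ac, Am, Fo, Pyr, PCho, PEtn, PGro — and is not
claimed complete.

## Canonical branch ordering

Two spellings of the same branched molecule differ only in sibling
order, so a canonical form needs a total order on sibling branches. At
each node, children sort by

1. longest monosaccharide chain of the branch (residues only —
   modifications and linkage labels do not count), descending;
2. acceptor position at the branch point, ascending; integer positions
   rank strictly before `?`, and a narrow-ambiguity set ranks by its
   minimum member (the monotone extension of "integer before wildcard");
3. alphabetically: first by the minimum leaf label of the branch, then —
   if still tied — by the full serialization of the already-canonicalized
   subtree, i.e. walking down the branch, depth-first along sorted
   children, until a difference appears. Whether this walk should be
   depth-first or breadth-first is genuinely open; depth-first is chosen
   because it compares exactly the strings a reader sees, and it is
   flagged here as a potential divergence from other implementations.

Keys are computed post-order, so ties at a parent are broken against
canonical subtrees; the pass is a projection (idempotent) and invariant
under any input sibling permutation — both properties are asserted in
the suite, the latter exhaustively for nodes with up to four siblings.

One visible consequence: with equal chain lengths the *lower* acceptor
comes first, so Lewis x canonicalizes to `Fuc(a1-3)[Gal(b1-4)]GlcNAc`
rather than the Gal-first spelling many databases print. The particular
choice matters far less than its enforceability; any input order maps to
the same output.

## The common stem

All inputs — parser output or raw user strings — pass through three
normalization stages, in a fixed order, each idempotent:

* **tokens**: whitespace and trailing separators removed; Greek anomers
  and typographic dashes mapped; synonym rules applied from a plain-text
  table (`inst/extdata/normalization_rules.json`); case repaired;
  default enantiomer/ring markers dropped and non-default ones
  normalized. Synonyms and modification dialects live in the data file
  so dialect additions are data edits; linkage expansion and bracket
  disambiguation need namespace context (per-residue donor defaults) and
  balanced-bracket scanning, so they are code. One deliberate ambiguity
  resolution: `Mana-` reads as Man + α (an anomer), not the uronic acid
  ManA; case repair of uronic tokens only fires where no linkage could
  follow.
* **linkages/brackets**: CSDB-linear prefixes folded
  (`bDGalp(1-4)` → `Gal(b1-4)`), dashless and partial linkages expanded
  with residue-aware donor defaults (`Galb4` → `(b1-4)`,
  `Neu5Aca3` → `(a2-3)`), bare trailing digits read as acceptors,
  parentheses-as-branches converted to square brackets.
* **modifications/floating**: `[4S]Gal`, `6SGal`, `S-Gal`, `SGal`,
  `Gal?S` and friends land on `Gal4S`/`GalOS`; `main + residue`
  notations become floating `{...}` prefixes, with the residue-class
  default anomer (α for sialic acids, `?` otherwise) when the input
  gives none.

The stem then parses the string, errors on tokens outside the namespace
(naming them), and repairs chemical impossibilities on the tree. The
blocked-position model per parent residue: the anomeric carbon, the
ring-oxygen carbon (C5 pyranose / C4 furanose), every modified position,
and C1–C3 + C5 for sialic acids; acceptors beyond the backbone length
are likewise infeasible. Violating acceptors become `?`; narrow
ambiguity sets drop only their blocked members; when two siblings claim
one hydroxyl the *later* sibling in reading order is wildcarded —
deterministic and minimal-change, since the sources specify repair but
not victim selection. Repair never rejects.

## Parsers and their deliberate crudeness

Each foreign-format parser only produces "something resembling
IUPAC-condensed" and leaves all cleanup to the stem; that keeps parsers
a few dozen lines and makes new formats cheap to add. Format-specific
choices:

* **WURCS**: the descriptor table covers the common skeletons (hexoses,
  HexNAc, deoxyhexoses, uronic acids, pentoses, nonulosonic acids) and
  substituent codes (N-acetyl, N-glycolyl, sulfate, phosphate, methyl,
  O-acetyl); anything else raises an error naming the descriptor. The
  donor side of a link is the side sitting on its own anomeric carbon.
* **GlycoCT**: substituent residues are merged into their parents
  (n-acetyl at C2 → `GlcNAc`; at C5 of the bare nonulosonic skeleton →
  `Neu5Ac`); `UND` sections (undetermined units) are out of scope and
  rejected explicitly.
* **Oxford**: antennae fill the a1-3 arm before the a1-6 arm; G caps
  antennae in creation order (position qualifier `G(3)` honoured); S
  caps galactoses with the default wildcard `a2-?` unless qualified,
  because Oxford underdetermines sialic linkage and wildcards are the
  designated uncertainty mechanism. M6–M9 add a1-2 mannose caps in the
  order 3-arm, 6-arm/3-branch, 6-arm/6-branch, then a second 3-arm cap,
  which reproduces the standard M9 isomer; intermediate isomer choices
  are conventions, stated here once.
* **KCF**: the donor of an edge is the side bearing an anomer letter;
  the root is the node that never donates; sibling order is taken from
  drawing coordinates and then overridden by canonicalization anyway.
* **GWS (GlycoWorkbench)**: branch groups in parentheses attach to the
  residue *preceding* the group, as in real GlycoWorkbench exports;
  `$...` settings suffixes are stripped; `freeEnd`/`redEnd` anchors are
  dropped.
* **GLYCAM**: `-OH` termini vanish; `-OME` is kept as a reducing-end
  annotation (`-OMe`) rather than silently dropped, since it records a
  real chemical difference.

## Compositions

`H5N4F1A2`, `Hex5HexNAc4Fuc1Neu5Ac2` and
`(Hex)3 (HexNAc)1 ... + (Man)3(GlcNAc)2` parse to one count multiset
over the classes Hex, HexNAc, dHex, Neu5Ac, Neu5Gc, Pen, HexA, Kdn, S,
P, Me, Ac (Fuc folds to dHex; Man/GlcNAc in a `+` appendix fold to
Hex/HexNAc). The letter `S` collides between sialic acid and sulfate
across dialects; it resolves to Neu5Ac when the same string uses H/N/F
letters and to sulfate otherwise — a deterministic rule rather than a
guess, documented so users of sulfo-glycomics letter codes know to spell
out `Neu5Ac`/`Sul`. Serialization uses a fixed class order, making it
injective (brute-force checked in the suite). Detection requires a count
digit, so bare residue names stay sequences.

## The fixture corpus and what green tests establish

No external databases are bundled. Instead, 60 curated real glycans
(milk oligosaccharides, Lewis/blood-group antigens, O-glycan cores,
gangliosides, N-glycans, GAG fragments) are stored in rule-canonical
form and *re-encoded programmatically* into WURCS, GlycoCT, LinearCode,
GLYCAM, KCF, IUPAC-extended and GWS, plus seeded IUPAC dialect variants
and an enumerated Oxford set — 539 records across 9 nomenclatures, all
required to re-canonicalize to their recorded string exactly.

Because the encoders live in this package, encoder/parser convergence
alone cannot catch a shared misreading of a format; that risk is covered
separately by hand-derived frozen fixtures for each format (worked out
from the formats' public definitions — no reference converter is
available in this environment). The corpus does establish: hook
detection priority is total on realistic strings, every parser survives
its own format's structures, the stem is idempotent, and canonical
strings are stable end to end. It does not establish coverage of the
long tail of rare residues, repeat units, or GlycoCT `UND`/WURCS
ambiguous-site syntax, all explicitly out of scope.

The dialect-variant generator inverts individual stem rules (dropping
parentheses or donor carbons, Greek letters, synonym swaps, branch
permutation, bracket-style changes, whitespace, case mangling) under a
seed, refusing rewrites that would create genuine ambiguity (e.g.
uppercasing `Glc(a1-4)` into the GlcA-ambiguous `GLCA4`). Defaults —
one to two composed rewrites per variant — emulate the typo density of
hand-curated supplementary tables; the generator does not emulate
semantic errors (wrong residues), only notational variance.

## Numerical and degenerate-input choices

Positions are 1-based carbon numbers throughout. Parsing is
deterministic with no tolerances anywhere; ties in branch ordering are
broken by the three-level key and nothing else, and label-isomorphic
siblings keep input order (their order is unobservable). Empty input,
unbalanced brackets (reported with the offending index), unknown tokens
(reported verbatim) and cyclic edge sets are errors; chemically
impossible linkages are repaired instead. Batch conversion isolates
records: one bad record yields one error row, never an abort.

## Known limitations

* The WURCS/GlycoCT vocabularies cover common residues only; rare
  tokens error out by design rather than guessing.
* CSDB-linear is folded in by the stem (no dedicated parser), so CSDB
  constructs far from IUPAC — repeat units, SMILES substituents — are
  unsupported.
* GlyTouCan/GlyConnect accession resolution needs a network and is out
  of scope, as are SMILES output, drawing, and mass calculation.
* Semantic validation beyond the occupancy model (e.g. biosynthetic
  plausibility) is not attempted.
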