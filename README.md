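# glycanbabel

Universal glycan input for R: detect, parse, repair and canonicalize any
common glycan nomenclature into one unique IUPAC-condensed string per
molecule.

## The problem

Glycobiology fragments across representation systems. Experimentalists
annotate N-glycans in Oxford shorthand (`FA2G2S2`) or loose
IUPAC-condensed dialects (`Galb4Glc`); databases and computational tools
speak WURCS 2.0, GlycoCT, LinearCode, KCF or GlycoWorkbench; structural
modelers use GLYCAM; mass spectrometrists report monosaccharide
compositions (`H5N4F1A2`). Even within IUPAC-condensed, one molecule has
many spellings — `Gal(b1-4)Glc`, `Galb1-4Glc` and `Galb4Glc` all mean
lactose, and a branched glycan can list its branches in any order.

`glycanbabel` takes a bare string in any of these languages — no format
declaration needed — and emits a *canonicalized IUPAC-condensed* string:
residue tokens drawn from a controlled namespace with implicit defaults
(D-enantiomer and pyranose omitted, L noted for Fuc/Rha/Ara/IdoA),
linkages written `(anomer donor-acceptor)` with `?` wildcards for
uncertainty, branches in square brackets, floating residues of unknown
attachment in curly brackets, and *one deterministic branch order*.

## The core algorithm

The pipeline has four stages:

1. **Detection** — string hooks (`WURCS=` prefix, `RES`/`LIN` sections,
   `NODE`/`EDGE` blocks, `freeEnd--` chains, `-OH` termini, arrow
   linkages, the LinearCode and Oxford grammars, composition patterns)
   pick the parser; a constant-time common-name dictionary resolves
   trivia like `LacNAc`; SMILES-like input is rejected with a clear
   error. Unhooked strings fall through to the IUPAC/CSDB path.
2. **Rudimentary parsers** — each foreign format is reduced to "anything
   resembling IUPAC-condensed"; all cleanup is deferred.
3. **Common stem** — an ordered rule set homogenizes token synonyms
   (`NeuAc→Neu5Ac`, `β→b`), case, enantiomer/ring markers, dashless and
   wildcard linkages, bracket conventions, modification dialects
   (`[4S]Gal`, `SGal`, `Gal?S` → `Gal4S`/`GalOS`) and floating-residue
   notations; then a chemical-feasibility pass replaces impossible
   acceptor positions (occupied, blocked by the ring or a modification,
   or duplicated among siblings) with `?` wildcards — repairs, never
   rejections.
4. **Branch canonicalization** — the glycan is a rooted tree (root =
   reducing end). At every node, post-order, siblings sort by
   (i) longest monosaccharide chain, descending; (ii) acceptor position,
   ascending, integers before wildcards; (iii) minimum leaf label, then
   the serialized subtree, alphabetically. The first-sorted child
   continues the main chain; the result is the unique string for that
   molecule, invariant under any input branch order.

## Worked example

```r
library(glycanbabel)
canonicalize_glycan("Galb4Glc")
#> [1] "Gal(b1-4)Glc"
canonicalize_glycan("NeuAca3Galb1-4[Fuca3]GlcNAc")   # sialyl-Lewis x, typo dialect
#> [1] "Neu5Ac(a2-3)Gal(b1-4)[Fuc(a1-3)]GlcNAc"
canonicalize_glycan("FA2G2S2")                       # Oxford N-glycan code
#> [1] "Neu5Ac(a2-?)Gal(b1-4)GlcNAc(b1-2)Man(a1-3)[Neu5Ac(a2-?)Gal(b1-4)GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)[Fuc(a1-6)]GlcNAc"
canonicalize_glycan("lacnac")                        # common name, case/space-blind
#> [1] "Gal(b1-4)GlcNAc"
canonicalize_glycan("H5N4F1A2")                      # MS composition
#> [1] "Hex5HexNAc4dHex1Neu5Ac2"
```

The Oxford expansion reads: a biantennary N-glycan on the invariant
Man3GlcNAc2 core, both antennae galactosylated and sialylated (linkage
unspecified, hence `a2-?`), with a core fucose. Mixed batches work
record-by-record and never abort:

```r
txt <- paste("Galb4Glc",
             "WURCS=2.0/2,2,1/[a2122h-1x_1-5][a2112h-1b_1-5]/1-2/a4-b1",
             "Ab4GN;", sep = "\n")
convert_batch(txt)
#>       input                      detected      canonical       status message
#> 1  Galb4Glc                      IUPAC_OR_CSDB Gal(b1-4)Glc    ok
#> 2  WURCS=2.0/2,2,1/[a2122h-...]  WURCS         Gal(b1-4)Glc    ok
#> 3  Ab4GN;                        LINEARCODE    Gal(b1-4)GlcNAc ok
```

All three records converge on the same molecules: the dialect string and
the WURCS encoding are both lactose, and the LinearCode string is
N-acetyllactosamine.

Any existing function gains universal input with one adapter:

```r
first_residue <- rescue_glycans(function(g) sub("\\(.*$", "", g))
first_residue("Galb4Glc")   # "Gal"
```

A batch CLI ships in `inst/cli/glycan-babel`
(`glycan-babel convert input.txt --out tsv`), and
`generate_dialect_variants()` / `build_fixture_corpus()` produce the
seeded test fixtures (539 records across 9 nomenclatures) used by the
suite.

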