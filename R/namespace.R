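# Controlled monosaccharide namespace and modification vocabulary.
#
# Every residue token the package understands lives in one table, together
# with the defaults that IUPAC-condensed leaves implicit: enantiomer (D for
# most sugars, L for Fuc/Rha/Ara/IdoA), ring size (pyranose), and the donor
# (anomeric) carbon used when a linkage omits it (C1, except C2 for the
# ulosonic acids Neu5Ac/Neu5Gc/Kdn/Kdo and the ketose Fru).

.gb_cache <- new.env(parent = emptyenv())

#' Monosaccharide namespace table
#'
#' Returns the controlled vocabulary of residue base tokens with their
#' implicit defaults. Non-default forms carry explicit markers in the
#' canonical string (`L-Gal`, `Galf`); default forms are written bare.
#'
#' @return A data.frame with one row per base token and columns
#'   `base` (token), `enantiomer` (default, `"D"`, `"L"` or `"?"`),
#'   `ring` (default ring, `"p"` or `"f"`), `donor` (default anomeric
#'   carbon, 1 or 2), `carbons` (backbone length; acceptor positions above
#'   it are chemically impossible), `sialic` (ulosonic-acid flag driving
#'   the blocked-position model), `anomer` (default anomeric configuration
#'   used only when rescuing floating residues; `"?"` when unknown) and
#'   `comp_class` (composition class the residue folds into).
#' @export
monosaccharide_table <- function() {
  if (!is.null(.gb_cache$mono_table)) return(.gb_cache$mono_table)
  r <- function(base, en = "D", ring = "p", donor = 1L, carbons = 6L,
                sialic = FALSE, anomer = "?", comp = "Hex") {
    data.frame(base = base, enantiomer = en, ring = ring, donor = donor,
               carbons = carbons, sialic = sialic, anomer = anomer,
               comp_class = comp, stringsAsFactors = FALSE)
  }
  tab <- rbind(
    # hexoses
    r("Glc"), r("Gal"), r("Man"), r("All"), r("Alt"), r("Gul"),
    r("Ido"), r("Tal"), r("Hex"),
    # N-acetylhexosamines
    r("GlcNAc", comp = "HexNAc"), r("GalNAc", comp = "HexNAc"),
    r("ManNAc", comp = "HexNAc"), r("HexNAc", comp = "HexNAc"),
    # hexosamines
    r("GlcN", comp = "Other"), r("GalN", comp = "Other"),
    r("ManN", comp = "Other"), r("HexN", comp = "Other"),
    r("GlcNS", comp = "Other"),
    # uronic acids
    r("GlcA", comp = "HexA"), r("GalA", comp = "HexA"),
    r("ManA", comp = "HexA"), r("GulA", comp = "HexA"),
    r("IdoA", en = "L", comp = "HexA"), r("HexA", comp = "HexA"),
    # deoxyhexoses
    r("Fuc", en = "L", comp = "dHex"), r("Rha", en = "L", comp = "dHex"),
    r("Qui", comp = "dHex"), r("dHex", comp = "dHex"),
    r("FucNAc", en = "L", comp = "Other"), r("QuiNAc", comp = "Other"),
    # pentoses
    r("Xyl", carbons = 5L, comp = "Pen"),
    r("Ara", en = "L", carbons = 5L, comp = "Pen"),
    r("Rib", carbons = 5L, comp = "Pen"),
    r("Lyx", carbons = 5L, comp = "Pen"),
    r("Pen", carbons = 5L, comp = "Pen"),
    r("Api", carbons = 5L, comp = "Other"),
    # sialic / ulosonic acids (anomeric carbon 2, 8-9 backbone carbons)
    r("Neu5Ac", donor = 2L, carbons = 9L, sialic = TRUE, anomer = "a",
      comp = "Neu5Ac"),
    r("Neu5Gc", donor = 2L, carbons = 9L, sialic = TRUE, anomer = "a",
      comp = "Neu5Gc"),
    r("Neu", donor = 2L, carbons = 9L, sialic = TRUE, anomer = "a",
      comp = "Other"),
    r("Kdn", donor = 2L, carbons = 9L, sialic = TRUE, anomer = "a",
      comp = "Kdn"),
    r("Kdo", donor = 2L, carbons = 8L, sialic = TRUE, anomer = "a",
      comp = "Other"),
    # ketose
    r("Fru", donor = 2L, comp = "Other"),
    # heptoses
    r("Hep", carbons = 7L, comp = "Other"),
    r("LDmanHep", carbons = 7L, comp = "Other"),
    r("DDmanHep", carbons = 7L, comp = "Other"),
    # bacterial / rare
    r("MurNAc", comp = "Other"), r("Bac", comp = "Other"),
    # wildcard monosaccharide
    r("Mon", en = "?", comp = "Other")
  )
  .gb_cache$mono_table <- tab
  tab
}

#' @keywords internal
mono_row <- function(base) {
  tab <- monosaccharide_table()
  i <- match(base, tab$base)
  if (is.na(i)) stop("unknown monosaccharide token: '", base, "'",
                     call. = FALSE)
  tab[i, ]
}

#' @keywords internal
is_known_base <- function(base) base %in% monosaccharide_table()$base

# longest-first alternation so GlcNAc wins over Glc, Neu5Ac over Neu
#' @keywords internal
base_alternation <- function() {
  if (!is.null(.gb_cache$base_alt)) return(.gb_cache$base_alt)
  b <- monosaccharide_table()$base
  b <- b[order(-nchar(b), b)]
  .gb_cache$base_alt <- paste(b, collapse = "|")
  .gb_cache$base_alt
}

#' Modification tag vocabulary
#'
#' Positioned modification tags written after their carbon number
#' (`Gal6S`) or after `O` when the position is unknown (`GalOS`). The set
#' is an extensible superset of the tags commonly seen in glycomics data;
#' it is not claimed complete.
#'
#' @return Character vector of tags, longest first.
#' @export
modification_tags <- function() {
  c("PCho", "PEtn", "PGro", "Pyr", "Ac", "Am", "Fo", "Me", "S", "P")
}

#' @keywords internal
tag_alternation <- function() paste(modification_tags(), collapse = "|")

#' @keywords internal
default_donor <- function(base) {
  if (!is_known_base(base)) return(1L)
  mono_row(base)$donor
}

#' @keywords internal
default_anomer <- function(base) {
  if (!is_known_base(base)) return("?")
  mono_row(base)$anomer
}
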