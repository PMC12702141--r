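# The bundled fixture corpus: curated real-world glycans (milk
# oligosaccharides, Lewis/blood-group antigens, O-glycan cores,
# gangliosides, N-glycans, GAG and bacterial fragments) written in
# canonical IUPAC-condensed over the residue subset every encoder
# supports. Each glycan is re-encoded in every foreign nomenclature and
# as seeded IUPAC dialect variants; re-canonicalization must recover the
# curated string exactly -- that equality IS the corpus test.

#' Curated corpus of canonical glycans
#'
#' @return Character vector of canonical IUPAC-condensed strings.
#' @export
glycan_corpus <- function() {
  c(
    # disaccharides and simple chains
    "Gal(b1-4)Glc",
    "Gal(b1-4)GlcNAc",
    "Gal(b1-3)GlcNAc",
    "GlcNAc(b1-4)GlcNAc",
    "Man",
    "Glc(a1-4)Glc",
    "Glc(b1-4)Glc",
    "Glc(b1-6)Glc",
    "Gal(a1-6)Glc",
    "GalNAc(b1-4)GlcNAc",
    "ManNAc(b1-4)GlcNAc",
    "Rha(a1-2)Glc",
    "Rha(a1-6)Glc",
    "Man(a1-6)Man",
    "Neu5Ac(a2-8)Neu5Ac",
    "Neu5Ac(a2-6)GalNAc",
    # milk oligosaccharides and sialylated/fucosylated lactose
    "Neu5Ac(a2-3)Gal(b1-4)Glc",
    "Neu5Ac(a2-6)Gal(b1-4)Glc",
    "Fuc(a1-2)Gal(b1-4)Glc",
    "Fuc(a1-3)[Gal(b1-4)]Glc",
    "Gal(b1-3)GlcNAc(b1-3)Gal(b1-4)Glc",
    "Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)Glc",
    "Fuc(a1-2)Gal(b1-3)GlcNAc(b1-3)Gal(b1-4)Glc",
    "Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)GlcNAc",
    # Lewis and blood-group antigens
    "Fuc(a1-3)[Gal(b1-4)]GlcNAc",
    "Gal(b1-3)[Fuc(a1-4)]GlcNAc",
    "Neu5Ac(a2-3)Gal(b1-4)[Fuc(a1-3)]GlcNAc",
    "Neu5Ac(a2-3)Gal(b1-3)[Fuc(a1-4)]GlcNAc",
    "Fuc(a1-2)[GalNAc(a1-3)]Gal",
    "Fuc(a1-2)[Gal(a1-3)]Gal",
    "Gal(a1-3)Gal(b1-4)GlcNAc",
    "Gal(a1-4)Gal(b1-4)Glc",
    # O-glycan cores and extensions
    "Gal(b1-3)GalNAc",
    "Gal(b1-3)[GlcNAc(b1-6)]GalNAc",
    "GlcNAc(b1-3)GalNAc",
    "GlcNAc(b1-3)[GlcNAc(b1-6)]GalNAc",
    "Neu5Ac(a2-3)Gal(b1-3)GalNAc",
    "Gal(b1-3)[Neu5Ac(a2-6)]GalNAc",
    "Neu5Ac(a2-3)Gal(b1-3)[Neu5Ac(a2-6)]GalNAc",
    "Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-6)[Neu5Ac(a2-3)Gal(b1-3)]GalNAc",
    # ganglioside glycans
    "Neu5Ac(a2-3)[GalNAc(b1-4)]Gal(b1-4)Glc",
    "Gal(b1-3)GalNAc(b1-4)[Neu5Ac(a2-3)]Gal(b1-4)Glc",
    "Neu5Ac(a2-8)Neu5Ac(a2-3)Gal(b1-4)Glc",
    "Neu5Ac(a2-3)Gal(b1-3)GalNAc(b1-4)[Neu5Ac(a2-3)]Gal(b1-4)Glc",
    # N-glycans
    "Man(a1-3)[Man(a1-6)]Man",
    "Man(a1-3)[Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc",
    "Man(a1-3)[Man(a1-6)]Man(a1-6)[Man(a1-3)]Man(b1-4)GlcNAc(b1-4)GlcNAc",
    "GlcNAc(b1-2)Man(a1-3)[GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc",
    "GlcNAc(b1-2)Man(a1-3)[GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)[Fuc(a1-6)]GlcNAc",
    "Gal(b1-4)GlcNAc(b1-2)Man(a1-3)[Gal(b1-4)GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc",
    "Neu5Ac(a2-6)Gal(b1-4)GlcNAc(b1-2)Man(a1-3)[Neu5Ac(a2-6)Gal(b1-4)GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc",
    "Man(a1-2)Man(a1-2)Man(a1-3)Man",
    "Man(a1-2)Man(a1-3)[Man(a1-2)Man(a1-6)]Man",
    "Xyl(b1-2)[Man(a1-3)][Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc",
    # GAG-related and acidic fragments
    "GlcA(b1-3)GlcNAc",
    "GlcA(b1-3)Gal(b1-3)Gal(b1-4)Xyl",
    "IdoA(a1-3)GalNAc",
    "GlcA(b1-3)GalNAc",
    # sialic-acid diversity
    "Neu5Gc(a2-3)Gal(b1-4)GlcNAc",
    "Kdn(a2-3)Gal(b1-4)GlcNAc"
  )
}

#' Additional modified-residue corpus (stem-only fixtures)
#'
#' Sulfated/phosphorylated/acetylated cases exercised through the stem
#' and the WURCS/GlycoCT/KCF encoders, but outside the LinearCode/GLYCAM
#' alphabets.
#' @return Character vector of canonical IUPAC-condensed strings.
#' @export
glycan_corpus_modified <- function() {
  c("Gal6S(b1-4)GlcNAc",
    "Gal4S(b1-4)GlcNAc6S",
    "GlcA(b1-3)GalNAc4S",
    "Man6P(a1-2)Man",
    "Neu5Ac9Ac(a2-3)Gal(b1-4)Glc",
    "GalOS(b1-4)GlcNAc")
}

#' Oxford code corpus
#'
#' Enumerates Oxford N-glycan shorthand strings over M3/M5-M9 and
#' F/A/B/G/S combinations.
#'
#' @param n Maximum number of codes.
#' @return Character vector of Oxford codes.
#' @export
oxford_corpus <- function(n = 60L) {
  out <- c("M3", "M5", "M6", "M7", "M8", "M9")
  for (f in c("", "F")) {
    for (b in c("", "B")) {
      for (a in 1:4) {
        for (g in 0:a) {
          for (s in 0:g) {
            out <- c(out, paste0(
              f, "A", a, b,
              if (g > 0) paste0("G", g) else "",
              if (s > 0) paste0("S", s) else ""))
          }
        }
      }
    }
  }
  out <- c(out, "FA2G(3)2", "A2G2S(6)2", "FA2G2S(3)1")
  unique(out)[seq_len(min(n, length(unique(out))))]
}

#' Build the cross-nomenclature fixture corpus
#'
#' Every curated glycan is encoded in each foreign nomenclature the
#' encoders support, plus seeded IUPAC dialect variants; Oxford codes are
#' appended as their own nomenclature. The invariant that every variant
#' re-canonicalizes to its recorded canonical string is the corpus test.
#'
#' @param seed Integer seed for the dialect-variant generator.
#' @param variants_per_glycan Number of IUPAC dialect variants per glycan.
#' @return A data.frame with columns `canonical`, `variant`, `kind`.
#' @export
build_fixture_corpus <- function(seed = 1L, variants_per_glycan = 1L) {
  encoders <- list(WURCS = encode_wurcs, GLYCOCT = encode_glycoct,
                   LINEARCODE = encode_linearcode, GLYCAM = encode_glycam,
                   KCF = encode_kcf, IUPAC_EXTENDED = encode_iupac_extended,
                   GWS = encode_gws)
  rows <- list()
  add <- function(canonical, variant, kind) {
    rows[[length(rows) + 1L]] <<- data.frame(
      canonical = canonical, variant = variant, kind = kind,
      stringsAsFactors = FALSE)
  }
  corpus <- glycan_corpus()
  for (i in seq_along(corpus)) {
    g <- corpus[i]
    for (kind in names(encoders)) {
      # a bare LinearCode letter ("M") offers no detection hook; the
      # universal entry point cannot be expected to recognize it
      if (kind == "LINEARCODE" && !grepl("(", g, fixed = TRUE)) next
      variant <- encoders[[kind]](g)
      # a linkage-free extended name ("D-Manp") carries no arrow hook and
      # is authored knowing it resolves through the CSDB/IUPAC fall-through
      label <- if (kind == "IUPAC_EXTENDED" &&
                     !grepl("→", variant)) "IUPAC_OR_CSDB" else kind
      add(g, variant, label)
    }
    for (v in generate_dialect_variants(g, seed + i, variants_per_glycan)) {
      add(g, v, "IUPAC_OR_CSDB")
    }
  }
  for (code in oxford_corpus()) {
    add(canonicalize_glycan(code), code, "OXFORD")
  }
  do.call(rbind, rows)
}
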