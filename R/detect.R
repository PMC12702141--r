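# Nomenclature detection: identify the input language from string "hooks"
# and dispatch to the right parser. Detection never throws; strings that
# match no hook fall through to IUPAC_OR_CSDB (the common stem handles
# both). Hooks are checked in a fixed priority order: common names, block
# formats (GlycoCT, KCF), prefixed formats (WURCS, GWS), suffixed
# (GLYCAM), IUPAC-extended, LinearCode, Oxford, compositions, fall-through.

#' Nomenclature kinds
#'
#' The tags [detect_nomenclature()] can return.
#' @return Character vector of kind names.
#' @export
nomenclature_kinds <- function() {
  c("WURCS", "GLYCOCT", "LINEARCODE", "GLYCAM", "OXFORD", "KCF",
    "IUPAC_EXTENDED", "GWS", "IUPAC_OR_CSDB", "COMMON_NAME", "COMPOSITION",
    "UNSUPPORTED")
}

#' @keywords internal
common_name_dict <- function() {
  if (!is.null(.gb_cache$common_names)) return(.gb_cache$common_names)
  path <- system.file("extdata", "common_names.json",
                      package = "glycanbabel")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "common_names.json")
  .gb_cache$common_names <- jsonlite::fromJSON(path)
  .gb_cache$common_names
}

#' @keywords internal
name_key <- function(s) gsub("[^a-z0-9]", "", tolower(s))

#' Resolve a glycan common name
#'
#' Constant-time dictionary lookup, ignoring capitalization, whitespace
#' and punctuation ("lac nac" resolves like "LacNAc").
#'
#' @param s A candidate common name.
#' @return The IUPAC-condensed string, or `NULL` when the name is absent.
#' @export
lookup_common_name <- function(s) {
  dict <- common_name_dict()
  hit <- dict[[name_key(s)]]
  if (is.null(hit)) NULL else hit
}

#' Detect the nomenclature of a glycan string
#'
#' @param s A raw glycan string (single- or multi-line).
#' @return One of [nomenclature_kinds()]. `IUPAC_OR_CSDB` is the
#'   fall-through default; misdetections surface as parse errors
#'   downstream, never as exceptions here.
#' @export
detect_nomenclature <- function(s) {
  s <- sub("^\\s+|\\s+$", "", s)
  if (!nzchar(s)) return("UNSUPPORTED")
  if (!is.null(lookup_common_name(s))) return("COMMON_NAME")
  # block formats
  if (grepl("(^|\\n)\\s*RES\\s*(\\n|$)", s) &&
      grepl("(^|\\n)\\s*\\d+[bs]:", s)) {
    return("GLYCOCT")
  }
  if (grepl("(^|\\n)\\s*NODE\\b", s) && grepl("(^|\\n)\\s*EDGE\\b", s)) {
    return("KCF")
  }
  # prefixed formats
  if (startsWith(s, "WURCS=")) return("WURCS")
  if (grepl("freeEnd|redEnd", s) ||
      (grepl("--", s, fixed = TRUE) && grepl(",[pf?]", s))) {
    return("GWS")
  }
  # suffixed: GLYCAM terminates in an aglycon and uses [DL]<stem>[pf] tokens
  if (grepl("-(OH|OME|OMe|OtBu)$", s) &&
      grepl("[DL][A-Z][a-z]+[pf]", s)) {
    return("GLYCAM")
  }
  # IUPAC-extended: arrow linkages with fully qualified residue names
  if (grepl("→", s) ||
      (grepl("-\\(\\d-?>?\\d?", s) && grepl("[abαβ]-[DL]-", s)) ||
      grepl("^[αβ]-[DL]-", s)) {
    return("IUPAC_EXTENDED")
  }
  # LinearCode: bare capital residue codes + inline anomer/position
  if (grepl("^[A-Z]{1,2}[ab?][1-9?]", s) &&
      grepl("^[A-Z0-9ab?();\\[\\]]+$", s, perl = TRUE)) {
    return("LINEARCODE")
  }
  # Oxford: N-glycan shorthand over the F/A/B/G/S/M alphabet
  if (grepl("^F?(\\(\\d\\))?(A\\d|B|G(\\(\\d\\))?\\d|S(\\(\\d\\))?\\d|M\\d)+$",
            s) || grepl("^(F(\\(\\d\\))?)?M\\d$", s)) {
    return("OXFORD")
  }
  if (detect_composition(s)) return("COMPOSITION")
  "IUPAC_OR_CSDB"
}

#' Reject unsupported molecular languages
#'
#' Called on strings that fell through to `IUPAC_OR_CSDB`; raises a
#' descriptive error for SMILES-like strings (stereo markers `@`,
#' carbonyl `=O`, ring-closure digits on lowercase aromatic atoms) and
#' for empty input. Returns silently otherwise.
#'
#' @param s A glycan string.
#' @return Invisibly `TRUE`; or an error naming the suspected language.
#' @export
check_nomenclature <- function(s) {
  s <- sub("^\\s+|\\s+$", "", s)
  if (!nzchar(s)) stop("empty glycan input", call. = FALSE)
  looks_smiles <- grepl("@", s, fixed = TRUE) ||
    grepl("=O", s, fixed = TRUE) ||
    grepl("[cnos]1.*[cnos1]", s) &&
      grepl("^[A-Za-z0-9@\\[\\]()=#+/\\\\-]+$", s, perl = TRUE) &&
      !grepl("[ab?][12?]-", s)
  if (looks_smiles) {
    stop("unsupported nomenclature: input looks like SMILES, which is not ",
         "a glycan sequence format", call. = FALSE)
  }
  invisible(TRUE)
}
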