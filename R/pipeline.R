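# Orchestration: one entry point from any nomenclature to the canonical
# IUPAC-condensed string -- common-name lookup, hook detection, dedicated
# parser, common stem, tree, branch canonicalization. Compositions are
# routed to the composition handler. Plus the rescue adapter and the
# batch interface used by the CLI.

#' Canonicalize any glycan string
#'
#' Universal input: detects the nomenclature of `s` (WURCS, GlycoCT,
#' LinearCode, GLYCAM, Oxford, KCF, IUPAC-extended, GlycoWorkbench,
#' common names, compositions, or any IUPAC-condensed/CSDB dialect) and
#' returns the unique canonicalized IUPAC-condensed representation.
#' Deterministic and idempotent; compositions come back in canonical
#' composition form.
#'
#' @param s A single glycan string (block formats may contain newlines).
#' @return The canonical string.
#' @export
#' @examples
#' canonicalize_glycan("Galb4Glc")
#' canonicalize_glycan("WURCS=2.0/2,2,1/[a2122h-1x_1-5][a2112h-1b_1-5]/1-2/a4-b1")
#' canonicalize_glycan("LacNAc")
#' canonicalize_glycan("H5N4F1A2")
canonicalize_glycan <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  s <- sub("^\\s+|\\s+$", "", s)
  if (!nzchar(s)) stop("empty glycan input", call. = FALSE)
  hit <- lookup_common_name(s)
  if (!is.null(hit)) s <- hit
  kind <- detect_nomenclature(s)
  raw <- switch(
    kind,
    WURCS = parse_wurcs(s),
    GLYCOCT = parse_glycoct(s),
    KCF = parse_kcf(s),
    LINEARCODE = parse_linearcode(s),
    GLYCAM = parse_glycam(s),
    OXFORD = parse_oxford(s),
    IUPAC_EXTENDED = parse_iupac_extended(s),
    GWS = parse_gws(s),
    COMPOSITION = return(composition_to_string(parse_composition(s))),
    UNSUPPORTED = stop("empty or unsupported glycan input", call. = FALSE),
    { check_nomenclature(s); s }  # IUPAC_OR_CSDB / COMMON_NAME fall-through
  )
  canonical_string(parse_iupac_to_tree(common_stem(raw)))
}

#' Equip a function with universal glycan input
#'
#' Returns a function identical to `f` except that every character
#' argument (scalar or vector) is passed through [canonicalize_glycan()]
#' -- or [parse_composition()] / [composition_to_string()] when
#' `composition = TRUE` -- before `f` sees it. Non-character arguments
#' are untouched; canonicalization errors are annotated with the
#' offending argument index.
#'
#' @param f A function taking glycan strings (or vectors of them).
#' @param composition Canonicalize compositions instead of sequences.
#' @return The adapted function.
#' @export
#' @examples
#' first_residue <- rescue_glycans(function(g) sub("\\(.*$", "", g))
#' first_residue("Galb4Glc")  # "Gal"
rescue_glycans <- function(f, composition = FALSE) {
  stopifnot(is.function(f))
  fix_one <- function(x) {
    if (composition) composition_to_string(parse_composition(x))
    else canonicalize_glycan(x)
  }
  function(...) {
    args <- list(...)
    for (i in seq_along(args)) {
      if (is.character(args[[i]])) {
        args[[i]] <- vapply(args[[i]], function(x) {
          tryCatch(fix_one(x), error = function(e) {
            stop("argument ", i, ": ", conditionMessage(e), call. = FALSE)
          })
        }, character(1), USE.NAMES = FALSE)
      }
    }
    do.call(f, args)
  }
}

#' @rdname rescue_glycans
#' @export
rescue_compositions <- function(f) rescue_glycans(f, composition = TRUE)

# ---- batch interface --------------------------------------------------------

#' Split batch text into records
#'
#' Single-line formats are one record per line; multi-line block formats
#' (GlycoCT, KCF) are blank-line-delimited blocks kept as one record.
#'
#' @param text Full input text (one string, possibly with newlines).
#' @return Character vector of records.
#' @export
split_records <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  blocks <- list()
  cur <- character(0)
  for (ln in c(lines, "")) {
    if (!nzchar(trimws(ln))) {
      if (length(cur)) blocks <- c(blocks, list(cur))
      cur <- character(0)
    } else {
      cur <- c(cur, ln)
    }
  }
  unlist(lapply(blocks, function(b) {
    if (length(b) == 1L) return(b)
    # a block is one record if it is a block format, else line records
    blk <- paste(b, collapse = "\n")
    if (detect_nomenclature(blk) %in% c("GLYCOCT", "KCF")) blk else b
  }))
}

#' Convert a batch of glycan records
#'
#' Errors never abort the batch; each record carries its own status.
#'
#' @param text Input text (string with newlines, or character vector of
#'   records).
#' @param format `"auto"` (hook detection) or a fixed nomenclature name
#'   (lower-case kind, e.g. `"wurcs"`).
#' @param compositions Force composition mode for all records.
#' @return A data.frame with columns `input`, `detected`, `canonical`,
#'   `status` (`"ok"`/`"error"`) and `message`.
#' @export
convert_batch <- function(text, format = "auto", compositions = FALSE) {
  records <- if (length(text) > 1L) text else split_records(text)
  parsers <- list(wurcs = parse_wurcs, glycoct = parse_glycoct,
                  kcf = parse_kcf, linearcode = parse_linearcode,
                  glycam = parse_glycam, oxford = parse_oxford,
                  iupac_extended = parse_iupac_extended, gws = parse_gws)
  one <- function(rec) {
    detected <- detect_nomenclature(rec)
    out <- tryCatch({
      canonical <-
        if (compositions) {
          composition_to_string(parse_composition(rec))
        } else if (format == "auto") {
          canonicalize_glycan(rec)
        } else if (format %in% names(parsers)) {
          canonical_string(parse_iupac_to_tree(common_stem(
            parsers[[format]](rec))))
        } else if (format %in% c("iupac", "csdb")) {
          canonical_string(parse_iupac_to_tree(common_stem(rec)))
        } else {
          stop("unknown --format value '", format, "'", call. = FALSE)
        }
      list(canonical = canonical, status = "ok", message = "")
    }, error = function(e) {
      list(canonical = NA_character_, status = "error",
           message = conditionMessage(e))
    })
    data.frame(input = gsub("\n", "\\\\n", rec), detected = detected,
               canonical = out$canonical, status = out$status,
               message = out$message, stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(records, one))
}

# ---- dialect-variant generator ---------------------------------------------

#' @keywords internal
gt_shuffle_children <- function(t) {
  for (i in seq_along(t$children)) {
    k <- t$children[[i]]
    if (length(k) > 1L) t$children[[i]] <- sample(k)
  }
  t
}

#' Generate dialect variants of a canonical string
#'
#' Reproducibly (seeded) emits `n` distinct strings by composing inverse
#' rewrites of the normalization rules: dropped parentheses/dashes/donor
#' carbons, `NeuAc`-style synonyms, Greek anomeric letters, permuted
#' sibling branches, parenthesis-style branches, prefix-style
#' modifications, inserted whitespace, case mangling. Every variant
#' canonicalizes back to `canonical`.
#'
#' @param canonical A valid canonical IUPAC-condensed string.
#' @param seed Integer seed.
#' @param n Number of variants (>= 1).
#' @return Character vector of `n` distinct variant strings.
#' @export
generate_dialect_variants <- function(canonical, seed, n) {
  stopifnot(n >= 1L)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)

  rewrites <- list(
    drop_parens = function(s) {
      gsub("\\(([ab?])([12?])-([1-9?])\\)", "\\1\\2-\\3", s, perl = TRUE)
    },
    drop_dash = function(s) {
      gsub("\\(([ab])[12]-([1-9])\\)", "\\1\\2", s, perl = TRUE)
    },
    greek = function(s) {
      s <- gsub("(\\(|^|\\b)b([12?]-)", "\\1β\\2", s, perl = TRUE)
      gsub("(\\(|^|\\b)a([12?]-)", "\\1α\\2", s, perl = TRUE)
    },
    synonyms = function(s) gsub("Neu5Ac", "NeuAc", s, fixed = TRUE),
    spaces = function(s) gsub(")", ") ", s, fixed = TRUE),
    semicolon = function(s) paste0(s, ";"),
    paren_branches = function(s) {
      chartr("[]", "()", s)
    },
    upper = function(s) {
      # unsafe when an anomer letter touches a residue token (GLCA4GLC is
      # ambiguous between GlcA-4 and Glc-a4) or case-sensitive tags exist
      if (grepl("[DL]-|-ol|-OMe|[1-9O](Me|Ac)", s) ||
          grepl("[A-Za-z][ab][0-9?]", s)) {
        s
      } else {
        toupper(s)
      }
    },
    mod_prefix = function(s) {
      sub("((?:[DL]-)?[A-Z][A-Za-z0-9]*?)([1-9])(S|P)(?![a-z])",
          "[\\2\\3]\\1", s, perl = TRUE)
    },
    permute = function(s) {
      t <- gt_shuffle_children(parse_iupac_to_tree(s))
      tree_to_string(t)
    }
  )
  out <- character(0)
  tries <- 0L
  while (length(out) < n && tries < n * 60L) {
    tries <- tries + 1L
    ops <- sample(names(rewrites), sample(1:2, 1L))
    # the structural permute re-parses its input, so it must precede any
    # textual rewrite in a composed variant
    ops <- c(intersect(ops, "permute"), setdiff(ops, "permute"))
    v <- canonical
    for (op in ops) v <- rewrites[[op]](v)
    if (!identical(v, canonical) && !v %in% out) out <- c(out, v)
  }
  while (length(out) < n) {
    # degenerate inputs (single short residue) support few rewrites;
    # pad with whitespace variants, which the stem strips
    v <- paste0(canonical, strrep(" ", length(out) + 1L))
    if (!v %in% out) out <- c(out, v)
  }
  out[seq_len(n)]
}
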