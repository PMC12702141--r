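# WURCS 2.0: machine-oriented linear notation of the form
#   WURCS=2.0/<u>,<r>,<l>/[desc1][desc2].../<seq>/<links>
# where each unique-residue descriptor encodes a backbone skeleton
# ("a2122h" = D-Glc), the anomeric centre and configuration ("-1b"), the
# ring closure ("_1-5") and substituents ("_2*NCC/3=O" = N-acetyl at C2).
# The link list ("a4-b1") names residue instances by letter; the side
# whose position equals its residue's anomeric carbon is the donor.
#
# The skeleton/substituent tables below cover the common monosaccharides;
# anything outside them raises an unsupported-token error naming the
# descriptor (the residual error class seen on rare glycans).

#' @keywords internal
wurcs_skeleton_map <- function() {
  list(
    a2122h = list(base = "Glc"),
    a2112h = list(base = "Gal"),
    a1122h = list(base = "Man"),
    a2222h = list(base = "All"),
    a1221m = list(base = "Fuc"),
    a2211m = list(base = "Rha"),
    a2122m = list(base = "Qui"),
    a212h  = list(base = "Xyl"),
    a211h  = list(base = "Ara"),
    a222h  = list(base = "Rib"),
    a2122A = list(base = "GlcA"),
    a2112A = list(base = "GalA"),
    a2121A = list(base = "IdoA"),
    Aad21122h = list(base = "Kdn"),  # bare nonulosonic skeleton
    axxxxh = list(base = "Hex"),
    adddh  = list(base = "Hex")
  )
}

# substituent (MAP) codes -> modification semantics
#' @keywords internal
wurcs_map_table <- function() {
  c("NCC/3=O"       = "NAc",
    "NCCO/3=O"      = "NGc",
    "OCC/3=O"       = "Ac",
    "OC"            = "Me",
    "OSO/3=O/3=O"   = "S",
    "OPO/3O/3=O"    = "P",
    "N"             = "N")
}

#' @keywords internal
wurcs_descriptor_to_token <- function(desc) {
  m <- regmatches(desc, regexec(
    "^([A-Za-z0-9]+)-([0-9?])([abxou?])(?:_([0-9?]+)-([0-9?]+))?(.*)$",
    desc))[[1]]
  if (!length(m)) unsupported_token(desc, "WURCS")
  skeleton <- sub("^u", "a", m[2])  # 'u' marks undefined anomeric state
  anomer <- switch(m[4], a = "a", b = "b", "?")
  skel <- wurcs_skeleton_map()[[skeleton]]
  if (is.null(skel)) unsupported_token(desc, "WURCS")
  base <- skel$base
  token <- base
  mods <- character(0)
  rest <- m[7]
  if (nzchar(rest)) {
    for (sub_ in strsplit(sub("^_", "", rest), "_", fixed = TRUE)[[1]]) {
      sm <- regmatches(sub_, regexec("^([0-9?]+)\\*(.*)$", sub_))[[1]]
      if (!length(sm)) unsupported_token(desc, "WURCS")
      pos <- sm[2]
      map <- wurcs_map_table()[sm[3]]
      if (is.na(map)) unsupported_token(desc, "WURCS")
      if (map == "NAc") {
        if (base %in% c("Glc", "Gal", "Man", "All", "Hex") && pos == "2") {
          token <- paste0(base, "NAc")
        } else if (base == "Kdn" && pos == "5") {
          token <- "Neu5Ac"
        } else {
          mods <- c(mods, paste0(if (pos == "?") "O" else pos, "Ac"))
        }
      } else if (map == "NGc") {
        if (base == "Kdn" && pos == "5") {
          token <- "Neu5Gc"
        } else {
          unsupported_token(desc, "WURCS")
        }
      } else if (map == "N") {
        if (base %in% c("Glc", "Gal", "Man") && pos == "2") {
          token <- paste0(base, "N")
        } else {
          unsupported_token(desc, "WURCS")
        }
      } else {
        mods <- c(mods, paste0(if (pos == "?") "O" else pos, map))
      }
    }
  }
  list(token = paste0(token, paste(mods, collapse = "")),
       anomer = anomer,
       anomeric_pos = m[3])
}

#' @keywords internal
wurcs_letter_index <- function(letter) {
  i <- match(letter, c(letters, LETTERS))
  if (is.na(i)) unsupported_token(letter, "WURCS link")
  i
}

#' Parse a WURCS 2.0 string into a raw IUPAC-like string
#'
#' @param s A `WURCS=2.0/...` string.
#' @return Flat string resembling IUPAC-condensed (finish with
#'   [common_stem()] / [canonicalize_glycan()]).
#' @export
parse_wurcs <- function(s) {
  s <- gsub("[[:space:]]+", "", s)
  if (!grepl("^WURCS=2\\.0/", s)) {
    stop("not a WURCS 2.0 string: '", substr(s, 1, 20), "...'",
         call. = FALSE)
  }
  body <- sub("^WURCS=2\\.0/", "", s)
  m <- regmatches(body, regexec("^(\\d+),(\\d+),(\\d+)\\+?/", body))[[1]]
  if (!length(m)) stop("malformed WURCS count section", call. = FALSE)
  body <- substr(body, nchar(m[1]) + 1L, nchar(body))

  # unique residue descriptors, each in [...] (MAPs may contain '/')
  descs <- character(0)
  while (startsWith(body, "[")) {
    dm <- regmatches(body, regexec("^\\[([^\\]]*)\\]", body,
                                   perl = TRUE))[[1]]
    descs <- c(descs, dm[2])
    body <- substr(body, nchar(dm[1]) + 1L, nchar(body))
  }
  if (length(descs) != as.integer(m[2])) {
    stop("WURCS descriptor count mismatch", call. = FALSE)
  }
  body <- sub("^/", "", body)
  parts <- strsplit(body, "/", fixed = TRUE)[[1]]
  seq_idx <- as.integer(strsplit(parts[1], "-", fixed = TRUE)[[1]])
  link_txt <- if (length(parts) >= 2L) parts[2] else ""

  info <- lapply(descs, wurcs_descriptor_to_token)
  tokens <- vapply(seq_idx, function(i) info[[i]]$token, character(1))
  anomers <- vapply(seq_idx, function(i) info[[i]]$anomer, character(1))
  apos <- vapply(seq_idx, function(i) info[[i]]$anomeric_pos, character(1))

  links <- data.frame(child = integer(0), parent = integer(0),
                      anomer = character(0), donor = integer(0),
                      acceptor = character(0), stringsAsFactors = FALSE)
  if (nzchar(link_txt)) {
    for (lnk in strsplit(link_txt, "_", fixed = TRUE)[[1]]) {
      lm <- regmatches(lnk, regexec(
        "^([a-zA-Z])([0-9?]+)-([a-zA-Z])([0-9?]+)$", lnk))[[1]]
      if (!length(lm)) unsupported_token(lnk, "WURCS link")
      r1 <- wurcs_letter_index(lm[2]); p1 <- lm[3]
      r2 <- wurcs_letter_index(lm[4]); p2 <- lm[5]
      # donor = the side sitting on its own anomeric carbon
      d1 <- !is.na(apos[r1]) && p1 == apos[r1]
      d2 <- !is.na(apos[r2]) && p2 == apos[r2]
      if (d2 || !d1) {
        child <- r2; dpos <- p2; parent <- r1; acc <- p1
      } else {
        child <- r1; dpos <- p1; parent <- r2; acc <- p2
      }
      links <- rbind(links, data.frame(
        child = child, parent = parent, anomer = anomers[child],
        donor = if (dpos == "?") NA_integer_ else as.integer(dpos),
        acceptor = acc, stringsAsFactors = FALSE))
    }
  }
  rlt_to_string(tokens, links)
}
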