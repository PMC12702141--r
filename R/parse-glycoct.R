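# GlycoCT (condensed): multi-line format with a RES section (residues
# `1b:` and substituents `2s:`) and a LIN section binding them:
#   RES
#   1b:b-dglc-HEX-1:5
#   2s:n-acetyl
#   3b:b-dgal-HEX-1:5
#   LIN
#   1:1d(2+1)2n
#   2:1o(4+1)3d
# Residue 1 is the reducing end; LIN rows read parent(pos + pos)child.
# Substituent children are merged into their parent residue (n-acetyl at
# C2 of Glc -> GlcNAc, sulfate -> S modification, ...).

#' @keywords internal
glycoct_base_map <- function() {
  list(
    "dglc|HEX"          = "Glc",
    "dgal|HEX"          = "Gal",
    "dman|HEX"          = "Man",
    "dall|HEX"          = "All",
    "lgal|HEX|6:d"      = "Fuc",
    "lman|HEX|6:d"      = "Rha",
    "dglc|HEX|6:d"      = "Qui",
    "dxyl|PEN"          = "Xyl",
    "lara|PEN"          = "Ara",
    "drib|PEN"          = "Rib",
    "dglc|HEX|6:a"      = "GlcA",
    "dgal|HEX|6:a"      = "GalA",
    "lido|HEX|6:a"      = "IdoA",
    # bare 3-deoxy-nonulosonic skeleton; substituents decide Neu5Ac/Neu5Gc
    "dgro-dgal|NON|1:a|2:keto|3:d" = "Kdn",
    "x|HEX"             = "Hex"
  )
}

#' @keywords internal
glycoct_parse_base_line <- function(content, line) {
  parts <- strsplit(content, "|", fixed = TRUE)[[1]]
  quals <- parts[-1]
  head_ <- strsplit(parts[1], "-", fixed = TRUE)[[1]]
  if (length(head_) < 4L) {
    stop("malformed GlycoCT residue line: '", line, "'", call. = FALSE)
  }
  anomer <- head_[1]
  ring <- head_[length(head_)]
  cls <- head_[length(head_) - 1L]
  stems <- paste(head_[2:(length(head_) - 2L)], collapse = "-")
  key <- paste(c(paste(stems, cls, sep = "|"), sort(quals)), collapse = "|")
  base <- glycoct_base_map()[[key]]
  if (is.null(base)) unsupported_token(content, "GlycoCT")
  list(base = base,
       anomer = if (anomer %in% c("a", "b")) anomer else "?",
       # ring "2:6" (nonulosonic) vs "1:5"; donor carbon = first ring atom
       donor = if (grepl("^2:", ring)) 2L else 1L)
}

#' @keywords internal
glycoct_substituent_map <- function() {
  c("n-acetyl" = "NAc", "n-glycolyl" = "NGc", "amino" = "N",
    "sulfate" = "S", "phosphate" = "P", "methyl" = "Me", "acetyl" = "Ac")
}

#' Parse a GlycoCT block into a raw IUPAC-like string
#'
#' @param s A GlycoCT condensed block (single string with embedded
#'   newlines).
#' @return Flat string resembling IUPAC-condensed.
#' @export
parse_glycoct <- function(s) {
  lines <- trimws(strsplit(s, "\n", fixed = TRUE)[[1]])
  lines <- lines[nzchar(lines)]
  section <- ""
  res <- list()   # idx -> list(type, ...)
  lin <- list()
  for (ln in lines) {
    if (ln %in% c("RES", "LIN")) { section <- ln; next }
    if (grepl("^[A-Z]{3}$", ln)) {
      stop("unsupported GlycoCT section: '", ln, "'", call. = FALSE)
    }
    if (section == "RES") {
      m <- regmatches(ln, regexec("^(\\d+)([bs]):(.*)$", ln))[[1]]
      if (!length(m)) {
        stop("malformed GlycoCT RES line: '", ln, "'", call. = FALSE)
      }
      idx <- as.integer(m[2])
      if (m[3] == "b") {
        res[[idx]] <- c(list(type = "b"),
                        glycoct_parse_base_line(m[4], ln))
      } else {
        sub_ <- glycoct_substituent_map()[m[4]]
        if (is.na(sub_)) unsupported_token(m[4], "GlycoCT")
        res[[idx]] <- list(type = "s", sub = unname(sub_))
      }
    } else if (section == "LIN") {
      m <- regmatches(ln, regexec(
        "^\\d+:(\\d+)[odnhx]\\((-?[0-9|]+)\\+(-?\\d+)\\)(\\d+)[odnhx]$",
        ln))[[1]]
      if (!length(m)) {
        stop("malformed GlycoCT LIN line: '", ln, "'", call. = FALSE)
      }
      lin[[length(lin) + 1L]] <-
        list(parent = as.integer(m[2]), ppos = m[3],
             cpos = m[4], child = as.integer(m[5]))
    }
  }
  n <- length(res)
  if (!n) stop("GlycoCT block without residues", call. = FALSE)
  for (i in seq_len(n)) {
    if (is.null(res[[i]])) {
      stop("dangling reference: residue ", i, " undefined", call. = FALSE)
    }
  }
  for (l in lin) {
    if (l$parent > n || l$child > n) {
      stop("dangling LIN reference to residue ",
           max(l$parent, l$child), call. = FALSE)
    }
  }

  # merge substituent nodes into their parent residues
  tokens <- character(n)
  extra_mods <- rep("", n)
  for (l in lin) {
    if (res[[l$child]]$type != "s") next
    pid <- l$parent
    if (res[[pid]]$type != "b") {
      stop("substituent attached to a substituent", call. = FALSE)
    }
    sub_ <- res[[l$child]]$sub
    base <- res[[pid]]$base
    pos <- l$ppos
    if (sub_ == "NAc" && base %in% c("Glc", "Gal", "Man", "Hex") &&
        pos == "2") {
      res[[pid]]$base <- paste0(base, "NAc")
    } else if (sub_ == "NAc" && base == "Kdn" && pos == "5") {
      res[[pid]]$base <- "Neu5Ac"
    } else if (sub_ == "NGc" && base == "Kdn" && pos == "5") {
      res[[pid]]$base <- "Neu5Gc"
    } else if (sub_ == "N" && base %in% c("Glc", "Gal", "Man") &&
               pos == "2") {
      res[[pid]]$base <- paste0(base, "N")
    } else if (sub_ %in% c("S", "P", "Me", "Ac")) {
      p <- if (pos %in% as.character(1:9)) pos else "O"
      extra_mods[pid] <- paste0(extra_mods[pid], p, sub_)
    } else {
      unsupported_token(paste0(sub_, " at ", pos), "GlycoCT")
    }
  }

  keep <- which(vapply(res, function(r) r$type == "b", logical(1)))
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  for (k in seq_along(keep)) {
    i <- keep[k]
    tokens[k] <- paste0(res[[i]]$base, extra_mods[i])
  }
  tokens <- tokens[seq_along(keep)]

  links <- data.frame(child = integer(0), parent = integer(0),
                      anomer = character(0), donor = integer(0),
                      acceptor = character(0), stringsAsFactors = FALSE)
  for (l in lin) {
    if (res[[l$child]]$type != "b") next
    acc <- gsub("|", "/", l$ppos, fixed = TRUE)
    if (acc == "-1") acc <- "?"
    links <- rbind(links, data.frame(
      child = remap[l$child], parent = remap[l$parent],
      anomer = res[[l$child]]$anomer,
      donor = res[[l$child]]$donor,
      acceptor = acc, stringsAsFactors = FALSE))
  }
  rlt_to_string(tokens, links)
}
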