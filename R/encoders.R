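# Fixture encoders: write a canonical IUPAC-condensed glycan out in each
# supported foreign nomenclature. These power the cross-nomenclature
# convergence corpus (encode in format X, re-canonicalize, compare) and
# deliberately cover only the common-residue subset -- they are test
# tooling, not general-purpose exporters.

#' @keywords internal
wurcs_encode_map <- function() {
  list(
    Glc = list(skel = "a2122h", ring = "1-5"),
    Gal = list(skel = "a2112h", ring = "1-5"),
    Man = list(skel = "a1122h", ring = "1-5"),
    All = list(skel = "a2222h", ring = "1-5"),
    Fuc = list(skel = "a1221m", ring = "1-5"),
    Rha = list(skel = "a2211m", ring = "1-5"),
    Qui = list(skel = "a2122m", ring = "1-5"),
    Xyl = list(skel = "a212h", ring = "1-5"),
    Ara = list(skel = "a211h", ring = "1-5"),
    Rib = list(skel = "a222h", ring = "1-5"),
    GlcA = list(skel = "a2122A", ring = "1-5"),
    GalA = list(skel = "a2112A", ring = "1-5"),
    IdoA = list(skel = "a2121A", ring = "1-5"),
    GlcNAc = list(skel = "a2122h", ring = "1-5", map = "2*NCC/3=O"),
    GalNAc = list(skel = "a2112h", ring = "1-5", map = "2*NCC/3=O"),
    ManNAc = list(skel = "a1122h", ring = "1-5", map = "2*NCC/3=O"),
    GlcN = list(skel = "a2122h", ring = "1-5", map = "2*N"),
    Kdn = list(skel = "Aad21122h", ring = "2-6"),
    Neu5Ac = list(skel = "Aad21122h", ring = "2-6", map = "5*NCC/3=O"),
    Neu5Gc = list(skel = "Aad21122h", ring = "2-6", map = "5*NCCO/3=O")
  )
}

#' @keywords internal
tree_nodes_bfs <- function(t) {
  out <- integer(0)
  queue <- t$root
  while (length(queue)) {
    i <- queue[1]
    queue <- queue[-1]
    out <- c(out, i)
    queue <- c(queue, t$children[[i]])
  }
  out
}

#' @keywords internal
mod_suffix_wurcs <- function(m) {
  map <- c(S = "OSO/3=O/3=O", P = "OPO/3O/3=O", Me = "OC", Ac = "OCC/3=O")
  code <- map[m$tag]
  if (is.na(code)) {
    stop("cannot encode modification '", m$tag, "' in WURCS",
         call. = FALSE)
  }
  paste0("_", if (is.na(m$pos)) "?" else m$pos, "*", code)
}

#' Encode a glycan as WURCS 2.0
#'
#' @param s Canonical IUPAC-condensed string (common-residue subset).
#' @return A `WURCS=2.0/...` string.
#' @export
encode_wurcs <- function(s) {
  t <- parse_iupac_to_tree(s)
  ord <- tree_nodes_bfs(t)
  emap <- wurcs_encode_map()
  desc_of <- function(i) {
    m <- t$nodes[[i]]
    e <- emap[[m$base]]
    if (is.null(e)) {
      stop("cannot encode '", m$base, "' in WURCS", call. = FALSE)
    }
    lk <- t$links[[i]]
    anom <- if (is.null(lk)) "x" else if (lk$anomer == "?") "x" else
      lk$anomer
    apos <- default_donor(m$base)
    paste0(e$skel, "-", apos, anom, "_", e$ring,
           if (!is.null(e$map)) paste0("_", e$map) else "",
           paste(vapply(m$mods, mod_suffix_wurcs, character(1)),
                 collapse = ""))
  }
  descs_all <- vapply(ord, desc_of, character(1))
  uniq <- unique(descs_all)
  seq_idx <- match(descs_all, uniq)
  letter_of <- function(pos) c(letters, LETTERS)[pos]
  pos_in_ord <- function(node) match(node, ord)
  links <- character(0)
  for (node in ord) {
    for (k in t$children[[node]]) {
      lk <- t$links[[k]]
      acc <- if (any(is.na(lk$acceptors))) "?" else
        as.character(min(lk$acceptors))
      dnr <- if (is.na(lk$donor)) "?" else as.character(lk$donor)
      links <- c(links, paste0(letter_of(pos_in_ord(node)), acc, "-",
                               letter_of(pos_in_ord(k)), dnr))
    }
  }
  paste0("WURCS=2.0/", length(uniq), ",", length(ord), ",", length(links),
         "/", paste0("[", uniq, "]", collapse = ""), "/",
         paste(seq_idx, collapse = "-"), "/",
         paste(links, collapse = "_"))
}

#' @keywords internal
glycoct_encode_map <- function() {
  list(
    Glc = list(body = "dglc-HEX-1:5"),
    Gal = list(body = "dgal-HEX-1:5"),
    Man = list(body = "dman-HEX-1:5"),
    All = list(body = "dall-HEX-1:5"),
    Fuc = list(body = "lgal-HEX-1:5|6:d"),
    Rha = list(body = "lman-HEX-1:5|6:d"),
    Qui = list(body = "dglc-HEX-1:5|6:d"),
    Xyl = list(body = "dxyl-PEN-1:5"),
    Ara = list(body = "lara-PEN-1:5"),
    Rib = list(body = "drib-PEN-1:5"),
    GlcA = list(body = "dglc-HEX-1:5|6:a"),
    GalA = list(body = "dgal-HEX-1:5|6:a"),
    IdoA = list(body = "lido-HEX-1:5|6:a"),
    GlcNAc = list(body = "dglc-HEX-1:5", sub = "n-acetyl", pos = 2L),
    GalNAc = list(body = "dgal-HEX-1:5", sub = "n-acetyl", pos = 2L),
    ManNAc = list(body = "dman-HEX-1:5", sub = "n-acetyl", pos = 2L),
    GlcN = list(body = "dglc-HEX-1:5", sub = "amino", pos = 2L),
    Kdn = list(body = "dgro-dgal-NON-2:6|1:a|2:keto|3:d"),
    Neu5Ac = list(body = "dgro-dgal-NON-2:6|1:a|2:keto|3:d",
                  sub = "n-acetyl", pos = 5L),
    Neu5Gc = list(body = "dgro-dgal-NON-2:6|1:a|2:keto|3:d",
                  sub = "n-glycolyl", pos = 5L)
  )
}

#' Encode a glycan as a GlycoCT condensed block
#'
#' @param s Canonical IUPAC-condensed string (common-residue subset).
#' @return GlycoCT block (string with embedded newlines).
#' @export
encode_glycoct <- function(s) {
  t <- parse_iupac_to_tree(s)
  ord <- tree_nodes_bfs(t)
  emap <- glycoct_encode_map()
  res_lines <- character(0)
  lin_lines <- character(0)
  idx_of <- integer(length(t$nodes))  # node -> RES id
  nid <- 0L
  sub_mod_map <- c(S = "sulfate", P = "phosphate", Me = "methyl",
                   Ac = "acetyl")
  pend_subs <- list()
  for (node in ord) {
    m <- t$nodes[[node]]
    e <- emap[[m$base]]
    if (is.null(e)) {
      stop("cannot encode '", m$base, "' in GlycoCT", call. = FALSE)
    }
    lk <- t$links[[node]]
    anom <- if (is.null(lk) || lk$anomer == "?") "x" else lk$anomer
    nid <- nid + 1L
    idx_of[node] <- nid
    res_lines <- c(res_lines, paste0(nid, "b:", anom, "-", e$body))
    if (!is.null(e$sub)) {
      nid <- nid + 1L
      res_lines <- c(res_lines, paste0(nid, "s:", e$sub))
      pend_subs <- c(pend_subs,
                     list(list(parent = idx_of[node], pos = e$pos,
                               sid = nid)))
    }
    for (md in m$mods) {
      subname <- sub_mod_map[md$tag]
      if (is.na(subname)) {
        stop("cannot encode modification '", md$tag, "' in GlycoCT",
             call. = FALSE)
      }
      nid <- nid + 1L
      res_lines <- c(res_lines, paste0(nid, "s:", subname))
      pend_subs <- c(pend_subs,
                     list(list(parent = idx_of[node],
                               pos = if (is.na(md$pos)) -1L else md$pos,
                               sid = nid)))
    }
  }
  ln <- 0L
  for (ps in pend_subs) {
    ln <- ln + 1L
    lin_lines <- c(lin_lines, paste0(ln, ":", ps$parent, "d(", ps$pos,
                                     "+1)", ps$sid, "n"))
  }
  for (node in ord) {
    for (k in t$children[[node]]) {
      lk <- t$links[[k]]
      acc <- if (any(is.na(lk$acceptors))) "-1" else
        paste(lk$acceptors, collapse = "|")
      dnr <- if (is.na(lk$donor)) 1L else lk$donor
      ln <- ln + 1L
      lin_lines <- c(lin_lines, paste0(ln, ":", idx_of[node], "o(", acc,
                                       "+", dnr, ")", idx_of[k], "d"))
    }
  }
  paste(c("RES", res_lines,
          if (length(lin_lines)) c("LIN", lin_lines)), collapse = "\n")
}

#' Encode a glycan in LinearCode
#'
#' @param s Canonical IUPAC-condensed string (LinearCode alphabet only).
#' @return LinearCode string with trailing `;`.
#' @export
encode_linearcode <- function(s) {
  t <- parse_iupac_to_tree(s)
  rev_map <- stats::setNames(names(linearcode_map()), linearcode_map())
  code_of <- function(i) {
    base <- t$nodes[[i]]$base
    cd <- rev_map[base]
    if (is.na(cd) || length(t$nodes[[i]]$mods)) {
      stop("cannot encode '", mono_to_string(t$nodes[[i]]),
           "' in LinearCode", call. = FALSE)
    }
    cd
  }
  lk_of <- function(i) {
    lk <- t$links[[i]]
    acc <- if (any(is.na(lk$acceptors))) "?" else
      as.character(min(lk$acceptors))
    paste0(lk$anomer, acc)
  }
  ser <- function(i) {
    kids <- t$children[[i]]
    if (!length(kids)) return(code_of(i))
    out <- paste0(ser(kids[1]), lk_of(kids[1]))
    for (k in kids[-1]) out <- paste0(out, "(", ser(k), lk_of(k), ")")
    paste0(out, code_of(i))
  }
  paste0(ser(t$root), ";")
}

#' Encode a glycan in GLYCAM condensed nomenclature
#'
#' @param s Canonical IUPAC-condensed string (unmodified common residues).
#' @return GLYCAM string terminating in `-OH`.
#' @export
encode_glycam <- function(s) {
  t <- parse_iupac_to_tree(s)
  tok_of <- function(i) {
    m <- t$nodes[[i]]
    if (!m$known || length(m$mods)) {
      stop("cannot encode '", mono_to_string(m), "' in GLYCAM",
           call. = FALSE)
    }
    row <- mono_row(m$base)
    ent <- m$enantiomer %||% row$enantiomer
    if (!ent %in% c("D", "L")) ent <- "D"
    ring <- m$ring %||% row$ring
    stem <- m$base
    if (stem %in% c("Neu5Ac", "Neu5Gc", "Kdn")) {
      # GLYCAM spells the ring letter inside: DNeup5Ac
      return(paste0("D", sub("^(Neu|Kdn)", paste0("\\1", ring), stem)))
    }
    tail_ <- ""
    for (sfx in c("NAc", "NGc", "NS", "A", "N")) {
      if (grepl(paste0(sfx, "$"), stem) &&
          nchar(stem) > nchar(sfx) + 1L) {
        cand <- substr(stem, 1, nchar(stem) - nchar(sfx))
        if (cand %in% c("Glc", "Gal", "Man", "Ido", "Gul", "Fuc",
                        "Qui")) {
          stem <- cand
          tail_ <- sfx
          break
        }
      }
    }
    paste0(ent, stem, ring, tail_)
  }
  lk_of <- function(i) {
    lk <- t$links[[i]]
    if (lk$anomer == "?" || is.na(lk$donor) || any(is.na(lk$acceptors))) {
      stop("cannot encode wildcard linkage in GLYCAM", call. = FALSE)
    }
    paste0(lk$anomer, lk$donor, "-", min(lk$acceptors))
  }
  ser <- function(i) {
    kids <- t$children[[i]]
    res <- tok_of(i)
    if (!length(kids)) return(list(txt = "", tok = res))
    sub1 <- ser(kids[1])
    out <- paste0(sub1$txt, sub1$tok, lk_of(kids[1]))
    for (k in kids[-1]) {
      subk <- ser(k)
      out <- paste0(out, "[", subk$txt, subk$tok, lk_of(k), "]")
    }
    list(txt = out, tok = res)
  }
  root <- ser(t$root)
  anom <- "b"  # reducing-end configuration is not represented in IUPAC
  paste0(root$txt, root$tok, anom, default_donor(t$nodes[[t$root]]$base),
         "-OH")
}

#' Encode a glycan as a KCF block
#'
#' @param s Canonical IUPAC-condensed string.
#' @return KCF block (string with embedded newlines).
#' @export
encode_kcf <- function(s) {
  t <- parse_iupac_to_tree(s)
  n <- length(t$nodes)
  x <- numeric(n); y <- numeric(n)
  place <- function(node, px, py) {
    kids <- t$children[[node]]
    for (r in seq_along(kids)) {
      k <- kids[r]
      x[k] <<- px - 8
      y[k] <<- py - r  # parser re-derives sibling order from y (desc)
      place(k, x[k], y[k])
    }
  }
  x[t$root] <- 0; y[t$root] <- 0
  place(t$root, 0, 0)
  node_lines <- vapply(seq_len(n), function(i) {
    sprintf("            %d   %s  %g  %g", i,
            mono_to_string(t$nodes[[i]]), x[i], y[i])
  }, character(1))
  edge_lines <- character(0)
  ei <- 0L
  for (node in seq_len(n)) {
    for (k in t$children[[node]]) {
      lk <- t$links[[k]]
      ei <- ei + 1L
      dnr <- paste0(lk$anomer, if (is.na(lk$donor)) "" else lk$donor)
      acc <- if (any(is.na(lk$acceptors))) "" else
        paste0(":", min(lk$acceptors))
      edge_lines <- c(edge_lines, sprintf("            %d   %d:%s %d%s",
                                          ei, k, dnr, node, acc))
    }
  }
  paste(c("ENTRY       G00000  Glycan",
          sprintf("NODE        %d", n), node_lines,
          sprintf("EDGE        %d", length(edge_lines)), edge_lines,
          "///"), collapse = "\n")
}

#' Encode a glycan in IUPAC-extended style
#'
#' @param s Canonical IUPAC-condensed string.
#' @return IUPAC-extended string with Greek anomers and arrow linkages.
#' @export
encode_iupac_extended <- function(s) {
  t <- parse_iupac_to_tree(s)
  name_of <- function(i) {
    m <- t$nodes[[i]]
    if (!m$known || length(m$mods)) {
      stop("cannot encode '", mono_to_string(m),
           "' in IUPAC-extended", call. = FALSE)
    }
    row <- mono_row(m$base)
    ent <- m$enantiomer %||% row$enantiomer
    if (!ent %in% c("D", "L")) ent <- "D"
    ring <- m$ring %||% row$ring
    base <- m$base
    nm <- if (grepl("NAc$", base) && base != "NAc") {
      paste0(sub("NAc$", "", base), ring, "NAc")
    } else if (base == "Neu5Ac") {
      paste0("Neu", ring, "5Ac")
    } else if (base == "Neu5Gc") {
      paste0("Neu", ring, "5Gc")
    } else {
      paste0(base, ring)
    }
    paste0(ent, "-", nm)
  }
  greek <- c(a = "α", b = "β", "?" = "?")
  ser <- function(i) {
    kids <- t$children[[i]]
    res <- name_of(i)
    if (!length(kids)) return(list(pre = "", res = res))
    lk1 <- t$links[[kids[1]]]
    s1 <- ser(kids[1])
    pre <- paste0(s1$pre, greek[lk1$anomer], "-", s1$res, "-(",
                  lk1$donor, "→", min(lk1$acceptors), ")-")
    for (k in kids[-1]) {
      lkk <- t$links[[k]]
      sk <- ser(k)
      pre <- paste0(pre, "[", sk$pre, greek[lkk$anomer], "-", sk$res,
                    "-(", lkk$donor, "→", min(lkk$acceptors), ")-]")
    }
    list(pre = pre, res = res)
  }
  r <- ser(t$root)
  paste0(r$pre, r$res)
}

#' Encode a glycan as a GlycoWorkbench (GWS) string
#'
#' @param s Canonical IUPAC-condensed string.
#' @return GWS string starting at `freeEnd` with a `$MONO` suffix.
#' @export
encode_gws <- function(s) {
  t <- parse_iupac_to_tree(s)
  seg_of <- function(i, acc) {
    m <- t$nodes[[i]]
    if (length(m$mods)) {
      stop("cannot encode '", mono_to_string(m), "' in GWS", call. = FALSE)
    }
    row <- if (m$known) mono_row(m$base) else NULL
    ent <- m$enantiomer %||% (if (is.null(row)) "D" else row$enantiomer)
    if (!ent %in% c("D", "L")) ent <- "D"
    ring <- m$ring %||% (if (is.null(row)) "p" else row$ring)
    lk <- t$links[[i]]
    anom <- if (is.null(lk)) "?" else lk$anomer
    dnr <- if (is.null(lk) || is.na(lk$donor)) {
      default_donor(m$base)
    } else {
      lk$donor
    }
    paste0("--", acc, anom, dnr, ent, "-", m$base, ",", ring)
  }
  chain <- function(i) {
    lk <- t$links[[i]]
    acc <- if (is.null(lk) || any(is.na(lk$acceptors))) "?" else
      min(lk$acceptors)
    out <- seg_of(i, acc)
    kids <- t$children[[i]]
    if (!length(kids)) return(out)
    for (k in kids[-1]) out <- paste0(out, "(", chain(k), ")")
    paste0(out, chain(kids[1]))
  }
  paste0("freeEnd", chain(t$root), "$MONO,perMe,Na,0,freeEnd")
}
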