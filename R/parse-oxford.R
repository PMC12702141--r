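# Oxford notation: human shorthand for N-glycans built around the
# invariant Man3GlcNAc2 core. Tokens: F = core fucose (a1-6 on the
# reducing GlcNAc), A<n> = number of GlcNAc antennae, B = bisecting
# GlcNAc, G<n> = galactoses (optional position qualifier "G(3)2"),
# S<n> = sialic acids (optional qualifier "S(6)2"; default linkage a2-?),
# M<n> = oligomannose. Antennae fill the a1-3 arm first; galactoses cap
# antennae in creation order; sialic acids cap galactoses in order.

#' Parse an Oxford string into a raw IUPAC-like string
#'
#' @param s An Oxford N-glycan code such as `"FA2G2S2"` or `"M5"`.
#' @return Flat string resembling IUPAC-condensed.
#' @export
parse_oxford <- function(s) {
  s0 <- gsub("[[:space:]]+", "", s)
  rest <- s0
  fuc <- FALSE
  bisect <- FALSE
  ant <- 0L
  gal <- 0L
  gal_pos <- "4"
  sia <- 0L
  sia_pos <- "?"
  man <- NA_integer_
  while (nzchar(rest)) {
    m <- regmatches(rest, regexec(
      "^(F(\\(\\d\\))?|A(\\d)|B|G(\\(\\d\\))?(\\d)|S(\\(\\d\\))?(\\d)|M(\\d))",
      rest))[[1]]
    if (!length(m)) unsupported_token(substr(rest, 1, 3), "Oxford")
    tok <- m[2]
    if (startsWith(tok, "F")) {
      fuc <- TRUE
    } else if (startsWith(tok, "A")) {
      ant <- as.integer(m[4])
    } else if (tok == "B") {
      bisect <- TRUE
    } else if (startsWith(tok, "G")) {
      gal <- as.integer(m[6])
      if (nzchar(m[5])) gal_pos <- substr(m[5], 2, 2)
    } else if (startsWith(tok, "S")) {
      sia <- as.integer(m[8])
      if (nzchar(m[7])) sia_pos <- substr(m[7], 2, 2)
    } else if (startsWith(tok, "M")) {
      man <- as.integer(m[9])
    }
    rest <- substr(rest, nchar(tok) + 1L, nchar(rest))
  }
  if (!is.na(man) && (ant > 0L || gal > 0L || sia > 0L || bisect)) {
    unsupported_token(s0, "Oxford")
  }
  if (ant > 4L) unsupported_token(s0, "Oxford")
  if (gal > ant || sia > gal) {
    stop("inconsistent Oxford code '", s0,
         "': more caps than free positions", call. = FALSE)
  }

  # the Man3GlcNAc2 core: 1 = reducing GlcNAc, 2 = GlcNAc, 3 = central
  # Man, 4 = a1-3 arm Man, 5 = a1-6 arm Man
  tokens <- c("GlcNAc", "GlcNAc", "Man", "Man", "Man")
  links <- data.frame(
    child = c(2L, 3L, 4L, 5L), parent = c(1L, 2L, 3L, 3L),
    anomer = c("b", "b", "a", "a"), donor = c(1L, 1L, 1L, 1L),
    acceptor = c("4", "4", "3", "6"), stringsAsFactors = FALSE)
  add <- function(token, parent, anomer, donor, acceptor) {
    tokens <<- c(tokens, token)
    idx <- length(tokens)
    links <<- rbind(links, data.frame(
      child = idx, parent = parent, anomer = anomer, donor = donor,
      acceptor = acceptor, stringsAsFactors = FALSE))
    idx
  }

  if (!is.na(man)) {
    if (man < 3L || man > 9L) unsupported_token(paste0("M", man), "Oxford")
    if (man >= 5L) {
      m63 <- add("Man", 5L, "a", 1L, "3")  # 6-arm, a1-3 branch
      m66 <- add("Man", 5L, "a", 1L, "6")  # 6-arm, a1-6 branch
      # a1-2 caps appended in a fixed order: 3-arm, 6-arm/3-branch,
      # 6-arm/6-branch, then a second cap on the 3-arm (M9)
      if (man >= 6L) cap3 <- add("Man", 4L, "a", 1L, "2")
      if (man >= 7L) add("Man", m63, "a", 1L, "2")
      if (man >= 8L) add("Man", m66, "a", 1L, "2")
      if (man >= 9L) add("Man", cap3, "a", 1L, "2")
    }
  } else {
    # antennae in canonical filling order: b1-2 on the 3-arm, b1-2 on the
    # 6-arm, b1-4 on the 3-arm, b1-6 on the 6-arm
    slots <- list(c(4L, 2L), c(5L, 2L), c(4L, 4L), c(5L, 6L))
    antennae <- integer(0)
    for (i in seq_len(ant)) {
      antennae <- c(antennae, add("GlcNAc", slots[[i]][1], "b", 1L,
                                  as.character(slots[[i]][2])))
    }
    if (bisect) add("GlcNAc", 3L, "b", 1L, "4")
    gals <- integer(0)
    for (i in seq_len(gal)) {
      gals <- c(gals, add("Gal", antennae[i], "b", 1L, gal_pos))
    }
    for (i in seq_len(sia)) {
      add("Neu5Ac", gals[i], "a", 2L, sia_pos)
    }
  }
  if (fuc) add("Fuc", 1L, "a", 1L, "6")
  rlt_to_string(tokens, links)
}
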