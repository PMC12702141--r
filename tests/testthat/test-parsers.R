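# Format parsers: each foreign nomenclature against hand-derived expected
# structures (no reference converter is bundled; expectations were worked
# out from the formats' public definitions and frozen here).

finish <- function(raw) canonical_string(parse_iupac_to_tree(common_stem(raw)))

test_that("WURCS parsing maps descriptors and links correctly", {
  expect_identical(
    finish(parse_wurcs(
      "WURCS=2.0/2,2,1/[a2122h-1x_1-5][a2112h-1b_1-5]/1-2/a4-b1")),
    "Gal(b1-4)Glc")
  expect_identical(
    finish(parse_wurcs("WURCS=2.0/1,1,0/[a2122h-1x_1-5]/1/")), "Glc")
  # N-acetyl substituent at C2 of a Glc skeleton = GlcNAc
  expect_identical(
    glycanbabel:::wurcs_descriptor_to_token(
      "a2122h-1b_1-5_2*NCC/3=O")$token,
    "GlcNAc")
  # donor side = the side on its own anomeric carbon (C2 for Neu5Ac)
  expect_identical(
    finish(parse_wurcs(paste0(
      "WURCS=2.0/3,3,2/[a2122h-1x_1-5][a2112h-1b_1-5]",
      "[Aad21122h-2a_2-6_5*NCC/3=O]/1-2-3/a4-b1_b3-c2"))),
    "Neu5Ac(a2-3)Gal(b1-4)Glc")
  err <- tryCatch(parse_wurcs("WURCS=2.0/1,1,0/[zzz9x-1b_1-5]/1/"),
                  error = identity)
  expect_match(conditionMessage(err), "zzz9x-1b_1-5", fixed = TRUE)
})

test_that("GlycoCT parsing merges substituents and reads LIN direction", {
  lac <- "RES\n1b:b-dglc-HEX-1:5\n2b:b-dgal-HEX-1:5\nLIN\n1:1o(4+1)2d"
  expect_identical(finish(parse_glycoct(lac)), "Gal(b1-4)Glc")
  expect_identical(finish(parse_glycoct("RES\n1b:b-dglc-HEX-1:5")), "Glc")
  sulfated <- paste(
    "RES", "1b:b-dglc-HEX-1:5", "2s:n-acetyl", "3b:b-dgal-HEX-1:5",
    "4s:sulfate", "LIN", "1:1d(2+1)2n", "2:1o(4+1)3d", "3:3o(6+1)4n",
    sep = "\n")
  expect_identical(finish(parse_glycoct(sulfated)), "Gal6S(b1-4)GlcNAc")
  neu <- paste(
    "RES", "1b:b-dgal-HEX-1:5", "2b:x-dgro-dgal-NON-2:6|1:a|2:keto|3:d",
    "3s:n-acetyl", "LIN", "1:1o(3+2)2d", "2:2d(5+1)3n", sep = "\n")
  expect_identical(finish(parse_glycoct(neu)), "Neu5Ac(?2-3)Gal")
  expect_error(parse_glycoct(
    "RES\n1b:b-dglc-HEX-1:5\nLIN\n1:1o(4+1)9d"), "dangling")
})

test_that("LinearCode translation follows the letter table", {
  expect_identical(finish(parse_linearcode("Ab4GN;")), "Gal(b1-4)GlcNAc")
  expect_identical(finish(parse_linearcode("M")), "Man")
  expect_identical(finish(parse_linearcode("NNa3Ab4GN")),
                   "Neu5Ac(a2-3)Gal(b1-4)GlcNAc")
  expect_identical(finish(parse_linearcode("Ab4(Fa3)GN")),
                   "Fuc(a1-3)[Gal(b1-4)]GlcNAc")
  err <- tryCatch(parse_linearcode("Zb4GN"), error = identity)
  expect_match(conditionMessage(err), "Z", fixed = TRUE)
})

test_that("GLYCAM strings lose their scaffolding", {
  expect_identical(finish(parse_glycam("DGalpb1-4DGlcpb1-OH")),
                   "Gal(b1-4)Glc")
  expect_identical(finish(parse_glycam("DGlcpb1-OH")), "Glc")
  expect_identical(finish(parse_glycam("DManpa1-3[DManpa1-6]DManpb1-OH")),
                   "Man(a1-3)[Man(a1-6)]Man")
  expect_identical(finish(parse_glycam("LFucpa1-2DGalpb1-4DGlcpb1-OH")),
                   "Fuc(a1-2)Gal(b1-4)Glc")
  # -OME is kept as a reducing-end annotation, -OH is dropped
  expect_identical(finish(parse_glycam("DGlcpNAcb1-4DGlcpNAcb1-OME")),
                   "GlcNAc(b1-4)GlcNAc-OMe")
  expect_error(parse_glycam("DGalpb1-4DGlcpb1"), "terminus")
})

test_that("Oxford codes expand around the Man3GlcNAc2 core", {
  expect_identical(finish(parse_oxford("M3")),
                   "Man(a1-3)[Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc")
  expect_identical(
    finish(parse_oxford("FA2")),
    paste0("GlcNAc(b1-2)Man(a1-3)[GlcNAc(b1-2)Man(a1-6)]",
           "Man(b1-4)GlcNAc(b1-4)[Fuc(a1-6)]GlcNAc"))
  fa2g2s2 <- finish(parse_oxford("FA2G2S2"))
  expect_identical(
    fa2g2s2,
    paste0("Neu5Ac(a2-?)Gal(b1-4)GlcNAc(b1-2)Man(a1-3)",
           "[Neu5Ac(a2-?)Gal(b1-4)GlcNAc(b1-2)Man(a1-6)]",
           "Man(b1-4)GlcNAc(b1-4)[Fuc(a1-6)]GlcNAc"))
  # position qualifiers pin the linkages
  expect_match(finish(parse_oxford("A2G(3)2S(6)2")),
               "Neu5Ac(a2-6)Gal(b1-3)", fixed = TRUE)
  expect_identical(
    finish(parse_oxford("M5")),
    paste0("Man(a1-3)[Man(a1-6)]Man(a1-6)[Man(a1-3)]",
           "Man(b1-4)GlcNAc(b1-4)GlcNAc"))
  expect_error(parse_oxford("Q7"), "Q7")
  expect_error(parse_oxford("A2G3"), "caps")
})

test_that("KCF blocks resolve donors by anomer and order by layout", {
  lac <- paste("ENTRY G1 Glycan", "NODE 2", " 1 Glc 0 0", " 2 Gal -10 0",
               "EDGE 1", " 1 2:b1 1:4", "///", sep = "\n")
  expect_identical(finish(parse_kcf(lac)), "Gal(b1-4)Glc")
  single <- "NODE 1\n 1 Man 0 0\nEDGE 0"
  expect_identical(finish(parse_kcf(single)), "Man")
  man3 <- paste("NODE 5", " 1 GlcNAc 0 0", " 2 GlcNAc -8 0",
                " 3 Man -16 0", " 4 Man -24 5", " 5 Man -24 -5",
                "EDGE 4", " 1 2:b1 1:4", " 2 3:b1 2:4", " 3 4:a1 3:3",
                " 4 5:a1 3:6", sep = "\n")
  expect_identical(finish(parse_kcf(man3)),
                   "Man(a1-3)[Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc")
  disco <- "NODE 2\n 1 Glc 0 0\n 2 Gal -8 0\nEDGE 0"
  expect_error(parse_kcf(disco), "root|disconnect")
})

test_that("IUPAC-extended arrows and qualifications are rewritten", {
  expect_identical(finish(parse_iupac_extended("β-D-Galp-(1→4)-D-Glcp")),
                   "Gal(b1-4)Glc")
  expect_identical(finish(parse_iupac_extended("D-Glcp")), "Glc")
  expect_identical(
    finish(parse_iupac_extended("α-L-Fucp-(1→2)-β-D-Galp-(1→4)-D-Glcp")),
    "Fuc(a1-2)Gal(b1-4)Glc")
})

test_that("GWS chains run from the reducing end with paren branches", {
  expect_identical(
    finish(parse_gws("freeEnd--?b1D-GlcNAc,p--4b1D-GlcNAc,p")),
    "GlcNAc(b1-4)GlcNAc")
  expect_identical(finish(parse_gws("freeEnd--?b1D-Glc,p")), "Glc")
  expect_identical(
    finish(parse_gws(paste0(
      "freeEnd--?b1D-GlcNAc,p--4b1D-GlcNAc,p--4b1D-Man,p",
      "(--3a1D-Man,p)--6a1D-Man,p$MONO,perMe,Na,0,freeEnd"))),
    "Man(a1-3)[Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc")
  expect_error(parse_gws("freeEnd--junk"), "segment")
})

test_that("unsupported-token errors carry the token verbatim", {
  cases <- list(
    function() parse_wurcs("WURCS=2.0/1,1,0/[qq999x-1b_1-5]/1/"),
    function() parse_linearcode("Qb4GN"),
    function() parse_oxford("Z9"))
  tokens <- c("qq999x-1b_1-5", "Q", "Z9")
  for (i in seq_along(cases)) {
    err <- tryCatch(cases[[i]](), error = identity)
    expect_match(conditionMessage(err), tokens[i], fixed = TRUE)
  }
})
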