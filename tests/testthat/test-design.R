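# The decoded guide/star strings asserted here were derived once with the
# hand oracle (reverse complement, promoter strip, arm split, per-position
# pairing) and frozen.

FULL_GUIDE <- "UAUGUUUCAGGUUCAGGGCGA"
FULL_STAR <- "GCCCUGACGCUGAAACCUAUG"

test_that("decoding the full-match template recovers the annotated parts", {
  d <- fixtureDesigns()$full_match
  expect_identical(d@guide, FULL_GUIDE)
  expect_identical(d@star, FULL_STAR)
  expect_identical(d@loop, "GUUGUCA")
  expect_identical(substr(d@guide, 1, 1), "U")
  expect_identical(substr(d@guide, 19, 19), "C")
  expect_identical(d@promoterName, "T7_STD")
  # the guide is the arm whose reverse complement occurs in the target
  mch <- loadFixtures("mcherry_mrna_nematostella_zebrafish")
  site <- substr(mch, d@siteStart, d@siteEnd)
  expect_identical(oracleMismatchSet(d@guide, dnaToRna(site)), 19L)
})

test_that("every decoded mimic guide obeys the 5'-U and position-19-C rules", {
  d <- fixtureDesigns()
  mimics <- d[setdiff(names(d), "shrna_neg_control")]
  expect_length(mimics, 7L)
  for (m in mimics) {
    expect_identical(substr(m@guide, 1, 1), "U")
    expect_identical(substr(m@guide, 19, 19), "C")
  }
  cpos <- Reduce(intersect, lapply(mimics, function(m)
    which(strsplit(m@guide, "")[[1]] == "C")))
  expect_identical(cpos, 19L)  # unique common cytosine position
})

test_that("single-central-mismatch guides differ from full match at 10 and 11", {
  d <- fixtureDesigns()
  diffPos <- function(a, b) which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_identical(diffPos(d$mismatch_10@guide, d$full_match@guide), 10L)
  expect_identical(diffPos(d$mismatch_11@guide, d$full_match@guide), 11L)
  expect_identical(diffPos(d$mismatch_10_11@guide, d$full_match@guide),
                   c(10L, 11L))
})

test_that("decode and reassembly round-trip all packaged templates byte-identically", {
  fx <- loadFixtures()
  d <- fixtureDesigns()
  scaffold <- mir2022Scaffold()
  t7 <- defaultPromoters()$T7_STD
  for (nm in names(d)) {
    re <- assembleDesign(d[[nm]]@guide, d[[nm]]@star, scaffold, t7,
                         loop = d[[nm]]@loop, strict = FALSE)
    expect_identical(re@template, fx$templates[[nm]])
  }
  # swapping guide and star breaks the identity (hairpin asymmetry)
  sw <- suppressWarnings(  # the swapped precursor starts with U, not the T7 +1 G
    assembleDesign(d$full_match@star, d$full_match@guide, scaffold, t7,
                   loop = d$full_match@loop, strict = FALSE))
  expect_false(sw@template == fx$templates[["full_match"]])
})

test_that("the generic shRNA decodes through fold mode with its own loop", {
  d <- fixtureDesigns()$shrna_neg_control
  expect_identical(d@loop, "CAAGAGA")
  expect_identical(nchar(d@guide), 21L)
  expect_identical(nchar(d@star), 21L)
  # arms are mutually near-complementary under the calibrated register
  gv <- strsplit(d@guide, "")[[1]]
  sv <- strsplit(d@star, "")[[1]]
  wc <- vapply(1:19, function(j)
    pairState(sv[j], gv[20 - j]) == "WATSON_CRICK", logical(1))
  expect_true(mean(wc) > 0.8)
  # a precursor too short to fold errors out
  short <- makeTemplate(paste0("G", randomSeq(30)), defaultPromoters()$T7_STD)
  expect_error(decodeTemplate(short), "cannot fold")
})

test_that("chooseTargetSite enumerates exactly the windows that support a 5' U guide", {
  mch <- loadFixtures("mcherry_mrna_nematostella_zebrafish")
  utr <- c(750L, 962L)
  cand <- chooseTargetSite(mch, utr)
  # oracle: every window in the region ending in A, ascending
  want <- Filter(function(s) substr(mch, s + 20, s + 20) == "A",
                 seq(utr[1], utr[2] - 20))
  expect_identical(cand$start, as.integer(want))
  expect_true(827L %in% cand$start)  # the printed full-match site
  expect_error(chooseTargetSite(mch, c(750, 760)), "shorter than")
  expect_error(chooseTargetSite(mch, c(900, 2000)), "outside")
  expect_identical(nrow(chooseTargetSite("GGGGGGGGGGGGGGGGGGGGGGGGG", c(1, 25))),
                   0L)
})

test_that("deriveGuide realises each requested category on random sites", {
  set.seed(97)
  spec <- patternSpec()
  scaffold <- mir2022Scaffold()
  cats <- c("NEAR_FULL", "SEED_ONLY", "SEED_SUPPLEMENTARY",
            "CENTRAL_MM_10", "CENTRAL_MM_11", "CENTRAL_MM_10_11")
  for (i in 1:35) {
    site <- paste0(randomSeq(20), "A")
    for (cat. in cats) {
      g <- deriveGuide(site, cat., scaffold, spec)
      expect_identical(substr(g, 1, 1), "U")
      expect_identical(substr(g, 19, 19), "C")
      expect_identical(classifyAlignment(alignDuplex(g, site), spec), cat.)
    }
  }
  expect_error(deriveGuide(paste0(randomSeq(20), "G"), "NEAR_FULL"),
               "5' U rule")
})

test_that("derived guides reproduce the printed design conventions", {
  d <- fixtureDesigns()
  mch <- loadFixtures("mcherry_mrna_nematostella_zebrafish")
  site <- substr(mch, d$full_match@siteStart, d$full_match@siteEnd)
  gNF <- deriveGuide(site, "NEAR_FULL")
  # near-full: differs from the exact complement only at fixed position 19
  expect_identical(which(strsplit(gNF, "")[[1]] !=
                           strsplit(revComp(dnaToRna(site)), "")[[1]]), 19L)
  expect_identical(gNF, d$full_match@guide)  # byte-identical to the decoded row
  g10 <- deriveGuide(site, "CENTRAL_MM_10")
  expect_identical(which(strsplit(g10, "")[[1]] != strsplit(gNF, "")[[1]]), 10L)
  # the substituted base neither pairs nor wobbles with the opposing base
  expect_identical(pairState(substr(g10, 10, 10),
                             dnaToRna(substr(site, 12, 12))), "MISMATCH")
  expect_identical(g10, d$mismatch_10@guide)
  expect_identical(deriveGuide(site, "CENTRAL_MM_11"), d$mismatch_11@guide)
  expect_identical(deriveGuide(site, "CENTRAL_MM_10_11"),
                   d$mismatch_10_11@guide)
})

test_that("deriveStar applies designed mismatches relative to the site image", {
  d <- fixtureDesigns()
  mch <- loadFixtures("mcherry_mrna_nematostella_zebrafish")
  scaffold <- mir2022Scaffold()
  # with no designed mismatches the star is the exact duplex complement
  plain <- scaffold
  plain@starMismatchPositions <- integer(0)
  st0 <- deriveStar(FULL_GUIDE, plain)
  stv <- strsplit(st0, "")[[1]]
  gv <- strsplit(FULL_GUIDE, "")[[1]]
  for (j in 1:19)
    expect_identical(pairState(stv[j], gv[20 - j]), "WATSON_CRICK")
  expect_identical(substr(st0, 20, 21), "UG")

  # decoded star deviates from the image of the target site exactly at the
  # scaffold's designated positions (string-comparison oracle)
  site <- substr(mch, d$full_match@siteStart, d$full_match@siteEnd)
  sv <- strsplit(dnaToRna(site), "")[[1]]
  dev <- which(vapply(1:19, function(j)
    strsplit(d$full_match@star, "")[[1]][j] != sv[j + 2], logical(1)))
  expect_identical(dev, c(1L, 8L, 9L, 17L))
  # and relative to the final (position-19-fixed) guide only 8, 9, 17 mismatch
  nonpair <- which(vapply(1:19, function(j)
    pairState(strsplit(d$full_match@star, "")[[1]][j], gv[20 - j]) !=
      "WATSON_CRICK", logical(1)))
  expect_identical(nonpair, c(8L, 9L, 17L))
  # scaffold-constant 3' end shared between rows
  expect_identical(substr(d$seed_match@star, 18, 21),
                   substr(d$full_match@star, 18, 21))
  expect_error(deriveStar(FULL_GUIDE, {
    s <- scaffold; s@starMismatchPositions <- 20L; s
  }), "outside the paired register")
})

test_that("designMimir produces a valid, decodable design end to end", {
  mch <- loadFixtures("mcherry_mrna_nematostella_zebrafish")
  des <- designMimir(mch, c(750, 962), "near_full", targetId = "mCherry")
  expect_identical(des@category, "NEAR_FULL")
  rt <- decodeTemplate(des@template, target = mch, targetId = "mCherry")
  expect_identical(rt@guide, des@guide)
  expect_identical(rt@precursor, des@precursor)
  expect_identical(rt@category, "NEAR_FULL")
})

test_that("the YAML scaffold fixture equals the built-in scaffold", {
  sc <- readScaffold(loadFixtures("scaffold_yaml"))
  expect_identical(sc@loop, mir2022Scaffold()@loop)
  expect_identical(sc@starMismatchPositions,
                   mir2022Scaffold()@starMismatchPositions)
  expect_identical(sc@guideLength, 21L)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("loop: GUUGUCA", "nonsense_key: 1"), bad)
  expect_error(readScaffold(bad), "unknown scaffold configuration")
})
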