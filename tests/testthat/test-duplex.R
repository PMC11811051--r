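test_that("pairState follows Watson-Crick and wobble rules", {
  expect_identical(pairState("G", "C"), "WATSON_CRICK")
  expect_identical(pairState("A", "U"), "WATSON_CRICK")
  expect_identical(pairState("G", "U"), "WOBBLE")
  expect_identical(pairState("U", "G"), "WOBBLE")
  expect_identical(pairState("C", "C"), "MISMATCH")
  expect_identical(pairState("N", "A"), "MISMATCH")
})

test_that("alignDuplex reproduces the decoded-duplex mismatch sets", {
  d <- fixtureDesigns()
  mch <- loadFixtures("mcherry_mrna_nematostella_zebrafish")
  full <- d$full_match
  site <- dnaToRna(substr(mch, full@siteStart, full@siteEnd))
  aln <- alignDuplex(full@guide, site)
  expect_identical(mismatchPositions(aln), 19L)
  expect_identical(mismatchPositions(aln), oracleMismatchSet(full@guide, site))

  # a guide against the exact reverse complement of itself pairs everywhere
  g <- "UAUGUUUCAGGUUCAGGGCGA"
  expect_length(mismatchPositions(alignDuplex(g, revComp(g))), 0L)

  seedAln <- alignDuplex(d$seed_match@guide, site)
  expect_identical(setdiff(1:21, mismatchPositions(seedAln)), 1:8)
  expect_identical(mismatchPositions(seedAln),
                   oracleMismatchSet(d$seed_match@guide, site))
  expect_error(alignDuplex("ACGU", "ACGUA"), "equal length")
})

test_that("classifyAlignment assigns the decoded guides their intended modes", {
  d <- fixtureDesigns()
  mch <- loadFixtures("mcherry_mrna_nematostella_zebrafish")
  full <- d$full_match
  site <- dnaToRna(substr(mch, full@siteStart, full@siteEnd))
  cls <- function(g) classifyAlignment(alignDuplex(g, site))
  expect_identical(cls(d$full_match@guide), "NEAR_FULL")
  expect_identical(cls(d$seed_match@guide), "SEED_ONLY")
  expect_identical(cls(d$seed_supplementary@guide), "SEED_SUPPLEMENTARY")
  expect_identical(cls(d$mismatch_10@guide), "CENTRAL_MM_10")
  expect_identical(cls(d$mismatch_11@guide), "CENTRAL_MM_11")
  expect_identical(cls(d$mismatch_10_11@guide), "CENTRAL_MM_10_11")
})

test_that("classification is total and deterministic on random duplexes", {
  set.seed(101)
  spec <- patternSpec()
  for (i in 1:2000) {
    g <- randomSeq(21)
    s <- randomSeq(21)
    aln <- alignDuplex(g, s)
    c1 <- classifyAlignment(aln, spec)
    expect_true(c1 %in% c("NEAR_FULL", "SEED_ONLY", "SEED_SUPPLEMENTARY",
                          "CENTRAL_MM_10", "CENTRAL_MM_11", "CENTRAL_MM_10_11",
                          "NONE"))
    expect_identical(classifyAlignment(aln, spec), c1)
  }
})

test_that("breaking a supplementary match never promotes towards NEAR_FULL", {
  set.seed(55)
  spec <- patternSpec()
  n_checked <- 0
  while (n_checked < 60) {
    site <- randomSeq(21)
    g <- strsplit(revComp(site), "")[[1]]
    # force central and 3'-tail mismatches so the alignment starts out as
    # seed + supplementary (identical bases never pair nor wobble)
    sv <- strsplit(site, "")[[1]]
    g[10] <- sv[12]; g[17] <- sv[5]; g[18] <- sv[4]
    guide <- paste(g, collapse = "")
    if (classifyAlignment(alignDuplex(guide, site), spec) != "SEED_SUPPLEMENTARY")
      next
    p <- sample(13:16, 1)
    g2 <- g
    g2[p] <- strsplit(site, "")[[1]][22 - p]  # identical base cannot pair
    got <- classifyAlignment(alignDuplex(paste(g2, collapse = ""), site), spec)
    expect_true(got %in% c("SEED_ONLY", "NONE"))
    n_checked <- n_checked + 1
  }
})

test_that("wobble handling is configurable", {
  # G:U wobble at position 5
  site <- "AAAAAAAAAAAAAAAAUAAAA"
  guide <- revComp(site)
  g <- strsplit(guide, "")[[1]]
  g[5] <- "G"  # faces U at site position 17
  guide <- paste(g, collapse = "")
  strict <- classifyAlignment(alignDuplex(guide, site), patternSpec())
  lax <- classifyAlignment(alignDuplex(guide, site),
                           patternSpec(wobbleIsMatch = TRUE))
  expect_false(strict == "NEAR_FULL")
  expect_identical(lax, "NEAR_FULL")
})

test_that("seed-mode scan finds the three reporter sites in the 3' UTR", {
  d <- fixtureDesigns()
  mch <- loadFixtures("mcherry_mrna_nematostella_zebrafish")
  val <- validateConstruct(mch, c(seed = d$seed_match@guide))
  hits <- scanTranscript(d$seed_match@guide, mch, annotation = val$regions,
                         mode = "seed", transcriptId = "mCherry")
  expect_identical(nrow(hits), 3L)
  expect_true(all(hits$region == "UTR3"))
  # disjoint and identically spaced
  expect_true(all(hits$start[-1] > hits$end[-3]))
  expect_identical(length(unique(diff(hits$start))), 1L)
})

test_that("scan of a transcript equal to the guide's complement yields one near-full hit", {
  set.seed(3)
  g <- paste0("U", randomSeq(20))
  hits <- scanTranscript(g, revComp(g), mode = "all")
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$category, "NEAR_FULL")
  expect_identical(hits$mismatch_positions, "")
})

test_that("seed-mode scan is empty when the seed complement is absent", {
  d <- fixtureDesigns()
  guide <- d$seed_match@guide
  motif <- rnaToDna(revComp(substr(guide, 1, 8)))
  set.seed(17)
  repeat {
    t1k <- randomSeq(1000, c("A", "C", "G", "T"))
    if (!grepl(motif, t1k, fixed = TRUE)) break  # motif absence by search
  }
  expect_identical(nrow(scanTranscript(guide, t1k, mode = "seed")), 0L)
})

test_that("scanTranscript(all) equals the exhaustive per-window oracle", {
  set.seed(29)
  d <- fixtureDesigns()
  spec <- patternSpec()
  nWindows <- 0
  while (nWindows < 1000) {
    tr <- randomSeq(270, c("A", "C", "G", "T"))
    # plant sites so the scan is not trivially empty
    g <- d$full_match@guide
    site <- rnaToDna(revComp(g))
    tr <- paste0(substr(tr, 1, 60), site, substr(tr, 82, 200), site)
    got <- scanTranscript(g, tr, spec = spec, mode = "all")
    want <- oracleScanAll(g, dnaToRna(tr), spec)
    expect_identical(nrow(got), length(want))
    if (length(want)) {
      expect_identical(got$start, vapply(want, function(h) h$start, integer(1)))
      expect_identical(got$category,
                       vapply(want, function(h) h$category, character(1)))
    }
    nWindows <- nWindows + (nchar(tr) - nchar(g) + 1)
  }
})

test_that("cleavage coordinates follow the position-10/11 bond arithmetic", {
  set.seed(41)
  g <- paste0("U", randomSeq(20))
  site <- revComp(g)
  flank5 <- randomSeq(99)
  tr <- paste0(flank5, site, randomSeq(80))
  hits <- scanTranscript(g, tr, mode = "near_full")
  expect_identical(hits$start[1], 100L)
  expect_identical(hits$cleavage_coord[1], 100L + 21L - 11L)  # bond 110-111
  # central mismatches abolish the predicted cleavage
  for (cat. in c("CENTRAL_MM_10", "CENTRAL_MM_11", "CENTRAL_MM_10_11")) {
    aln <- alignDuplex(deriveGuide(rnaToDna(site), cat.), site)
    expect_identical(cleavageCoordinate(aln, 100L), NA_integer_)
  }
  aln <- alignDuplex(g, site)
  expect_identical(cleavageCoordinate(aln, 100L), 110L)
})
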