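# A decoded precursor with its guide/star/loop partition, shared across tests
quantAnnotation <- function(id = "mimir_full") {
  annotationFromDesign(fixtureDesigns()$full_match, precursorId = id)
}

test_that("length filtering keeps the 18-nt boundary and preserves order", {
  reads <- c(a = strrep("A", 17), b = strrep("C", 18), c = strrep("G", 30))
  expect_identical(unname(lengthFilter(reads)), unname(reads[c("b", "c")]))
  expect_identical(lengthFilter(character(0)), character(0))
  longs <- c(strrep("A", 20), strrep("U", 25))
  expect_identical(lengthFilter(longs), longs)
})

test_that("collapseReads deduplicates while conserving total counts", {
  got <- collapseReads(c("AC", "AC", "GU"))
  expect_identical(got$sequence, c("AC", "GU"))
  expect_identical(got$count, c(2L, 1L))
  expect_identical(sum(got$count), 3L)
  distinct <- collapseReads(c("A", "C", "G"))
  expect_true(all(distinct$count == 1L))
  expect_identical(nrow(collapseReads(character(0))), 0L)
})

test_that("assignReads labels reads by maximal interval overlap", {
  ann <- quantAnnotation()
  pre <- ann@precursor
  gIv <- ann@guideInterval; lIv <- ann@loopInterval
  guideRead <- substr(pre, gIv[1], gIv[2])
  asg <- assignReads(guideRead, ann)
  expect_identical(asg$label, "guide")
  expect_false(asg$loop_spanning[1])
  expect_identical(asg$offset[1], gIv[1])

  # a read starting 3 nt inside the loop and covering most of the guide:
  # guide overlap dominates, loop overlap flags it
  spanning <- substr(pre, gIv[1] - 3L, gIv[1] + 17L)
  asg <- assignReads(spanning, ann)
  expect_identical(asg$label, "guide")
  expect_true(asg$loop_spanning[1])

  starRead <- substr(pre, ann@starInterval[1], ann@starInterval[2])
  expect_identical(assignReads(starRead, ann)$label, "star")

  expect_identical(assignReads(strrep("ACGU", 6), ann)$label, "other")
})

test_that("count conservation holds across strand classes", {
  set.seed(71)
  ann <- quantAnnotation()
  cfg <- synthReadConfig(nReads = 2000, guideFraction = 0.6,
                         loopSpanningFraction = 0.1, seed = 5)
  reads <- simulateReads(cfg, ann)
  asg <- assignReads(reads, ann)
  ct <- countReads(asg, precursorIds = ann@precursorId)
  expect_identical(ct$guide + ct$star + ct$loop + ct$other, length(reads))
})

test_that("RPM normalization is linear and guards its denominator", {
  expect_identical(normalizeCounts(200, 4e6), 50)
  expect_identical(normalizeCounts(0, 123), 0)
  expect_error(normalizeCounts(5, 0), "positive")
  counts <- c(3, 50, 1200)
  base <- normalizeCounts(counts, 2e6)
  # scaling counts and denominator together leaves RPM unchanged
  expect_equal(normalizeCounts(counts * 7, 2e6 * 7), base)
  # scaling counts alone scales RPM by the same factor
  expect_equal(normalizeCounts(counts * 3, 2e6), base * 3)
})

test_that("replicate averaging is the arithmetic mean", {
  expect_identical(averageReplicates(list(c(10, 4), c(20, 8))), c(15, 6))
  expect_identical(averageReplicates(5), 5)
  expect_identical(averageReplicates(list(c(0, 0), c(0, 0))), c(0, 0))
})

test_that("homogeneity metrics recover simulated processing parameters", {
  ann <- quantAnnotation()
  # all reads exactly the annotated guide: perfectly homogeneous
  perfect <- assignReads(rep(substr(ann@precursor, ann@guideInterval[1],
                                    ann@guideInterval[2]), 50), ann)
  h <- homogeneity(perfect, ann)
  expect_identical(h$canonicalFraction, 1)
  expect_identical(h$loopSpanningFraction, 0)

  # loop-spanning fraction recovered within 3 binomial SD (n = 10,000)
  cfg <- synthReadConfig(nReads = 10000, guideFraction = 0.55,
                         loopSpanningFraction = 0.3, seed = 42)
  asg <- assignReads(simulateReads(cfg, ann), ann)
  h <- homogeneity(asg, ann)
  pLoop <- 0.3 / (0.55 + 0.3)  # among guide-labelled reads
  sd3 <- 3 * sqrt(pLoop * (1 - pLoop) / h$nGuideReads)
  expect_lt(abs(h$loopSpanningFraction - pLoop), sd3)

  # 5' jitter: canonical fraction tracks P(offset == 0) among guide reads
  cfg <- synthReadConfig(nReads = 10000, guideFraction = 1,
                         loopSpanningFraction = 0,
                         jitterProbs = c(`-1` = 0.5, `0` = 0.5), seed = 9)
  asg <- assignReads(simulateReads(cfg, ann), ann)
  h <- homogeneity(asg, ann)
  sd3 <- 3 * sqrt(0.25 / h$nGuideReads)
  expect_lt(abs(h$canonicalFraction - 0.5), sd3)
  expect_warning(homogeneity(perfect[0, ], ann), "no guide-assigned")
})

test_that("simulateReads is byte-deterministic and respects its window", {
  ann <- quantAnnotation()
  cfg <- synthReadConfig(nReads = 500, guideFraction = 0.7,
                         loopSpanningFraction = 0.1, seed = 42)
  r1 <- simulateReads(cfg, ann)
  r2 <- simulateReads(cfg, ann)
  expect_identical(r1, r2)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  writeFastq(r1, f1); writeFastq(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(all(nchar(r1) <= 30))
  cfg2 <- synthReadConfig(nReads = 500, guideFraction = 0.7,
                          loopSpanningFraction = 0.1, seed = 43)
  expect_false(identical(simulateReads(cfg2, ann), r1))
  expect_error(synthReadConfig(guideFraction = 0.9, loopSpanningFraction = 0.2),
               "<= 1")
})

test_that("simulated class fractions are recovered within 3 binomial SD", {
  ann <- quantAnnotation()
  set.seed(303)
  for (i in 1:8) {
    gf <- runif(1, 0.4, 0.9)
    lf <- runif(1, 0, min(0.2, 1 - gf))
    cfg <- synthReadConfig(nReads = 10000, guideFraction = gf,
                           loopSpanningFraction = lf,
                           seed = sample.int(1e6, 1))
    asg <- assignReads(simulateReads(cfg, ann), ann)
    ct <- countReads(asg, ann@precursorId)
    # all guide-class reads (clean + loop-spanning) are guide-labelled
    pG <- gf + lf
    n <- ct$guide + ct$star
    sd3 <- 3 * sqrt(pG * (1 - pG) / n)
    expect_lt(abs(ct$guide / n - pG), sd3)
    if (gf + lf > 0.5 + sd3) expect_gt(ct$guide, ct$star)
  }
})

test_that("quantifyLoading runs the full pipeline over replicates", {
  ann <- quantAnnotation()
  cfg1 <- synthReadConfig(nReads = 4000, guideFraction = 0.75,
                          loopSpanningFraction = 0.05, seed = 11)
  cfg2 <- synthReadConfig(nReads = 4000, guideFraction = 0.75,
                          loopSpanningFraction = 0.05, seed = 12)
  lq <- quantifyLoading(list(rep1 = simulateReads(cfg1, ann),
                             rep2 = simulateReads(cfg2, ann)),
                        ann, unmappedTotals = c(2e6, 1e6))
  counts <- loadingCounts(lq)
  rpm <- loadingRpm(lq)
  expect_identical(nrow(counts), 2L)
  expect_equal(rpm$guide_rpm,
               counts$guide / c(2e6, 1e6) * 1e6)
  means <- loadingMeans(lq)
  expect_equal(means$guide_rpm_mean, mean(rpm$guide_rpm))
  # guide strand dominates the star strand, as designed
  expect_true(all(counts$guide > counts$star))
  homo <- loadingHomogeneity(lq)
  expect_identical(nrow(homo), 2L)
  expect_true(all(homo$canonical_fraction > 0.8))
})
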