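# Desk-scale quantification of mimic loading from AGO-IP small-RNA reads:
# length filtering, read collapsing, precursor assignment with strand
# labelling, RPM-of-unmapped normalization, replicate averaging, processing
# homogeneity, and the seeded synthetic-read generator used for testing.

#' Precursor annotation constructor
#'
#' @param precursorId identifier.
#' @param precursor precursor sequence (RNA or DNA; stored as RNA).
#' @param guideInterval,starInterval,loopInterval 1-based inclusive intervals
#'   partitioning the precursor.
#' @return a [PrecursorAnnotation-class].
#' @export
precursorAnnotation <- function(precursorId, precursor, guideInterval,
                                starInterval, loopInterval) {
  precursor <- .asChar(precursor)
  if (.seqAlphabet(precursor) == "DNA") precursor <- dnaToRna(precursor)
  new("PrecursorAnnotation", precursorId = precursorId, precursor = precursor,
      guideInterval = as.integer(guideInterval),
      starInterval = as.integer(starInterval),
      loopInterval = as.integer(loopInterval))
}

#' Annotation of a decoded or assembled design's precursor
#'
#' Builds the guide/star/loop interval partition of a [MimirDesign-class]
#' precursor for read assignment, with the whole arms (scaffold flanks
#' included) assigned to the guide and star intervals.
#'
#' @param design a [MimirDesign-class].
#' @param precursorId identifier (defaults to the design's target id or
#'   "precursor").
#' @return a [PrecursorAnnotation-class].
#' @export
annotationFromDesign <- function(design, precursorId = NULL) {
  id <- precursorId %||%
    (if (!is.na(design@targetId)) design@targetId else "precursor")
  nStar <- nchar(design@star); nLoop <- nchar(design@loop)
  nGuide <- nchar(design@guide)
  pre <- design@precursor
  if (startsWith(pre, design@star)) {
    precursorAnnotation(id, pre,
                        guideInterval = c(nStar + nLoop + 1L, nStar + nLoop + nGuide),
                        starInterval = c(1L, nStar),
                        loopInterval = c(nStar + 1L, nStar + nLoop))
  } else {
    precursorAnnotation(id, pre,
                        guideInterval = c(1L, nGuide),
                        starInterval = c(nGuide + nLoop + 1L, nGuide + nLoop + nStar),
                        loopInterval = c(nGuide + 1L, nGuide + nLoop))
  }
}

#' Filter reads by minimum length
#'
#' Retains reads of at least \code{minLen} nucleotides (the boundary is
#' kept), preserving order. The default reproduces the standard small-RNA
#' pipeline cutoff of 18 nt.
#'
#' @param reads character vector of read sequences.
#' @param minLen minimum retained length.
#' @return filtered character vector.
#' @export
lengthFilter <- function(reads, minLen = 18L) {
  stopifnot(minLen >= 1L)
  reads[nchar(reads) >= minLen]
}

#' Collapse reads to unique sequences with multiplicities
#'
#' @param reads character vector of read sequences.
#' @return data.frame with columns \code{sequence} and \code{count} in
#'   first-seen order; counts sum to \code{length(reads)}.
#' @export
collapseReads <- function(reads) {
  if (!length(reads)) {
    return(data.frame(sequence = character(0), count = integer(0)))
  }
  tab <- table(factor(reads, levels = unique(reads)))
  data.frame(sequence = names(tab), count = as.integer(tab),
             row.names = NULL)
}

# locate a read within a precursor (both RNA), exact or <= k mismatches;
# returns first match start or NA
.locateRead <- function(read, precursor, maxMismatches = 0L) {
  if (nchar(read) > nchar(precursor)) return(NA_integer_)
  if (maxMismatches == 0L) {
    at <- as.integer(regexpr(read, precursor, fixed = TRUE))
    return(if (at > 0L) at else NA_integer_)
  }
  m <- Biostrings::matchPattern(Biostrings::DNAString(rnaToDna(read)),
                                Biostrings::DNAString(rnaToDna(precursor)),
                                max.mismatch = maxMismatches)
  if (length(m)) Biostrings::start(m)[1] else NA_integer_
}

#' Assign reads to precursors and strand classes
#'
#' Each read is placed on the first annotated precursor containing it as an
#' ungapped substring (exact match by default; \code{maxMismatches} allows a
#' tolerant mode). Within a precursor the strand label is the annotated
#' interval (guide, star or loop) with maximal overlap with the read;
#' equal-overlap ties resolve to guide. Reads overlapping the loop by at
#' least one base while assigned to an arm are flagged \code{loop_spanning}.
#' Reads matching no precursor are labelled \code{other}.
#'
#' @param reads character vector of read sequences (RNA or DNA).
#' @param annotations a [PrecursorAnnotation-class] or list of them.
#' @param maxMismatches substring-match tolerance (default 0, exact).
#' @return a [S4Vectors::DataFrame] with one row per read: \code{read},
#'   \code{precursor_id}, \code{offset} (1-based match start or \code{NA}),
#'   \code{label} (guide/star/loop/other), \code{loop_spanning}.
#' @export
assignReads <- function(reads, annotations, maxMismatches = 0L) {
  if (is(annotations, "PrecursorAnnotation")) annotations <- list(annotations)
  reads <- vapply(reads, function(r) {
    r <- .upperSeq(r)
    if (.seqAlphabet(r) == "DNA") dnaToRna(r) else r
  }, character(1), USE.NAMES = FALSE)

  n <- length(reads)
  pid <- rep(NA_character_, n); off <- rep(NA_integer_, n)
  label <- rep("other", n); loopSpan <- rep(FALSE, n)

  # collapse first: identical reads share one lookup
  uniq <- unique(reads)
  lookup <- lapply(uniq, function(rd) {
    for (ann in annotations) {
      at <- .locateRead(rd, ann@precursor, maxMismatches)
      if (!is.na(at)) {
        rdEnd <- at + nchar(rd) - 1L
        ivs <- list(guide = ann@guideInterval, star = ann@starInterval,
                    loop = ann@loopInterval)
        ov <- vapply(ivs, function(iv)
          max(0L, min(rdEnd, iv[2]) - max(at, iv[1]) + 1L), integer(1))
        lab <- names(ivs)[which.max(ov)]  # ties resolve to guide (first)
        span <- lab == "guide" && ov[["loop"]] >= 1L
        return(list(pid = ann@precursorId, off = at, label = lab, span = span))
      }
    }
    NULL
  })
  names(lookup) <- uniq
  for (i in seq_len(n)) {
    hit <- lookup[[reads[i]]]
    if (!is.null(hit)) {
      pid[i] <- hit$pid; off[i] <- hit$off
      label[i] <- hit$label; loopSpan[i] <- hit$span
    }
  }
  S4Vectors::DataFrame(read = reads, precursor_id = pid, offset = off,
                       label = label, loop_spanning = loopSpan)
}

#' Count assigned reads per precursor
#'
#' @param assignments output of [assignReads()].
#' @param precursorIds precursor ids to report (defaults to those observed).
#' @return data.frame with columns \code{precursor_id}, \code{guide},
#'   \code{star}, \code{loop}, \code{loop_spanning}, \code{other}; the
#'   \code{other} count (reads matching no precursor) is repeated on every
#'   row, and guide + star + loop summed over precursors plus other equals
#'   the number of input reads.
#' @export
countReads <- function(assignments, precursorIds = NULL) {
  ids <- precursorIds %||% unique(assignments$precursor_id[!is.na(assignments$precursor_id)])
  if (!length(ids)) ids <- character(0)
  other <- sum(assignments$label == "other")
  do.call(rbind, lapply(ids, function(id) {
    sel <- !is.na(assignments$precursor_id) & assignments$precursor_id == id
    data.frame(precursor_id = id,
               guide = sum(sel & assignments$label == "guide"),
               star = sum(sel & assignments$label == "star"),
               loop = sum(sel & assignments$label == "loop"),
               loop_spanning = sum(sel & assignments$loop_spanning),
               other = other)
  }))
}

#' Normalize counts to reads per million of genome-unmapped reads
#'
#' \code{rpm = count / unmappedTotal * 1e6}. The denominator is the number
#' of reads that did not map to the host genome — the appropriate library
#' size for exogenous mimics, which themselves are absent from the genome.
#'
#' @param counts numeric vector (or single value) of read counts.
#' @param unmappedTotal genome-unmapped read total; must be positive.
#' @return numeric RPM values.
#' @export
normalizeCounts <- function(counts, unmappedTotal) {
  if (length(unmappedTotal) != 1L || is.na(unmappedTotal) || unmappedTotal <= 0)
    stop("unmappedTotal must be a single positive count", call. = FALSE)
  counts / unmappedTotal * 1e6
}

#' Average normalized values across replicates
#'
#' Arithmetic mean per precursor per strand across biological replicates.
#'
#' @param rpm numeric vector, matrix (replicates in columns) or list of
#'   equal-length numeric vectors.
#' @return numeric vector of means.
#' @export
averageReplicates <- function(rpm) {
  if (is.list(rpm)) rpm <- do.call(cbind, rpm)
  if (is.matrix(rpm)) rowMeans(rpm) else mean(rpm)
}

#' Processing-homogeneity metrics of guide-assigned reads
#'
#' Canonical processing places the read 5' end exactly at the annotated
#' guide start; loop-spanning guide reads indicate imprecise hairpin
#' processing. Returns the canonical 5'-end fraction, the loop-spanning
#' fraction and the histogram of 5'-end offsets relative to the annotated
#' guide start (negative = upstream, into the loop for a 3'-arm guide).
#'
#' @param assignments output of [assignReads()].
#' @param annotation the [PrecursorAnnotation-class] to evaluate.
#' @return list with \code{nGuideReads}, \code{canonicalFraction},
#'   \code{loopSpanningFraction} and \code{offsetHistogram} (a table);
#'   fractions are \code{NA} (with a warning) when no guide reads are
#'   present.
#' @export
homogeneity <- function(assignments, annotation) {
  sel <- !is.na(assignments$precursor_id) &
    assignments$precursor_id == annotation@precursorId &
    assignments$label == "guide"
  nG <- sum(sel)
  if (nG == 0L) {
    warning("no guide-assigned reads for ", annotation@precursorId,
            call. = FALSE)
    return(list(nGuideReads = 0L, canonicalFraction = NA_real_,
                loopSpanningFraction = NA_real_,
                offsetHistogram = table(integer(0))))
  }
  offs <- assignments$offset[sel] - annotation@guideInterval[1]
  list(nGuideReads = nG,
       canonicalFraction = mean(offs == 0L),
       loopSpanningFraction = mean(assignments$loop_spanning[sel]),
       offsetHistogram = table(offs))
}

#' Synthetic-read configuration
#'
#' Configuration for [simulateReads()]: total reads, the fraction of
#' cleanly processed guide reads, the fraction of loop-spanning guide reads
#' (5' ends inside the loop), the 5'-end jitter distribution applied to
#' clean guide reads, the read-length window (default 18--30 nt, the gel
#' size-selection window of a typical small-RNA library), and the RNG seed.
#' The remainder fraction (1 - guideFraction - loopSpanningFraction) is
#' drawn as star reads.
#'
#' @param nReads number of reads.
#' @param guideFraction fraction of cleanly processed guide reads.
#' @param loopSpanningFraction fraction of guide reads starting in the loop.
#' @param jitterProbs named numeric vector of 5'-offset probabilities for
#'   clean guide reads (names are offsets; must sum to 1).
#' @param lengthRange length-2 integer read-length window.
#' @param seed RNG seed.
#' @return list of class \code{synthReadConfig}.
#' @export
synthReadConfig <- function(nReads = 10000L, guideFraction = 0.8,
                            loopSpanningFraction = 0.05,
                            jitterProbs = c(`0` = 1),
                            lengthRange = c(18L, 30L), seed = 1L) {
  stopifnot(nReads >= 1L, guideFraction >= 0, loopSpanningFraction >= 0)
  if (guideFraction + loopSpanningFraction > 1)
    stop("guideFraction + loopSpanningFraction must be <= 1", call. = FALSE)
  if (abs(sum(jitterProbs) - 1) > 1e-8)
    stop("jitterProbs must sum to 1", call. = FALSE)
  if (is.null(names(jitterProbs)))
    stop("jitterProbs must be named by integer offsets", call. = FALSE)
  structure(list(nReads = as.integer(nReads), guideFraction = guideFraction,
                 loopSpanningFraction = loopSpanningFraction,
                 jitterProbs = jitterProbs,
                 lengthRange = as.integer(lengthRange), seed = as.integer(seed)),
            class = "synthReadConfig")
}

# run expr with a local, restored RNG state seeded from `seed`
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate AGO-IP small-RNA reads from an annotated precursor
#'
#' Draws reads from three classes per the configured fractions: clean guide
#' reads (5' end at the annotated guide start plus jitter), loop-spanning
#' guide reads (5' end inside the loop, within reach of the guide so the
#' maximal-overlap label remains guide) and star reads (5' end at the
#' annotated star start). Read lengths are uniform on the configured window,
#' clipped at the precursor 3' end. Output is byte-identical for a fixed
#' seed.
#'
#' @param config a [synthReadConfig()].
#' @param annotation a [PrecursorAnnotation-class].
#' @return named character vector of read sequences (RNA).
#' @export
simulateReads <- function(config, annotation) {
  stopifnot(inherits(config, "synthReadConfig"))
  pre <- annotation@precursor
  n <- config$nReads
  gIv <- annotation@guideInterval
  sIv <- annotation@starInterval
  lIv <- annotation@loopInterval
  .withSeed(config$seed, {
    classes <- sample(c("guide", "loop_spanning", "star"), n, replace = TRUE,
                      prob = c(config$guideFraction, config$loopSpanningFraction,
                               1 - config$guideFraction - config$loopSpanningFraction))
    offsets <- as.integer(names(config$jitterProbs))
    starts <- integer(n)
    starts[classes == "guide"] <- gIv[1] +
      sample(offsets, sum(classes == "guide"), replace = TRUE,
             prob = config$jitterProbs)
    # loop-spanning reads start 1..min(3, loop length) bases into the loop
    reach <- min(3L, lIv[2] - lIv[1] + 1L)
    starts[classes == "loop_spanning"] <- gIv[1] -
      sample(seq_len(reach), sum(classes == "loop_spanning"), replace = TRUE)
    starts[classes == "star"] <- sIv[1]
    starts <- pmax(1L, pmin(starts, nchar(pre)))
    lens <- sample(seq(config$lengthRange[1], config$lengthRange[2]), n,
                   replace = TRUE)
    ends <- pmin(starts + lens - 1L, nchar(pre))
    reads <- substring(pre, starts, ends)
    names(reads) <- sprintf("%s_%s_%06d", annotation@precursorId, classes,
                            seq_len(n))
    reads
  })
}

#' Quantify guide/star loading across replicates
#'
#' Full desk-scale pipeline: length-filter each replicate's reads, assign
#' them to the annotated precursors, count strand classes, normalize to
#' reads per million of genome-unmapped reads, average replicates, and
#' compute per-replicate processing-homogeneity metrics.
#'
#' @param readSets list of character vectors, one per replicate (named or
#'   numbered).
#' @param annotations a [PrecursorAnnotation-class] or list of them.
#' @param unmappedTotals numeric vector of genome-unmapped totals, one per
#'   replicate (recycled if length 1).
#' @param minLen length filter threshold.
#' @param maxMismatches read-to-precursor match tolerance.
#' @return a [LoadingQuant-class].
#' @export
quantifyLoading <- function(readSets, annotations, unmappedTotals,
                            minLen = 18L, maxMismatches = 0L) {
  if (is(annotations, "PrecursorAnnotation")) annotations <- list(annotations)
  if (!is.list(readSets)) readSets <- list(readSets)
  nRep <- length(readSets)
  if (is.null(names(readSets))) names(readSets) <- paste0("rep", seq_len(nRep))
  unmappedTotals <- rep_len(unmappedTotals, nRep)
  ids <- vapply(annotations, function(a) a@precursorId, character(1))

  counts <- list(); rpm <- list(); homo <- list()
  for (r in seq_len(nRep)) {
    reads <- lengthFilter(readSets[[r]], minLen)
    asg <- assignReads(reads, annotations, maxMismatches)
    ct <- countReads(asg, precursorIds = ids)
    ct$replicate <- names(readSets)[r]
    counts[[r]] <- ct
    rpm[[r]] <- data.frame(
      precursor_id = ct$precursor_id, replicate = ct$replicate,
      guide_rpm = normalizeCounts(ct$guide, unmappedTotals[r]),
      star_rpm = normalizeCounts(ct$star, unmappedTotals[r]))
    homo[[r]] <- do.call(rbind, lapply(annotations, function(a) {
      h <- suppressWarnings(homogeneity(asg, a))
      data.frame(precursor_id = a@precursorId, replicate = names(readSets)[r],
                 canonical_fraction = h$canonicalFraction,
                 loop_spanning_fraction = h$loopSpanningFraction)
    }))
  }
  counts <- do.call(rbind, counts)
  rpm <- do.call(rbind, rpm)
  means <- do.call(rbind, lapply(ids, function(id) {
    sel <- rpm$precursor_id == id
    data.frame(precursor_id = id,
               guide_rpm_mean = mean(rpm$guide_rpm[sel]),
               star_rpm_mean = mean(rpm$star_rpm[sel]))
  }))
  new("LoadingQuant", counts = counts, rpm = rpm, means = means,
      homogeneity = do.call(rbind, homo), unmappedTotals = unmappedTotals)
}

#' Accessors for loading quantification results
#'
#' @param x a [LoadingQuant-class].
#' @return the corresponding data.frame slot.
#' @name quant-accessors
NULL

#' @rdname quant-accessors
#' @export
loadingCounts <- function(x) x@counts
#' @rdname quant-accessors
#' @export
loadingRpm <- function(x) x@rpm
#' @rdname quant-accessors
#' @export
loadingMeans <- function(x) x@means
#' @rdname quant-accessors
#' @export
loadingHomogeneity <- function(x) x@homogeneity
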