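# Reporter mRNA constructs: promoter + kozak + CDS + engineered 3' UTR with
# a configurable number of seed sites at fixed spacing, plus polyA handling.

#' EF1-alpha kozak sequence used by the packaged reporter constructs
#' @export
EF1A_KOZAK <- "TGTTAAACCAACCAACCACC"

# leading promoter match on a SENSE sequence (promoter readable directly)
.senseStartPromoter <- function(seq, promoters) {
  best <- NULL; bestSpec <- -1L
  for (p in promoters) {
    if (!startsWith(seq, p@motif)) next
    body <- substring(seq, nchar(p@motif) + 1L)
    if (nzchar(p@plusOne) && !startsWith(body, p@plusOne)) next
    spec <- nchar(p@plusOne) * 100L + nchar(p@motif)
    if (spec > bestSpec) { best <- p; bestSpec <- spec }
  }
  best
}

#' Parse a reporter mRNA sequence into its construct parts
#'
#' Splits a sense mRNA (or gBlock) sequence into promoter, leader, kozak,
#' CDS, 3' UTR and an encoded polyA run: the promoter is recognised at the 5'
#' end (sense orientation, most specific +1-compatible candidate wins; absent
#' promoters are tolerated), the kozak by its first occurrence, the CDS as
#' the first in-frame open reading frame from the first ATG after the kozak,
#' and a trailing run of at least \code{minPolyA} A's as an ENCODED polyA
#' tail. [assembleMrna()] on the result reproduces the input byte for byte.
#'
#' @param seq sense DNA sequence.
#' @param promoters promoter candidates.
#' @param kozak kozak sequence to look for.
#' @param minPolyA minimum trailing A-run length parsed as an encoded tail.
#' @return a [ReporterConstruct-class].
#' @export
parseReporter <- function(seq, promoters = defaultPromoters(),
                          kozak = EF1A_KOZAK, minPolyA = 10L) {
  seq <- .asChar(seq)
  .checkBases(seq, "DNA", what = "construct")
  prom <- .senseStartPromoter(seq, promoters)
  body <- if (is.null(prom)) seq else substring(seq, nchar(prom@motif) + 1L)

  kAt <- as.integer(regexpr(kozak, body, fixed = TRUE))
  if (kAt > 0L) {
    leader <- substr(body, 1L, kAt - 1L)
    afterKozak <- substring(body, kAt + nchar(kozak))
    kz <- kozak
  } else {
    leader <- ""
    afterKozak <- body
    kz <- ""
  }

  atg <- as.integer(regexpr("ATG", afterKozak, fixed = TRUE))
  if (atg < 1L) stop("no ATG found downstream of the kozak", call. = FALSE)
  if (kAt < 1L) {
    # without a kozak anchor, everything before the ATG is leader
    leader <- substr(afterKozak, 1L, atg - 1L)
    afterKozak <- substring(afterKozak, atg)
    atg <- 1L
  }
  cdsRegion <- substring(afterKozak, atg)
  ncod <- nchar(cdsRegion) %/% 3L
  codons <- substring(cdsRegion, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
  stopAt <- which(codons %in% c("TAA", "TAG", "TGA"))
  if (!length(stopAt)) stop("no in-frame stop codon found", call. = FALSE)
  cds <- substr(cdsRegion, 1L, 3L * stopAt[1])
  utr3 <- substring(cdsRegion, 3L * stopAt[1] + 1L)
  pre <- substr(afterKozak, 1L, atg - 1L)
  leader <- paste0(leader, pre)

  polyA <- "NONE"; polyALen <- 0L
  tail <- regmatches(utr3, regexpr("A+$", utr3))
  if (length(tail) && nchar(tail) >= minPolyA) {
    polyA <- "ENCODED"; polyALen <- nchar(tail)
    utr3 <- substr(utr3, 1L, nchar(utr3) - polyALen)
  }

  new("ReporterConstruct",
      promoterName = if (is.null(prom)) NA_character_ else prom@name,
      leader = leader, kozak = kz, cds = cds, utr3 = utr3,
      polyA = polyA, polyALength = polyALen)
}

#' Assemble a reporter construct into a sequence
#'
#' Concatenates promoter motif (sense), leader, kozak, CDS, 3' UTR and the
#' encoded polyA run (if any). \code{what = "sense"} returns the sense
#' sequence as synthesised/printed; \code{what = "template"} returns the
#' ordered single-stranded template (reverse complement of the sense
#' sequence), which round-trips through [transcribeTemplate()].
#'
#' @param construct a [ReporterConstruct-class].
#' @param what \code{"sense"} or \code{"template"}.
#' @param promoters promoter set used to resolve the construct's promoter
#'   name back to its motif.
#' @return DNA sequence string.
#' @export
assembleMrna <- function(construct, what = c("sense", "template"),
                         promoters = defaultPromoters()) {
  what <- match.arg(what)
  motif <- ""
  if (!is.na(construct@promoterName)) {
    prom <- promoters[[construct@promoterName]]
    if (is.null(prom))
      stop("unknown promoter name: ", construct@promoterName, call. = FALSE)
    motif <- prom@motif
    body <- paste0(construct@leader, construct@kozak, construct@cds)
    if (nzchar(prom@plusOne) && !startsWith(body, prom@plusOne))
      stop(sprintf("transcript start incompatible with %s +1 requirement '%s'",
                   prom@name, prom@plusOne), call. = FALSE)
  } else if (what == "template") {
    stop("cannot emit an ordered template without a promoter", call. = FALSE)
  }
  sense <- paste0(motif, construct@leader, construct@kozak, construct@cds,
                  construct@utr3,
                  if (construct@polyA == "ENCODED")
                    strrep("A", construct@polyALength) else "")
  if (what == "sense") sense else revComp(sense)
}

#' Engineer a 3' UTR with uniformly spaced seed sites
#'
#' Inserts copies of an existing seed site so the UTR carries \code{nSites}
#' occurrences with exactly \code{gap} intervening bases between consecutive
#' sites (end-to-start). New copies are inserted upstream of the original
#' (first) occurrence; the spacer between inserted copies reuses the
#' \code{gap} bases immediately preceding the original site, so the local
#' sequence context of every site is identical. An optional full-match site
#' elsewhere in the UTR is verified to survive the edit.
#'
#' @param baseUtr UTR sequence (DNA) containing at least one \code{seedSite}.
#' @param seedSite the seed-site motif (DNA, sense strand; for a guide g this
#'   is \code{revComp} of the guide's design-seed bases).
#' @param nSites desired total number of sites.
#' @param gap intervening bases between consecutive sites.
#' @param fullSite optional full-match site sequence that must remain intact.
#' @return the engineered UTR (DNA).
#' @export
buildUtr <- function(baseUtr, seedSite, nSites, gap = 21L, fullSite = NULL) {
  baseUtr <- .asChar(baseUtr); seedSite <- .asChar(seedSite)
  if (nSites < 1L) stop("nSites must be >= 1", call. = FALSE)
  if (gap < 0L) stop("gap must be >= 0", call. = FALSE)
  occ <- gregexpr(seedSite, baseUtr, fixed = TRUE)[[1]]
  if (occ[1] == -1L)
    stop("base UTR does not contain the seed site", call. = FALSE)
  nExisting <- length(occ)
  if (nExisting > nSites)
    stop(sprintf("base UTR already contains %d sites (> nSites = %d)",
                 nExisting, nSites), call. = FALSE)
  if (nExisting == nSites) return(baseUtr)
  if (nExisting > 1L)
    stop("insertion with multiple pre-existing sites is not supported; ",
         "start from a UTR with one original site", call. = FALSE)

  p <- occ[1]
  if (p <= gap)
    stop("not enough bases upstream of the original site to reuse as spacer",
         call. = FALSE)
  spacer <- substr(baseUtr, p - gap, p - 1L)
  block <- strrep(paste0(seedSite, spacer), nSites - nExisting)
  out <- paste0(substr(baseUtr, 1L, p - 1L), block, substring(baseUtr, p))

  occ2 <- gregexpr(seedSite, out, fixed = TRUE)[[1]]
  if (length(occ2) != nSites)
    stop("insertion created or destroyed seed-site occurrences; ",
         "choose a different spacer context", call. = FALSE)
  gaps <- diff(occ2) - nchar(seedSite)
  if (any(gaps != gap))
    stop("inserted sites are not uniformly spaced", call. = FALSE)
  if (!is.null(fullSite)) {
    nFull <- length(gregexpr(fullSite, baseUtr, fixed = TRUE)[[1]])
    nFull2 <- gregexpr(fullSite, out, fixed = TRUE)[[1]]
    nFull2 <- if (nFull2[1] == -1L) 0L else length(nFull2)
    if (nFull2 != nFull)
      stop("insertions would overlap or disrupt the full-match site",
           call. = FALSE)
  }
  out
}

#' Validate a reporter mRNA against its guides
#'
#' Reports the construct architecture as found in the sequence: kozak
#' position, CDS bounds, every guide's binding sites (seed-mode and
#' near-full-mode scans with region annotation), the seed-site count and the
#' pairwise gaps between consecutive seed regions, and the full-match-site
#' count. The seed region of a hit is the stretch pairing the guide's design
#' seed interval (the last 8 bases of a default site), which is the region
#' whose spacing the construct design fixes.
#'
#' @param mrna reporter mRNA sequence (sense, DNA; may include the promoter).
#' @param guides named character vector (or list) of guide sequences.
#' @param spec a [PatternSpec-class].
#' @param kozak kozak sequence to locate.
#' @return a list of class \code{reporterValidation}: \code{kozakFound},
#'   \code{kozakPos}, \code{cdsStart}, \code{cdsEnd}, \code{regions}
#'   (annotation data.frame), \code{hits} (per guide, seed-mode),
#'   \code{seedSiteCount}, \code{seedRegionStarts}, \code{seedGaps},
#'   \code{fullMatchCount} (per guide, near-full mode).
#' @export
validateConstruct <- function(mrna, guides, spec = patternSpec(),
                              kozak = EF1A_KOZAK) {
  mrna <- .asChar(mrna)
  if (.seqAlphabet(mrna) == "RNA") mrna <- rnaToDna(mrna)
  if (is.list(guides)) guides <- unlist(guides)
  if (is.null(names(guides))) names(guides) <- paste0("guide", seq_along(guides))

  kozakPos <- as.integer(regexpr(kozak, mrna, fixed = TRUE))
  kozakFound <- kozakPos > 0L

  cons <- tryCatch(parseReporter(mrna, kozak = kozak), error = function(e) NULL)
  regions <- NULL
  cdsStart <- NA_integer_; cdsEnd <- NA_integer_
  if (!is.null(cons)) {
    cdsStart <- as.integer(regexpr(cons@cds, mrna, fixed = TRUE))
    cdsEnd <- cdsStart + nchar(cons@cds) - 1L
    regions <- data.frame(
      region = c("UTR5", "CDS", "UTR3"),
      start = c(1L, cdsStart, cdsEnd + 1L),
      end = c(cdsStart - 1L, cdsEnd, nchar(mrna)))
    regions <- regions[regions$start <= regions$end, , drop = FALSE]
  }

  ds <- spec@designSeedInterval
  seedLen <- ds[2] - ds[1] + 1L
  hits <- lapply(guides, function(g)
    scanTranscript(g, mrna, annotation = regions, spec = spec, mode = "seed"))
  fullHits <- lapply(guides, function(g)
    scanTranscript(g, mrna, annotation = regions, spec = spec,
                   mode = "near_full"))

  allSeed <- do.call(rbind, lapply(hits, as.data.frame))
  L <- nchar(guides[1])
  if (!is.null(allSeed) && nrow(allSeed)) {
    # the seed region pairs guide positions ds[1]..ds[2], i.e. the site tail
    seedStarts <- sort(allSeed$end - seedLen + 1L)
    seedGaps <- if (length(seedStarts) > 1L)
      diff(seedStarts) - seedLen else integer(0)
  } else {
    seedStarts <- integer(0); seedGaps <- integer(0)
  }

  structure(list(
    kozakFound = kozakFound, kozakPos = if (kozakFound) kozakPos else NA_integer_,
    cdsStart = cdsStart, cdsEnd = cdsEnd, regions = regions,
    hits = hits,
    seedSiteCount = sum(vapply(hits, nrow, integer(1))),
    seedRegionStarts = seedStarts, seedGaps = seedGaps,
    fullMatchCount = sum(vapply(fullHits, nrow, integer(1))),
    fullHits = fullHits), class = "reporterValidation")
}

#' @export
print.reporterValidation <- function(x, ...) {
  cat("Reporter validation\n")
  cat(sprintf("  kozak: %s\n",
              if (x$kozakFound) sprintf("found at %d", x$kozakPos) else "MISSING"))
  cat(sprintf("  CDS: %s\n",
              if (is.na(x$cdsStart)) "not found" else
                sprintf("%d-%d", x$cdsStart, x$cdsEnd)))
  cat(sprintf("  seed sites: %d (gaps: %s)\n", x$seedSiteCount,
              paste(x$seedGaps, collapse = ",")))
  cat(sprintf("  full-match sites: %d\n", x$fullMatchCount))
  invisible(x)
}
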