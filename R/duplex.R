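# Guide-target pairing model: antiparallel, ungapped, 1-based guide
# positions counted from the guide 5' end.

.WC <- c(AU = TRUE, UA = TRUE, GC = TRUE, CG = TRUE)
.WOBBLE <- c(GU = TRUE, UG = TRUE)

# vectorized pair-state over single RNA bases
.pairStateVec <- function(g, s) {
  key <- paste0(g, s)
  out <- rep("MISMATCH", length(key))
  out[!is.na(.WC[key])] <- "WATSON_CRICK"
  out[!is.na(.WOBBLE[key])] <- "WOBBLE"
  out
}

#' Pair state of two opposing RNA bases
#'
#' \code{WATSON_CRICK} for A:U, U:A, G:C, C:G; \code{WOBBLE} for G:U and U:G;
#' \code{MISMATCH} otherwise (including any pair involving N).
#'
#' @param guideBase,siteBase single RNA bases (vectorized).
#' @return character vector of pair states.
#' @examples
#' pairState("G", "C")  # WATSON_CRICK
#' pairState("G", "U")  # WOBBLE
#' @export
pairState <- function(guideBase, siteBase) {
  g <- .upperSeq(guideBase); s <- .upperSeq(siteBase)
  stopifnot(all(nchar(g) == 1L), all(nchar(s) == 1L))
  .checkBases(paste(c(g, s), collapse = ""), "RNA", what = "base")
  .pairStateVec(g, s)
}

#' Complementarity rule set constructor
#'
#' Returns a [PatternSpec-class] with the packaged defaults: classification
#' seed at positions 2--8 (position 1 additionally required to pair), design
#' seed 1--8 for seed-mode scanning, supplementary interval 13--16, central
#' positions 10--11, fixed base C at guide position 19, wobbles counted as
#' mismatches, and a near-full mismatch budget of 2.
#'
#' @param seedInterval,designSeedInterval,suppInterval length-2 intervals of
#'   guide positions.
#' @param centralPositions central (cleavage-site) guide positions.
#' @param fixedBases named character vector, guide position -> base; fixed
#'   positions never disqualify a near-full call.
#' @param wobbleIsMatch treat G:U wobble as a match.
#' @param nearFullMaxMismatches maximum mismatch count (fixed positions
#'   included) for the NEAR_FULL category.
#' @param requirePos1 require guide position 1 to pair for the seed to count
#'   as matched in classification.
#' @return a [PatternSpec-class].
#' @export
patternSpec <- function(seedInterval = c(2L, 8L),
                        designSeedInterval = c(1L, 8L),
                        suppInterval = c(13L, 16L),
                        centralPositions = c(10L, 11L),
                        fixedBases = c(`19` = "C"),
                        wobbleIsMatch = FALSE,
                        nearFullMaxMismatches = 2L,
                        requirePos1 = TRUE) {
  new("PatternSpec",
      seedInterval = as.integer(seedInterval),
      designSeedInterval = as.integer(designSeedInterval),
      suppInterval = as.integer(suppInterval),
      centralPositions = as.integer(centralPositions),
      fixedBases = if (length(fixedBases)) {
        fb <- vapply(fixedBases, .upperSeq, character(1))
        names(fb) <- names(fixedBases); fb
      } else character(0),
      wobbleIsMatch = isTRUE(wobbleIsMatch),
      nearFullMaxMismatches = as.integer(nearFullMaxMismatches),
      requirePos1 = isTRUE(requirePos1))
}

#' Align a guide against a target site
#'
#' Ungapped antiparallel register: guide position i (from the guide 5' end)
#' faces site position L+1-i, where the site is given in transcript sense
#' orientation 5'->3'. Both sequences must be the same length; DNA input is
#' converted to RNA.
#'
#' @param guide guide sequence, 5'->3'.
#' @param site target site, transcript sense 5'->3', same length.
#' @return a [DuplexAlignment-class].
#' @export
alignDuplex <- function(guide, site) {
  guide <- .asChar(guide); site <- .asChar(site)
  if (.seqAlphabet(guide) == "DNA") guide <- dnaToRna(guide)
  if (.seqAlphabet(site) == "DNA") site <- dnaToRna(site)
  if (nchar(guide) != nchar(site))
    stop("guide and site must have equal length (ungapped model)", call. = FALSE)
  .checkBases(guide, "RNA", what = "guide")
  .checkBases(site, "RNA", what = "site")
  g <- .splitBases(guide)
  s <- rev(.splitBases(site))  # site position L+1-i faces guide position i
  new("DuplexAlignment", guide = guide, site = site,
      states = .pairStateVec(g, s))
}

# positions whose state does not count as a match under the spec
.mismatchPositions <- function(aln, spec) {
  ok <- aln@states == "WATSON_CRICK"
  if (spec@wobbleIsMatch) ok <- ok | aln@states == "WOBBLE"
  which(!ok)
}

#' Mismatch positions of an alignment
#'
#' Guide positions whose pair state does not count as a match under the
#' supplied rule set (wobbles count as mismatches unless
#' \code{wobbleIsMatch}).
#'
#' @param aln a [DuplexAlignment-class].
#' @param spec a [PatternSpec-class].
#' @return sorted integer vector of guide positions.
#' @export
mismatchPositions <- function(aln, spec = patternSpec()) {
  .mismatchPositions(aln, spec)
}

.CATEGORIES <- c("NEAR_FULL", "SEED_ONLY", "SEED_SUPPLEMENTARY",
                 "CENTRAL_MM_10", "CENTRAL_MM_11", "CENTRAL_MM_10_11", "NONE")

#' Classify a guide-site alignment into a complementarity mode
#'
#' Deterministic, mutually exclusive classification, evaluated in precedence
#' order:
#' \enumerate{
#'   \item \code{NEAR_FULL}: total mismatch count within the budget
#'     (\code{nearFullMaxMismatches}, fixed-base positions counted but never
#'     disqualifying) and no non-fixed mismatch in the seed or at a central
#'     position;
#'   \item \code{CENTRAL_MM_10_11} / \code{CENTRAL_MM_10} /
#'     \code{CENTRAL_MM_11}: the only non-fixed deviations from near-full lie
#'     at central positions;
#'   \item \code{SEED_SUPPLEMENTARY}: seed fully matched, supplementary
#'     interval fully matched, at least one central position mismatched;
#'   \item \code{SEED_ONLY}: seed fully matched, supplementary interval not
#'     fully matched;
#'   \item \code{NONE} otherwise.
#' }
#' "Seed fully matched" means no mismatch in \code{seedInterval} (positions
#' 2--8 by default) and, when \code{requirePos1}, none at position 1 either.
#'
#' @param aln a [DuplexAlignment-class].
#' @param spec a [PatternSpec-class].
#' @return a single category string.
#' @export
classifyAlignment <- function(aln, spec = patternSpec()) {
  mm <- .mismatchPositions(aln, spec)
  fixedPos <- as.integer(names(spec@fixedBases))
  nonFixed <- setdiff(mm, fixedPos)
  seedPos <- seq(spec@seedInterval[1], spec@seedInterval[2])
  if (spec@requirePos1) seedPos <- union(1L, seedPos)
  suppPos <- seq(spec@suppInterval[1], spec@suppInterval[2])
  central <- spec@centralPositions

  seedStrict <- !any(mm %in% seedPos)   # used for seed categories below

  if (length(mm) <= spec@nearFullMaxMismatches &&
      !any(nonFixed %in% seedPos) && !any(nonFixed %in% central))
    return("NEAR_FULL")

  centralHit <- intersect(nonFixed, central)
  if (length(centralHit) && all(nonFixed %in% central)) {
    if (setequal(centralHit, c(10L, 11L))) return("CENTRAL_MM_10_11")
    if (identical(centralHit, 10L)) return("CENTRAL_MM_10")
    if (identical(centralHit, 11L)) return("CENTRAL_MM_11")
    return(paste0("CENTRAL_MM_", paste(sort(centralHit), collapse = "_")))
  }

  suppOK <- !any(mm %in% suppPos)
  if (seedStrict && suppOK && any(central %in% mm)) return("SEED_SUPPLEMENTARY")
  if (seedStrict && !suppOK) return("SEED_ONLY")
  "NONE"
}

#' Predicted cleavage coordinate of an alignment placed on a transcript
#'
#' Slicing AGOs cut the target between the bases facing guide positions 10
#' and 11. For a guide of length L whose site starts at transcript position
#' \code{start}, that is the phosphodiester bond between transcript positions
#' \code{start + L - 11} and \code{start + L - 10}; the returned coordinate is
#' the 5' base of the bond. \code{NA} when either central position is not
#' Watson-Crick paired.
#'
#' @param aln a [DuplexAlignment-class].
#' @param start 1-based transcript coordinate of the site start.
#' @return integer coordinate or \code{NA}.
#' @export
cleavageCoordinate <- function(aln, start = 1L) {
  L <- nchar(aln@guide)
  if (L < 11L) return(NA_integer_)
  if (all(aln@states[c(10L, 11L)] == "WATSON_CRICK"))
    as.integer(start + L - 11L)
  else NA_integer_
}

# map hit intervals to regions by maximal overlap; annotation is a
# data.frame(region, start, end)
.annotateRegion <- function(starts, ends, annotation) {
  if (is.null(annotation)) return(rep("UNANNOTATED", length(starts)))
  stopifnot(all(c("region", "start", "end") %in% names(annotation)))
  vapply(seq_along(starts), function(i) {
    ov <- pmin(ends[i], annotation$end) - pmax(starts[i], annotation$start) + 1L
    if (all(ov <= 0L)) return("UNANNOTATED")
    as.character(annotation$region[which.max(ov)])
  }, character(1))
}

#' Scan a transcript for guide binding sites
#'
#' Slides a guide-length window over the transcript and reports windows that
#' qualify under the chosen mode: \code{"seed"} requires a full Watson-Crick
#' match across the design seed interval (guide positions 1--8 by default),
#' \code{"near_full"} requires a NEAR_FULL classification, and \code{"all"}
#' reports every window whose category is not NONE. Overlapping qualifying
#' windows are resolved greedily left to right, so a transcript base belongs
#' to at most one reported site.
#'
#' @param guide guide sequence (RNA or DNA), 5'->3'.
#' @param transcript transcript sequence, sense 5'->3'.
#' @param annotation optional region map, a data.frame with columns
#'   \code{region} (e.g. UTR5/CDS/UTR3), \code{start}, \code{end} in
#'   transcript coordinates; hits are \code{UNANNOTATED} when absent.
#' @param spec a [PatternSpec-class].
#' @param mode \code{"seed"}, \code{"near_full"} or \code{"all"}.
#' @param transcriptId identifier used in the report.
#' @return a [S4Vectors::DataFrame] with columns \code{transcript_id},
#'   \code{start}, \code{end}, \code{region}, \code{category},
#'   \code{mismatch_positions} (comma-separated guide positions) and
#'   \code{cleavage_coord} (\code{NA} when the central positions are not both
#'   paired).
#' @export
scanTranscript <- function(guide, transcript, annotation = NULL,
                           spec = patternSpec(),
                           mode = c("seed", "near_full", "all"),
                           transcriptId = "transcript") {
  mode <- match.arg(mode)
  guide <- .asChar(guide); transcript <- .asChar(transcript)
  if (.seqAlphabet(guide) == "DNA") guide <- dnaToRna(guide)
  rnaT <- if (.seqAlphabet(transcript) == "DNA") dnaToRna(transcript) else transcript
  L <- nchar(guide)
  n <- nchar(rnaT)
  if (L > n) stop("guide longer than transcript", call. = FALSE)

  empty <- S4Vectors::DataFrame(transcript_id = character(0), start = integer(0),
                                end = integer(0), region = character(0),
                                category = character(0),
                                mismatch_positions = character(0),
                                cleavage_coord = integer(0))
  starts <- seq_len(n - L + 1L)

  if (mode == "seed") {
    # a window qualifies iff its bases facing the design seed interval are the
    # exact Watson-Crick complement of the guide there; for the default
    # interval [1,8] that is: window[(L-7)..L] == revComp(guide[1..8])
    ds <- spec@designSeedInterval
    motif <- revComp(substr(guide, ds[1], ds[2]))
    lo <- L + 1L - ds[2]; hi <- L + 1L - ds[1]
    keep <- vapply(starts, function(s)
      substr(rnaT, s + lo - 1L, s + hi - 1L) == motif, logical(1))
    starts <- starts[keep]
  }

  if (!length(starts)) return(empty)
  rows <- lapply(starts, function(s) {
    aln <- alignDuplex(guide, substr(rnaT, s, s + L - 1L))
    cat. <- classifyAlignment(aln, spec)
    list(start = s, category = cat.,
         mm = .mismatchPositions(aln, spec),
         cleave = cleavageCoordinate(aln, s))
  })
  keep <- switch(mode,
    seed = rep(TRUE, length(rows)),
    near_full = vapply(rows, function(r) r$category == "NEAR_FULL", logical(1)),
    all = vapply(rows, function(r) r$category != "NONE", logical(1)))
  rows <- rows[keep]
  if (!length(rows)) return(empty)

  # greedy left-to-right overlap resolution
  lastEnd <- 0L
  sel <- logical(length(rows))
  for (i in seq_along(rows)) {
    if (rows[[i]]$start > lastEnd) {
      sel[i] <- TRUE
      lastEnd <- rows[[i]]$start + L - 1L
    }
  }
  rows <- rows[sel]

  st <- vapply(rows, `[[`, integer(1), "start")
  en <- st + L - 1L
  S4Vectors::DataFrame(
    transcript_id = rep(transcriptId, length(rows)),
    start = st, end = en,
    region = .annotateRegion(st, en, annotation),
    category = vapply(rows, `[[`, character(1), "category"),
    mismatch_positions = vapply(rows, function(r)
      paste(r$mm, collapse = ","), character(1)),
    cleavage_coord = vapply(rows, `[[`, integer(1), "cleave"))
}
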