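#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Bacteriophage promoter specification
#'
#' Describes a single-subunit RNA polymerase promoter as used when decoding or
#' emitting ordered in vitro transcription templates. The \code{motif} is the
#' promoter sequence on the sense (transcript-bearing) strand and \code{plusOne}
#' is the base (or bases) required at the transcript's 5' end, immediately
#' after the motif. \code{plusOne} encodes the +1 convention: transcription is
#' taken to start at the first base following the motif, and a promoter only
#' matches a template when the transcript begins with \code{plusOne}.
#'
#' @slot name promoter name, e.g. \code{"T7_STD"}.
#' @slot motif promoter motif, DNA, sense strand.
#' @slot plusOne required transcript start (e.g. \code{"G"} for standard T7,
#'   \code{"A"} for T7 class II phi2.5, \code{"AG"} for CleanCap-AG
#'   templates). May be \code{""} for no requirement.
#' @seealso [defaultPromoters()], [transcribeTemplate()], [makeTemplate()]
#' @exportClass PromoterSpec
setClass("PromoterSpec",
  representation(name = "character", motif = "character", plusOne = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@motif) != 1L || !nzchar(object@motif))
      msg <- c(msg, "motif must be a single non-empty DNA string")
    else .checkBases(object@motif, "DNA", allowN = FALSE, what = "promoter motif")
    if (length(object@plusOne) != 1L)
      msg <- c(msg, "plusOne must be a single string (possibly empty)")
    if (is.null(msg)) TRUE else msg
  }
)

setMethod("show", "PromoterSpec", function(object) {
  cat(sprintf("PromoterSpec %s: %s / +1 '%s'\n",
              object@name, object@motif, object@plusOne))
})

#' Positional complementarity rule set
#'
#' A \code{PatternSpec} carries the guide-position rules that define the
#' complementarity modes: the seed interval used for classification (default
#' positions 2--8, with position 1 additionally required to pair), the design
#' seed interval used for seed-mode scanning (default 1--8), the 3'
#' supplementary interval (default 13--16), the central cleavage-site
#' positions (default 10 and 11), fixed guide bases that are never allowed to
#' disqualify a near-full call (default position 19 = C, a transcription
#' constraint), and whether a G:U wobble counts as a match.
#'
#' @slot seedInterval integer length-2, classification seed interval.
#' @slot designSeedInterval integer length-2, seed interval for seed-mode scans.
#' @slot suppInterval integer length-2, supplementary interval.
#' @slot centralPositions integer, central (cleavage-site) positions.
#' @slot fixedBases named character, guide position -> base.
#' @slot wobbleIsMatch logical, treat G:U as a match (default \code{FALSE}).
#' @slot nearFullMaxMismatches integer, mismatch budget for NEAR_FULL.
#' @slot requirePos1 logical, classification also requires position 1 to pair.
#' @seealso [patternSpec()], [classifyAlignment()]
#' @exportClass PatternSpec
setClass("PatternSpec",
  representation(seedInterval = "integer", designSeedInterval = "integer",
                 suppInterval = "integer", centralPositions = "integer",
                 fixedBases = "character", wobbleIsMatch = "logical",
                 nearFullMaxMismatches = "integer", requirePos1 = "logical"),
  validity = function(object) {
    msg <- NULL
    for (s in c("seedInterval", "designSeedInterval", "suppInterval")) {
      iv <- slot(object, s)
      if (length(iv) != 2L || any(iv < 1L) || iv[1] > iv[2])
        msg <- c(msg, sprintf("%s must be an increasing positive interval", s))
    }
    if (any(object@centralPositions < 1L))
      msg <- c(msg, "centralPositions must be positive")
    if (length(object@fixedBases)) {
      p <- suppressWarnings(as.integer(names(object@fixedBases)))
      if (any(is.na(p)) || any(p < 1L))
        msg <- c(msg, "fixedBases must be named by positive integer positions")
      .checkBases(paste(object@fixedBases, collapse = ""), "RNA",
                  allowN = FALSE, what = "fixed base")
    }
    if (is.null(msg)) TRUE else msg
  }
)

#' Antiparallel guide/target duplex alignment
#'
#' Ungapped, antiparallel register between a guide (5'->3', positions 1..L)
#' and a target site given in transcript sense orientation (5'->3', same
#' length): guide position i faces site position L+1-i. \code{states} holds
#' one pair state per guide position (\code{"WATSON_CRICK"}, \code{"WOBBLE"}
#' or \code{"MISMATCH"}).
#'
#' @slot guide RNA guide sequence.
#' @slot site RNA site sequence, transcript sense.
#' @slot states per-guide-position pair states.
#' @seealso [alignDuplex()], [classifyAlignment()]
#' @exportClass DuplexAlignment
setClass("DuplexAlignment",
  representation(guide = "character", site = "character", states = "character"),
  validity = function(object) {
    L <- nchar(object@guide)
    msg <- NULL
    if (nchar(object@site) != L) msg <- c(msg, "guide and site lengths differ")
    if (length(object@states) != L) msg <- c(msg, "states length != guide length")
    g <- .splitBases(object@guide)
    s <- rev(.splitBases(object@site))
    ok <- .pairStateVec(g, s)
    if (length(ok) == length(object@states) && !all(ok == object@states))
      msg <- c(msg, "states inconsistent with annotated base pairs")
    if (is.null(msg)) TRUE else msg
  }
)

setMethod("show", "DuplexAlignment", function(object) {
  glyph <- c(WATSON_CRICK = "|", WOBBLE = ":", MISMATCH = " ")
  cat("DuplexAlignment (guide 5'->3' over reversed site)\n")
  cat("  guide 5'-", object@guide, "-3'\n", sep = "")
  cat("           ", paste(glyph[object@states], collapse = ""), "\n", sep = "")
  cat("  site  3'-", .revString(object@site), "-5'\n", sep = "")
})

#' Hairpin scaffold for mimic design
#'
#' The endogenous precursor scaffold onto which designed guides are grafted.
#' The packaged default ([mir2022Scaffold()]) is derived from the miR-2022
#' stem-loop: a 21-nt star arm, a 7-nt loop and a 21-nt guide arm, with the
#' guide on the 3' arm. \code{starMismatchPositions} are the star positions
#' (star's own 5'->3' numbering) substituted to non-pairing bases relative to
#' the exactly target-complementary duplex partner; \code{overhang} is the
#' 3'-overhang length of the duplex register (guide position g pairs star
#' position \code{guideLength - overhang + 1 - g}); \code{starOverhang} is the
#' scaffold-supplied star 3'-overhang sequence.
#'
#' @slot name scaffold name.
#' @slot loop loop sequence, RNA.
#' @slot armOrder \code{"STAR_5PRIME_GUIDE_3PRIME"} or
#'   \code{"GUIDE_5PRIME_STAR_3PRIME"}.
#' @slot starMismatchPositions integer star positions for designed mismatches.
#' @slot fixedGuideBases named character, guide position -> base.
#' @slot guide5PrimeBase required guide 5' base (default \code{"U"}).
#' @slot guideLength mature guide length in nt.
#' @slot overhang 3'-overhang length of the duplex register.
#' @slot starOverhang star 3'-overhang sequence, RNA.
#' @seealso [mir2022Scaffold()], [decodeTemplate()], [deriveStar()]
#' @exportClass MimirScaffold
setClass("MimirScaffold",
  representation(name = "character", loop = "character", armOrder = "character",
                 starMismatchPositions = "integer", fixedGuideBases = "character",
                 guide5PrimeBase = "character", guideLength = "integer",
                 overhang = "integer", starOverhang = "character"),
  validity = function(object) {
    msg <- NULL
    if (!nzchar(object@loop)) msg <- c(msg, "loop must be non-empty")
    if (!object@armOrder %in% c("STAR_5PRIME_GUIDE_3PRIME",
                                "GUIDE_5PRIME_STAR_3PRIME"))
      msg <- c(msg, "unknown armOrder")
    if (any(object@starMismatchPositions < 1L) ||
        any(object@starMismatchPositions > object@guideLength))
      msg <- c(msg, "starMismatchPositions outside star length")
    if (nchar(object@starOverhang) != object@overhang)
      msg <- c(msg, "starOverhang length must equal overhang")
    if (is.null(msg)) TRUE else msg
  }
)

setMethod("show", "MimirScaffold", function(object) {
  cat(sprintf("MimirScaffold '%s': %d-nt guide on %s arm, loop %s\n",
              object@name, object@guideLength,
              if (object@armOrder == "STAR_5PRIME_GUIDE_3PRIME") "3'" else "5'",
              object@loop))
  cat(sprintf("  star mismatches at %s; fixed guide bases: %s; 5' base %s\n",
              paste(object@starMismatchPositions, collapse = ","),
              paste(sprintf("%s=%s", names(object@fixedGuideBases),
                            object@fixedGuideBases), collapse = ","),
              object@guide5PrimeBase))
})

#' A complete designed (or decoded) miRNA mimic
#'
#' Holds all parts of a mimic: mature guide and star strands (RNA, 5'->3'),
#' the loop, the assembled precursor hairpin, the ordered single-stranded DNA
#' template (reverse complement of promoter + precursor), the promoter used,
#' the complementarity category the guide realises on its target site, and
#' the target-site coordinates when a target was supplied.
#'
#' @slot guide,star,loop,precursor RNA sequences.
#' @slot template ordered DNA template.
#' @slot promoterName promoter used for the template.
#' @slot category complementarity category vs the target site (or \code{NA}).
#' @slot targetId target transcript identifier (or \code{NA}).
#' @slot siteStart,siteEnd 1-based target-site coordinates (or \code{NA}).
#' @seealso [decodeTemplate()], [assembleDesign()]
#' @exportClass MimirDesign
setClass("MimirDesign",
  representation(guide = "character", star = "character", loop = "character",
                 precursor = "character", template = "character",
                 promoterName = "character", category = "character",
                 targetId = "character", siteStart = "integer",
                 siteEnd = "integer"),
  validity = function(object) {
    msg <- NULL
    parts <- c(object@star, object@loop, object@guide)
    if (!object@precursor %in% c(paste(parts, collapse = ""),
                                 paste(parts[c(3, 2, 1)], collapse = "")))
      msg <- c(msg, "precursor is not the concatenation of arms and loop")
    if (is.null(msg)) TRUE else msg
  }
)

setMethod("show", "MimirDesign", function(object) {
  cat("MimirDesign", if (!is.na(object@category)) sprintf("[%s]", object@category),
      "\n")
  cat("  guide 5'->3':", object@guide, "\n")
  cat("  star  5'->3':", object@star, "\n")
  cat("  loop        :", object@loop, "\n")
  cat("  precursor   :", object@precursor, "\n")
  cat("  template    :", object@template, sprintf("(%s)\n", object@promoterName))
  if (!is.na(object@siteStart))
    cat(sprintf("  target site : %s:%d-%d\n",
                object@targetId, object@siteStart, object@siteEnd))
})

#' Reporter mRNA construct
#'
#' A promoter + leader + kozak + CDS + 3' UTR reporter, with the polyA mode
#' used for the transcript: \code{"NONE"}, \code{"ENCODED"} (a template-encoded
#' A-run of \code{polyALength} nt) or \code{"ENZYMATIC"} (post-transcriptional
#' polyadenylation, metadata only, no sequence change).
#'
#' @slot promoterName promoter name or \code{NA} when the stored sequence has
#'   no recognised promoter.
#' @slot leader transcript bases between the +1 and the kozak (DNA).
#' @slot kozak kozak sequence (DNA, may be empty).
#' @slot cds coding sequence, ATG..stop (DNA).
#' @slot utr3 3' UTR (DNA, without any encoded polyA run).
#' @slot polyA one of NONE/ENCODED/ENZYMATIC.
#' @slot polyALength encoded polyA length (0 unless ENCODED).
#' @seealso [parseReporter()], [assembleMrna()], [validateConstruct()]
#' @exportClass ReporterConstruct
setClass("ReporterConstruct",
  representation(promoterName = "character", leader = "character",
                 kozak = "character", cds = "character", utr3 = "character",
                 polyA = "character", polyALength = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@polyA %in% c("NONE", "ENCODED", "ENZYMATIC"))
      msg <- c(msg, "polyA must be NONE, ENCODED or ENZYMATIC")
    if (object@polyA == "ENCODED" && object@polyALength < 1L)
      msg <- c(msg, "ENCODED polyA requires polyALength >= 1")
    if (nzchar(object@cds)) {
      if (substr(object@cds, 1, 3) != "ATG")
        msg <- c(msg, "cds must begin with ATG")
      if (!substring(object@cds, nchar(object@cds) - 2) %in%
            c("TAA", "TAG", "TGA"))
        msg <- c(msg, "cds must end with a stop codon")
    }
    if (is.null(msg)) TRUE else msg
  }
)

setMethod("show", "ReporterConstruct", function(object) {
  cat(sprintf("ReporterConstruct: promoter %s, kozak %s, CDS %d nt, 3' UTR %d nt, polyA %s%s\n",
              object@promoterName, if (nzchar(object@kozak)) object@kozak else "(none)",
              nchar(object@cds), nchar(object@utr3), object@polyA,
              if (object@polyA == "ENCODED") sprintf("(%d)", object@polyALength) else ""))
})

#' Precursor interval annotation for read assignment
#'
#' Partition of a precursor into guide, star and loop intervals (1-based,
#' inclusive); any scaffold flanks are assigned to the arms so the three
#' intervals cover the precursor.
#'
#' @slot precursorId identifier.
#' @slot precursor precursor sequence, RNA.
#' @slot guideInterval,starInterval,loopInterval integer length-2 intervals.
#' @seealso [precursorAnnotation()], [assignReads()]
#' @exportClass PrecursorAnnotation
setClass("PrecursorAnnotation",
  representation(precursorId = "character", precursor = "character",
                 guideInterval = "integer", starInterval = "integer",
                 loopInterval = "integer"),
  validity = function(object) {
    n <- nchar(object@precursor)
    ivs <- list(guide = object@guideInterval, star = object@starInterval,
                loop = object@loopInterval)
    msg <- NULL
    for (nm in names(ivs)) {
      iv <- ivs[[nm]]
      if (length(iv) != 2L || iv[1] > iv[2] || iv[1] < 1L || iv[2] > n)
        msg <- c(msg, sprintf("%sInterval out of bounds", nm))
    }
    if (is.null(msg)) {
      cov <- sort(unlist(lapply(ivs, function(iv) iv[1]:iv[2]),
                         use.names = FALSE))
      if (anyDuplicated(cov)) msg <- c(msg, "intervals overlap")
      if (!identical(cov, seq_len(n)))
        msg <- c(msg, "intervals do not cover precursor")
    }
    if (is.null(msg)) TRUE else msg
  }
)

setMethod("show", "PrecursorAnnotation", function(object) {
  cat(sprintf("PrecursorAnnotation %s (%d nt): star %d-%d, loop %d-%d, guide %d-%d\n",
              object@precursorId, nchar(object@precursor),
              object@starInterval[1], object@starInterval[2],
              object@loopInterval[1], object@loopInterval[2],
              object@guideInterval[1], object@guideInterval[2]))
})

#' Guide/star loading quantification result
#'
#' Per-precursor, per-replicate read counts and normalized values from a
#' desk-scale AGO-IP quantification: raw counts per strand class, reads per
#' million of genome-unmapped reads (RPM), replicate means and processing
#' homogeneity metrics.
#'
#' @slot counts data.frame: precursor_id, replicate, guide, star, loop,
#'   loop_spanning, other.
#' @slot rpm data.frame: precursor_id, replicate, guide_rpm, star_rpm.
#' @slot means data.frame: precursor_id, guide_rpm_mean, star_rpm_mean.
#' @slot homogeneity data.frame: precursor_id, replicate, canonical_fraction,
#'   loop_spanning_fraction.
#' @slot unmappedTotals numeric, per-replicate genome-unmapped read counts.
#' @seealso [quantifyLoading()]
#' @exportClass LoadingQuant
setClass("LoadingQuant",
  representation(counts = "data.frame", rpm = "data.frame", means = "data.frame",
                 homogeneity = "data.frame", unmappedTotals = "numeric"))

setMethod("show", "LoadingQuant", function(object) {
  cat(sprintf("LoadingQuant: %d precursor(s) x %d replicate(s)\n",
              length(unique(object@counts$precursor_id)),
              length(unique(object@counts$replicate))))
  print(object@means, row.names = FALSE)
})
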