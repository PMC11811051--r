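# Mimic design on an endogenous hairpin scaffold: site selection, guide
# derivation per complementarity pattern, star derivation under the duplex
# register, precursor/template assembly, and decoding of printed templates.

#' The packaged miR-2022-derived scaffold
#'
#' Default scaffold for mimic design, calibrated once against the packaged
#' decoded templates: 21-nt guide on the 3' arm, 7-nt loop \code{GUUGUCA},
#' designed star mismatches at star positions 1, 8, 9 and 17 (star's own
#' 5'->3' numbering, relative to the exactly target-complementary duplex
#' partner), fixed guide base C at position 19 (a transcription constraint:
#' position 19 faces the star's 5'-terminal G, which standard T7 requires as
#' the +1 base of the precursor), required guide 5' base U, and a duplex
#' register with 2-nt 3' overhangs on both strands whose star-side overhang
#' is \code{UG}.
#'
#' @return a [MimirScaffold-class].
#' @export
mir2022Scaffold <- function() {
  new("MimirScaffold", name = "miR-2022", loop = "GUUGUCA",
      armOrder = "STAR_5PRIME_GUIDE_3PRIME",
      starMismatchPositions = c(1L, 8L, 9L, 17L),
      fixedGuideBases = c(`19` = "C"), guide5PrimeBase = "U",
      guideLength = 21L, overhang = 2L, starOverhang = "UG")
}

#' Read a scaffold from a YAML configuration
#'
#' Expected keys: \code{name}, \code{loop}, \code{arm_order},
#' \code{star_mismatch_positions}, \code{fixed_guide_bases} (position ->
#' base map), \code{guide_5prime_base}, \code{guide_length}, \code{overhang},
#' \code{star_overhang}. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a [MimirScaffold-class].
#' @export
readScaffold <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("name", "loop", "arm_order", "star_mismatch_positions",
             "fixed_guide_bases", "guide_5prime_base", "guide_length",
             "overhang", "star_overhang")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown scaffold configuration key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  fb <- unlist(cfg$fixed_guide_bases) %||% character(0)
  if (length(fb)) fb <- vapply(fb, .upperSeq, character(1))
  new("MimirScaffold",
      name = cfg$name %||% basename(path),
      loop = .upperSeq(cfg$loop),
      armOrder = cfg$arm_order %||% "STAR_5PRIME_GUIDE_3PRIME",
      starMismatchPositions = as.integer(cfg$star_mismatch_positions %||% integer(0)),
      fixedGuideBases = fb,
      guide5PrimeBase = .upperSeq(cfg$guide_5prime_base %||% "U"),
      guideLength = as.integer(cfg$guide_length %||% 21L),
      overhang = as.integer(cfg$overhang %||% 2L),
      starOverhang = .upperSeq(cfg$star_overhang %||% "UG"))
}

# --- accessors -------------------------------------------------------------

#' Accessors for designed mimics
#'
#' Slot accessors for [MimirDesign-class] objects.
#'
#' @param x a [MimirDesign-class].
#' @return a character scalar (sequences, category) or integer coordinates.
#' @name design-accessors
NULL

#' @rdname design-accessors
#' @export
guideSeq <- function(x) x@guide
#' @rdname design-accessors
#' @export
starSeq <- function(x) x@star
#' @rdname design-accessors
#' @export
loopSeq <- function(x) x@loop
#' @rdname design-accessors
#' @export
precursorSeq <- function(x) x@precursor
#' @rdname design-accessors
#' @export
templateSeq <- function(x) x@template
#' @rdname design-accessors
#' @export
designCategory <- function(x) x@category
#' @rdname design-accessors
#' @export
targetSite <- function(x) c(start = x@siteStart, end = x@siteEnd)

# --- helpers ---------------------------------------------------------------

.patternAlias <- c(near_full = "NEAR_FULL", seed = "SEED_ONLY",
                   seed_supp = "SEED_SUPPLEMENTARY", mm10 = "CENTRAL_MM_10",
                   mm11 = "CENTRAL_MM_11", mm10_11 = "CENTRAL_MM_10_11")

.normCategory <- function(category) {
  if (category %in% names(.patternAlias)) return(unname(.patternAlias[category]))
  if (category %in% .CATEGORIES) return(category)
  stop("unknown pattern category: ", category, call. = FALSE)
}

# Best ungapped site of an arm in a target transcript. Every window is
# scored by mismatches of the arm against revComp(window); windows whose
# tail exactly complements the arm's first seedLen bases (seed-anchored
# windows) are preferred, which keeps partially matching guides (seed-only
# designs) anchored at their designed site. Returns list(start, mismatches,
# anchored) or NULL when nothing better than half-mismatched exists.
.bestArmSite <- function(arm, target, seedLen = 8L) {
  armD <- rnaToDna(arm)
  tgt <- if (.seqAlphabet(target) == "RNA") rnaToDna(target) else target
  L <- nchar(armD)
  n <- nchar(tgt)
  if (L > n) return(NULL)
  rcArm <- .splitBases(revComp(armD))
  tv <- .splitBases(tgt)
  nw <- n - L + 1L
  mm <- integer(nw)
  for (i in seq_len(L)) mm <- mm + (tv[seq_len(nw) + i - 1L] != rcArm[i])
  seedC <- revComp(substr(armD, 1L, seedLen))
  anchored <- which(substring(tgt, seq_len(nw) + L - seedLen, seq_len(nw) + L - 1L) == seedC)
  if (length(anchored)) {
    s <- anchored[which.min(mm[anchored])]
    return(list(start = s, mismatches = mm[s], anchored = TRUE))
  }
  s <- which.min(mm)
  if (mm[s] > L %/% 2L) return(NULL)
  list(start = s, mismatches = mm[s], anchored = FALSE)
}

# --- operations ------------------------------------------------------------

#' Decode an ordered template into its mimic parts
#'
#' Reverse of [assembleDesign()]: transcribes the ordered template (promoter
#' located and stripped), splits the precursor into 5' arm, loop and 3' arm
#' by locating the scaffold loop — or, when the loop is not found (e.g. a
#' generic shRNA), by taking the outermost \code{guideLength} bases of each
#' side as arms and the remainder as loop — and assigns guide and star per
#' the scaffold's arm order. When a target transcript is supplied, the arm
#' whose reverse complement best matches the target is verified to be the
#' guide, the site coordinates are annotated and the guide's complementarity
#' category against its site is classified.
#'
#' @param template ordered DNA template.
#' @param scaffold a [MimirScaffold-class].
#' @param target optional target transcript (sense).
#' @param targetId identifier for the target.
#' @param promoters promoter candidates, see [defaultPromoters()].
#' @param spec a [PatternSpec-class] for site classification.
#' @return a [MimirDesign-class].
#' @export
decodeTemplate <- function(template, scaffold = mir2022Scaffold(),
                           target = NULL, targetId = "target",
                           promoters = defaultPromoters(),
                           spec = patternSpec()) {
  template <- .asChar(template)
  tr <- transcribeTemplate(template, promoters)
  pre <- tr$transcript
  L <- scaffold@guideLength
  n <- nchar(pre)
  if (n < 2L * L + 1L)
    stop("precursor cannot fold into two arms of guide length plus a loop",
         call. = FALSE)

  loopHits <- Biostrings::matchPattern(
    Biostrings::DNAString(rnaToDna(scaffold@loop)),
    Biostrings::DNAString(rnaToDna(pre)))
  if (length(loopHits) == 1L &&
      Biostrings::start(loopHits)[1] > L &&
      Biostrings::end(loopHits)[1] <= n - L) {
    ls <- Biostrings::start(loopHits)[1]; le <- Biostrings::end(loopHits)[1]
  } else {
    # generic fold mode: outermost guide-length arms, middle is the loop
    ls <- L + 1L; le <- n - L
  }
  arm5 <- substr(pre, 1L, ls - 1L)
  loop <- substr(pre, ls, le)
  arm3 <- substr(pre, le + 1L, n)
  if (nchar(arm5) < L || nchar(arm3) < L)
    stop("decoded arms shorter than the scaffold guide length", call. = FALSE)

  if (scaffold@armOrder == "STAR_5PRIME_GUIDE_3PRIME") {
    star <- arm5; guide <- arm3
  } else {
    guide <- arm5; star <- arm3
  }

  category <- NA_character_
  siteStart <- NA_integer_; siteEnd <- NA_integer_
  if (!is.null(target)) {
    target <- .asChar(target)
    hitG <- .bestArmSite(guide, target)
    hitS <- .bestArmSite(star, target)
    starWins <- !is.null(hitS) &&
      (is.null(hitG) ||
         (hitS$anchored && !hitG$anchored) ||
         (hitS$anchored == hitG$anchored && hitS$mismatches < hitG$mismatches))
    if (starWins) {
      warning("the arm matching the target is not the scaffold's guide arm; ",
              "swapping guide and star", call. = FALSE)
      tmp <- guide; guide <- star; star <- tmp
      hitG <- hitS
    }
    if (!is.null(hitG)) {
      siteStart <- hitG$start
      siteEnd <- hitG$start + nchar(guide) - 1L
      site <- substr(target, siteStart, siteEnd)
      category <- classifyAlignment(alignDuplex(guide, site), spec)
    }
  }

  new("MimirDesign", guide = guide, star = star, loop = loop, precursor = pre,
      template = template, promoterName = tr$promoter@name,
      category = category, targetId = targetId,
      siteStart = siteStart, siteEnd = siteEnd)
}

#' Enumerate candidate target sites in a transcript region
#'
#' Returns every guide-length window of the region that supports a guide with
#' the scaffold's required 5' base: for the default 5' U, windows ending in A
#' on the sense strand. Candidates are returned in ascending position order
#' (the documented deterministic ranking).
#'
#' @param transcript target transcript (sense).
#' @param region length-2 integer interval within the transcript.
#' @param scaffold a [MimirScaffold-class].
#' @return a [S4Vectors::DataFrame] with columns \code{start}, \code{end},
#'   \code{site}.
#' @export
chooseTargetSite <- function(transcript, region, scaffold = mir2022Scaffold()) {
  transcript <- .asChar(transcript)
  L <- scaffold@guideLength
  region <- as.integer(region)
  if (length(region) != 2L || region[1] > region[2])
    stop("region must be a non-empty interval", call. = FALSE)
  if (region[1] < 1L || region[2] > nchar(transcript))
    stop("region outside the transcript", call. = FALSE)
  if (region[2] - region[1] + 1L < L)
    stop("region shorter than the guide length", call. = FALSE)
  lastBase <- rnaToDna(.complement(scaffold@guide5PrimeBase, "RNA"))
  starts <- seq(region[1], region[2] - L + 1L)
  ends <- starts + L - 1L
  tdna <- if (.seqAlphabet(transcript) == "RNA") rnaToDna(transcript) else transcript
  keep <- substring(tdna, ends, ends) == lastBase
  if (!any(keep)) {
    return(S4Vectors::DataFrame(start = integer(0), end = integer(0),
                                site = character(0)))
  }
  S4Vectors::DataFrame(start = starts[keep], end = ends[keep],
                       site = substring(tdna, starts[keep], ends[keep]))
}

#' Derive a guide realising a complementarity pattern on a site
#'
#' Starts from the exact reverse complement of the site, applies the
#' scaffold's fixed guide bases (position 19 -> C by default), and then
#' converts the positions the requested category requires to be mismatched
#' into non-pairing bases. The substitution rule is: use the base identical
#' to the opposing target base, which can never Watson-Crick pair nor wobble
#' with it (and reproduces the printed central-mismatch designs, where C
#' faces C). The returned guide is verified to classify as the requested
#' category against the site.
#'
#' @param site target site sequence (sense), of the scaffold's guide length.
#' @param category one of \code{NEAR_FULL}, \code{SEED_ONLY},
#'   \code{SEED_SUPPLEMENTARY}, \code{CENTRAL_MM_10}, \code{CENTRAL_MM_11},
#'   \code{CENTRAL_MM_10_11} (or the aliases \code{near_full}, \code{seed},
#'   \code{seed_supp}, \code{mm10}, \code{mm11}, \code{mm10_11}).
#' @param scaffold a [MimirScaffold-class].
#' @param spec a [PatternSpec-class].
#' @return RNA guide sequence, 5'->3'.
#' @export
deriveGuide <- function(site, category, scaffold = mir2022Scaffold(),
                        spec = patternSpec()) {
  category <- .normCategory(category)
  site <- .asChar(site)
  siteRna <- if (.seqAlphabet(site) == "DNA") dnaToRna(site) else site
  L <- scaffold@guideLength
  if (nchar(siteRna) != L)
    stop("site length must equal the scaffold guide length", call. = FALSE)
  g <- .splitBases(revComp(siteRna))
  if (g[1] != scaffold@guide5PrimeBase)
    stop(sprintf("site incompatible with the guide 5' %s rule (sense window must end in %s)",
                 scaffold@guide5PrimeBase,
                 .complement(scaffold@guide5PrimeBase, "RNA")), call. = FALSE)

  fixedPos <- as.integer(names(scaffold@fixedGuideBases))
  g[fixedPos] <- scaffold@fixedGuideBases

  ds <- seq(spec@designSeedInterval[1], spec@designSeedInterval[2])
  supp <- seq(spec@suppInterval[1], spec@suppInterval[2])
  mmPos <- switch(category,
    NEAR_FULL = integer(0),
    CENTRAL_MM_10 = 10L,
    CENTRAL_MM_11 = 11L,
    CENTRAL_MM_10_11 = c(10L, 11L),
    SEED_ONLY = setdiff(seq_len(L), ds),
    SEED_SUPPLEMENTARY = setdiff(seq_len(L), c(ds, supp)),
    stop("cannot derive a guide for category ", category, call. = FALSE))
  mmPos <- setdiff(mmPos, fixedPos)
  s <- .splitBases(siteRna)
  # identical-to-opposing substitution: x:x is never a pair nor a wobble
  g[mmPos] <- s[L + 1L - mmPos]

  guide <- paste(g, collapse = "")
  got <- classifyAlignment(alignDuplex(guide, siteRna), spec)
  if (got != category)
    stop(sprintf("derived guide classifies as %s, not %s", got, category),
         call. = FALSE)
  guide
}

#' Derive the star strand of a guide under the scaffold register
#'
#' The star is the duplex partner of the guide: star position j pairs guide
#' position \code{guideLength - overhang + 1 - j}, the last \code{overhang}
#' star bases being the scaffold's 3' overhang. Positions listed in the
#' scaffold's \code{starMismatchPositions} are substituted to non-pairing
#' bases (identical-to-opposing rule). Designed mismatches are applied
#' relative to the exactly target-complementary duplex partner, so when the
#' guide itself carries fixed-base substitutions the original \code{site}
#' should be supplied as the reference.
#'
#' @param guide RNA guide, 5'->3'.
#' @param scaffold a [MimirScaffold-class].
#' @param site optional target site (sense) used as the reference duplex
#'   partner; defaults to the guide itself.
#' @return RNA star sequence, 5'->3'.
#' @export
deriveStar <- function(guide, scaffold = mir2022Scaffold(), site = NULL) {
  guide <- .asChar(guide)
  if (.seqAlphabet(guide) == "DNA") guide <- dnaToRna(guide)
  L <- scaffold@guideLength
  if (nchar(guide) != L)
    stop("guide length must equal the scaffold guide length", call. = FALSE)
  ref <- if (!is.null(site)) {
    site <- .asChar(site)
    revComp(if (.seqAlphabet(site) == "DNA") dnaToRna(site) else site)
  } else guide
  refB <- .splitBases(ref)
  paired <- L - scaffold@overhang  # star positions 1..paired are in the duplex
  bad <- scaffold@starMismatchPositions[scaffold@starMismatchPositions > paired]
  if (length(bad))
    stop("star mismatch position(s) outside the paired register: ",
         paste(bad, collapse = ","), call. = FALSE)
  st <- character(L)
  for (j in seq_len(paired)) {
    gpos <- paired + 1L - j
    st[j] <- if (j %in% scaffold@starMismatchPositions)
      refB[gpos] else .complement(refB[gpos], "RNA")
  }
  st[(paired + 1L):L] <- .splitBases(scaffold@starOverhang)
  paste(st, collapse = "")
}

#' Assemble a complete mimic from its parts
#'
#' Concatenates the arms and loop per the scaffold's arm order into the
#' precursor, emits the ordered DNA template via [makeTemplate()], and
#' returns the complete [MimirDesign-class]. In strict mode the guide must
#' satisfy the scaffold's 5'-base and fixed-base rules.
#'
#' @param guide,star RNA strands, 5'->3'.
#' @param scaffold a [MimirScaffold-class].
#' @param promoter a [PromoterSpec-class].
#' @param category,targetId,siteStart,siteEnd optional annotation carried
#'   into the design.
#' @param loop loop sequence; defaults to the scaffold's loop (override when
#'   reassembling a decoded hairpin that uses a different loop).
#' @param strict enforce guide rules and the promoter +1 requirement.
#' @return a [MimirDesign-class].
#' @export
assembleDesign <- function(guide, star, scaffold = mir2022Scaffold(),
                           promoter = defaultPromoters()$T7_STD,
                           category = NA_character_, targetId = NA_character_,
                           siteStart = NA_integer_, siteEnd = NA_integer_,
                           loop = NULL, strict = TRUE) {
  guide <- .asChar(guide); star <- .asChar(star)
  if (.seqAlphabet(guide) == "DNA") guide <- dnaToRna(guide)
  if (.seqAlphabet(star) == "DNA") star <- dnaToRna(star)
  if (strict) {
    if (substr(guide, 1, 1) != scaffold@guide5PrimeBase)
      stop("guide does not start with the scaffold 5' base ",
           scaffold@guide5PrimeBase, call. = FALSE)
    fp <- as.integer(names(scaffold@fixedGuideBases))
    got <- substring(guide, fp, fp)
    if (any(got != scaffold@fixedGuideBases))
      stop("guide violates the scaffold's fixed-base rule", call. = FALSE)
  }
  loop <- .asChar(loop %||% scaffold@loop)
  if (.seqAlphabet(loop) == "DNA") loop <- dnaToRna(loop)
  pre <- if (scaffold@armOrder == "STAR_5PRIME_GUIDE_3PRIME")
    paste0(star, loop, guide)
  else paste0(guide, loop, star)
  template <- makeTemplate(pre, promoter, strict = strict)
  new("MimirDesign", guide = guide, star = star, loop = loop,
      precursor = pre, template = template, promoterName = promoter@name,
      category = if (is.na(category)) category else .normCategory(category),
      targetId = targetId,
      siteStart = as.integer(siteStart), siteEnd = as.integer(siteEnd))
}

#' End-to-end mimic design against a target region
#'
#' Enumerates candidate sites in the region ([chooseTargetSite()]), derives
#' the guide for the requested pattern from the first compatible site
#' ([deriveGuide()]), derives the star ([deriveStar()]) and assembles the
#' ordered template ([assembleDesign()]).
#'
#' @inheritParams chooseTargetSite
#' @inheritParams deriveGuide
#' @inheritParams assembleDesign
#' @param targetId identifier recorded in the design.
#' @return a [MimirDesign-class].
#' @export
designMimir <- function(transcript, region, category,
                        scaffold = mir2022Scaffold(),
                        promoter = defaultPromoters()$T7_STD,
                        spec = patternSpec(), targetId = "target") {
  sites <- chooseTargetSite(transcript, region, scaffold)
  if (!nrow(sites))
    stop("no candidate site in the region supports the guide 5' base rule",
         call. = FALSE)
  err <- NULL
  for (i in seq_len(nrow(sites))) {
    des <- tryCatch({
      guide <- deriveGuide(sites$site[i], category, scaffold, spec)
      star <- deriveStar(guide, scaffold, site = sites$site[i])
      # assembly can fail on the promoter +1 requirement (the precursor
      # starts with the star 5' base); such sites are skipped
      assembleDesign(guide, star, scaffold, promoter,
                     category = category, targetId = targetId,
                     siteStart = sites$start[i], siteEnd = sites$end[i])
    }, error = function(e) {err <<- e; NULL})
    if (!is.null(des)) return(des)
  }
  stop("no site in the region yields the requested pattern: ",
       conditionMessage(err), call. = FALSE)
}
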