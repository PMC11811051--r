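# Packaged fixture set: the published template and reporter sequences this
# toolkit was calibrated against, plus promoter motifs and the kozak.

.FIXTURE_MD5 <- c(
  mimir_templates.fasta = "55ae4a1e999a7f50c9e081a4cefd8ba2",
  reporter_mrnas.fasta = "85add9a96f8af71e7d23090a77fb749c",
  mir2022_scaffold.yaml = "fddb8ea77091fc3fa36438f692f663ef"
)

.fixturePath <- function(file) {
  p <- system.file("extdata", file, package = "mimircraft", mustWork = TRUE)
  got <- unname(tools::md5sum(p))
  want <- .FIXTURE_MD5[[file]]
  if (!identical(got, want))
    stop(sprintf("packaging error: checksum mismatch for %s (got %s)", file, got),
         call. = FALSE)
  p
}

# intended guide complementarity category of each packaged template row
.TEMPLATE_CATEGORIES <- c(
  full_match = "NEAR_FULL", seed_match = "SEED_ONLY",
  seed_supplementary = "SEED_SUPPLEMENTARY",
  mismatch_10_11 = "CENTRAL_MM_10_11", mismatch_10 = "CENTRAL_MM_10",
  mismatch_11 = "CENTRAL_MM_11", full_match_mrna = "NEAR_FULL"
)

#' Load packaged fixture sequences
#'
#' The fixture set carries the packaged mimic/shRNA ordered templates (8
#' entries; a non-targeting shRNA negative control, six mimics against the
#' mCherry reporter and one against the engineered multi-seed-site reporter),
#' the five reporter mRNA sequences, the kozak, and the promoter motifs.
#' Files are checksum-verified at load; a mismatch is a packaging error.
#'
#' @param name \code{"all"} for the whole set as a list, or a single fixture
#'   name. Template rows can also be fetched as \code{"<row>_template"},
#'   e.g. \code{"full_match_template"}.
#' @return a list (for \code{"all"}) or a character sequence.
#' @examples
#' substr(loadFixtures("full_match_template"), 1, 12)  # "TCGCCCTGAACC"
#' loadFixtures("kozak")
#' @export
loadFixtures <- function(name = "all") {
  templates <- readFastaSeqs(.fixturePath("mimir_templates.fasta"))
  mrnas <- readFastaSeqs(.fixturePath("reporter_mrnas.fasta"))
  all <- list(templates = templates, mrnas = mrnas, kozak = EF1A_KOZAK,
              promoters = defaultPromoters(),
              template_categories = .TEMPLATE_CATEGORIES,
              scaffold_yaml = .fixturePath("mir2022_scaffold.yaml"))
  if (identical(name, "all")) return(all)
  if (name %in% names(templates)) return(templates[[name]])
  tname <- sub("_template$", "", name)
  if (tname %in% names(templates)) return(templates[[tname]])
  if (name %in% names(mrnas)) return(mrnas[[name]])
  if (name %in% names(all)) return(all[[name]])
  stop("unknown fixture: ", name, call. = FALSE)
}

#' Verify the packaged sequence architecture
#'
#' Recomputes, from the packaged fixtures alone, the design rules the
#' toolkit encodes: every template decodes with a single standard-T7
#' promoter hit; decode and reassembly round-trip byte-identically; every
#' mimic guide starts with U and carries C at position 19 (the unique
#' position with C common to all mimic guides); each mimic guide classifies
#' against its reporter site as its intended category; the reporter carries
#' three seed sites in the 3' UTR with a uniform 21-base gap and one
#' full-match site.
#'
#' @param quiet suppress per-check console output.
#' @return data.frame with columns \code{check}, \code{pass}, \code{detail};
#'   invisibly when \code{quiet} is \code{FALSE}.
#' @export
verifyPaper <- function(quiet = FALSE) {
  fx <- loadFixtures()
  scaffold <- mir2022Scaffold()
  spec <- patternSpec()
  mcherry <- fx$mrnas[["mcherry_mrna_nematostella_zebrafish"]]
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(check = check, pass = pass,
                                                 detail = detail)
  }

  designs <- lapply(names(fx$templates), function(nm) {
    tryCatch(decodeTemplate(fx$templates[[nm]], scaffold,
                            target = if (nm == "shrna_neg_control") NULL else mcherry,
                            targetId = "mCherry"),
             error = function(e) e)
  })
  names(designs) <- names(fx$templates)
  ok <- !vapply(designs, inherits, logical(1), "error")
  add("all 8 templates decode", all(ok), paste(sum(ok), "of 8"))
  add("single T7_STD promoter hit per template",
      all(vapply(designs[ok], function(d) d@promoterName == "T7_STD", logical(1))))

  promoter <- defaultPromoters()$T7_STD
  rt <- vapply(designs[ok], function(d) {
    re <- assembleDesign(d@guide, d@star, scaffold, promoter, loop = d@loop,
                         strict = FALSE)
    re@template == d@template
  }, logical(1))
  add("decode/assemble round trip byte-identical", all(rt),
      paste(sum(rt), "of", length(rt)))

  mimics <- designs[setdiff(names(designs), "shrna_neg_control")]
  add("every mimic guide starts with U",
      all(vapply(mimics, function(d) startsWith(d@guide, "U"), logical(1))))
  cpos <- Reduce(intersect, lapply(mimics, function(d)
    which(.splitBases(d@guide) == "C")))
  add("position 19 is the unique common cytosine position",
      identical(cpos, 19L), paste(cpos, collapse = ","))

  cats <- vapply(mimics, function(d) d@category, character(1))
  want <- .TEMPLATE_CATEGORIES[names(cats)]
  add("guide categories match the intended patterns",
      all(cats == want), paste(names(cats)[cats != want], collapse = ","))

  seedGuide <- mimics$seed_match@guide
  val <- validateConstruct(mcherry, c(seed = seedGuide), spec)
  add("reporter carries 3 seed sites", val$seedSiteCount == 3L,
      as.character(val$seedSiteCount))
  add("seed sites uniformly 21 bases apart",
      length(val$seedGaps) == 2L && all(val$seedGaps == 21L),
      paste(val$seedGaps, collapse = ","))
  add("all seed sites in the 3' UTR",
      all(val$hits$seed$region == "UTR3"),
      paste(unique(val$hits$seed$region), collapse = ","))
  fullVal <- validateConstruct(mcherry, c(full = mimics$full_match_mrna@guide), spec)
  add("one full-match site for the mRNA-experiment mimic",
      fullVal$fullMatchCount == 1L, as.character(fullVal$fullMatchCount))

  out <- do.call(rbind, checks)
  if (!quiet) {
    status <- ifelse(out$pass, "PASS", "FAIL")
    cat(sprintf("[%s] %s %s\n", status, format(out$check, width = 48),
                out$detail), sep = "")
    invisible(out)
  } else out
}
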