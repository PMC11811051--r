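# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: direct lookup tables and exhaustive loops, no calls
# into the code paths they check.

# character-wise complement, written out by hand
ORACLE_COMP_DNA <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
ORACLE_COMP_RNA <- c(A = "U", C = "G", G = "C", U = "A", N = "N")

oracleRevComp <- function(x, rna = FALSE) {
  tab <- if (rna) ORACLE_COMP_RNA else ORACLE_COMP_DNA
  paste(rev(tab[strsplit(x, "")[[1]]]), collapse = "")
}

# per-position pair states of guide i vs site L+1-i, by explicit enumeration
oraclePairStates <- function(guide, site) {
  g <- strsplit(guide, "")[[1]]
  s <- strsplit(site, "")[[1]]
  L <- length(g)
  vapply(seq_len(L), function(i) {
    a <- g[i]; b <- s[L + 1 - i]
    pr <- paste0(a, b)
    if (pr %in% c("AU", "UA", "GC", "CG")) "WATSON_CRICK"
    else if (pr %in% c("GU", "UG")) "WOBBLE"
    else "MISMATCH"
  }, character(1))
}

oracleMismatchSet <- function(guide, site) {
  which(oraclePairStates(guide, site) != "WATSON_CRICK")
}

randomSeq <- function(len, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# exhaustive per-window scan + greedy left-to-right overlap resolution,
# independent of scanTranscript's windowing
oracleScanAll <- function(guide, transcript, spec) {
  L <- nchar(guide)
  n <- nchar(transcript)
  hits <- list()
  lastEnd <- 0
  for (s in seq_len(n - L + 1)) {
    site <- substr(transcript, s, s + L - 1)
    cat. <- classifyAlignment(alignDuplex(guide, site), spec)
    if (cat. != "NONE" && s > lastEnd) {
      hits[[length(hits) + 1]] <- list(start = s, category = cat.)
      lastEnd <- s + L - 1
    }
  }
  hits
}

# shared decoded fixture set (computed once per test run)
fixtureDesigns <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- loadFixtures()
      mch <- fx$mrnas[["mcherry_mrna_nematostella_zebrafish"]]
      cache <<- lapply(stats::setNames(nm = names(fx$templates)), function(nm)
        decodeTemplate(fx$templates[[nm]], mir2022Scaffold(),
                       target = if (nm == "shrna_neg_control") NULL else mch,
                       targetId = "mCherry"))
    }
    cache
  }
})
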