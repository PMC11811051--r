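# Internal sequence helpers. The toolkit's currency is a plain uppercase
# character string plus an alphabet flag; Biostrings does the heavy lifting
# (reverse complement, pattern matching, FASTA/FASTQ I/O) behind this surface.

DNA_BASES <- c("A", "C", "G", "T")
RNA_BASES <- c("A", "C", "G", "U")

.upperSeq <- function(x) {
  x <- as.character(x)
  if (any(grepl("[a-z]", x))) {
    x <- toupper(x)
  }
  x
}

#' @keywords internal
.checkBases <- function(x, alphabet = c("DNA", "RNA"), allowN = TRUE,
                        what = "sequence") {
  alphabet <- match.arg(alphabet)
  legal <- if (alphabet == "DNA") DNA_BASES else RNA_BASES
  if (allowN) legal <- c(legal, "N")
  bad <- setdiff(unique(strsplit(paste(x, collapse = ""), "")[[1]]), legal)
  if (length(bad)) {
    stop(sprintf("illegal %s character(s) for %s alphabet: %s",
                 what, alphabet, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

.isRNA <- function(x) grepl("U", x, fixed = TRUE) && !grepl("T", x, fixed = TRUE)

.seqAlphabet <- function(x) {
  if (grepl("U", x, fixed = TRUE)) {
    if (grepl("T", x, fixed = TRUE)) {
      stop("sequence mixes T and U; alphabet is ambiguous", call. = FALSE)
    }
    "RNA"
  } else {
    "DNA"
  }
}

.asChar <- function(x) {
  if (is(x, "XString") || is(x, "XStringSet")) as.character(x) else .upperSeq(x)
}

.splitBases <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# complement within a declared alphabet, preserving N
.complement <- function(x, alphabet) {
  if (alphabet == "DNA") chartr("ACGTN", "TGCAN", x) else chartr("ACGUN", "UGCAN", x)
}

.revString <- function(x) {
  vapply(x, function(s) paste(rev(.splitBases(s)), collapse = ""), character(1),
         USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
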