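#' @importFrom Biostrings DNAString DNAStringSet RNAStringSet reverseComplement
#'   readDNAStringSet readBStringSet writeXStringSet matchPattern
NULL

#' Reverse complement
#'
#' Reverse complement of a DNA or RNA sequence (alphabet auto-detected from
#' the presence of U; a sequence without T or U is treated as DNA).
#' \code{revComp} is an involution: \code{revComp(revComp(x)) == x}.
#'
#' @param x character vector of sequences (upper- or lowercase; stored and
#'   returned uppercase), or an \code{XString}/\code{XStringSet}.
#' @return character vector of reverse complements, same alphabet.
#' @examples
#' revComp("TATAGTGAGTCGTATTA")  # -> "TAATACGACTCACTATA"
#' revComp("GGGAAACUU")          # RNA in, RNA out
#' @export
revComp <- function(x) {
  x <- .asChar(x)
  vapply(x, function(s) {
    if (!nzchar(s)) return(s)
    alph <- .seqAlphabet(s)
    .checkBases(s, alph)
    .revString(.complement(s, alph))
  }, character(1), USE.NAMES = FALSE)
}

#' Convert between DNA and RNA alphabets
#'
#' T/U substitution with the alphabet flag flipped; the length and the
#' orientation of the sequence are preserved, and the two functions are
#' mutual inverses.
#'
#' @param x character vector of sequences.
#' @return converted character vector.
#' @export
dnaToRna <- function(x) {
  x <- .asChar(x)
  .checkBases(paste(x, collapse = ""), "DNA")
  chartr("T", "U", x)
}

#' @rdname dnaToRna
#' @export
rnaToDna <- function(x) {
  x <- .asChar(x)
  .checkBases(paste(x, collapse = ""), "RNA")
  chartr("U", "T", x)
}

#' Promoter constructor and packaged defaults
#'
#' \code{promoterSpec} builds a [PromoterSpec-class]; \code{defaultPromoters}
#' returns the packaged promoter set: standard T7 (motif
#' \code{TAATACGACTCACTATA}, transcripts start G), T7 class II phi2.5 (motif
#' \code{TAATACGACTCACTATT}, transcripts start A), CleanCap-AG style T7
#' templates (standard motif, transcripts start AG) and SP6. Transcription is
#' taken to start at the first base after the motif; the \code{plusOne}
#' requirement is what tells the three T7 variants apart when decoding.
#'
#' @param name promoter name.
#' @param motif sense-strand promoter motif, DNA.
#' @param plusOne required transcript start ("" for no requirement).
#' @return \code{promoterSpec}: a [PromoterSpec-class]. \code{defaultPromoters}:
#'   a named list of them.
#' @export
promoterSpec <- function(name, motif, plusOne = "") {
  new("PromoterSpec", name = name, motif = .upperSeq(motif),
      plusOne = .upperSeq(plusOne))
}

#' @rdname promoterSpec
#' @export
defaultPromoters <- function() {
  list(
    T7_STD = promoterSpec("T7_STD", "TAATACGACTCACTATA", "G"),
    T7_PHI25 = promoterSpec("T7_PHI25", "TAATACGACTCACTATT", "A"),
    T7_CLEANCAP_AG = promoterSpec("T7_CLEANCAP_AG", "TAATACGACTCACTATA", "AG"),
    SP6 = promoterSpec("SP6", "ATTTAGGTGACACTATA", "G")
  )
}

# count occurrences of a motif in a subject string
.countMotif <- function(motif, subject) {
  length(Biostrings::matchPattern(Biostrings::DNAString(motif),
                                  Biostrings::DNAString(subject)))
}

#' Decode an ordered template into promoter and transcript
#'
#' Ordered single-stranded templates are synthesised as the reverse complement
#' of promoter + transcript. \code{transcribeTemplate} reverse-complements the
#' template, locates exactly one promoter motif among the candidates, and
#' returns the matched promoter together with the RNA transcript starting at
#' the base after the motif (the +1). A promoter is only accepted when the
#' transcript satisfies its \code{plusOne} requirement; if several candidates
#' remain, the most specific one (longest \code{plusOne}, then longest motif)
#' wins.
#'
#' @param template ordered DNA template (character or \code{DNAString}).
#' @param promoters list of [PromoterSpec-class] candidates.
#' @return list with elements \code{promoter} ([PromoterSpec-class]) and
#'   \code{transcript} (RNA character).
#' @examples
#' transcribeTemplate(revComp(paste0("TAATACGACTCACTATA", "GGGAAA")))
#' @export
transcribeTemplate <- function(template, promoters = defaultPromoters()) {
  template <- .asChar(template)
  .checkBases(template, "DNA", what = "template")
  sense <- revComp(template)
  hits <- list()
  for (p in promoters) {
    n <- .countMotif(p@motif, sense)
    if (n > 1L)
      stop(sprintf("promoter motif %s matches the template more than once; ambiguous",
                   p@name), call. = FALSE)
    if (n == 0L) next
    at <- as.integer(regexpr(p@motif, sense, fixed = TRUE))
    transcript <- substring(sense, at + nchar(p@motif))
    if (!nzchar(transcript))
      stop("transcript is empty after the promoter motif", call. = FALSE)
    if (nzchar(p@plusOne) && !startsWith(transcript, p@plusOne)) next
    hits[[p@name]] <- list(promoter = p, transcript = dnaToRna(transcript))
  }
  if (!length(hits))
    stop("no promoter motif (with a compatible +1 base) found in template",
         call. = FALSE)
  spec <- vapply(hits, function(h)
    nchar(h$promoter@plusOne) * 100L + nchar(h$promoter@motif), integer(1))
  hits[[which.max(spec)]]
}

#' Emit an ordered template for a transcript
#'
#' Inverse of [transcribeTemplate()]: returns
#' \code{revComp(motif + transcript)} as DNA, the form in which templates are
#' ordered for in vitro transcription. In strict mode the transcript must
#' begin with the promoter's required +1 base(s); otherwise a warning is
#' issued and the template emitted anyway.
#'
#' @param transcript RNA (or DNA) transcript, 5'->3'.
#' @param promoter a [PromoterSpec-class].
#' @param strict error (TRUE) or warn (FALSE) on a +1 incompatibility.
#' @return ordered DNA template string.
#' @export
makeTemplate <- function(transcript, promoter, strict = TRUE) {
  transcript <- .asChar(transcript)
  if (!nzchar(transcript)) stop("transcript must be non-empty", call. = FALSE)
  tdna <- if (.seqAlphabet(transcript) == "RNA") rnaToDna(transcript) else transcript
  if (nzchar(promoter@plusOne) && !startsWith(tdna, promoter@plusOne)) {
    msg <- sprintf("transcript start '%s' is incompatible with %s +1 requirement '%s'",
                   substr(tdna, 1, nchar(promoter@plusOne)), promoter@name,
                   promoter@plusOne)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  revComp(paste0(promoter@motif, tdna))
}

#' Read and write FASTA; read small-RNA reads
#'
#' Thin wrappers over Biostrings I/O returning plain named character vectors
#' (uppercased on read; lowercase input is accepted with a message). FASTQ
#' qualities are parsed for validity but discarded, as nothing downstream
#' uses them.
#'
#' @param path file path.
#' @param alphabet \code{"auto"}, \code{"DNA"} or \code{"RNA"}; with
#'   \code{"auto"} the alphabet is detected from the sequence content.
#' @return \code{readFastaSeqs}/\code{readSmallReads}: named character vector
#'   of uppercase sequences.
#' @export
readFastaSeqs <- function(path, alphabet = c("auto", "DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  if (any(grepl("[a-z]", seqs))) {
    message("lowercase bases in ", basename(path), " uppercased on read")
    seqs <- toupper(seqs)
  }
  names(seqs) <- sub("\\s.*$", "", names(set))
  for (i in seq_along(seqs)) {
    alph <- if (alphabet == "auto") .seqAlphabet(seqs[i]) else alphabet
    tryCatch(.checkBases(seqs[i], alph),
             error = function(e) stop(sprintf("malformed FASTA record %d (%s): %s",
                                              i, names(seqs)[i], conditionMessage(e)),
                                      call. = FALSE))
  }
  seqs
}

#' @param seqs named character vector of sequences.
#' @rdname readFastaSeqs
#' @export
writeFastaSeqs <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named before writing", call. = FALSE)
  writeLines(paste0(">", names(seqs), "\n", as.character(seqs)), path)
  invisible(path)
}

#' @rdname readFastaSeqs
#' @export
readSmallReads <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) return(character(0))
  if (startsWith(first, "@")) {
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L)
      stop("malformed FASTQ: number of lines not a multiple of 4", call. = FALSE)
    ids <- lines[seq(1L, length(lines), by = 4L)]
    seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
    quals <- lines[seq(4L, length(lines), by = 4L)]
    bad <- which(nchar(quals) != nchar(seqs))
    if (length(bad))
      stop(sprintf("malformed FASTQ record %d: quality length != sequence length",
                   bad[1]), call. = FALSE)
    names(seqs) <- sub("\\s.*$", "", sub("^@", "", ids))
    seqs
  } else if (startsWith(first, ">")) {
    readFastaSeqs(path)
  } else {
    stop("unrecognised reads format (expected FASTA or FASTQ): ", path,
         call. = FALSE)
  }
}

#' Write reads as FASTQ
#'
#' Writes reads with constant placeholder qualities (\code{I}, Sanger Q40);
#' the toolkit never consumes qualities.
#'
#' @param reads named character vector of read sequences.
#' @param path output path.
#' @export
writeFastq <- function(reads, path) {
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  if (is.null(names(reads))) names(reads) <- ids
  writeLines(paste0("@", names(reads), "\n", as.character(reads), "\n+\n",
                    vapply(nchar(reads), function(n)
                      paste(rep("I", n), collapse = ""), character(1))),
             path)
  invisible(path)
}
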