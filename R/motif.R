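#' Construct a HapMotif
#'
#' Variants inside the HVS-I window [16051, 16384] go to the \code{hvs1}
#' slot, all others to \code{coding}.
#'
#' @param variants data.frame with columns pos, kind, base, span.
#' @param markers character vector of special markers (e.g. "9bp_del").
#' @return A \linkS4class{HapMotif}.
#' @export
HapMotif <- function(variants = .emptyVariants(), markers = character(0)) {
  inWin <- variants$pos >= HVS1_START & variants$pos <= HVS1_END
  new("HapMotif", hvs1 = variants[inWin, , drop = FALSE],
      coding = variants[!inWin, , drop = FALSE],
      markers = unique(markers))
}

.variantRow <- function(pos, kind, base = NA_character_, span = 1L) {
  data.frame(pos = as.integer(pos), kind = kind, base = base,
             span = as.integer(span), stringsAsFactors = FALSE)
}

#' Variant positions of a motif
#' @param x a \linkS4class{HapMotif}.
#' @param where "hvs1", "coding" or "both".
#' @return Integer vector of rCRS positions.
#' @export
motifPositions <- function(x, where = c("both", "hvs1", "coding")) {
  where <- match.arg(where)
  out <- switch(where,
                hvs1 = x@hvs1$pos,
                coding = x@coding$pos,
                both = c(x@hvs1$pos, x@coding$pos))
  sort(as.integer(out))
}

#' Special markers of a motif
#' @param x a \linkS4class{HapMotif}.
#' @return Character vector.
#' @export
motifMarkers <- function(x) x@markers

#' Is the motif empty?
#' @param x a \linkS4class{HapMotif}.
#' @return Logical.
#' @export
isEmptyMotif <- function(x)
  nrow(x@hvs1) == 0L && nrow(x@coding) == 0L && length(x@markers) == 0L

setMethod("show", "HapMotif", function(object) {
  cat("HapMotif:", nrow(object@hvs1), "HVS-I variant(s),",
      nrow(object@coding), "coding variant(s)")
  if (length(object@markers))
    cat(", markers:", paste(object@markers, collapse = ","))
  cat("\n")
  if (nrow(object@hvs1)) cat("  HVS-I:", formatMotif(object), "\n")
})

# phrases recognised as special markers in motif shorthand
.SPECIAL_PHRASES <- c("9 bp deletion" = "9bp_del", "9bp_del" = "9bp_del",
                      "9bp deletion" = "9bp_del")

#' Parse HVS-I motif shorthand
#'
#' Motifs are written as dash-separated tokens relative to an offset
#' (default 16000): a bare number N is a transition at \code{offset + N}; a
#' trailing base letter marks a transversion to that base ("183C"); a
#' trailing "d" marks a single-site deletion; recognised phrases such as
#' "9 bp deletion" become special markers. The empty string yields the empty
#' motif.
#'
#' @param shorthand character scalar.
#' @param offset integer added to bare numeric tokens (default 16000).
#' @return A \linkS4class{HapMotif}.
#' @examples
#' parseMotif("093-129-223-284-290-319-362")
#' parseMotif("183C-189-232A-249-304")
#' @export
parseMotif <- function(shorthand, offset = 16000L) {
  stopifnot(length(shorthand) == 1L)
  shorthand <- trimws(shorthand)
  if (is.na(shorthand) || shorthand == "") return(HapMotif())
  markers <- character(0)
  for (ph in names(.SPECIAL_PHRASES)) {
    if (grepl(ph, shorthand, fixed = TRUE)) {
      markers <- c(markers, .SPECIAL_PHRASES[[ph]])
      shorthand <- gsub(ph, "", shorthand, fixed = TRUE)
    }
  }
  toks <- strsplit(shorthand, "-", fixed = TRUE)[[1]]
  toks <- trimws(toks)
  toks <- toks[toks != ""]
  rows <- lapply(toks, function(tk) {
    m <- regmatches(tk, regexec("^([0-9]+)([ACGTd]?)$", tk))[[1]]
    if (length(m) == 0L)
      stop("cannot parse motif token '", tk, "'", call. = FALSE)
    pos <- as.integer(m[2]) + as.integer(offset)
    if (pos < 1L || pos > 16569L)
      stop("motif token '", tk, "' maps outside [1, 16569]", call. = FALSE)
    suf <- m[3]
    if (suf == "") .variantRow(pos, "transition")
    else if (suf == "d") .variantRow(pos, "deletion")
    else .variantRow(pos, "transversion", base = suf)
  })
  v <- if (length(rows)) do.call(rbind, rows) else .emptyVariants()
  if (anyDuplicated(v$pos))
    stop("duplicate position in motif: ",
         paste(v$pos[duplicated(v$pos)], collapse = ","), call. = FALSE)
  HapMotif(v, markers)
}

#' Format a motif back to shorthand
#'
#' Inverse of \code{\link{parseMotif}} for motifs expressible in the
#' shorthand (HVS-I variants relative to the offset, plus special markers).
#'
#' @param motif a \linkS4class{HapMotif}.
#' @param offset integer offset (default 16000).
#' @return Character scalar.
#' @export
formatMotif <- function(motif, offset = 16000L) {
  v <- motif@hvs1
  v <- v[order(v$pos), , drop = FALSE]
  toks <- vapply(seq_len(nrow(v)), function(i) {
    num <- sprintf("%03d", v$pos[i] - offset)
    switch(v$kind[i],
           transition = num,
           transversion = paste0(num, v$base[i]),
           deletion = paste0(num, "d"),
           insertion = paste0(num, v$base[i]))
  }, character(1))
  if ("9bp_del" %in% motif@markers) toks <- c(toks, "9bp_del")
  paste(toks, collapse = "-")
}

#' Parse a diagnostic coding-SNP field
#'
#' Canonical format: semicolon-separated tokens, each a position optionally
#' followed by an explicit derived base ("10400;663", "15487T"), or a
#' special marker label ("9bp_del"). Thousands separators and whitespace are
#' tolerated inside tokens.
#'
#' @param field character scalar.
#' @return A \linkS4class{HapMotif} holding only coding variants/markers.
#' @export
parseCodingSnps <- function(field) {
  if (is.na(field) || trimws(field) == "") return(HapMotif())
  toks <- trimws(strsplit(field, ";", fixed = TRUE)[[1]])
  toks <- toks[toks != ""]
  markers <- character(0)
  rows <- list()
  for (tk in toks) {
    if (tk %in% .SPECIAL_PHRASES) { markers <- c(markers, .SPECIAL_PHRASES[[tk]]); next }
    clean <- gsub("[, ]", "", tk)
    m <- regmatches(clean, regexec("^([0-9]+)([ACGT]?)$", clean))[[1]]
    if (length(m) == 0L)
      stop("cannot parse coding SNP token '", tk, "'", call. = FALSE)
    pos <- as.integer(m[2])
    if (pos < 1L || pos > 16569L)
      stop("coding SNP '", tk, "' outside [1, 16569]", call. = FALSE)
    # allele recorded verbatim when printed; kind is unknown for
    # presence/absence typed SNPs, stored as transition by convention
    rows[[length(rows) + 1L]] <-
      if (m[3] == "") .variantRow(pos, "transition")
      else .variantRow(pos, "transversion", base = m[3])
  }
  v <- if (length(rows)) do.call(rbind, rows) else .emptyVariants()
  HapMotif(v, markers)
}

#' Merge two motifs
#' @param a,b \linkS4class{HapMotif} objects with disjoint positions.
#' @return Combined \linkS4class{HapMotif}.
#' @export
mergeMotifs <- function(a, b) {
  HapMotif(rbind(a@hvs1, a@coding, b@hvs1, b@coding),
           c(a@markers, b@markers))
}

## ---- sequence block ------------------------------------------------------

#' Construct a SequenceBlock
#'
#' @param seqs named character vector or \code{DNAStringSet} of aligned
#'   sequences.
#' @param window integer (start, end) rCRS coordinates; default the HVS-I
#'   window.
#' @return A \linkS4class{SequenceBlock}.
#' @export
SequenceBlock <- function(seqs, window = c(HVS1_START, HVS1_END)) {
  if (!is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  new("SequenceBlock", seqs = seqs, window = as.integer(window))
}

#' @describeIn SequenceBlock Sequences as a plain character vector.
#' @param x a \linkS4class{SequenceBlock}.
#' @export
blockSequences <- function(x) as.character(x@seqs)

#' @describeIn SequenceBlock Sample labels.
#' @export
blockLabels <- function(x) names(x@seqs)

#' @describeIn SequenceBlock Coordinate window (start, end).
#' @export
blockWindow <- function(x) x@window

setMethod("show", "SequenceBlock", function(object) {
  cat("SequenceBlock:", length(object@seqs), "sequence(s) of width",
      if (length(object@seqs)) Biostrings::width(object@seqs)[1] else 0,
      "| window", object@window[1], "-", object@window[2], "\n")
})

#' The packaged HVS-I reference sequence
#'
#' A deterministic 334-bp stand-in for the revised Cambridge reference over
#' the HVS-I window. It is synthetic (the true rCRS bases are not shipped);
#' every statistic in the package depends only on variant positions, not on
#' the reference bases themselves.
#'
#' @return A single-sequence \linkS4class{SequenceBlock}.
#' @export
hvs1Reference <- function() {
  if (is.null(.pmEnv$ref)) {
    f <- system.file("extdata", "hvs1_reference_synthetic.fasta",
                     package = "paleomito")
    ss <- Biostrings::readDNAStringSet(f)
    names(ss) <- "reference"
    .pmEnv$ref <- SequenceBlock(ss)
  }
  .pmEnv$ref
}

.TRANSIT <- c(A = "G", G = "A", C = "T", T = "C")

#' Reconstruct a sequence from a motif
#'
#' Applies the HVS-I variants of a motif to a reference row: transitions flip
#' the purine/pyrimidine partner (A<->G, C<->T), transversions and insertions
#' set the derived base, deletions become "-" gap characters. Coding variants
#' are outside the window and are ignored with a notice.
#'
#' @param motif a \linkS4class{HapMotif}.
#' @param reference a single-sequence \linkS4class{SequenceBlock} covering
#'   the HVS-I window (default the packaged reference).
#' @param quiet suppress the coding-variant notice.
#' @return Character scalar (the reconstructed sequence).
#' @export
motifToSequence <- function(motif, reference = hvs1Reference(),
                            quiet = FALSE) {
  win <- blockWindow(reference)
  refseq <- strsplit(blockSequences(reference)[1], "")[[1]]
  if (nrow(motif@coding) && !quiet)
    message(nrow(motif@coding),
            " coding variant(s) outside the window ignored")
  v <- motif@hvs1
  if (nrow(v) && (any(v$pos < win[1]) || any(v$pos > win[2])))
    stop("variant position outside the reference window", call. = FALSE)
  for (i in seq_len(nrow(v))) {
    idx <- v$pos[i] - win[1] + 1L
    refseq[idx] <- switch(v$kind[i],
      transition = .TRANSIT[[refseq[idx]]],
      transversion = v$base[i],
      insertion = v$base[i],
      deletion = { refseq[seq(idx, min(idx + v$span[i] - 1L,
                                       length(refseq)))] <- "-"; "-" })
  }
  paste(refseq, collapse = "")
}

#' Recover a motif from a sequence
#'
#' Compares a sequence to the reference row position by position and builds
#' the corresponding variant set: transition pairs become transitions, other
#' base changes transversions, gap runs single deletion variants with the
#' run length as span.
#'
#' @param seq character scalar aligned to the reference window.
#' @param reference a single-sequence \linkS4class{SequenceBlock}.
#' @return A \linkS4class{HapMotif}.
#' @export
sequenceToMotif <- function(seq, reference = hvs1Reference()) {
  win <- blockWindow(reference)
  r <- strsplit(blockSequences(reference)[1], "")[[1]]
  s <- strsplit(seq, "")[[1]]
  if (length(s) != length(r))
    stop("sequence length does not match the reference window", call. = FALSE)
  rows <- list(); i <- 1L
  while (i <= length(r)) {
    if (s[i] == "-") {
      j <- i
      while (j < length(r) && s[j + 1L] == "-") j <- j + 1L
      rows[[length(rows) + 1L]] <-
        .variantRow(win[1] + i - 1L, "deletion", span = j - i + 1L)
      i <- j + 1L
    } else {
      if (s[i] != r[i] && s[i] != "N") {
        kind <- if (identical(.TRANSIT[[r[i]]], s[i])) "transition"
                else "transversion"
        rows[[length(rows) + 1L]] <-
          .variantRow(win[1] + i - 1L, kind,
                      base = if (kind == "transversion") s[i]
                             else NA_character_)
      }
      i <- i + 1L
    }
  }
  v <- if (length(rows)) do.call(rbind, rows) else .emptyVariants()
  HapMotif(v)
}

#' Build an aligned SequenceBlock for a dataset
#'
#' Reconstructs one sequence per sample from its HVS-I motif against the
#' packaged reference.
#'
#' @param dataset a \linkS4class{PopulationDataset}.
#' @param reference reference \linkS4class{SequenceBlock}.
#' @return A \linkS4class{SequenceBlock} with one row per sample.
#' @export
datasetToBlock <- function(dataset, reference = hvs1Reference()) {
  seqs <- vapply(dataset@samples$sample_id, function(id)
    motifToSequence(dataset@motifs[[id]], reference, quiet = TRUE),
    character(1))
  SequenceBlock(setNames(seqs, dataset@samples$sample_id),
                blockWindow(reference))
}

#' Write a SequenceBlock as FASTA
#'
#' One record per sample; the window is noted in each header.
#'
#' @param block a \linkS4class{SequenceBlock}.
#' @param file output path.
#' @return The file path, invisibly.
#' @export
writeBlockFasta <- function(block, file) {
  ss <- block@seqs
  names(ss) <- paste0(names(ss), " window=", block@window[1], "-",
                      block@window[2])
  Biostrings::writeXStringSet(ss, file)
  invisible(file)
}
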