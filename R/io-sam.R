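#' Parse a CIGAR string into operation lengths and codes
#'
#' @param cigar A single CIGAR string (e.g. `"20M2D18M"`).
#' @param qname Read id used in error messages.
#' @return A data.frame with columns `len` (integer) and `op` (character).
#' @examples
#' parse_cigar("20M2D18M")
#' @export
parse_cigar <- function(cigar, qname = "<read>") {
  if (length(cigar) != 1L || is.na(cigar) || !grepl("^([0-9]+[MIDNSHP=X])+$", cigar))
    stop("malformed CIGAR '", cigar, "' for read ", qname)
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  data.frame(len = len, op = op, stringsAsFactors = FALSE)
}

#' Reference span of an alignment from its CIGAR
#'
#' Number of reference nucleotides consumed by the alignment
#' (M, D, N, =, X operations).
#'
#' @inheritParams parse_cigar
#' @return Integer span in reference nucleotides.
#' @examples
#' cigar_reference_span("20M2D18M")  # 40
#' @export
cigar_reference_span <- function(cigar, qname = "<read>") {
  ops <- parse_cigar(cigar, qname)
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

#' 0-based reference positions deleted by an alignment
#'
#' @param pos1 1-based leftmost mapping position (SAM POS).
#' @inheritParams parse_cigar
#' @return Integer vector of 0-based deleted reference positions (may be empty).
#' @export
cigar_deleted_positions <- function(cigar, pos1, qname = "<read>") {
  ops <- parse_cigar(cigar, qname)
  ref <- pos_to0(pos1)
  out <- integer(0)
  for (i in seq_len(nrow(ops))) {
    n <- ops$len[i]
    switch(ops$op[i],
      M = , `=` = , X = , N = { ref <- ref + n },
      D = { out <- c(out, seq.int(ref, length.out = n)); ref <- ref + n },
      I = , S = , H = , P = NULL
    )
  }
  out
}

#' Read aligned reads from SAM text
#'
#' A minimal reader for the single-end, sense-strand SAM files produced by
#' [simulate_clip_reads()] or any standard aligner.  Only the mandatory
#' columns are retained.  Header `@SQ` lines provide reference lengths.
#'
#' @param path Path to a SAM text file.
#' @return A list with `records` (data.frame: qname, flag, rname, pos, mapq,
#'   cigar, seq) and `ref_lengths` (named integer vector from `@SQ` lines).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  ref_lengths <- integer(0)
  if (length(sq)) {
    nm <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    ref_lengths <- stats::setNames(ln, nm)
  }
  if (!length(body)) {
    return(list(records = data.frame(qname = character(), flag = integer(),
                                     rname = character(), pos = integer(),
                                     mapq = integer(), cigar = character(),
                                     seq = character(), stringsAsFactors = FALSE),
                ref_lengths = ref_lengths))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nfield <- vapply(f, length, integer(1))
  if (any(nfield < 11L)) {
    bad <- which(nfield < 11L)[1L]
    stop("malformed SAM record at line ", bad, " of ", path,
         ": fewer than 11 fields")
  }
  records <- data.frame(
    qname = vapply(f, `[[`, "", 1L),
    flag  = as.integer(vapply(f, `[[`, "", 2L)),
    rname = vapply(f, `[[`, "", 3L),
    pos   = as.integer(vapply(f, `[[`, "", 4L)),
    mapq  = as.integer(vapply(f, `[[`, "", 5L)),
    cigar = vapply(f, `[[`, "", 6L),
    seq   = vapply(f, `[[`, "", 10L),
    stringsAsFactors = FALSE
  )
  list(records = records, ref_lengths = ref_lengths)
}

#' Write aligned reads as SAM text
#'
#' @param records data.frame with columns qname, flag, rname, pos (1-based),
#'   mapq, cigar, seq.
#' @param ref_lengths Named integer vector of reference lengths for `@SQ`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, ref_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), ref_lengths))
  body <- if (nrow(records)) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
            records$qname, records$flag, records$rname, records$pos,
            records$mapq, records$cigar, records$seq)
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
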