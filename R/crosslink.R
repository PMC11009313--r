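#' Call crosslink tags from aligned iCLIP reads
#'
#' Converts aligned reads to single-nucleotide crosslink evidence.  Each read
#' yields one *truncation* tag at the nucleotide immediately 5' of its start
#' (the iCLIP cDNA-truncation convention); reads starting at reference
#' position 0 have no upstream nucleotide and are dropped, with the count
#' reported.  Each reference nucleotide deleted by the alignment (CIGAR `D`)
#' additionally yields one *deletion* tag.  The two evidence classes are
#' never mixed in one count.  Antisense alignments (FLAG 0x10) are discarded
#' with a reported count.
#'
#' @param reads Either the path to a SAM file, a list as returned by
#'   [read_sam()], or an alignment data.frame with columns `qname`, `flag`,
#'   `rname`, `pos`, `cigar` (and optionally `sample`).
#' @param references Named vector of reference lengths, or a `DNAStringSet`.
#' @param sample Sample id recorded on the tags when the reads carry no
#'   `sample` column.
#' @return data.frame with columns `reference`, `position` (0-based),
#'   `evidence` (`"truncation"` or `"deletion"`), `sample`; attributes
#'   `dropped_start0` and `dropped_antisense` report discarded reads.
#' @examples
#' recs <- data.frame(qname = c("r1", "r2", "r3"), flag = 0L, rname = "U6",
#'                    pos = c(12L, 12L, 13L), mapq = 255L, cigar = "10M",
#'                    seq = "*")
#' tags <- call_crosslinks(recs, c(U6 = 106L), sample = "s1")
#' table(tags$position)
#' @export
call_crosslinks <- function(reads, references = NULL, sample = "sample1") {
  if (is.character(reads) && length(reads) == 1L) reads <- read_sam(reads)
  if (is.list(reads) && !is.data.frame(reads) && !is.null(reads$records)) {
    if (is.null(references) && length(reads$ref_lengths))
      references <- reads$ref_lengths
    reads <- reads$records
  }
  if (is.null(references)) stop("reference lengths are required")
  ref_len <- reference_lengths(references)
  if (!nrow(reads)) {
    out <- data.frame(reference = character(), position = integer(),
                      evidence = character(), sample = character(),
                      stringsAsFactors = FALSE)
    attr(out, "dropped_start0") <- 0L
    attr(out, "dropped_antisense") <- 0L
    return(out)
  }
  unknown <- setdiff(unique(reads$rname), names(ref_len))
  if (length(unknown))
    stop("read references unknown sequence(s): ", paste(unknown, collapse = ", "))
  if (is.null(reads$sample)) reads$sample <- sample
  antisense <- bitwAnd(reads$flag, 16L) != 0L
  n_anti <- sum(antisense)
  reads <- reads[!antisense, , drop = FALSE]
  start0 <- pos_to0(reads$pos)
  at_zero <- start0 == 0L
  n_zero <- sum(at_zero)
  trunc <- data.frame(reference = reads$rname[!at_zero],
                      position = start0[!at_zero] - 1L,
                      evidence = "truncation",
                      sample = reads$sample[!at_zero],
                      stringsAsFactors = FALSE)
  has_d <- grepl("D", reads$cigar, fixed = TRUE)
  del <- NULL
  if (any(has_d)) {
    idx <- which(has_d)
    dl <- lapply(idx, function(i)
      cigar_deleted_positions(reads$cigar[i], reads$pos[i], reads$qname[i]))
    nd <- lengths(dl)
    del <- data.frame(reference = rep(reads$rname[idx], nd),
                      position = unlist(dl),
                      evidence = "deletion",
                      sample = rep(reads$sample[idx], nd),
                      stringsAsFactors = FALSE)
  }
  out <- rbind(trunc, del)
  bad <- out$position < 0L | out$position >= ref_len[out$reference]
  if (any(bad)) stop("crosslink tag outside reference bounds")
  rownames(out) <- NULL
  attr(out, "dropped_start0") <- n_zero
  attr(out, "dropped_antisense") <- n_anti
  out
}

reference_lengths <- function(references) {
  if (methods::is(references, "DNAStringSet"))
    return(stats::setNames(Biostrings::width(references), names(references)))
  if (is.character(references))
    return(stats::setNames(nchar(references), names(references)))
  stats::setNames(as.integer(references), names(references))
}

#' Build a per-nucleotide crosslink profile
#'
#' Tallies truncation and deletion tags per nucleotide of one reference for
#' one sample.  Tag counts are conserved: the sums of the two count vectors
#' equal the numbers of input tags of each evidence class.
#'
#' @param tags Tag data.frame from [call_crosslinks()].
#' @param sample Sample id to select.
#' @param reference Reference name to select.
#' @param ref_length Length of the reference in nucleotides.
#' @param library_size Total mapped reads in the sample (defaults to the
#'   sample's truncation tag count plus dropped reads if recorded).
#' @return Object of class `nt_profile`: list with `reference`, `sample`,
#'   `truncation`, `deletion` (integer vectors of length `ref_length`,
#'   index i = 0-based position i-1), and `library_size`.
#' @export
build_profile <- function(tags, sample, reference, ref_length,
                          library_size = NULL) {
  sel <- tags$sample == sample & tags$reference == reference
  t <- tags[sel & tags$evidence == "truncation", ]
  d <- tags[sel & tags$evidence == "deletion", ]
  trunc <- tabulate(t$position + 1L, nbins = ref_length)
  del <- tabulate(d$position + 1L, nbins = ref_length)
  if (is.null(library_size)) library_size <- nrow(t)
  structure(list(reference = reference, sample = sample,
                 truncation = trunc, deletion = del,
                 library_size = library_size),
            class = "nt_profile")
}

#' @export
print.nt_profile <- function(x, ...) {
  cat("nt_profile: ", x$reference, " / ", x$sample, ", ",
      sum(x$truncation), " truncation + ", sum(x$deletion),
      " deletion tags over ", length(x$truncation), " nt\n", sep = "")
  invisible(x)
}

#' @export
plot.nt_profile <- function(x, evidence = c("truncation", "deletion"), ...) {
  evidence <- match.arg(evidence)
  y <- x[[evidence]]
  plot(seq_along(y), y, type = "h", xlab = paste(x$reference, "position (1-based)"),
       ylab = paste(evidence, "tags"), ...)
  invisible(x)
}

#' Per-position deletion fraction from covering reads
#'
#' For a given reference position, the fraction of reads overlapping that
#' position whose alignment deletes it.  Only reads for which the position is
#' strictly interior to the aligned span are counted: a deletion must be
#' anchored by aligned bases on both sides, so reads starting or ending at
#' the position itself carry no deletion information there.  Positions with
#' zero eligible coverage are flagged undefined (`NA` fraction), never
#' reported as 0.  The across-sample average is the unweighted mean of
#' per-sample fractions (see [mean_deletion_fraction()]).
#'
#' @param reads Alignments as accepted by [call_crosslinks()].
#' @param reference Reference name.
#' @param position 1-based reference position.
#' @param references Named reference lengths (optional; for validation).
#' @return data.frame of class `crosslink_site` with one row per sample:
#'   `reference`, `position` (1-based), `sample`, `coverage`,
#'   `deletion_reads`, `deletion_fraction`, `undefined`.
#' @export
deletion_fraction <- function(reads, reference, position, references = NULL) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_sam(reads)
  if (is.list(reads) && !is.data.frame(reads) && !is.null(reads$records))
    reads <- reads$records
  pos0 <- pos_to0(position)
  r <- reads[reads$rname == reference, , drop = FALSE]
  if (is.null(r$sample)) r$sample <- "sample1"
  start0 <- pos_to0(r$pos)
  # fast path for plain xM CIGARs; full parse only for the rest
  span <- integer(nrow(r))
  plain <- grepl("^[0-9]+M$", r$cigar)
  span[plain] <- as.integer(sub("M", "", r$cigar[plain], fixed = TRUE))
  for (i in which(!plain))
    span[i] <- cigar_reference_span(r$cigar[i], r$qname[i])
  interior <- start0 < pos0 & pos0 < start0 + span - 1L
  deleted <- logical(nrow(r))
  cand <- which(interior & grepl("D", r$cigar, fixed = TRUE))
  for (i in cand)
    deleted[i] <- pos0 %in% cigar_deleted_positions(r$cigar[i], r$pos[i],
                                                    r$qname[i])
  samples <- unique(r$sample)
  out <- do.call(rbind, lapply(samples, function(s) {
    sel <- r$sample == s
    cov <- sum(interior & sel)
    dr <- sum(deleted & sel)
    data.frame(reference = reference, position = position, sample = s,
               coverage = cov, deletion_reads = dr,
               deletion_fraction = if (cov > 0) dr / cov else NA_real_,
               undefined = cov == 0L, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("crosslink_site", "data.frame")
  out
}

#' Unweighted across-sample mean deletion fraction
#'
#' @param site A `crosslink_site` data.frame from [deletion_fraction()].
#' @return Mean of the defined per-sample fractions.
#' @export
mean_deletion_fraction <- function(site) {
  mean(site$deletion_fraction[!site$undefined])
}

#' Proportion of a reference's crosslink tags falling in a window
#'
#' The "proportion of total hits" statistic: the window's truncation-tag
#' count divided by the reference's total truncation-tag count, per sample.
#' Windows are 1-based inclusive at the interface and converted internally to
#' 0-based half-open coordinates.  Proportions over a disjoint exhaustive
#' partition of the reference sum to 1.  An empty reference profile yields an
#' undefined (NA) proportion, never 0.
#'
#' @param profile An `nt_profile` from [build_profile()], or a list of them.
#' @param window Length-2 integer vector `c(start, end)`, 1-based inclusive.
#' @param evidence Which evidence class to summarise (default truncation).
#' @return data.frame of class `region_summary`: `reference`, `sample`,
#'   `window_start`, `window_end`, `window_tags`, `total_tags`, `proportion`,
#'   `undefined`.
#' @export
region_proportion <- function(profile, window,
                              evidence = c("truncation", "deletion")) {
  evidence <- match.arg(evidence)
  if (inherits(profile, "nt_profile")) profile <- list(profile)
  out <- do.call(rbind, lapply(profile, function(p) {
    L <- length(p[[evidence]])
    if (window[1L] < 1L || window[2L] > L || window[2L] < window[1L])
      stop("window [", window[1L], ", ", window[2L],
           "] outside reference of length ", L)
    iv <- interval_to0(window[1L], window[2L])
    counts <- p[[evidence]]
    wt <- sum(counts[(iv$start + 1L):iv$end])
    tot <- sum(counts)
    data.frame(reference = p$reference, sample = p$sample,
               window_start = window[1L], window_end = window[2L],
               window_tags = wt, total_tags = tot,
               proportion = if (tot > 0) wt / tot else NA_real_,
               undefined = tot == 0L, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("region_summary", "data.frame")
  out
}

#' Per-RNA tag abundance with biotype roll-up
#'
#' Counts crosslink tags per reference RNA and sample, converts to
#' counts-per-million (CPM = count * 1e6 / library size, where the library
#' size is the sample's total tag count of the chosen evidence class), and
#' aggregates counts by biotype.  Tags on references missing from the
#' annotation are counted in an explicit `"unassigned"` bucket.
#'
#' @param tags Tag data.frame from [call_crosslinks()].
#' @param annotation data.frame with columns `reference` and `biotype`.
#' @param evidence Evidence class to count (default truncation).
#' @return List with `per_rna` (reference, biotype, sample, count, cpm) and
#'   `per_biotype` (biotype, sample, count, cpm).
#' @export
transcript_abundance <- function(tags, annotation,
                                 evidence = c("truncation", "deletion")) {
  evidence <- match.arg(evidence)
  t <- tags[tags$evidence == evidence, , drop = FALSE]
  bt <- stats::setNames(annotation$biotype, annotation$reference)
  t$biotype <- ifelse(t$reference %in% names(bt), bt[t$reference], "unassigned")
  agg <- stats::aggregate(list(count = rep(1L, nrow(t))),
                          by = list(reference = t$reference,
                                    biotype = t$biotype, sample = t$sample),
                          FUN = sum)
  lib <- stats::aggregate(list(library_size = agg$count),
                          by = list(sample = agg$sample), FUN = sum)
  agg <- merge(agg, lib, by = "sample")
  agg$cpm <- agg$count * 1e6 / agg$library_size
  per_bt <- stats::aggregate(list(count = agg$count, cpm = agg$cpm),
                             by = list(biotype = agg$biotype,
                                       sample = agg$sample), FUN = sum)
  list(per_rna = agg[order(agg$sample, -agg$count),
                     c("reference", "biotype", "sample", "count",
                       "library_size", "cpm")],
       per_biotype = per_bt)
}
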