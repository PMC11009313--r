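#' Format readers and writers
#'
#' Thin wrappers over Biostrings/rtracklayer/fgsea that keep all file-format
#' handling (and its coordinate conventions) in one place: FASTA and GTF are
#' 1-based inclusive, BED is 0-based half-open, crosslink tags are 0-based
#' internally.
#'
#' @name formats
NULL

#' @describeIn formats Read a FASTA file into a `Biostrings::DNAStringSet`.
#' @param path File path.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @describeIn formats Write sequences (`DNAStringSet` or named character) to FASTA.
#' @param x Sequences.
#' @export
write_fasta <- function(x, path) {
  if (!methods::is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @describeIn formats Read exon features from a GTF file as a `GRanges`.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr[gr$type == "exon"]
}

#' @describeIn formats Write exon features (`GRanges` with `gene_id`,
#'   `transcript_id`) to GTF.
#' @param gr Exon `GRanges`.
#' @export
write_gtf <- function(gr, path) {
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @describeIn formats Read gene sets from a GMT file as a named list.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' @describeIn formats Write crosslink tags as BED6 (0-based half-open;
#'   name = evidence class, score = tag count at that position).
#' @param tags Crosslink tag data.frame from [call_crosslinks()].
#' @export
write_bed6 <- function(tags, path) {
  key <- paste(tags$reference, tags$position, tags$evidence, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  df <- data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    start = as.integer(vapply(parts, `[[`, "", 2L)),
    name = vapply(parts, `[[`, "", 3L),
    score = as.integer(tab),
    stringsAsFactors = FALSE
  )
  df$end <- df$start + 1L
  df <- df[order(df$chrom, df$start), c("chrom", "start", "end", "name", "score")]
  df$strand <- "+"
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @describeIn formats Write a data.frame as TSV with a header line.
#' @param df A data.frame.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn formats Read a TSV written by [write_tsv()].
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a machine-readable run manifest
#'
#' Every analysis run can record its configuration, seed, package version and
#' the MD5 checksums of its input files, enabling byte-level reproduction.
#'
#' @param config Named list of run parameters (thresholds, seeds, paths).
#' @param path Output JSON path.
#' @param inputs Character vector of input file paths to checksum (optional).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, inputs = character(0)) {
  manifest <- list(
    package = "clipsplice",
    version = as.character(utils::packageVersion("clipsplice")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config
  )
  if (length(inputs)) {
    manifest$input_md5 <- as.list(tools::md5sum(inputs))
  }
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
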