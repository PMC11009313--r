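#' Extract donor and acceptor windows at exon-intron boundaries
#'
#' For every internal exon boundary of every transcript, extracts the
#' strand-corrected donor window (last 3 exonic + first 6 intronic
#' nucleotides, a 9-mer) and acceptor window (last 20 intronic + 3 exonic
#' nucleotides, a 23-mer).  Reverse-strand windows are reverse-complemented
#' so they always read 5' to 3' in the transcript sense.  Windows that would
#' run past a contig end are skipped with a warning, as are donor windows at
#' introns shorter than 6 nt and acceptor windows at introns shorter than
#' 26 nt.
#'
#' @param annotation Exon annotation: a GTF path, an exon `GRanges` with
#'   `gene_id`/`transcript_id`, or the list returned by
#'   [simulate_annotation()] / [annotation_from_exons()].
#' @param genome A `DNAStringSet` (or FASTA path) with the contig sequences.
#' @return data.frame of class `boundary_sites`: `gene`, `transcript`,
#'   `side` (donor/acceptor), `contig`, `boundary` (genomic 1-based
#'   coordinate of the terminal exonic nucleotide), `strand`, `window`
#'   (window sequence).
#' @export
extract_boundary_windows <- function(annotation, genome) {
  exons <- as_exon_granges(annotation)
  if (is.character(genome) && length(genome) == 1L) genome <- read_fasta(genome)
  jx <- junctions_from_exons(exons)
  if (!nrow(jx)) {
    return(structure(data.frame(gene = character(), transcript = character(),
                                side = character(), contig = character(),
                                boundary = integer(), strand = character(),
                                window = character(), stringsAsFactors = FALSE),
                     class = c("boundary_sites", "data.frame")))
  }
  rows <- vector("list", nrow(jx) * 2L)
  n_skip <- 0L
  for (i in seq_len(nrow(jx))) {
    contig <- jx$contig[i]
    if (!contig %in% names(genome)) {
      warning("contig ", contig, " not in genome; boundary skipped")
      n_skip <- n_skip + 1L
      next
    }
    cs <- genome[[contig]]
    clen <- length(cs)
    strand <- jx$strand[i]
    don <- jx$donor[i]
    acc <- jx$acceptor[i]
    intron_len <- abs(acc - don) - 1L
    # donor 9-mer: 3 exonic + 6 intronic
    if (intron_len < 6L) {
      warning("intron of ", intron_len, " nt too short for donor window at ",
              contig, ":", don, "; skipped")
    } else {
      rng <- if (strand == "+") c(don - 2L, don + 6L) else c(don - 6L, don + 2L)
      if (rng[1L] < 1L || rng[2L] > clen) {
        warning("donor window at ", contig, ":", don,
                " extends past contig end; skipped")
      } else {
        w <- Biostrings::subseq(cs, rng[1L], rng[2L])
        if (strand == "-") w <- Biostrings::reverseComplement(w)
        rows[[2L * i - 1L]] <- data.frame(
          gene = jx$gene_id[i], transcript = jx$transcript_id[i],
          side = "donor", contig = contig, boundary = don, strand = strand,
          window = as.character(w), stringsAsFactors = FALSE)
      }
    }
    # acceptor 23-mer: 20 intronic + 3 exonic
    if (intron_len < 26L) {
      warning("intron of ", intron_len, " nt too short for acceptor window at ",
              contig, ":", acc, "; skipped")
    } else {
      rng <- if (strand == "+") c(acc - 20L, acc + 2L) else c(acc - 2L, acc + 20L)
      if (rng[1L] < 1L || rng[2L] > clen) {
        warning("acceptor window at ", contig, ":", acc,
                " extends past contig end; skipped")
      } else {
        w <- Biostrings::subseq(cs, rng[1L], rng[2L])
        if (strand == "-") w <- Biostrings::reverseComplement(w)
        rows[[2L * i]] <- data.frame(
          gene = jx$gene_id[i], transcript = jx$transcript_id[i],
          side = "acceptor", contig = contig, boundary = acc, strand = strand,
          window = as.character(w), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  class(out) <- c("boundary_sites", "data.frame")
  out
}

as_exon_granges <- function(annotation) {
  if (is.character(annotation) && length(annotation) == 1L)
    return(read_gtf(annotation))
  if (methods::is(annotation, "GRanges")) return(annotation)
  if (is.list(annotation) && !is.null(annotation$exons))
    return(annotation$exons)
  stop("annotation must be a GTF path, exon GRanges, or annotation list")
}

junctions_from_exons <- function(exons) {
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(exons)),
    start = GenomicRanges::start(exons), end = GenomicRanges::end(exons),
    strand = as.character(GenomicRanges::strand(exons)),
    gene_id = exons$gene_id, transcript_id = exons$transcript_id,
    stringsAsFactors = FALSE)
  annotation_from_exons(df)$junctions
}

#' Assign crosslink tags to splice-site boundaries
#'
#' A tag supports a boundary when its position lies within `flank`
#' nucleotides of the junction coordinate on the same contig.  A tag falling
#' within the flank of more than one boundary is assigned to all of them; the
#' number of such multiply-assigned tags is reported in the
#' `multi_assigned` attribute.
#'
#' @param tags data.frame with columns `contig` (or `reference`), `position`
#'   (0-based), `sample`.
#' @param boundaries `boundary_sites` from [extract_boundary_windows()].
#' @param flank Maximum distance in nt (default 10).
#' @return The boundaries with one count column per sample
#'   (`count.<sample>`); attribute `multi_assigned` and `unassigned` report
#'   tag fates.
#' @export
assign_tags_to_boundaries <- function(tags, boundaries, flank = 10L) {
  if (is.null(tags$contig)) tags$contig <- tags$reference
  samples <- unique(tags$sample)
  b_gr <- GenomicRanges::GRanges(
    seqnames = boundaries$contig,
    ranges = IRanges::IRanges(start = boundaries$boundary - flank,
                              end = boundaries$boundary + flank))
  t_gr <- GenomicRanges::GRanges(
    seqnames = tags$contig,
    ranges = IRanges::IRanges(start = pos_to1(tags$position), width = 1L))
  hits <- GenomicRanges::findOverlaps(t_gr, b_gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  out <- boundaries
  for (s in samples) {
    sel <- tags$sample[qh] == s
    out[[paste0("count.", s)]] <- tabulate(sh[sel], nbins = nrow(boundaries))
  }
  attr(out, "multi_assigned") <- sum(table(qh) > 1L)
  attr(out, "unassigned") <- nrow(tags) - length(unique(qh))
  out
}

#' Splice-site category fold-change stratification
#'
#' Partitions per-boundary log2 fold changes into the weak / intermediate /
#' strong maxent categories and summarises each category's distribution
#' (histogram counts and excess kurtosis when the category holds at least 4
#' sites).  Boundaries whose combined tag count across conditions falls below
#' `min_total` are excluded from fold-change reporting to suppress
#' noise-driven extreme values.
#'
#' @param boundaries `boundary_sites` with a `category` column (from scoring
#'   the windows with [maxent_score()]) and per-sample `count.<sample>`
#'   columns (from [assign_tags_to_boundaries()]).
#' @param conditions Named character vector mapping sample id to condition;
#'   exactly two conditions, the first level treated as case.
#' @param case Condition treated as case (numerator); default the first.
#' @param pseudocount,lfc_cutoff Passed to [log2_fold_change()].
#' @param min_total Minimum combined raw tag count (default 10).
#' @param n_boot Bootstrap replicates for the per-category kurtosis CI.
#' @return List of class `stratified_fc` with `sites` (per-boundary log2fc
#'   and category), `by_category` (list of per-category fold-change vectors),
#'   and `kurtosis` (per-category `fc_summary` or NULL when n < 4).
#' @export
stratified_fold_changes <- function(boundaries, conditions, case = NULL,
                                    pseudocount = 0.5, lfc_cutoff = 1,
                                    min_total = 10L, n_boot = 0L) {
  if (is.null(boundaries$category)) stop("boundaries need a maxent category column")
  samp <- names(conditions)
  cnt_cols <- paste0("count.", samp)
  if (!all(cnt_cols %in% names(boundaries)))
    stop("boundaries lack count columns for some samples")
  conds <- unique(unname(conditions))
  if (length(conds) != 2L) stop("exactly two conditions required")
  if (is.null(case)) case <- conds[1L]
  ctrl <- setdiff(conds, case)
  counts <- as.matrix(boundaries[, cnt_cols, drop = FALSE])
  lib <- colSums(counts)
  cpm <- normalize_cpm(counts, lib, conditions = unname(conditions[samp]))
  keep <- rowSums(counts) >= min_total
  fc <- log2_fold_change(cpm$condition_means[keep, case],
                         cpm$condition_means[keep, ctrl],
                         feature = rownames(boundaries)[keep],
                         pseudocount = pseudocount, lfc_cutoff = lfc_cutoff)
  sites <- cbind(boundaries[keep, setdiff(names(boundaries), cnt_cols)],
                 fc[, c("log2fc", "direction")])
  cats <- c("weak", "intermediate", "strong")
  by_cat <- lapply(stats::setNames(cats, cats), function(cc)
    sites$log2fc[sites$category == cc])
  kurt <- lapply(stats::setNames(cats, cats), function(cc) {
    v <- by_cat[[cc]]
    if (length(v) >= 4L && stats::var(v) > 0)
      excess_kurtosis(v, label = cc, n_boot = n_boot) else NULL
  })
  structure(list(sites = sites, by_category = by_cat, kurtosis = kurt,
                 case = case, control = ctrl, min_total = min_total),
            class = "stratified_fc")
}

#' @export
print.stratified_fc <- function(x, ...) {
  cat("stratified fold changes (", x$case, " / ", x$control, ")\n", sep = "")
  for (cc in names(x$by_category)) {
    v <- x$by_category[[cc]]
    cat("  ", format(cc, width = 12), length(v), " sites",
        if (!is.null(x$kurtosis[[cc]]))
          paste0(", excess kurtosis ",
                 signif(x$kurtosis[[cc]]$excess_kurtosis, 3)),
        "\n", sep = "")
  }
  invisible(x)
}

#' Fisher exact gene-set enrichment
#'
#' Two-sided Fisher exact test of each gene set's overlap with a selected
#' gene list against a background, with Benjamini-Hochberg adjustment across
#' sets.  The odds ratio is the sample odds ratio with Haldane correction
#' (0.5 added to every cell) whenever a cell is zero.
#'
#' @param selected Character vector of selected genes (must be a subset of
#'   `background`).
#' @param background Character vector of background genes.
#' @param gene_sets Named list of gene vectors, or a GMT file path.
#' @param direction Optional label (`"up"`/`"down"`) carried into the result.
#' @return data.frame of class `enrichment_result`: `gene_set`, the 2x2
#'   table cells (`in_set_selected`, `in_set_not`, `out_set_selected`,
#'   `out_set_not`), `odds_ratio`, `p`, `p_adj`, `direction`.
#' @export
fisher_enrichment <- function(selected, background, gene_sets,
                              direction = NA_character_) {
  if (is.character(gene_sets) && length(gene_sets) == 1L)
    gene_sets <- read_gmt(gene_sets)
  background <- unique(background)
  if (!length(background)) stop("empty background")
  selected <- unique(selected)
  if (!all(selected %in% background))
    stop("selected genes must be a subset of the background")
  rows <- lapply(names(gene_sets), function(gs) {
    set <- intersect(unique(gene_sets[[gs]]), background)
    if (!length(set)) return(NULL)
    a <- length(intersect(set, selected))
    b <- length(set) - a
    cc <- length(selected) - a
    d <- length(background) - length(set) - cc
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2L, byrow = TRUE),
                            alternative = "two.sided")$p.value
    or <- if (min(a, b, cc, d) == 0L)
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    else (a * d) / (b * cc)
    data.frame(gene_set = gs, in_set_selected = a, in_set_not = b,
               out_set_selected = cc, out_set_not = d, odds_ratio = or,
               p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    stop("no gene set overlaps the background")
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$direction <- direction
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Nucleotide composition contrast between two exon sequence sets
#'
#' Compares per-position base frequencies (when all windows share one
#' length) and aggregate single-base fractions between two sequence sets,
#' e.g. exons with up- versus down-regulated crosslink binding.  Aggregate
#' fractions carry percentile bootstrap CIs (resampling sequences).  Both a
#' plain frequency difference and a log-odds difference are reported
#' per position.
#'
#' @param up_seqs,down_seqs Character vectors or `DNAStringSet`s (non-empty).
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Bootstrap seed.
#' @return List of class `composition_contrast` with `aggregate` (per base:
#'   fraction in each set, difference, bootstrap CI of the difference) and
#'   `per_position` (NULL when lengths differ: position, base, freq_up,
#'   freq_down, difference, log_odds).
#' @export
composition_contrast <- function(up_seqs, down_seqs, n_boot = 200L, seed = 1L) {
  up <- toupper(as.character(up_seqs))
  dn <- toupper(as.character(down_seqs))
  if (!length(up) || !length(dn)) stop("empty sequence set")
  base_frac <- function(seqs) {
    counts <- colSums(Biostrings::alphabetFrequency(
      Biostrings::DNAStringSet(seqs))[, BASES, drop = FALSE])
    counts / sum(counts)
  }
  f_up <- base_frac(up)
  f_dn <- base_frac(dn)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  boot <- replicate(n_boot, {
    bu <- base_frac(up[sample.int(length(up), replace = TRUE)])
    bd <- base_frac(dn[sample.int(length(dn), replace = TRUE)])
    bu - bd
  })
  ci <- apply(boot, 1L, stats::quantile, probs = c(0.025, 0.975))
  aggregate <- data.frame(
    base = BASES, frac_up = unname(f_up), frac_down = unname(f_dn),
    difference = unname(f_up - f_dn),
    ci_lo = ci[1L, ], ci_hi = ci[2L, ], stringsAsFactors = FALSE)
  per_position <- NULL
  if (length(unique(nchar(c(up, dn)))) == 1L) {
    pwm <- function(seqs) {
      m <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs),
                                       as.prob = TRUE)[BASES, , drop = FALSE]
      m
    }
    pu <- pwm(up)
    pd <- pwm(dn)
    eps <- 1e-3
    L <- ncol(pu)
    per_position <- data.frame(
      position = rep(seq_len(L), each = 4L),
      base = rep(BASES, L),
      freq_up = as.vector(pu), freq_down = as.vector(pd),
      difference = as.vector(pu - pd),
      log_odds = as.vector(log2(((pu + eps) / (1 - pu + eps)) /
                                  ((pd + eps) / (1 - pd + eps)))),
      stringsAsFactors = FALSE)
  }
  structure(list(aggregate = aggregate, per_position = per_position,
                 n_up = length(up), n_down = length(dn)),
            class = "composition_contrast")
}

#' @export
print.composition_contrast <- function(x, ...) {
  cat("composition contrast (", x$n_up, " up vs ", x$n_down, " down)\n",
      sep = "")
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}
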