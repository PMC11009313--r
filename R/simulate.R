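#' Construct the generative ground truth for a simulation
#'
#' A `simulation_truth` object holds every parameter the synthetic-data
#' generators need: short reference sequences (e.g. snRNAs), a per-nucleotide
#' crosslink probability profile, designated deletion-bearing crosslink
#' nucleotides with a per-read deletion probability, the read geometry and
#' sample sheet, and (optionally) per-event PSI means/dispersions for
#' junction-count simulation.  All downstream generators are deterministic
#' functions of this object: the single integer seed is split hierarchically
#' per sample, so identical truth objects yield byte-identical outputs.
#'
#' @param seed Single integer master seed.
#' @param references Named character vector (or `DNAStringSet`) of reference
#'   sequences.
#' @param binding_profile Named list (one entry per reference) of non-negative
#'   numeric vectors, one value per nucleotide, each summing to 1.  The value
#'   at a nucleotide is the probability that a read's crosslink site (the
#'   nucleotide immediately 5' of the read start) is there.  The final
#'   nucleotide of a reference must carry zero mass, since a read crosslinked
#'   there would have no room to start.
#' @param deletion_sites Named list of 1-based positions (per reference) at
#'   which covering reads may carry a crosslink-induced deletion.
#' @param deletion_prob Probability in \[0,1\] that a read covering a
#'   designated deletion nucleotide carries a deletion there (independently
#'   per nucleotide).
#' @param read_length Read length in nucleotides.
#' @param n_reads_per_sample Number of reads per sample.
#' @param samples data.frame with columns `sample_id` and `condition`.
#' @param reference_weights Optional named numeric vector of per-reference
#'   sampling weights (defaults to uniform).
#' @param psi_truth Optional data.frame with columns `event_id`, `condition`,
#'   `mean` (PSI in \[0,1\]) and `dispersion` (beta-binomial overdispersion
#'   rho in (0,1)); an optional `type` column gives the event type.
#' @param planted_cryptic Optional data.frame of junctions (columns `contig`,
#'   `donor`, `acceptor`, `strand`) absent from any emitted annotation.
#' @return An object of class `simulation_truth`.
#' @examples
#' tr <- simulation_truth(
#'   seed = 1, references = c(U6 = strrep("ACGU", 10)),
#'   binding_profile = list(U6 = c(rep(0, 19), 1, rep(0, 20))),
#'   read_length = 10, n_reads_per_sample = 100,
#'   samples = data.frame(sample_id = "s1", condition = "case")
#' )
#' @export
simulation_truth <- function(seed, references, binding_profile,
                             deletion_sites = list(), deletion_prob = 0,
                             read_length = 35L, n_reads_per_sample = 10000L,
                             samples = data.frame(
                               sample_id = c("case_1", "case_2", "ctrl_1", "ctrl_2"),
                               condition = c("case", "case", "control", "control"),
                               stringsAsFactors = FALSE),
                             reference_weights = NULL,
                             psi_truth = NULL, planted_cryptic = NULL) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  seed <- as.integer(seed)
  if (methods::is(references, "DNAStringSet"))
    references <- stats::setNames(as.character(references), names(references))
  references <- vapply(references, function(s)
    chartr("u", "t", toupper(s)), "")
  if (is.null(names(references)) || any(names(references) == ""))
    stop("references must be named")
  ref_len <- nchar(references)
  if (!setequal(names(binding_profile), names(references)))
    stop("binding_profile must have one entry per reference")
  for (nm in names(binding_profile)) {
    p <- binding_profile[[nm]]
    if (length(p) != ref_len[[nm]])
      stop("binding_profile for ", nm, " has length ", length(p),
           " but reference has ", ref_len[[nm]], " nt")
    if (any(p < 0)) stop("binding_profile for ", nm, " has negative entries")
    if (abs(sum(p) - 1) > 1e-9)
      stop("binding_profile for ", nm, " sums to ", sum(p), ", not 1")
    if (p[length(p)] > 0)
      stop("binding_profile for ", nm, " has mass on the final nucleotide; ",
           "no read can start 3' of it")
  }
  if (deletion_prob < 0 || deletion_prob > 1)
    stop("deletion_prob must be in [0,1]")
  for (nm in names(deletion_sites)) {
    d <- deletion_sites[[nm]]
    if (!nm %in% names(references)) stop("deletion_sites names unknown reference ", nm)
    if (any(d < 1L) || any(d > ref_len[[nm]]))
      stop("deletion_sites for ", nm, " outside reference")
  }
  stopifnot(read_length >= 1L, n_reads_per_sample >= 0L)
  if (!all(c("sample_id", "condition") %in% names(samples)))
    stop("samples needs sample_id and condition columns")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  if (is.null(reference_weights)) {
    reference_weights <- stats::setNames(
      rep(1 / length(references), length(references)), names(references))
  }
  if (!is.null(psi_truth)) {
    if (!all(c("event_id", "condition", "mean", "dispersion") %in% names(psi_truth)))
      stop("psi_truth needs event_id, condition, mean, dispersion columns")
    if (any(psi_truth$mean < 0 | psi_truth$mean > 1))
      stop("psi_truth mean PSI must be in [0,1]")
    if (any(psi_truth$dispersion <= 0 | psi_truth$dispersion >= 1))
      stop("psi_truth dispersion must be in (0,1)")
  }
  structure(list(
    seed = seed, references = references, binding_profile = binding_profile,
    deletion_sites = deletion_sites, deletion_prob = deletion_prob,
    read_length = as.integer(read_length),
    n_reads_per_sample = as.integer(n_reads_per_sample),
    samples = samples, reference_weights = reference_weights,
    psi_truth = psi_truth, planted_cryptic = planted_cryptic
  ), class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("simulation_truth (seed ", x$seed, ")\n", sep = "")
  cat("  references: ", paste0(names(x$references), " (", nchar(x$references),
                               " nt)", collapse = ", "), "\n", sep = "")
  cat("  samples: ", nrow(x$samples), " (",
      paste(unique(x$samples$condition), collapse = " vs "), ")\n", sep = "")
  cat("  reads/sample: ", x$n_reads_per_sample, ", read length ",
      x$read_length, "\n", sep = "")
  if (length(x$deletion_sites))
    cat("  deletion sites: ",
        paste0(names(x$deletion_sites), ":",
               vapply(x$deletion_sites, paste, "", collapse = ","),
               collapse = "; "),
        " at per-read probability ", x$deletion_prob, "\n", sep = "")
  if (!is.null(x$psi_truth))
    cat("  PSI events: ", length(unique(x$psi_truth$event_id)), "\n", sep = "")
  invisible(x)
}

# per-sample seeds derived reproducibly from the master seed
sample_seeds <- function(seed, n, stream = 0L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed + 10000L * stream)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate aligned iCLIP reads with truncation and deletion evidence
#'
#' Reads are placed on the truth's references so that the nucleotide
#' immediately 5' of each read start is drawn from the per-reference binding
#' profile (the iCLIP truncation convention).  A read covering a designated
#' crosslink nucleotide carries a deletion there (a CIGAR `D` operation) with
#' probability `deletion_prob`, independently per nucleotide.  Reads running
#' off the reference end are truncated.  Output is standard single-end SAM
#' text (one file per sample when `dir` is given) plus a per-read ground-truth
#' tag table.
#'
#' @param truth A [simulation_truth()] object.
#' @param dir Optional output directory; SAM files (`<sample_id>.sam`) and
#'   `tags_truth.tsv` are written there.
#' @return A list of class `clip_simulation` with `records` (all samples'
#'   alignments), `truth_tags` (per-read crosslink position and deletions),
#'   `ref_lengths`, and `paths` when files were written.
#' @export
simulate_clip_reads <- function(truth, dir = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  ref_len <- nchar(truth$references)
  short <- names(ref_len)[ref_len < truth$read_length]
  if (length(short))
    stop("read_length ", truth$read_length, " exceeds reference length of ",
         paste(short, collapse = ", "))
  n_samp <- nrow(truth$samples)
  seeds <- sample_seeds(truth$seed, n_samp, stream = 1L)
  ref_names <- names(truth$references)
  all_rec <- vector("list", n_samp)
  all_tag <- vector("list", n_samp)
  for (i in seq_len(n_samp)) {
    sid <- truth$samples$sample_id[i]
    set.seed(seeds[i])
    n <- truth$n_reads_per_sample
    ridx <- if (length(ref_names) == 1L) rep(1L, n) else
      sample.int(length(ref_names), n, replace = TRUE,
                 prob = truth$reference_weights[ref_names])
    rec <- vector("list", length(ref_names))
    tag <- vector("list", length(ref_names))
    for (r in seq_along(ref_names)) {
      nr <- sum(ridx == r)
      if (!nr) next
      sim <- simulate_reads_one_ref(
        truth$references[[r]], truth$binding_profile[[ref_names[r]]],
        truth$deletion_sites[[ref_names[r]]], truth$deletion_prob,
        truth$read_length, nr)
      sim$records$rname <- ref_names[r]
      sim$records$qname <- sprintf("%s_%s_%06d", sid, ref_names[r], seq_len(nr))
      sim$tags$reference <- ref_names[r]
      sim$tags$read_id <- sim$records$qname
      rec[[r]] <- sim$records
      tag[[r]] <- sim$tags
    }
    rec <- do.call(rbind, rec)
    tag <- do.call(rbind, tag)
    rec$sample <- sid
    tag$sample <- sid
    all_rec[[i]] <- rec
    all_tag[[i]] <- tag
  }
  records <- do.call(rbind, all_rec)
  truth_tags <- do.call(rbind, all_tag)
  rownames(records) <- rownames(truth_tags) <- NULL
  out <- list(records = records, truth_tags = truth_tags,
              ref_lengths = stats::setNames(as.integer(ref_len), ref_names))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- character(0)
    for (sid in truth$samples$sample_id) {
      p <- file.path(dir, paste0(sid, ".sam"))
      write_sam(records[records$sample == sid,
                        c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")],
                out$ref_lengths, p)
      paths[sid] <- p
    }
    tp <- file.path(dir, "tags_truth.tsv")
    write_tsv(truth_tags, tp)
    out$paths <- c(paths, truth = tp)
  }
  class(out) <- "clip_simulation"
  out
}

# core placement for one sample x one reference; positions 0-based internally
simulate_reads_one_ref <- function(refseq, profile, del_sites1, del_prob,
                                   read_len, n) {
  L <- nchar(refseq)
  xl <- sample.int(L, n, replace = TRUE, prob = profile) - 1L  # crosslink, 0-based
  start0 <- xl + 1L
  del_sites0 <- sort(pos_to0(del_sites1))
  ext <- integer(n)
  del_mat <- matrix(FALSE, n, length(del_sites0))
  if (length(del_sites0) && del_prob > 0) {
    for (k in seq_along(del_sites0)) {
      d <- del_sites0[k]
      # a deletion must be anchored by aligned bases on both sides, so only
      # reads for which d is strictly interior to the alignment are eligible;
      # earlier deletions extend the reference span (ext)
      eligible <- start0 < d & d < start0 + read_len - 1L + ext & d < L - 1L
      hit <- eligible & stats::runif(n) < del_prob
      del_mat[, k] <- hit
      ext <- ext + hit
    }
  }
  n_del <- rowSums(del_mat)
  # query length after truncation at the reference end
  ref_avail <- L - start0
  qlen <- pmin(read_len, ref_avail - n_del)
  span <- qlen + n_del
  cigar <- paste0(qlen, "M")
  seqs <- substr(rep(refseq, n), start0 + 1L, start0 + span)
  has_del <- which(n_del > 0L)
  for (i in has_del) {
    dels <- del_sites0[del_mat[i, ]]
    cigar[i] <- build_cigar_with_deletions(start0[i], span[i], dels)
    keep <- setdiff(seq.int(start0[i], start0[i] + span[i] - 1L), dels)
    seqs[i] <- paste(strsplit(seqs[i], "")[[1L]][keep - start0[i] + 1L],
                     collapse = "")
  }
  records <- data.frame(
    qname = "", flag = 0L, rname = "", pos = pos_to1(start0), mapq = 255L,
    cigar = cigar, seq = seqs, stringsAsFactors = FALSE)
  tags <- data.frame(
    reference = "", read_id = "", crosslink_pos0 = xl,
    deletions0 = vapply(seq_len(n), function(i)
      paste(del_sites0[del_mat[i, ]], collapse = ","), ""),
    stringsAsFactors = FALSE)
  list(records = records, tags = tags)
}

build_cigar_with_deletions <- function(start0, span, dels0) {
  is_del <- seq.int(start0, start0 + span - 1L) %in% dels0
  r <- rle(is_del)
  paste0(r$lengths, ifelse(r$values, "D", "M"), collapse = "")
}

#' Simulate splice-junction count tables with group-specific PSI dispersion
#'
#' For every event and sample, a per-sample inclusion level is drawn from a
#' beta distribution with the condition's mean PSI and overdispersion rho
#' (`dispersion` in the truth's `psi_truth`), and inclusion/skipping counts
#' are then drawn binomially so that they always sum to `depth`.  `rho`
#' controls the between-sample PSI variance beyond binomial sampling:
#' `Var(PSI) ~ psi(1-psi) * (rho + (1-rho)/depth)`.
#'
#' @param truth A [simulation_truth()] object with `psi_truth` set.
#' @param depth Total junction reads per event per sample (> 0).
#' @return data.frame with columns event_id, type, sample, condition,
#'   inclusion, skipping, psi.
#' @export
simulate_junction_counts <- function(truth, depth) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (is.null(truth$psi_truth)) stop("truth has no psi_truth")
  if (depth <= 0) stop("depth must be > 0")
  pt <- truth$psi_truth
  if (any(pt$dispersion <= 0)) stop("dispersion must be > 0")
  if (is.null(pt$type)) pt$type <- "SE"
  n_samp <- nrow(truth$samples)
  seeds <- sample_seeds(truth$seed, n_samp, stream = 2L)
  out <- vector("list", n_samp)
  for (i in seq_len(n_samp)) {
    set.seed(seeds[i])
    cond <- truth$samples$condition[i]
    ev <- pt[pt$condition == cond, ]
    if (!nrow(ev)) next
    rho <- ev$dispersion
    mu <- ev$mean
    a <- mu * (1 - rho) / rho
    b <- (1 - mu) * (1 - rho) / rho
    p <- ifelse(mu <= 0 | mu >= 1, mu, stats::rbeta(nrow(ev), a, b))
    inc <- stats::rbinom(nrow(ev), depth, p)
    out[[i]] <- data.frame(
      event_id = ev$event_id, type = ev$type,
      sample = truth$samples$sample_id[i], condition = cond,
      inclusion = inc, skipping = depth - inc, psi = inc / depth,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# smallest consensus-base probability achieving a per-position information
# content of `bits` over a 4-letter alphabet (entropy 2 - bits)
consensus_prob_for_bits <- function(bits) {
  if (bits < 0 || bits > 2) stop("information content must be in [0, 2] bits")
  if (bits < 1e-12) return(0.25)
  if (bits > 2 - 1e-12) return(1)
  h <- function(q) -q * log2(q) - (1 - q) * log2((1 - q) / 3)
  stats::uniroot(function(q) h(q) - (2 - bits), c(0.25 + 1e-12, 1 - 1e-12),
                 tol = 1e-12)$root
}

#' Simulate signal and decoy splice-site sequence sets
#'
#' Signal sequences are drawn from a position-specific model whose
#' per-position information content (in bits, 0--2) is requested by the
#' caller; decoys are drawn uniformly over ACGT.  Window lengths follow the
#' donor (9-mer) / acceptor (23-mer) conventions.
#'
#' @param info_content Numeric vector of per-position target bits; its length
#'   (9 or 23) sets the window length.  Values above 2 bits are unreachable
#'   and raise an error.
#' @param n_signal,n_decoy Numbers of sequences to draw.
#' @param seed Integer seed.
#' @param consensus Optional consensus string (length matching
#'   `info_content`); defaults to the canonical donor/acceptor consensus.
#' @param dir Optional directory; `signal.fa` and `decoy.fa` are written.
#' @return List with `signal` and `decoy` (`DNAStringSet`), the position
#'   weight matrix `pwm`, and the consensus used.
#' @export
simulate_splice_site_sets <- function(info_content, n_signal, n_decoy, seed,
                                      consensus = NULL, dir = NULL) {
  L <- length(info_content)
  if (!L %in% c(9L, 23L))
    stop("window length must be 9 (donor) or 23 (acceptor)")
  if (any(info_content > 2))
    stop("information content above 2 bits/position is unreachable")
  if (is.null(consensus)) {
    consensus <- if (L == 9L) "CAGGTAAGT" else "TTTTTTTTTTTTTTTTTTAGGAA"
  }
  cons <- strsplit(toupper(consensus), "")[[1L]]
  if (length(cons) != L) stop("consensus length must match info_content")
  bases <- c("A", "C", "G", "T")
  set.seed(as.integer(seed))
  cons[cons == "N"] <- sample(bases, sum(cons == "N"), replace = TRUE)
  if (!all(cons %in% bases)) stop("consensus must be over A/C/G/T/N")
  pwm <- matrix(0, 4, L, dimnames = list(bases, NULL))
  for (j in seq_len(L)) {
    q <- consensus_prob_for_bits(info_content[j])
    pwm[, j] <- (1 - q) / 3
    pwm[cons[j], j] <- q
  }
  draw <- function(n, probs) {
    m <- vapply(seq_len(L), function(j)
      sample(bases, n, replace = TRUE, prob = probs[, j]), character(n))
    if (n == 1L) m <- matrix(m, nrow = 1L)
    apply(m, 1L, paste, collapse = "")
  }
  signal <- Biostrings::DNAStringSet(draw(n_signal, pwm))
  decoy <- Biostrings::DNAStringSet(draw(n_decoy, matrix(0.25, 4, L,
                                                         dimnames = list(bases, NULL))))
  names(signal) <- sprintf("signal_%d", seq_len(n_signal))
  names(decoy) <- sprintf("decoy_%d", seq_len(n_decoy))
  out <- list(signal = signal, decoy = decoy, pwm = pwm,
              consensus = paste(cons, collapse = ""))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$paths <- c(signal = write_fasta(signal, file.path(dir, "signal.fa")),
                   decoy = write_fasta(decoy, file.path(dir, "decoy.fa")))
  }
  out
}

#' Build an annotation from an explicit exon table
#'
#' Validates per-transcript exon structure (no overlaps, positive widths) and
#' derives the annotated junction set (donor = last exonic nucleotide of the
#' upstream exon in transcription order, acceptor = first exonic nucleotide of
#' the downstream exon; genomic 1-based, strand-aware).
#'
#' @param exons data.frame with columns contig, start, end (1-based
#'   inclusive), strand, gene_id, transcript_id.
#' @return List with `exons` (a `GRanges` of exon features) and `junctions`
#'   (data.frame contig, donor, acceptor, strand, gene_id, transcript_id).
#' @export
annotation_from_exons <- function(exons) {
  need <- c("contig", "start", "end", "strand", "gene_id", "transcript_id")
  if (!all(need %in% names(exons))) stop("exons needs columns: ",
                                         paste(need, collapse = ", "))
  jx <- vector("list", 0L)
  for (tx in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == tx, ]
    e <- e[order(e$start), ]
    if (any(e$end < e$start)) stop("exon with end < start in transcript ", tx)
    if (nrow(e) > 1L && any(e$start[-1L] <= e$end[-nrow(e)]))
      stop("overlapping exons within transcript ", tx)
    if (nrow(e) < 2L) next
    minus <- e$strand[1L] == "-"
    # transcription order: genomic left-to-right on +, right-to-left on -
    up <- if (minus) e[-1L, ] else e[-nrow(e), ]
    dn <- if (minus) e[-nrow(e), ] else e[-1L, ]
    jx[[tx]] <- data.frame(
      contig = e$contig[1L],
      donor = if (minus) up$start else up$end,
      acceptor = if (minus) dn$end else dn$start,
      strand = e$strand[1L], gene_id = e$gene_id[1L], transcript_id = tx,
      stringsAsFactors = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = exons$contig,
    ranges = IRanges::IRanges(start = exons$start, end = exons$end),
    strand = exons$strand)
  gr$type <- "exon"
  gr$gene_id <- exons$gene_id
  gr$transcript_id <- exons$transcript_id
  junctions <- if (length(jx)) do.call(rbind, jx) else
    data.frame(contig = character(), donor = integer(), acceptor = integer(),
               strand = character(), gene_id = character(),
               transcript_id = character(), stringsAsFactors = FALSE)
  rownames(junctions) <- NULL
  list(exons = gr, junctions = junctions)
}

#' Simulate a toy gene annotation with planted unannotated junctions
#'
#' Generates a single synthetic contig carrying `n_genes` multi-exon genes
#' (alternating strands), a matching random genome with canonical GT..AG
#' intron boundaries, a syntactically valid GTF exon annotation, and a set of
#' planted "cryptic" junctions that reuse an annotated donor or acceptor but
#' pair it with a splice site guaranteed absent from the annotation.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Exons per gene (scalar, >= 2).
#' @param planted_cryptic Number of cryptic junctions to plant.
#' @param seed Integer seed.
#' @param dir Optional directory; `annotation.gtf` and `genome.fa` are written.
#' @return List with `genome` (`DNAStringSet`), `exons` (`GRanges`),
#'   `annotated_junctions`, `cryptic_junctions` (data.frames), and `paths`
#'   when files were written.
#' @export
simulate_annotation <- function(n_genes, exons_per_gene, planted_cryptic = 0,
                                seed = 1, dir = NULL) {
  stopifnot(n_genes >= 1L, exons_per_gene >= 2L)
  set.seed(as.integer(seed))
  contig <- "chrS"
  cursor <- 301L
  rows <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    strand <- if (g %% 2L == 1L) "+" else "-"
    ex_len <- sample(60:120, exons_per_gene, replace = TRUE)
    in_len <- sample(80:200, exons_per_gene - 1L, replace = TRUE)
    starts <- integer(exons_per_gene)
    ends <- integer(exons_per_gene)
    pos <- cursor
    for (e in seq_len(exons_per_gene)) {
      starts[e] <- pos
      ends[e] <- pos + ex_len[e] - 1L
      pos <- ends[e] + 1L + if (e < exons_per_gene) in_len[e] else 0L
    }
    rows[[g]] <- data.frame(
      contig = contig, start = starts, end = ends, strand = strand,
      gene_id = sprintf("G%03d", g), transcript_id = sprintf("T%03d", g),
      stringsAsFactors = FALSE)
    cursor <- pos + 300L
  }
  exons <- do.call(rbind, rows)
  ann <- annotation_from_exons(exons)
  genome_len <- max(exons$end) + 300L
  genome <- sample(c("A", "C", "G", "T"), genome_len, replace = TRUE)
  # canonical splice dinucleotides at every annotated intron boundary
  jx <- ann$junctions
  for (i in seq_len(nrow(jx))) {
    if (jx$strand[i] == "+") {
      genome[jx$donor[i] + 1:2] <- c("G", "T")
      genome[jx$acceptor[i] - 2:1] <- c("A", "G")
    } else {
      genome[jx$donor[i] - c(2L, 1L)] <- c("A", "C")  # revcomp of GT
      genome[jx$acceptor[i] + 1:2] <- c("C", "T")  # revcomp of AG
    }
  }
  genome_ss <- Biostrings::DNAStringSet(stats::setNames(
    paste(genome, collapse = ""), contig))
  # plant cryptic junctions: annotated donor paired with a novel acceptor (or
  # vice versa) strictly inside the intron, never coinciding with any
  # annotated boundary coordinate
  cryptic <- NULL
  if (planted_cryptic > 0) {
    if (!nrow(jx)) stop("cannot plant cryptic junctions without introns")
    pick <- sample.int(nrow(jx), planted_cryptic, replace = planted_cryptic > nrow(jx))
    crows <- vector("list", planted_cryptic)
    for (k in seq_along(pick)) {
      j <- jx[pick[k], ]
      novel_end <- if (k %% 2L == 0L) "donor" else "acceptor"
      lo <- min(j$donor, j$acceptor)
      hi <- max(j$donor, j$acceptor)
      repeat {
        cand <- sample((lo + 10L):(hi - 10L), 1L)
        if (!cand %in% c(jx$donor, jx$acceptor)) break
      }
      if (novel_end == "acceptor") {
        crows[[k]] <- data.frame(contig = j$contig, donor = j$donor,
                                 acceptor = cand, strand = j$strand,
                                 novel = "acceptor", stringsAsFactors = FALSE)
      } else {
        crows[[k]] <- data.frame(contig = j$contig, donor = cand,
                                 acceptor = j$acceptor, strand = j$strand,
                                 novel = "donor", stringsAsFactors = FALSE)
      }
    }
    cryptic <- do.call(rbind, crows)
    rownames(cryptic) <- NULL
  }
  out <- list(genome = genome_ss, exons = ann$exons,
              annotated_junctions = jx, cryptic_junctions = cryptic)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$paths <- c(
      gtf = write_gtf(ann$exons, file.path(dir, "annotation.gtf")),
      genome = write_fasta(genome_ss, file.path(dir, "genome.fa")))
  }
  out
}
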