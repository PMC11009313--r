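#' Percent spliced in (PSI) from junction counts
#'
#' PSI = mean(inclusion junction counts) / (mean(inclusion) + skipping).
#' With two inclusion junctions (e.g. a skipped exon) the mean of the two
#' junction counts enters the numerator.  Events with zero total supporting
#' counts are undefined (`NA`) and flagged, never reported as 0.
#'
#' @param event_counts data.frame with a `skipping` column and one or more
#'   columns whose names start with `inclusion`; one row per event-sample.
#' @return The input with `psi` and `psi_undefined` columns added.
#' @examples
#' compute_psi(data.frame(inclusion1 = 20, inclusion2 = 40, skipping = 10))$psi
#' @export
compute_psi <- function(event_counts) {
  inc_cols <- grep("^inclusion", names(event_counts), value = TRUE)
  if (!length(inc_cols)) stop("no inclusion count columns")
  if (is.null(event_counts$skipping)) stop("no skipping column")
  inc <- as.matrix(event_counts[, inc_cols, drop = FALSE])
  if (any(inc < 0) || any(event_counts$skipping < 0))
    stop("negative counts")
  inc_mean <- rowMeans(inc)
  denom <- inc_mean + event_counts$skipping
  event_counts$psi <- ifelse(denom > 0, inc_mean / denom, NA_real_)
  event_counts$psi_undefined <- denom == 0
  event_counts
}

#' Per-event PSI variance test and global variability comparison
#'
#' Per event, compares PSI variance between conditions with a variance-ratio
#' F test: `F = var(case) / var(control)` with `(n_case - 1, n_control - 1)`
#' degrees of freedom and a two-sided p-value.  Events with zero control
#' variance are flagged and excluded (their count is reported).  Globally,
#' the per-event PSI standard deviations of the two groups are compared with
#' an independent two-sample t test (Student by default, Welch by flag).
#'
#' @param psi_case,psi_control Numeric matrices (events x samples) of PSI
#'   values; rows are matched events.
#' @param welch Use Welch's t test for the global comparison.
#' @return List of class `psi_variability`: `per_event` (data.frame event,
#'   sd_case, sd_control, f_statistic, p, excluded), `global` (htest),
#'   `n_excluded`.
#' @export
psi_variability_test <- function(psi_case, psi_control, welch = FALSE) {
  psi_case <- as.matrix(psi_case)
  psi_control <- as.matrix(psi_control)
  if (nrow(psi_case) != nrow(psi_control)) stop("event rows must match")
  n1 <- ncol(psi_case)
  n2 <- ncol(psi_control)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 PSI values per group")
  v1 <- apply(psi_case, 1L, stats::var)
  v2 <- apply(psi_control, 1L, stats::var)
  excluded <- v2 == 0 | is.na(v1) | is.na(v2)
  f <- ifelse(excluded, NA_real_, v1 / v2)
  pf1 <- stats::pf(f, n1 - 1L, n2 - 1L)
  # with equal group sizes the F median is 1, so equal variances give p = 1
  p <- pmin(1, 2 * pmin(pf1, 1 - pf1))
  per_event <- data.frame(
    event = if (!is.null(rownames(psi_case))) rownames(psi_case)
            else as.character(seq_len(nrow(psi_case))),
    sd_case = sqrt(v1), sd_control = sqrt(v2),
    f_statistic = f, p = p, excluded = excluded,
    stringsAsFactors = FALSE)
  keep <- !excluded
  global <- if (sum(keep) >= 2L)
    stats::t.test(per_event$sd_case[keep], per_event$sd_control[keep],
                  var.equal = !welch)
  else NULL
  structure(list(per_event = per_event, global = global,
                 n_excluded = sum(excluded)),
            class = "psi_variability")
}

#' @export
print.psi_variability <- function(x, ...) {
  cat("PSI variability: ", nrow(x$per_event), " events (",
      x$n_excluded, " excluded for zero control variance)\n", sep = "")
  cat("  mean SD case ", signif(mean(x$per_event$sd_case, na.rm = TRUE), 4),
      " vs control ", signif(mean(x$per_event$sd_control, na.rm = TRUE), 4),
      "\n  global independent t test p = ",
      format(x$global$p.value, digits = 4), "\n", sep = "")
  invisible(x)
}

# binomial likelihood-ratio test of common vs group-specific inclusion
# proportion on pooled counts (df = 1)
binom_lrt <- function(inc1, tot1, inc2, tot2) {
  ll <- function(k, n) {
    if (n == 0L) return(0)
    p <- k / n
    if (p <= 0 || p >= 1) return(0)
    k * log(p) + (n - k) * log(1 - p)
  }
  lr <- 2 * (ll(inc1, tot1) + ll(inc2, tot2) - ll(inc1 + inc2, tot1 + tot2))
  stats::pchisq(max(lr, 0), df = 1L, lower.tail = FALSE)
}

#' Differential alternative splicing event selection
#'
#' Computes per-event inclusion-difference statistics between two conditions
#' and keeps events passing `p_adj < alpha` **and** `|delta PSI| >
#' min_delta`.  The per-event p-value is a binomial likelihood-ratio test of
#' a common versus group-specific inclusion proportion on the pooled
#' inclusion/skipping counts (df = 1), adjusted across events by
#' Benjamini-Hochberg.  `delta_psi` is the difference in mean per-sample PSI
#' (case minus control).
#'
#' @param counts data.frame with columns `event_id`, `sample`, `condition`,
#'   `inclusion`, `skipping`, and optionally `type` (as produced by
#'   [simulate_junction_counts()]).
#' @param case Condition treated as case; defaults to the first condition.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param min_delta Minimum absolute PSI difference (default 0.05, i.e. 5%).
#' @return List of class `ase_result`: `events` (per-event table with
#'   delta_psi, p, p_adj, significant), `significant` (the retained subset),
#'   `counts_by_type` (table of significant events per event type).
#' @export
differential_ase <- function(counts, case = NULL, alpha = 0.05,
                             min_delta = 0.05) {
  need <- c("event_id", "sample", "condition", "inclusion", "skipping")
  if (!all(need %in% names(counts))) stop("counts needs columns: ",
                                          paste(need, collapse = ", "))
  if (is.null(counts$type)) counts$type <- "SE"
  conds <- unique(counts$condition)
  if (length(conds) != 2L) stop("exactly two conditions required")
  if (is.null(case)) case <- conds[1L]
  ctrl <- setdiff(conds, case)
  counts <- compute_psi(counts)[, c(need, "type", "psi")]
  ev_ids <- unique(counts$event_id)
  rows <- lapply(ev_ids, function(ev) {
    e <- counts[counts$event_id == ev, ]
    e1 <- e[e$condition == case, ]
    e2 <- e[e$condition == ctrl, ]
    p <- binom_lrt(sum(e1$inclusion), sum(e1$inclusion) + sum(e1$skipping),
                   sum(e2$inclusion), sum(e2$inclusion) + sum(e2$skipping))
    data.frame(event_id = ev, type = e$type[1L],
               psi_case = mean(e1$psi, na.rm = TRUE),
               psi_control = mean(e2$psi, na.rm = TRUE),
               delta_psi = mean(e1$psi, na.rm = TRUE) -
                 mean(e2$psi, na.rm = TRUE),
               p = p, stringsAsFactors = FALSE)
  })
  events <- do.call(rbind, rows)
  events$p_adj <- stats::p.adjust(events$p, method = "BH")
  events$significant <- events$p_adj < alpha & abs(events$delta_psi) > min_delta
  significant <- events[events$significant, ]
  structure(list(events = events, significant = significant,
                 counts_by_type = table(factor(significant$type,
                                               levels = unique(events$type))),
                 alpha = alpha, min_delta = min_delta,
                 case = case, control = ctrl),
            class = "ase_result")
}

#' @export
print.ase_result <- function(x, ...) {
  cat("differential ASE selection (", x$case, " vs ", x$control,
      "): ", nrow(x$significant), " of ", nrow(x$events),
      " events at p_adj < ", x$alpha, " and |dPSI| > ", x$min_delta,
      "\n", sep = "")
  print(x$counts_by_type)
  invisible(x)
}

#' Classify junctions as annotated or cryptic
#'
#' A junction is cryptic when its donor **or** acceptor coordinate is absent
#' from the strand-aware annotated splice-site sets derived from the exon
#' annotation; an event is cryptic when any constituent junction is cryptic.
#' This is a pure set-membership classification: deterministic and
#' permutation invariant.
#'
#' @param junctions data.frame with columns `contig`, `donor`, `acceptor`
#'   (genomic 1-based terminal exonic coordinates), `strand`.
#' @param annotation Exon annotation as accepted by
#'   [extract_boundary_windows()], or a data.frame of annotated junctions
#'   with the same columns as `junctions`.
#' @return The input with logical columns `annotated_donor`,
#'   `annotated_acceptor`, and `cryptic` added.
#' @export
classify_cryptic <- function(junctions, annotation) {
  ann_jx <- if (is.data.frame(annotation)) annotation else
    junctions_from_exons(as_exon_granges(annotation))
  known_contigs <- unique(ann_jx$contig)
  bad <- setdiff(unique(junctions$contig), known_contigs)
  if (length(bad))
    stop("junction on unknown contig: ", paste(bad, collapse = ", "))
  dkey <- function(df, col) paste(df$contig, df$strand, df[[col]], sep = ":")
  junctions$annotated_donor <- dkey(junctions, "donor") %in% dkey(ann_jx, "donor")
  junctions$annotated_acceptor <-
    dkey(junctions, "acceptor") %in% dkey(ann_jx, "acceptor")
  junctions$cryptic <- !(junctions$annotated_donor & junctions$annotated_acceptor)
  junctions
}
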