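#' Counts-per-million normalization
#'
#' @param counts Numeric matrix (features x samples) or vector.
#' @param library_sizes Numeric vector of per-sample library sizes (> 0).
#' @param conditions Optional character vector (one per sample); when given,
#'   per-condition mean CPM columns are returned in `$condition_means`.
#' @return List with `cpm` (matrix, features x samples) and, when
#'   `conditions` is given, `condition_means`.
#' @examples
#' normalize_cpm(matrix(c(10, 30), 2, 1), 1e6)$cpm
#' @export
normalize_cpm <- function(counts, library_sizes, conditions = NULL) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = length(library_sizes))
  if (any(library_sizes <= 0)) stop("zero or negative library size")
  if (length(library_sizes) != ncol(counts))
    stop("one library size per sample column required")
  cpm <- sweep(counts, 2L, library_sizes, "/") * 1e6
  out <- list(cpm = cpm)
  if (!is.null(conditions)) {
    stopifnot(length(conditions) == ncol(counts))
    out$condition_means <- vapply(unique(conditions), function(g)
      rowMeans(cpm[, conditions == g, drop = FALSE]),
      numeric(nrow(cpm)))
    if (is.null(dim(out$condition_means)))
      out$condition_means <- matrix(out$condition_means, nrow = nrow(cpm),
                                    dimnames = list(rownames(cpm),
                                                    unique(conditions)))
  }
  out
}

#' Log2 fold change between conditions with pseudocount
#'
#' `log2fc = log2((cpm_case + c) / (cpm_control + c))`; the pseudocount `c`
#' keeps fold changes finite at zero counts and makes swapping case and
#' control negate every value exactly.  Features move in direction `"up"`
#' when `log2fc > lfc_cutoff`, `"down"` when `log2fc < -lfc_cutoff`, else
#' `"unchanged"` (default cutoff 1, i.e. a two-fold change).
#'
#' @param cpm_case,cpm_control Non-negative per-feature CPM values.
#' @param feature Optional feature ids.
#' @param pseudocount Pseudocount added to both CPMs (default 0.5).
#' @param lfc_cutoff Absolute log2FC threshold for calling direction.
#' @return data.frame of class `differential_sites`: `feature`, `cpm_case`,
#'   `cpm_control`, `log2fc`, `direction`.
#' @examples
#' log2_fold_change(40, 10)   # log2(40.5/10.5) ~ 1.9475, up
#' @export
log2_fold_change <- function(cpm_case, cpm_control, feature = NULL,
                             pseudocount = 0.5, lfc_cutoff = 1) {
  if (any(cpm_case < 0) || any(cpm_control < 0)) stop("CPMs must be >= 0")
  if (is.null(feature)) feature <- as.character(seq_along(cpm_case))
  # difference of logs rather than log of a ratio: exact antisymmetry in
  # floating point when case and control are swapped
  lfc <- log2(cpm_case + pseudocount) - log2(cpm_control + pseudocount)
  out <- data.frame(
    feature = feature, cpm_case = cpm_case, cpm_control = cpm_control,
    log2fc = lfc,
    direction = ifelse(lfc > lfc_cutoff, "up",
                       ifelse(lfc < -lfc_cutoff, "down", "unchanged")),
    stringsAsFactors = FALSE)
  class(out) <- c("differential_sites", "data.frame")
  out
}

#' Fisher excess kurtosis of a fold-change distribution
#'
#' Population-moment estimator `m4 / m2^2 - 3` (no small-sample bias
#' correction by default, since the intended inputs are thousands of fold
#' changes), with a percentile bootstrap 95% confidence interval.  The
#' theoretical minimum is -2, attained by a symmetric two-point distribution;
#' a normal distribution has excess kurtosis 0; flatter distributions with
#' more mass in the shoulders score below 0.
#'
#' @param values Numeric vector, length >= 4, non-constant.
#' @param label Optional label (e.g. tissue) carried into the result.
#' @param n_boot Bootstrap replicates for the CI (default 1000; 0 disables).
#' @param seed Seed for the bootstrap resampling.
#' @param bias_correct Use the standard small-sample unbiased-under-normality
#'   estimator instead of raw population moments.
#' @return List of class `fc_summary`: `label`, `n`, `excess_kurtosis`,
#'   `bootstrap_ci` (95%), `seed`.
#' @examples
#' excess_kurtosis(c(-1, -1, 1, 1), n_boot = 0)$excess_kurtosis  # -2
#' @export
excess_kurtosis <- function(values, label = NA_character_, n_boot = 1000L,
                            seed = 1L, bias_correct = FALSE) {
  n <- length(values)
  if (n < 4L) stop("need at least 4 values")
  if (stats::var(values) == 0) stop("zero variance")
  est <- function(x) {
    m <- mean(x)
    m2 <- mean((x - m)^2)
    m4 <- mean((x - m)^4)
    g2 <- m4 / m2^2 - 3
    if (bias_correct) {
      k <- length(x)
      g2 <- ((k + 1) * g2 + 6) * (k - 1) / ((k - 2) * (k - 3))
    }
    g2
  }
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(i)
      est(values[sample.int(n, n, replace = TRUE)]), numeric(1))
    ci <- unname(stats::quantile(boot, c(0.025, 0.975)))
  }
  structure(list(label = label, n = n, excess_kurtosis = est(values),
                 bootstrap_ci = ci, seed = seed),
            class = "fc_summary")
}

#' @export
print.fc_summary <- function(x, ...) {
  cat("excess kurtosis", if (!is.na(x$label)) paste0(" (", x$label, ")"),
      ": ", signif(x$excess_kurtosis, 4), " (n = ", x$n, sep = "")
  if (!is.na(x$bootstrap_ci[1L]))
    cat(", 95% bootstrap CI ", signif(x$bootstrap_ci[1L], 4), " to ",
        signif(x$bootstrap_ci[2L], 4), sep = "")
  cat(")\n")
  invisible(x)
}

#' Permutation test for a windowed region's binding difference
#'
#' Tests whether the proportion of a reference's crosslink tags falling in a
#' window differs between conditions.  The observed statistic is the
#' difference in mean per-sample window proportions (case minus control).
#' The null distribution permutes tag-to-sample assignment: tags from all
#' samples are pooled and re-dealt to samples keeping each sample's total tag
#' count, which for the window statistic is equivalent to drawing each
#' sample's in-window count from a multivariate hypergeometric distribution.
#' Tag-level permutation gives the test fine p-value resolution even with
#' few samples per group.  The p-value is two-sided by absolute value and
#' uses the add-one convention `(1 + #{|perm| >= |obs|}) / (1 + n_perm)`.
#'
#' @param profiles_case,profiles_control Lists of `nt_profile` objects (one
#'   per sample) from [build_profile()], all for the same reference.
#' @param window 1-based inclusive `c(start, end)` window.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param evidence Evidence class (default truncation).
#' @return List of class `region_test`: `observed` (mean proportion
#'   difference), `p_value`, `window`, `n_perm`, `seed`, and the per-sample
#'   proportions.
#' @export
region_difference_test <- function(profiles_case, profiles_control, window,
                                   n_perm = 1000L, seed = 1L,
                                   evidence = c("truncation", "deletion")) {
  evidence <- match.arg(evidence)
  if (length(profiles_case) < 2L || length(profiles_control) < 2L)
    stop("need at least 2 samples per condition")
  rp_case <- region_proportion(profiles_case, window, evidence)
  rp_ctrl <- region_proportion(profiles_control, window, evidence)
  if (any(rp_case$undefined) || any(rp_ctrl$undefined))
    stop("empty profile: region proportion undefined for some sample")
  obs <- mean(rp_case$proportion) - mean(rp_ctrl$proportion)
  w <- c(rp_case$window_tags, rp_ctrl$window_tags)
  tot <- c(rp_case$total_tags, rp_ctrl$total_tags)
  n_case <- nrow(rp_case)
  n_all <- length(tot)
  K <- sum(w)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    rem_k <- K
    rem_n <- sum(tot)
    wp <- numeric(n_all)
    for (j in seq_len(n_all - 1L)) {
      wp[j] <- stats::rhyper(1L, rem_k, rem_n - rem_k, tot[j])
      rem_k <- rem_k - wp[j]
      rem_n <- rem_n - tot[j]
    }
    wp[n_all] <- rem_k
    prop <- wp / tot
    perm[b] <- mean(prop[seq_len(n_case)]) - mean(prop[-seq_len(n_case)])
  }
  p <- (1 + sum(abs(perm) >= abs(obs))) / (1 + n_perm)
  structure(list(observed = obs, p_value = p, window = window,
                 n_perm = n_perm, seed = seed,
                 proportions_case = rp_case$proportion,
                 proportions_control = rp_ctrl$proportion),
            class = "region_test")
}

#' @export
print.region_test <- function(x, ...) {
  cat("region difference test, window [", x$window[1L], ", ", x$window[2L],
      "]\n  observed mean proportion difference: ", signif(x$observed, 4),
      "\n  permutation p (", x$n_perm, " permutations): ",
      signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}
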