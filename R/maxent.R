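#' Maximum-entropy splice-site strength models
#'
#' [fit_maxent()] fits the maximum-entropy distribution over fixed-length
#' splice-site windows subject to empirical marginal constraints from a
#' training (signal) set, together with a background model (a maxent fit to a
#' decoy set, or uniform).  [maxent_score()] then scores any window as
#' `log2(p_signal / p_background)` — the "maxent score" used to stratify
#' donor sites as weak (< 3), intermediate (3--8) or strong (> 8).
#'
#' For enumerable windows (length <= 10) the fit is computed by iterative
#' proportional fitting (IPF) over the full 4^L space; for acceptor-length
#' windows (23-mers) the adjacent-pairwise constraint set is decomposable and
#' the model is represented exactly as a first-order Markov chain.
#'
#' @name maxent
NULL

BASES <- c("A", "C", "G", "T")

# sequences -> integer matrix (n x L) in 1..4, with informative errors
seqs_to_ints <- function(seqs, window_length = NULL) {
  if (methods::is(seqs, "DNAStringSet") || methods::is(seqs, "DNAString"))
    seqs <- as.character(seqs)
  seqs <- chartr("u", "t", toupper(seqs))
  if (!length(seqs)) stop("empty training set")
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("sequences have differing lengths: ", paste(L, collapse = ", "))
  if (!is.null(window_length) && L != window_length)
    stop("sequence length ", L, " does not match window length ", window_length)
  m <- matrix(match(unlist(strsplit(seqs, "")), BASES), ncol = L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("non-ACGT character in sequence ", bad[1L], " at position ", bad[2L])
  }
  m
}

default_constraints <- function(L) {
  c(lapply(seq_len(L), identity),
    lapply(seq_len(L - 1L), function(i) c(i, i + 1L)))
}

# smoothed empirical marginal for a constraint subset.  The per-cell
# pseudocount is scaled so that lower-order constraints are consistent with
# the margins implied by the highest-order smoothed tables (a pair table with
# pseudocount c implies single margins with pseudocount 4c), which makes the
# constraint system exactly satisfiable.
constraint_target <- function(ints, cs, pseudocount, kmax) {
  k <- length(cs)
  pc <- pseudocount * 4^(kmax - k)
  idx <- rep(1L, nrow(ints))
  for (j in seq_along(cs)) idx <- idx + (ints[, cs[j]] - 1L) * 4L^(j - 1L)
  counts <- tabulate(idx, nbins = 4L^k) + pc
  counts / sum(counts)
}

# IPF over the enumerated 4^L space
fit_ipf <- function(ints, constraints, pseudocount, tol = 1e-6,
                    max_sweeps = 500L) {
  L <- ncol(ints)
  kmax <- max(lengths(constraints))
  ncell <- 4L^L
  digits <- matrix(0L, ncell, L)
  v <- 0:(ncell - 1L)
  for (j in seq_len(L)) digits[, j] <- (v %/% 4L^(j - 1L)) %% 4L
  midx <- lapply(constraints, function(cs) {
    idx <- rep(1L, ncell)
    for (j in seq_along(cs)) idx <- idx + digits[, cs[j]] * 4L^(j - 1L)
    idx
  })
  targets <- lapply(constraints, constraint_target,
                    ints = ints, pseudocount = pseudocount, kmax = kmax)
  p <- rep(1 / ncell, ncell)
  converged <- FALSE
  sweeps <- 0L
  repeat {
    for (k in seq_along(constraints)) {
      cur <- as.vector(rowsum(p, midx[[k]]))
      p <- p * (targets[[k]] / cur)[midx[[k]]]
    }
    sweeps <- sweeps + 1L
    dev <- max(vapply(seq_along(constraints), function(k)
      max(abs(as.vector(rowsum(p, midx[[k]])) - targets[[k]])), 0))
    if (dev < tol) { converged <- TRUE; break }
    if (sweeps >= max_sweeps) break
  }
  list(method = "ipf", log_p = log(p), constraints = constraints,
       targets = targets, converged = converged, sweeps = sweeps,
       max_marginal_deviation = dev, L = L)
}

# exact Markov-chain representation for the adjacent-pairwise constraint set
fit_chain <- function(ints, pseudocount) {
  L <- ncol(ints)
  n <- nrow(ints)
  pairs <- lapply(seq_len(L - 1L), function(i) {
    counts <- matrix(tabulate(ints[, i] + (ints[, i + 1L] - 1L) * 4L,
                              nbins = 16L) + pseudocount, 4L, 4L)
    counts / sum(counts)
  })
  singles <- lapply(seq_len(L), function(i)
    (tabulate(ints[, i], nbins = 4L) + 4 * pseudocount) / (n + 16 * pseudocount))
  list(method = "chain", pairs = pairs, singles = singles,
       constraints = default_constraints(L),
       converged = TRUE, sweeps = 0L, max_marginal_deviation = 0, L = L)
}

fit_component <- function(seqs, constraints, window_length, pseudocount,
                          tol, max_sweeps) {
  ints <- seqs_to_ints(seqs, window_length)
  L <- ncol(ints)
  if (is.null(constraints)) constraints <- default_constraints(L)
  if (L <= 10L) {
    fit_ipf(ints, constraints, pseudocount, tol, max_sweeps)
  } else {
    if (!identical(lapply(constraints, as.integer),
                   lapply(default_constraints(L), as.integer)))
      stop("windows longer than 10 nt support only the default ",
           "single-position + adjacent-pair constraint set (chain model)")
    fit_chain(ints, pseudocount)
  }
}

component_logprob <- function(fit, ints) {
  if (fit$method == "uniform") return(rep(-ncol(ints) * log(4), nrow(ints)))
  if (fit$method == "ipf") {
    idx <- rep(1L, nrow(ints))
    for (j in seq_len(fit$L)) idx <- idx + (ints[, j] - 1L) * 4L^(j - 1L)
    return(fit$log_p[idx])
  }
  # chain
  lp <- log(fit$pairs[[1L]])[cbind(ints[, 1L], ints[, 2L])]
  for (i in 2:(fit$L - 1L)) {
    lp <- lp + log(fit$pairs[[i]])[cbind(ints[, i], ints[, i + 1L])] -
      log(fit$singles[[i]])[ints[, i]]
  }
  lp
}

component_entropy <- function(fit) {
  if (fit$method == "uniform") return(2 * fit$L)
  if (fit$method == "ipf") {
    p <- exp(fit$log_p)
    keep <- p > 0
    return(-sum(p[keep] * fit$log_p[keep]) / log(2))
  }
  # chain: H(X1,X2) + sum_i H(X_{i+1} | X_i)
  h2 <- function(m) -sum(m[m > 0] * log2(m[m > 0]))
  h1 <- function(v) -sum(v[v > 0] * log2(v[v > 0]))
  h <- h2(fit$pairs[[1L]])
  for (i in 2:(fit$L - 1L))
    h <- h + h2(fit$pairs[[i]]) - h1(fit$singles[[i]])
  h
}

#' Fit a maximum-entropy splice-site model
#'
#' @param signal_seqs Training splice-site windows (character vector or
#'   `DNAStringSet`), all of one length over A/C/G/T.
#' @param background Either `"uniform"`, or a set of decoy sequences of the
#'   same length to which a maxent model is fitted as background.
#' @param constraints List of integer position subsets whose joint marginals
#'   are constrained; default: all single positions plus all adjacent pairs.
#' @param window_length Expected window length (9 = donor, 23 = acceptor);
#'   inferred from the sequences when `NULL`.
#' @param side `"donor"` or `"acceptor"`; inferred from the window length
#'   when `NULL` (9 -> donor, 23 -> acceptor).
#' @param pseudocount Laplace pseudocount per marginal cell (default 0.5) so
#'   unseen k-mers keep finite scores.
#' @param weak,strong Score thresholds for the weak/intermediate/strong
#'   classification (defaults 3 and 8).
#' @param tol IPF convergence tolerance: maximum absolute deviation of any
#'   constrained marginal (default 1e-6).
#' @param max_sweeps Maximum IPF sweeps (default 500).
#' @return An object of class `maxent_model` with components `signal` and
#'   `background` (each the fitted distribution), the constraint set, the
#'   thresholds, and convergence diagnostics.
#' @examples
#' sets <- simulate_splice_site_sets(rep(1, 9), 200, 200, seed = 1)
#' m <- fit_maxent(sets$signal, background = sets$decoy)
#' maxent_score(m, c("CAGGTAAGT", "ACGTACGTA"))
#' @export
fit_maxent <- function(signal_seqs, background = "uniform", constraints = NULL,
                       window_length = NULL, side = NULL, pseudocount = 0.5,
                       weak = 3, strong = 8, tol = 1e-6, max_sweeps = 500L) {
  sig <- fit_component(signal_seqs, constraints, window_length, pseudocount,
                       tol, max_sweeps)
  bg <- if (identical(background, "uniform")) {
    list(method = "uniform", L = sig$L, converged = TRUE,
         max_marginal_deviation = 0)
  } else {
    fit_component(background, constraints, sig$L, pseudocount, tol, max_sweeps)
  }
  if (is.null(side))
    side <- if (sig$L == 23L) "acceptor" else "donor"
  structure(list(
    window_length = sig$L, side = side, signal = sig, background = bg,
    pseudocount = pseudocount, thresholds = c(weak = weak, strong = strong),
    n_train = length(signal_seqs),
    note = paste("constraint set: single-position + adjacent-pair marginals;",
                 "not the full MaxEntScan fragment decomposition")
  ), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat("maxent_model: ", x$side, " window of ", x$window_length, " nt, ",
      x$n_train, " training sequences\n", sep = "")
  cat("  signal fit: ", x$signal$method,
      if (x$signal$method == "ipf")
        paste0(" (", x$signal$sweeps, " sweeps, max marginal deviation ",
               signif(x$signal$max_marginal_deviation, 3), ")"),
      "\n", sep = "")
  cat("  background: ", x$background$method, "\n", sep = "")
  cat("  thresholds: weak < ", x$thresholds[["weak"]], ", strong > ",
      x$thresholds[["strong"]], "\n", sep = "")
  invisible(x)
}

#' @export
summary.maxent_model <- function(object, ...) {
  out <- list(
    window_length = object$window_length, side = object$side,
    n_train = object$n_train,
    signal_entropy_bits = component_entropy(object$signal),
    background_entropy_bits = component_entropy(object$background),
    max_marginal_deviation = object$signal$max_marginal_deviation,
    converged = object$signal$converged,
    thresholds = object$thresholds)
  class(out) <- "summary.maxent_model"
  out
}

#' @export
print.summary.maxent_model <- function(x, ...) {
  cat("maxent_model summary\n")
  cat("  ", x$side, " ", x$window_length, "-mer, n_train ", x$n_train, "\n",
      sep = "")
  cat("  signal entropy ", round(x$signal_entropy_bits, 3), " bits (uniform ",
      2 * x$window_length, ")\n", sep = "")
  cat("  converged: ", x$converged, " (max marginal deviation ",
      signif(x$max_marginal_deviation, 3), ")\n", sep = "")
  invisible(x)
}

#' Score splice-site windows with a fitted maxent model
#'
#' The score of a window is `log2(p_signal / p_background)`; swapping the
#' signal and background components negates every score.
#'
#' @param model A [fit_maxent()] model.
#' @param sequences Character vector or `DNAStringSet` of windows matching
#'   the model's window length.
#' @return data.frame with columns `sequence`, `side`, `score`, `category`.
#' @export
maxent_score <- function(model, sequences) {
  stopifnot(inherits(model, "maxent_model"))
  ints <- seqs_to_ints(sequences, model$window_length)
  score <- (component_logprob(model$signal, ints) -
              component_logprob(model$background, ints)) / log(2)
  data.frame(
    sequence = if (methods::is(sequences, "DNAStringSet"))
      as.character(sequences) else toupper(sequences),
    side = model$side, score = score,
    category = classify_splice_site(score, model$side,
                                    weak = model$thresholds[["weak"]],
                                    strong = model$thresholds[["strong"]]),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
#' @rdname maxent_score
#' @param object,newdata,... `predict` method arguments (`newdata` as in
#'   `sequences`).
predict.maxent_model <- function(object, newdata, ...) {
  maxent_score(object, newdata)
}

#' Classify splice-site strength from a maxent score
#'
#' Weak if score < `weak`, strong if score > `strong`, otherwise intermediate
#' (the boundary values themselves are intermediate).
#'
#' @param score Numeric vector of finite maxent scores.
#' @param side `"donor"` or `"acceptor"` (recorded, thresholds may differ by
#'   side in the caller).
#' @param weak,strong Thresholds (defaults 3 and 8).
#' @return Character vector in `c("weak", "intermediate", "strong")`.
#' @examples
#' classify_splice_site(c(2, 3, 8, 9), "donor")
#' @export
classify_splice_site <- function(score, side = c("donor", "acceptor"),
                                 weak = 3, strong = 8) {
  side <- match.arg(side)
  if (any(!is.finite(score))) stop("non-finite score")
  ifelse(score < weak, "weak", ifelse(score > strong, "strong", "intermediate"))
}

#' Histogram summary and modality diagnostic for a score distribution
#'
#' Returns a kernel-smoothed density of the scores together with its local
#' maxima and minima, used to diagnose biphasic (bimodal) score
#' distributions.
#'
#' @param scores Numeric vector (length >= 10).
#' @param bw,adjust Bandwidth arguments passed to [stats::density()].
#' @param breaks Passed to [graphics::hist()] machinery via
#'   [base::pretty()]; binned counts are returned alongside the density.
#' @return List of class `score_density` with `density` (data.frame x, y),
#'   `maxima`, `minima` (score coordinates), and `histogram` (data.frame
#'   mid, count).
#' @export
score_distribution <- function(scores, bw = "nrd0", adjust = 1, breaks = 30) {
  scores <- sort(scores)
  if (length(scores) < 10L) stop("need at least 10 scores")
  if (max(scores) - min(scores) < .Machine$double.eps^0.5) {
    out <- list(density = data.frame(x = scores[1L], y = Inf),
                maxima = scores[1L], minima = numeric(0),
                histogram = data.frame(mid = scores[1L],
                                       count = length(scores)))
    class(out) <- "score_density"
    return(out)
  }
  d <- stats::density(scores, bw = bw, adjust = adjust)
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  is_min <- c(FALSE, y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n], FALSE)
  br <- pretty(range(scores), n = breaks)
  h <- graphics::hist(scores, breaks = br, plot = FALSE)
  out <- list(density = data.frame(x = d$x, y = d$y),
              maxima = d$x[is_max], minima = d$x[is_min],
              histogram = data.frame(mid = h$mids, count = h$counts))
  class(out) <- "score_density"
  out
}

#' @export
print.score_density <- function(x, ...) {
  cat("score distribution: ", length(x$maxima), " local maxima at ",
      paste(signif(x$maxima, 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
plot.score_density <- function(x, ...) {
  plot(x$density$x, x$density$y, type = "l", xlab = "maxent score",
       ylab = "density", ...)
  graphics::abline(v = x$maxima, lty = 2)
  invisible(x)
}

#' Serialize a maxent model to a portable JSON text file
#'
#' The file stores the constraint targets and configuration; [read_maxent()]
#' reconstructs the fitted distribution by re-running the deterministic fit,
#' so the round trip is exact to fitting tolerance.
#'
#' @param model A `maxent_model`.
#' @param path Output path.
#' @export
write_maxent <- function(model, path) {
  comp_json <- function(fit) {
    if (fit$method == "uniform") return(list(method = "uniform"))
    if (fit$method == "chain") {
      return(list(method = "chain",
                  pairs = lapply(fit$pairs, function(m) as.vector(m)),
                  singles = fit$singles))
    }
    list(method = "ipf",
         constraints = lapply(fit$constraints, as.integer),
         targets = fit$targets)
  }
  obj <- list(format = "clipsplice_maxent", version = 1L,
              window_length = model$window_length, side = model$side,
              pseudocount = model$pseudocount,
              thresholds = as.list(model$thresholds),
              n_train = model$n_train,
              signal = comp_json(model$signal),
              background = comp_json(model$background))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_maxent
#' @export
read_maxent <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "clipsplice_maxent"))
    stop("not a clipsplice maxent model file: ", path)
  rebuild <- function(comp, L) {
    if (identical(comp$method, "uniform"))
      return(list(method = "uniform", L = L, converged = TRUE,
                  max_marginal_deviation = 0))
    if (identical(comp$method, "chain")) {
      # jsonlite may simplify equal-length vectors into a row-major matrix
      rows_as_list <- function(x) {
        if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) x[i, ])
        else lapply(x, unlist)
      }
      return(list(method = "chain",
                  pairs = lapply(rows_as_list(comp$pairs),
                                 function(v) matrix(v, 4L, 4L)),
                  singles = rows_as_list(comp$singles),
                  constraints = default_constraints(L),
                  converged = TRUE, sweeps = 0L,
                  max_marginal_deviation = 0, L = L))
    }
    constraints <- if (is.matrix(comp$constraints))
      lapply(seq_len(nrow(comp$constraints)),
             function(i) as.integer(comp$constraints[i, ]))
    else lapply(comp$constraints, as.integer)
    targets <- if (is.matrix(comp$targets))
      lapply(seq_len(nrow(comp$targets)), function(i) comp$targets[i, ])
    else lapply(comp$targets, unlist)
    ipf_from_targets(constraints, targets, L)
  }
  L <- as.integer(obj$window_length)
  model <- list(window_length = L, side = obj$side,
                signal = rebuild(obj$signal, L),
                background = rebuild(obj$background, L),
                pseudocount = obj$pseudocount,
                thresholds = unlist(obj$thresholds),
                n_train = obj$n_train,
                note = "restored from serialized constraint targets")
  class(model) <- "maxent_model"
  model
}

# IPF when targets (not raw sequences) are given, e.g. on deserialization
ipf_from_targets <- function(constraints, targets, L, tol = 1e-6,
                             max_sweeps = 500L) {
  ncell <- 4L^L
  digits <- matrix(0L, ncell, L)
  v <- 0:(ncell - 1L)
  for (j in seq_len(L)) digits[, j] <- (v %/% 4L^(j - 1L)) %% 4L
  midx <- lapply(constraints, function(cs) {
    idx <- rep(1L, ncell)
    for (j in seq_along(cs)) idx <- idx + digits[, cs[j]] * 4L^(j - 1L)
    idx
  })
  p <- rep(1 / ncell, ncell)
  converged <- FALSE
  sweeps <- 0L
  repeat {
    for (k in seq_along(constraints)) {
      cur <- as.vector(rowsum(p, midx[[k]]))
      p <- p * (unlist(targets[[k]]) / cur)[midx[[k]]]
    }
    sweeps <- sweeps + 1L
    dev <- max(vapply(seq_along(constraints), function(k)
      max(abs(as.vector(rowsum(p, midx[[k]])) - unlist(targets[[k]]))), 0))
    if (dev < tol) { converged <- TRUE; break }
    if (sweeps >= max_sweeps) break
  }
  list(method = "ipf", log_p = log(p), constraints = constraints,
       targets = targets, converged = converged, sweeps = sweeps,
       max_marginal_deviation = dev, L = L)
}
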