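test_that("single-position constraints give the product of marginals", {
  # all 16 dinucleotides once -> uniform, each probability 1/16
  dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0))
  m <- fit_maxent(dinucs, constraints = list(1L, 2L))
  p <- exp(m$signal$log_p)
  expect_equal(unname(p), rep(1 / 16, 16), tolerance = 1e-12)
  # a skewed training set: fitted distribution = outer product of marginals
  set.seed(1)
  seqs <- simulate_splice_site_sets(c(1.5, 0.2, 0.9, 2, 0.1, 1, 0.5, 0.3, 0.7),
                                    200, 1, seed = 6)$signal
  m2 <- fit_maxent(seqs, constraints = as.list(1:9))
  marg <- lapply(1:9, function(j) dist_marginal(exp(m2$signal$log_p), j, 9))
  prod_p <- Reduce(function(a, b) as.vector(outer(a, b)), marg)
  expect_equal(exp(m2$signal$log_p), prod_p, tolerance = 1e-9)
})

test_that("IPF matches the direct convex-optimization maxent oracle", {
  # tiny instance over {A,C}, length 3, adjacent-pairwise constraints
  set.seed(42)
  seqs <- apply(matrix(sample(c("A", "C"), 60, replace = TRUE), 20), 1,
                paste, collapse = "")
  constraints <- list(1L, 2L, 3L, c(1L, 2L), c(2L, 3L))
  m <- fit_maxent(seqs, constraints = constraints)
  targets <- oracle_targets(seqs, constraints)
  q <- oracle_maxent(targets, constraints, 3)
  p <- exp(m$signal$log_p)
  expect_lt(kl_div(p, q), 1e-8)
  expect_lt(kl_div(q, p), 1e-8)
})

test_that("fitted distribution satisfies every constrained marginal", {
  sets <- simulate_splice_site_sets(c(0.5, 0.5, 1, 2, 2, 1, 0.8, 0.5, 0.3),
                                    300, 1, seed = 12)
  m <- fit_maxent(sets$signal)
  expect_true(m$signal$converged)
  p <- exp(m$signal$log_p)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  targets <- oracle_targets(as.character(sets$signal), m$signal$constraints)
  devs <- vapply(seq_along(targets), function(k)
    max(abs(dist_marginal(p, m$signal$constraints[[k]], 9) - targets[[k]])),
    numeric(1))
  expect_lt(max(devs), 1e-6)
})

test_that("maxent optimality: constraint-preserving perturbations lower entropy", {
  set.seed(7)
  seqs <- apply(matrix(sample(c("A", "C", "G", "T"), 90, replace = TRUE), 30),
                1, paste, collapse = "")
  constraints <- list(1L, 2L, 3L, c(1L, 2L), c(2L, 3L))
  m <- fit_maxent(seqs, constraints = constraints)
  p <- exp(m$signal$log_p)
  H <- function(x) -sum(x[x > 0] * log(x[x > 0]))
  A <- oracle_feature_matrix(constraints, 3)
  # null space of the constraint matrix (plus total mass) spans the feasible
  # directions; any perturbation along it keeps all constrained marginals
  basis <- MASS::Null(cbind(A, 1))
  expect_gt(ncol(basis), 0)
  set.seed(8)
  for (i in 1:5) {
    dir <- basis %*% rnorm(ncol(basis))
    eps <- 0.5 * min(p) / max(abs(dir))
    q <- p + eps * as.vector(dir)
    expect_equal(max(abs(as.vector(crossprod(A, q)) -
                           as.vector(crossprod(A, p)))), 0, tolerance = 1e-12)
    expect_lt(H(q), H(p))
  }
})

test_that("scores are log2 likelihood ratios with exact antisymmetry", {
  # handcrafted single-position model: p_signal(A) = 0.5, background 0.25
  fit <- list(method = "ipf", log_p = log(c(0.5, 0.25, 0.125, 0.125)),
              constraints = list(1L), targets = list(), converged = TRUE,
              sweeps = 1L, max_marginal_deviation = 0, L = 1L)
  bg <- list(method = "uniform", L = 1L, converged = TRUE,
             max_marginal_deviation = 0)
  model <- structure(list(window_length = 1L, side = "donor", signal = fit,
                          background = bg, pseudocount = 0.5,
                          thresholds = c(weak = 3, strong = 8), n_train = 0L),
                     class = "maxent_model")
  expect_equal(maxent_score(model, "A")$score, 1)
  expect_equal(maxent_score(model, "C")$score, 0)
  # identical signal and background -> score 0 everywhere
  sets <- simulate_splice_site_sets(rep(0.8, 9), 100, 100, seed = 21)
  m_same <- fit_maxent(sets$signal, background = sets$signal)
  expect_equal(maxent_score(m_same, sets$decoy)$score, rep(0, 100),
               tolerance = 1e-10)
  # swapping signal and background negates every score
  m_fwd <- fit_maxent(sets$signal, background = sets$decoy)
  m_rev <- fit_maxent(sets$decoy, background = sets$signal)
  probe <- simulate_splice_site_sets(rep(0.8, 9), 50, 1, seed = 22)$signal
  expect_equal(maxent_score(m_fwd, probe)$score,
               -maxent_score(m_rev, probe)$score, tolerance = 1e-9)
})

test_that("acceptor chain model scores match brute-force chain probabilities", {
  sets <- simulate_splice_site_sets(rep(0.6, 23), 200, 200, seed = 30)
  m <- fit_maxent(sets$signal, background = "uniform")
  expect_equal(m$side, "acceptor")
  expect_equal(m$signal$method, "chain")
  # independent recomputation of one sequence's chain log-probability
  s <- as.character(sets$signal[[1]])
  ints <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  lp <- log(m$signal$pairs[[1]][ints[1], ints[2]])
  for (i in 2:22)
    lp <- lp + log(m$signal$pairs[[i]][ints[i], ints[i + 1]]) -
      log(m$signal$singles[[i]][ints[i]])
  expect_equal(maxent_score(m, s)$score, (lp - (-23 * log(4))) / log(2),
               tolerance = 1e-10)
  # chain marginals reproduce the smoothed pair tables exactly by construction
  expect_equal(m$signal$max_marginal_deviation, 0)
})

test_that("batch FASTA scoring equals elementwise scoring", {
  sets <- simulate_splice_site_sets(rep(1, 9), 40, 1, seed = 13)
  m <- fit_maxent(sets$signal)
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(sets$signal, path)
  batch <- maxent_score(m, read_fasta(path))
  single <- vapply(as.character(sets$signal), function(s)
    maxent_score(m, s)$score, numeric(1))
  expect_equal(batch$score, unname(single))
})

test_that("classification uses strict thresholds with intermediate boundaries", {
  expect_equal(classify_splice_site(c(2, 3, 8, 9), "donor"),
               c("weak", "intermediate", "intermediate", "strong"))
  expect_equal(classify_splice_site(-5, "acceptor"), "weak")
  expect_error(classify_splice_site(NaN, "donor"), "non-finite")
  expect_error(classify_splice_site(Inf, "donor"), "non-finite")
  # custom thresholds propagate through scoring
  sets <- simulate_splice_site_sets(rep(1, 9), 50, 50, seed = 14)
  m <- fit_maxent(sets$signal, background = sets$decoy, weak = -1, strong = 1)
  sc <- maxent_score(m, sets$signal)
  expect_equal(sc$category,
               classify_splice_site(sc$score, "donor", weak = -1, strong = 1))
})

test_that("raising training information content does not lower consensus scores", {
  cons <- "CAGGTAAGT"
  score_at <- function(bits) {
    sets <- simulate_splice_site_sets(rep(bits, 9), 400, 1, seed = 15,
                                      consensus = cons)
    m <- fit_maxent(sets$signal, background = "uniform")
    maxent_score(m, cons)$score
  }
  s <- vapply(c(0.3, 0.8, 1.4, 1.9), score_at, numeric(1))
  expect_true(all(diff(s) >= 0))
})

test_that("score distribution reports modality and is order invariant", {
  set.seed(31)
  mix <- c(rnorm(300, 0), rnorm(300, 10))
  d <- score_distribution(mix)
  expect_equal(length(d$maxima), 2L)
  expect_equal(length(d$minima), 1L)
  d_perm <- score_distribution(sample(mix))
  expect_identical(d, d_perm)
  expect_equal(length(score_distribution(rep(1.5, 20))$maxima), 1L)
  expect_error(score_distribution(rnorm(9)), "at least 10")
})

test_that("model serialization round-trips scores", {
  sets <- simulate_splice_site_sets(c(0.5, 0.5, 1, 2, 2, 1, 0.8, 0.5, 0.3),
                                    150, 150, seed = 16)
  m <- fit_maxent(sets$signal, background = sets$decoy)
  path <- withr::local_tempfile(fileext = ".json")
  write_maxent(m, path)
  m2 <- read_maxent(path)
  probe <- sets$signal[1:20]
  expect_equal(maxent_score(m2, probe)$score, maxent_score(m, probe)$score,
               tolerance = 1e-6)
  # acceptor (chain) model round trip
  setsA <- simulate_splice_site_sets(rep(0.7, 23), 100, 1, seed = 17)
  mA <- fit_maxent(setsA$signal)
  pathA <- withr::local_tempfile(fileext = ".json")
  write_maxent(mA, pathA)
  expect_equal(maxent_score(read_maxent(pathA), setsA$signal[1:10])$score,
               maxent_score(mA, setsA$signal[1:10])$score, tolerance = 1e-10)
})

test_that("invalid training input raises informative errors", {
  expect_error(fit_maxent(character(0)), "empty")
  expect_error(fit_maxent(c("ACGTACGTA", "ACGTACGNA")),
               "non-ACGT character in sequence 2 at position 8")
  expect_error(fit_maxent(c("ACGT", "ACGTA")), "differing lengths")
  m <- fit_maxent(c("ACGTACGTA"))
  expect_error(maxent_score(m, "ACGT"), "does not match")
})
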