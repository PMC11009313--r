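test_that("boundary windows match hand-extracted substrings on both strands", {
  # one 2-exon gene on +: exons 1-60 and 201-260, intron 61-200
  genome_seq <- random_dna(400, seed = 55)
  plus <- data.frame(contig = "chrT", start = c(1L, 201L), end = c(60L, 260L),
                     strand = "+", gene_id = "g1", transcript_id = "t1",
                     stringsAsFactors = FALSE)
  genome <- Biostrings::DNAStringSet(c(chrT = genome_seq))
  bw <- extract_boundary_windows(annotation_from_exons(plus), genome)
  expect_equal(nrow(bw), 2L)
  don <- bw[bw$side == "donor", ]
  acc <- bw[bw$side == "acceptor", ]
  expect_equal(don$boundary, 60)
  expect_equal(don$window, substr(genome_seq, 58, 66))   # 3 exonic + 6 intronic
  expect_equal(acc$boundary, 201)
  expect_equal(acc$window, substr(genome_seq, 181, 203)) # 20 intronic + 3 exonic
  # minus-strand copy of the same exon layout: reverse-complement windows
  minus <- plus
  minus$strand <- "-"
  bwm <- extract_boundary_windows(annotation_from_exons(minus), genome)
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  donm <- bwm[bwm$side == "donor", ]
  accm <- bwm[bwm$side == "acceptor", ]
  expect_equal(donm$boundary, 201)  # transcription right-to-left
  expect_equal(donm$window, rc(substr(genome_seq, 195, 203)))
  expect_equal(accm$boundary, 60)
  expect_equal(accm$window, rc(substr(genome_seq, 58, 80)))
})

test_that("short introns skip windows with a warning", {
  ex <- data.frame(contig = "chrT", start = c(1L, 81L), end = c(60L, 140L),
                   strand = "+", gene_id = "g", transcript_id = "t",
                   stringsAsFactors = FALSE)  # intron 61-80: 20 nt
  genome <- Biostrings::DNAStringSet(c(chrT = random_dna(200, seed = 56)))
  expect_warning(
    bw <- extract_boundary_windows(annotation_from_exons(ex), genome),
    "too short for acceptor")
  expect_equal(bw$side, "donor")
})

test_that("window extraction round-trips against the genome", {
  ann <- simulate_annotation(6, 4, seed = 57)
  bw <- extract_boundary_windows(ann, ann$genome)
  g <- ann$genome[["chrS"]]
  for (i in seq_len(nrow(bw))) {
    rng <- if (bw$side[i] == "donor") {
      if (bw$strand[i] == "+") c(bw$boundary[i] - 2L, bw$boundary[i] + 6L)
      else c(bw$boundary[i] - 6L, bw$boundary[i] + 2L)
    } else {
      if (bw$strand[i] == "+") c(bw$boundary[i] - 20L, bw$boundary[i] + 2L)
      else c(bw$boundary[i] - 2L, bw$boundary[i] + 20L)
    }
    w <- Biostrings::subseq(g, rng[1], rng[2])
    if (bw$strand[i] == "-") w <- Biostrings::reverseComplement(w)
    expect_equal(as.character(w), bw$window[i])
  }
  # donor windows carry the canonical GT at the first intronic positions
  don <- bw$window[bw$side == "donor"]
  expect_true(all(substr(don, 4, 5) == "GT"))
  acc <- bw$window[bw$side == "acceptor"]
  expect_true(all(substr(acc, 19, 20) == "AG"))
})

test_that("tags assign to boundaries within the flank, multi-hits reported", {
  b <- data.frame(gene = "g", transcript = "t", side = "donor",
                  contig = "chrT", boundary = c(100L, 115L), strand = "+",
                  window = "NNNNNNNNN", stringsAsFactors = FALSE)
  mk_tag <- function(pos0) data.frame(contig = "chrT", position = pos0,
                                      sample = "s1", stringsAsFactors = FALSE)
  # tag exactly at the junction (1-based 100 -> 0-based 99)
  hit <- assign_tags_to_boundaries(mk_tag(99L), b, flank = 10L)
  expect_equal(hit$count.s1, c(1L, 0L))
  # tag at junction + flank + 1 is unassigned
  miss <- assign_tags_to_boundaries(mk_tag(128L), b, flank = 10L)
  expect_equal(sum(miss$count.s1), 0L)
  expect_equal(attr(miss, "unassigned"), 1L)
  # a tag within both flanks is assigned to both, and reported
  dbl <- assign_tags_to_boundaries(mk_tag(107L), b, flank = 10L)
  expect_equal(dbl$count.s1, c(1L, 1L))
  expect_equal(attr(dbl, "multi_assigned"), 1L)
})

test_that("uniform random tags assign at roughly the flank-coverage rate", {
  ann <- simulate_annotation(5, 3, seed = 58)
  bw <- extract_boundary_windows(ann, ann$genome)
  L <- length(ann$genome[["chrS"]])
  flank <- 10L
  set.seed(59)
  tags <- data.frame(contig = "chrS",
                     position = sample.int(L, 5000, replace = TRUE) - 1L,
                     sample = "s1", stringsAsFactors = FALSE)
  hit <- assign_tags_to_boundaries(tags, bw, flank = flank)
  covered <- length(unique(unlist(lapply(bw$boundary, function(b)
    (b - flank):(b + flank)))))
  frac_assigned <- 1 - attr(hit, "unassigned") / nrow(tags)
  expected <- covered / L
  expect_lt(abs(frac_assigned - expected),
            3 * sqrt(expected * (1 - expected) / nrow(tags)))
})

test_that("fold-change stratification partitions categories and recovers shifts", {
  set.seed(60)
  n <- 240
  cat <- rep(c("weak", "intermediate", "strong"), each = n / 3)
  b <- data.frame(gene = sprintf("g%03d", seq_len(n)), transcript = "t",
                  side = "donor", contig = "chrS", boundary = seq_len(n) * 100L,
                  strand = "+", window = "NNNNNNNNN", category = cat,
                  stringsAsFactors = FALSE)
  # weak sites enriched 4x in case samples; others exchangeable
  lam <- ifelse(cat == "weak", 80, 20)
  for (s in c("case_1", "case_2", "ctrl_1", "ctrl_2")) {
    boost <- if (grepl("case", s)) ifelse(cat == "weak", 4, 1) else 1
    b[[paste0("count.", s)]] <- rpois(n, lam * boost)
  }
  conds <- c(case_1 = "case", case_2 = "case",
             ctrl_1 = "control", ctrl_2 = "control")
  sf <- stratified_fold_changes(b, conds, case = "case")
  expect_equal(sum(lengths(sf$by_category)), nrow(sf$sites))
  expect_gt(mean(sf$by_category$weak),
            mean(sf$by_category$strong) + 2 * sd(sf$by_category$strong) /
              sqrt(length(sf$by_category$strong)))
  # all-intermediate input leaves weak and strong empty, not an error
  b2 <- b
  b2$category <- "intermediate"
  sf2 <- stratified_fold_changes(b2, conds, case = "case")
  expect_length(sf2$by_category$weak, 0L)
  expect_length(sf2$by_category$strong, 0L)
  # low-coverage sites are filtered by min_total
  b3 <- b
  b3$count.case_1[1:10] <- 0L
  b3$count.case_2[1:10] <- 0L
  b3$count.ctrl_1[1:10] <- 0L
  b3$count.ctrl_2[1:10] <- 0L
  sf3 <- stratified_fold_changes(b3, conds, case = "case", min_total = 10L)
  expect_equal(nrow(sf3$sites), n - 10L)
})

test_that("Fisher enrichment matches hypergeometric enumeration", {
  bg <- sprintf("g%03d", 1:100)
  sel <- bg[1:10]
  gs <- list(SET = bg[6:15])  # 2x2 table: a=5, b=5, c=5, d=85
  res <- fisher_enrichment(sel, bg, gs)
  # exact enumeration oracle: sum of hypergeometric point masses <= observed
  phyper_exact <- function(a, set_n, sel_n, bg_n) {
    support <- max(0, set_n + sel_n - bg_n):min(set_n, sel_n)
    d <- dhyper(support, set_n, bg_n - set_n, sel_n)
    sum(d[d <= dhyper(a, set_n, bg_n - set_n, sel_n) * (1 + 1e-7)])
  }
  expect_equal(res$p, phyper_exact(5, 10, 10, 100), tolerance = 1e-12)
  expect_equal(res$in_set_selected, 5L)
  expect_equal(res$out_set_not, 85L)
  # randomized tables against the same oracle
  set.seed(61)
  for (i in 1:25) {
    bg_n <- sample(30:200, 1)
    bgi <- sprintf("x%03d", seq_len(bg_n))
    seli <- sample(bgi, sample(5:(bg_n / 2), 1))
    gsi <- list(S = sample(bgi, sample(5:(bg_n / 2), 1)))
    a <- length(intersect(gsi$S, seli))
    expect_equal(fisher_enrichment(seli, bgi, gsi)$p,
                 phyper_exact(a, length(gsi$S), length(seli), bg_n),
                 tolerance = 1e-9)
  }
})

test_that("Fisher enrichment: extremes, BH adjustment, null conservativeness", {
  bg <- sprintf("g%04d", 1:500)
  sel <- bg[1:40]
  # gene set identical to the selection: minimal p, odds ratio > 1
  res <- fisher_enrichment(sel, bg, list(SAME = sel, OTHER = bg[301:340]))
  expect_lt(res$p[res$gene_set == "SAME"], 1e-20)
  expect_gt(res$odds_ratio[res$gene_set == "SAME"], 1)
  expect_true(all(res$p_adj >= res$p))
  expect_error(fisher_enrichment(sel, character(0), list(S = sel)), "background")
  expect_error(fisher_enrichment(c(sel, "zz"), bg, list(S = sel)), "subset")
  # under random selection, p-values are stochastically >= uniform
  set.seed(62)
  ps <- replicate(200, {
    s <- sample(bg, 50)
    fisher_enrichment(s, bg, list(S = bg[1:50]))$p
  })
  expect_gt(suppressWarnings(
    stats::ks.test(ps, "punif", alternative = "greater")$p.value), 0.01)
})

test_that("GMT files round into enrichment analysis", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tna\tg001\tg002\tg003",
               "setB\tna\tg004\tg005"), path)
  gs <- read_gmt(path)
  expect_equal(names(gs), c("setA", "setB"))
  bg <- sprintf("g%03d", 1:50)
  res <- fisher_enrichment(bg[1:3], bg, path)
  expect_equal(res$in_set_selected[res$gene_set == "setA"], 3L)
})

test_that("composition contrast: identity, extremes, planted excess recovery", {
  s <- c("ACGT", "TTAA", "CGCG")
  id <- composition_contrast(s, s, n_boot = 50)
  expect_equal(id$aggregate$difference, rep(0, 4))
  ext <- composition_contrast(c("TTTT", "TTTT"), c("CCCC", "CCCC"), n_boot = 50)
  expect_equal(ext$aggregate$difference[ext$aggregate$base == "T"], 1)
  expect_equal(ext$aggregate$difference[ext$aggregate$base == "C"], -1)
  expect_error(composition_contrast(character(0), s), "empty")
  # planted 10% thymidine excess recovered within the bootstrap CI
  set.seed(63)
  draw <- function(n, pT) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE,
                 prob = c((1 - pT) / 3, (1 - pT) / 3, (1 - pT) / 3, pT)),
          collapse = ""), "")
  up <- draw(150, 0.35)
  dn <- draw(150, 0.25)
  cmp <- composition_contrast(up, dn, n_boot = 300, seed = 64)
  t_row <- cmp$aggregate[cmp$aggregate$base == "T", ]
  expect_true(t_row$ci_lo <= 0.10 && 0.10 <= t_row$ci_hi)
  # per-position table present for equal-length windows, with both statistics
  expect_false(is.null(cmp$per_position))
  expect_true(all(c("difference", "log_odds") %in% names(cmp$per_position)))
})
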