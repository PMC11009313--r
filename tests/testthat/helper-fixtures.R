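# Shared fixtures: a synthetic U6-like snRNA truth with crosslink hotspots
# over the ACAGA-box region (nt 25-47) and the internal stem-loop, and
# deletion-bearing crosslink nucleotides at 64-65.

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

u6_profile <- function(acaga_weight = 0.5) {
  p <- numeric(106)
  p[25:47] <- acaga_weight / 23        # ACAGA-box region
  p[48:80] <- (1 - acaga_weight) / 33  # ISL region (covers nt 64-65)
  p / sum(p)
}

u6_truth <- function(seed, n_reads = 20000L, deletion_prob = 0.043,
                     n_case = 2L, n_ctrl = 2L, profile = u6_profile(),
                     read_length = 35L) {
  simulation_truth(
    seed = seed,
    references = c(U6 = random_dna(106, seed = 106L)),
    binding_profile = list(U6 = profile),
    deletion_sites = list(U6 = c(64L, 65L)),
    deletion_prob = deletion_prob,
    read_length = read_length,
    n_reads_per_sample = n_reads,
    samples = data.frame(
      sample_id = c(sprintf("case_%d", seq_len(n_case)),
                    sprintf("ctrl_%d", seq_len(n_ctrl))),
      condition = rep(c("case", "control"), c(n_case, n_ctrl)),
      stringsAsFactors = FALSE))
}

psi_truth_table <- function(n_events, mean_case, mean_ctrl, rho_case,
                            rho_ctrl, type = "SE") {
  ids <- sprintf("ev%04d", seq_len(n_events))
  data.frame(
    event_id = rep(ids, each = 2L),
    condition = rep(c("case", "control"), n_events),
    mean = rep(c(mean_case, mean_ctrl), n_events),
    dispersion = rep(c(rho_case, rho_ctrl), n_events),
    type = type, stringsAsFactors = FALSE)
}

psi_samples <- function(n_case = 3L, n_ctrl = 3L) {
  data.frame(
    sample_id = c(sprintf("case_%d", seq_len(n_case)),
                  sprintf("ctrl_%d", seq_len(n_ctrl))),
    condition = rep(c("case", "control"), c(n_case, n_ctrl)),
    stringsAsFactors = FALSE)
}

# junction-count long table -> events x samples PSI matrix for one condition
psi_matrix <- function(jc, cond) {
  sub <- jc[jc$condition == cond, ]
  ev <- unique(sub$event_id)
  sm <- unique(sub$sample)
  m <- matrix(NA_real_, length(ev), length(sm), dimnames = list(ev, sm))
  m[cbind(match(sub$event_id, ev), match(sub$sample, sm))] <- sub$psi
  m
}

# hand-built single-end sense alignment records
make_reads <- function(pos1, cigar, rname = "REF", sample = "s1",
                       seq = "*") {
  n <- max(length(pos1), length(cigar))
  data.frame(qname = sprintf("r%03d", seq_len(n)),
             flag = rep_len(0L, n), rname = rep_len(rname, n),
             pos = as.integer(rep_len(pos1, n)), mapq = rep_len(255L, n),
             cigar = rep_len(cigar, n), seq = rep_len(seq, n),
             sample = rep_len(sample, n), stringsAsFactors = FALSE)
}
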