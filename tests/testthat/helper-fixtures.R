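# Shared fixtures and independent oracles for the test suite.

# A 2-group x 3-replicate toy design.
toy_design <- function(n_rep = 3, groups = c("caput", "cauda")) {
  study_design(sprintf("C%02d", seq_len(n_rep * length(groups))),
               rep(groups, each = n_rep),
               rep(seq_len(n_rep), times = length(groups)))
}

# A tiny hand-built site table on the toy design.
toy_sites <- function(design = toy_design()) {
  nch <- nrow(design)
  d <- data.frame(
    site_id = c("P1_S10", "P1_T20", "P2_S5"),
    protein_accession = c("P1", "P1", "P2"),
    position = c(10L, 20L, 5L),
    residue = c("S", "T", "S"),
    localization_prob = c(0.99, 0.80, 0.60),
    window = c("AAAAAAASAAAAAAA", "RRRRRRRTRRRRRRR", "KKKKKKKSKKKKKK_"),
    stringsAsFactors = FALSE
  )
  ints <- matrix(seq_len(3 * nch) * 100, nrow = 3,
                 dimnames = list(NULL, design$channel))
  cbind(d, as.data.frame(ints))
}

toy_proteins <- function(design = toy_design()) {
  nch <- nrow(design)
  d <- data.frame(protein_accession = c("P1", "P2"), stringsAsFactors = FALSE)
  ints <- matrix(c(rep(1000, nch), 500 + seq_len(nch)), nrow = 2,
                 byrow = TRUE, dimnames = list(NULL, design$channel))
  cbind(d, as.data.frame(ints))
}

# Two-sided pooled-variance t-test p-value by numeric integration of the
# explicit t density (independent of pt / t.test).
oracle_ttest_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
  tval <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
  dens <- function(x) gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
    (1 + x^2 / df)^(-(df + 1) / 2)
  2 * stats::integrate(dens, abs(tval), Inf, rel.tol = 1e-12)$value
}

# Exhaustive hypergeometric upper tail by combinatorial summation,
# binomial coefficients built from explicit factor products.
oracle_choose <- function(n, k) {
  if (k < 0 || k > n) return(0)
  if (k == 0) return(1)
  prod((n - k + seq_len(k)) / seq_len(k))
}

oracle_hyper_tail <- function(k, N, K, n) {
  if (k < max(0, n - (N - K))) k <- max(0, n - (N - K))
  terms <- vapply(k:min(K, n), function(i)
    oracle_choose(K, i) * oracle_choose(N - K, n - i), 0)
  sum(terms) / oracle_choose(N, n)
}

# Hand step-up Benjamini-Hochberg, literal formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Small seeded synthetic experiment with one planted up-kinase and one
# planted down-kinase plus decoys, reused across modules.
planted_experiment <- function(n_sites = 800, seed = 42,
                               effect_log2fc = 1.5,
                               frac_diff_sites = 0.1) {
  pan <- default_kinase_panel()
  cfg <- simulation_config(
    n_proteins = 100, n_sites = n_sites,
    frac_diff_sites = frac_diff_sites, effect_log2fc = effect_log2fc,
    planted_kinases = list(c(pan[[3]], direction = "up"),
                           c(pan[[6]], direction = "down")),
    decoy_kinases = pan[-c(3, 6)], seed = seed)
  generate_experiment(cfg)
}
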