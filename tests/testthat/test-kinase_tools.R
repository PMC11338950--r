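blosum <- default_substitution_matrix()

test_that("window similarity sums per-position substitution scores", {
  wA <- strrep("A", 15)
  # identical all-alanine windows score 15 x s(A,A), with s(A,A) read
  # from the matrix itself
  expect_equal(window_similarity(wA, wA, blosum), 15 * blosum["A", "A"])
  # a position padded in either window contributes 0
  w1 <- paste0(strrep("A", 14), "_")
  w2 <- paste0(strrep("A", 14), "W")
  expect_equal(window_similarity(w1, w2, blosum),
               window_similarity(w1, w1, blosum))
  # symmetry
  wR <- paste0(strrep("R", 7), "S", strrep("K", 7))
  wQ <- paste0(strrep("Q", 7), "S", strrep("E", 7))
  expect_equal(window_similarity(wR, wQ, blosum),
               window_similarity(wQ, wR, blosum))
  expect_error(window_similarity(paste0(strrep("A", 14), "1"), wA, blosum),
               "alphabet")
})

test_that("site scores average over reference windows", {
  wA <- strrep("A", 15)
  wR <- paste0(strrep("R", 7), "S", strrep("R", 7))
  k1 <- kinase_spec("K1", "CAMK", paste0(strrep("A", 7), "S", strrep("A", 7)))
  q <- paste0(strrep("A", 7), "S", strrep("A", 7))
  expect_equal(score_site(q, k1, blosum), window_similarity(q, q, blosum))
  k2 <- kinase_spec("K2", "CAMK", c(q, wR))
  expect_equal(score_site(q, k2, blosum),
               mean(c(window_similarity(q, q, blosum),
                      window_similarity(q, wR, blosum))))
  # an all-padding query scores 0 against anything
  expect_equal(window_similarity(strrep("_", 15), q, blosum), 0)
  # padding everywhere but the center leaves only the center match
  pad <- paste0(strrep("_", 7), "S", strrep("_", 7))
  expect_equal(score_site(pad, k2, blosum), blosum["S", "S"])
  expect_error(kinase_spec("K3", "CAMK", character(0)), "at least one")
})

test_that("cutoff calibration bounds the background hit fraction by the FPR", {
  set.seed(5)
  bg <- generate_windows(paste0(strrep("X", 7), "S", strrep("X", 7)),
                         1000, seed = 77)
  k <- kinase_spec("K1", "CAMK",
                   generate_windows("XXXXRXXSXXXFXXX", 5, seed = 78))
  kc <- calibrate_cutoff(k, bg, fpr = 0.02, mat = blosum)
  scores <- vapply(bg, score_site, 0, kinase = kc, mat = blosum)
  expect_lte(sum(scores >= kc$cutoff), 20)
  # sort-based quantile oracle: the cutoff admits as many background
  # windows as possible within the budget
  srt <- sort(scores, decreasing = TRUE)
  expect_gte(sum(scores >= kc$cutoff), sum(srt > srt[21]))

  # fpr below 1/n: cutoff exceeds every background score
  k0 <- calibrate_cutoff(k, bg[1:10], fpr = 0.05, mat = blosum)
  s10 <- vapply(bg[1:10], score_site, 0, kinase = k0, mat = blosum)
  expect_true(all(s10 < k0$cutoff))
  # fpr = 1: cutoff at or below the minimum
  k1 <- calibrate_cutoff(k, bg[1:10], fpr = 1, mat = blosum)
  expect_lte(k1$cutoff, min(s10))
  expect_error(calibrate_cutoff(k, character(0)), "nonempty")
  expect_error(calibrate_cutoff(k, bg, fpr = 0), "fpr")
})

test_that("held-out background FPR stays within binomial tolerance of nominal", {
  bg_all <- shuffle_background(
    generate_windows(paste0(strrep("X", 7), "S", strrep("X", 7)), 400,
                     seed = 301), 2000, seed = 302)
  train <- bg_all[1:1000]
  held <- bg_all[1001:2000]
  k <- kinase_spec("K1", "CAMK",
                   generate_windows("XXXXRXXSXXXFXXX", 8, seed = 303))
  kc <- calibrate_cutoff(k, train, fpr = 0.02, mat = blosum)
  sc <- vapply(held, score_site, 0, kinase = kc, mat = blosum)
  fpr_hat <- mean(sc >= kc$cutoff)
  tol <- 3 * sqrt(0.02 * 0.98 / 1000)
  expect_lte(fpr_hat, 0.02 + tol)
})

test_that("substrate prediction gates on residue class and recovers planted motifs", {
  ex <- planted_experiment(n_sites = 800, seed = 41)
  class1 <- suppressMessages(filter_class1(ex$sites))
  bg <- shuffle_background(class1$window, 1000, seed = 42)
  kins <- lapply(ex$kinases, calibrate_cutoff, background_windows = bg,
                 fpr = 0.02, mat = blosum)
  rel <- predict_substrates(class1, kins, mat = blosum)
  planted <- intersect(ex$truth$kinase_site_ids[["TSSK2"]], class1$site_id)
  expect_gte(mean(planted %in% rel[["TSSK2"]]), 0.8)
  # residue gate: an S/T kinase never claims a pY site
  y_sites <- class1$site_id[class1$residue == "Y"]
  expect_length(intersect(rel[["TSSK2"]], y_sites), 0)
  # uncalibrated kinase errors
  expect_error(predict_substrates(class1, ex$kinases["TSSK2"]), "cutoff")
  # a kinase whose references match nothing predicts nothing
  far <- kinase_spec("FAR", "Other", paste0(strrep("W", 7), "Y", strrep("W", 7)))
  far <- calibrate_cutoff(far, bg, fpr = 0.001, mat = blosum)
  relf <- predict_substrates(class1, list(FAR = far), mat = blosum)
  expect_lte(length(relf$FAR), 2)
})

test_that("Fisher enrichment matches the combinatorial oracle on small tables", {
  # worked example: a=5, b=5, c=0, d=10
  uni <- paste0("s", 1:20)
  reg <- uni[1:10]
  pred <- uni[1:5]
  fe <- fisher_enrich(pred, reg, uni)
  expect_identical(c(fe$a, fe$b, fe$c, fe$d), c(5L, 5L, 0L, 10L))
  expect_equal(fe$p_value, oracle_hyper_tail(5, 20, 5, 10), tolerance = 1e-12)
  expect_identical(fe$odds_ratio, Inf)

  # exhaustive scan over tables with N <= 60
  set.seed(11)
  for (i in 1:300) {
    N <- sample(4:60, 1)
    K <- sample(0:N, 1)          # substrates
    n <- sample(1:N, 1)          # regulated
    uni <- paste0("s", seq_len(N))
    pred <- if (K) sample(uni, K) else character(0)
    reg <- sample(uni, n)
    fe <- fisher_enrich(pred, reg, uni)
    expect_equal(fe$p_value,
                 oracle_hyper_tail(fe$a, N, K, n), tolerance = 1e-10)
    # cross-check against fisher.test one-sided p
    tab <- matrix(c(fe$a, fe$c, fe$b, fe$d), 2)
    expect_equal(fe$p_value,
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }

  # degenerate margins
  expect_equal(fisher_enrich(character(0), reg, uni)$p_value, 1)
  expect_equal(fisher_enrich(pred, uni, uni)$p_value, 1)
  expect_error(fisher_enrich(pred, c("zz", reg), uni), "subset")
})

test_that("adding a regulated substrate never increases the enrichment p", {
  uni <- paste0("s", 1:40)
  pred <- uni[1:12]
  reg <- uni[c(1:3, 20:26)]
  p0 <- fisher_enrich(pred, reg, uni)$p_value
  # swap a regulated non-substrate for a substrate: a rises, margins fixed
  reg2 <- uni[c(1:4, 20:25)]
  p1 <- fisher_enrich(pred, reg2, uni)$p_value
  expect_lte(p1, p0)
})

test_that("family rollup counts significant kinases per direction", {
  e <- data.frame(
    kinase = c("K1", "K2", "K3", "K1", "K2", "K3"),
    family = rep(c("CAMK", "CAMK", "CMGC"), 2),
    direction_set = rep(c("up", "down"), each = 3),
    p_value = c(0.001, 0.01, 0.2, 0.9, 0.8, 0.003),
    stringsAsFactors = FALSE)
  fam <- family_summary(e, alpha = 0.05)
  expect_identical(fam$n_enriched_up[fam$family == "CAMK"], 2L)
  expect_identical(fam$n_enriched_down[fam$family == "CMGC"], 1L)
  expect_identical(fam$n_enriched_down[fam$family == "CAMK"], 0L)
  none <- family_summary(transform(e, p_value = 1), alpha = 0.05)
  expect_true(all(none$n_enriched_up == 0) && all(none$n_enriched_down == 0))
})

test_that("planted family activities dominate the family rollup", {
  ex <- planted_experiment(n_sites = 800, seed = 43)
  res <- suppressMessages(run_pipeline(ex$sites, ex$proteins, ex$design,
                                       kinases = ex$kinases, seed = 44))
  fam <- res$family_summary
  # CAMK (planted up) tops the up column, CMGC (planted down) the down column
  expect_identical(fam$family[which.max(fam$n_enriched_up)], "CAMK")
  expect_identical(fam$family[which.max(fam$n_enriched_down)], "CMGC")
})
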