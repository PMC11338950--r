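test_that("pooled t-test matches hand arithmetic and the integration oracle", {
  # identical groups
  r <- ttest_two_group(c(1, 2, 3), c(1, 2, 3), log_scale = FALSE)
  expect_equal(r$t_stat, 0)
  expect_equal(r$p_value, 1)

  # hand case: pooled variance 2.5, se = 1, t = 1 (b over a), df = 8
  r <- ttest_two_group(1:5, 2:6, log_scale = FALSE)
  expect_equal(r$t_stat, 1, tolerance = 1e-12)
  expect_equal(r$df, 8)
  expect_equal(r$p_value, oracle_ttest_p(1:5, 2:6), tolerance = 1e-10)

  # degenerate contracts
  r <- ttest_two_group(c(1, 1, 1), c(2, 2, 2), log_scale = FALSE)
  expect_equal(r$p_value, 0)
  expect_identical(r$t_stat, Inf)
  r <- ttest_two_group(c(2, 2), c(1, 1), log_scale = FALSE)
  expect_identical(r$t_stat, -Inf)

  expect_error(ttest_two_group(1, c(1, 2)), "at least 2")
  expect_error(ttest_two_group(c(-1, 2, 3), c(1, 2, 3)), "positive")
})

test_that("t-test p-values track the numeric-integration oracle over random draws", {
  set.seed(101)
  for (i in 1:200) {
    na <- sample(2:8, 1)
    nb <- sample(2:8, 1)
    a <- rnorm(na)
    b <- rnorm(nb, mean = runif(1, -1, 1))
    if (var(a) == 0 && var(b) == 0) next
    r <- ttest_two_group(a, b, log_scale = FALSE)
    expect_equal(r$p_value, oracle_ttest_p(a, b), tolerance = 1e-8)
  }
})

test_that("fold change is the linear-scale ratio with reciprocal symmetry", {
  expect_equal(fold_change(2, 3), 1.5)
  expect_equal(fold_change(3, 2), 2 / 3)
  expect_equal(fold_change(7, 7), 1)
  expect_equal(fold_change(2, 3) * fold_change(3, 2), 1)
  expect_error(fold_change(0, 1), "positive")
  expect_error(fold_change(1, -2), "positive")
})

test_that("classification applies inclusive FC and strict alpha thresholds", {
  design <- toy_design(n_rep = 5)
  cha <- design$channel[design$group == "caput"]
  chb <- design$channel[design$group == "cauda"]
  # crafted rows with known outcomes: an exactly representable FC of 1.5
  # (dyadic values, so the linear means are exact) with p < 0.05, an FC-2
  # row too noisy to reach significance, and a flat row
  base <- c(0.75, 0.875, 1, 1.125, 1.25)  # mean exactly 1
  eps <- c(-2, -1, 0, 1, 2) * 1e-4
  m <- rbind(
    fc15 = c(base, 1.5 * base),
    fc20_noisy = c(exp(c(-2, -1, 0, 1, 2)), 2 * exp(c(2, -1, 0, 1, -2))),
    flat = c(1 + eps, 1 + eps))
  colnames(m) <- c(cha, chb)
  res <- classify_sites(m, design, "caput", "cauda")
  expect_equal(res$fold_change[res$site_id == "fc15"], 1.5, tolerance = 1e-12)
  expect_identical(res$direction[res$site_id == "fc15"], "up")
  expect_gt(res$p_value[res$site_id == "fc20_noisy"], 0.05)
  expect_identical(res$direction[res$site_id == "fc20_noisy"], "ns")
  expect_identical(res$direction[res$site_id == "flat"], "ns")
  expect_error(classify_sites(m, design, "caput", "nowhere"), "unknown group")
})

test_that("sites with insufficient data are reported ns with a reason", {
  design <- toy_design(n_rep = 3)
  m <- matrix(c(1, NA, NA, 2, 2.1, 1.9), nrow = 1,
              dimnames = list("s1", design$channel))
  res <- classify_sites(m, design, "caput", "cauda")
  expect_identical(res$direction, "ns")
  expect_identical(res$reason, "insufficient_values")
  expect_true(is.na(res$p_value))
})

test_that("swapping group labels inverts fold changes and swaps directions", {
  ex <- planted_experiment(n_sites = 400, seed = 19)
  cal <- calibrate_sites(
    normalize_rows(quant_matrix(suppressMessages(filter_class1(ex$sites)),
                                ex$design)),
    normalize_rows(quant_matrix(ex$proteins, ex$design)),
    setNames(ex$sites$protein_accession, ex$sites$site_id))
  ab <- classify_sites(cal$matrix, ex$design, "caput", "cauda")
  ba <- classify_sites(cal$matrix, ex$design, "cauda", "caput")
  tested <- !is.na(ab$p_value)
  expect_equal(ab$fold_change[tested], 1 / ba$fold_change[tested],
               tolerance = 1e-10)
  expect_equal(ab$p_value[tested], ba$p_value[tested], tolerance = 1e-10)
  expect_identical(sum(ab$direction == "up"), sum(ba$direction == "down"))
  expect_identical(sum(ab$direction == "down"), sum(ba$direction == "up"))
  # counting identity
  expect_identical(sum(ab$direction == "up") + sum(ab$direction == "down") +
                     sum(ab$direction == "ns"), nrow(ab))
})

test_that("planted differential sites are recovered with high recall and few flips", {
  ex <- planted_experiment(n_sites = 1500, seed = 23, effect_log2fc = 1.5)
  class1 <- suppressMessages(filter_class1(ex$sites))
  cal <- calibrate_sites(
    normalize_rows(quant_matrix(class1, ex$design)),
    normalize_rows(quant_matrix(ex$proteins, ex$design)),
    setNames(class1$protein_accession, class1$site_id))
  res <- classify_sites(cal$matrix, ex$design, "caput", "cauda")
  up_called <- res$site_id[res$direction == "up"]
  down_called <- res$site_id[res$direction == "down"]
  recall_up <- mean(ex$truth$diff_site_ids_up %in% up_called)
  recall_down <- mean(ex$truth$diff_site_ids_down %in% down_called)
  expect_gte(recall_up, 0.8)
  expect_gte(recall_down, 0.8)
  flips <- sum(ex$truth$diff_site_ids_up %in% down_called) +
    sum(ex$truth$diff_site_ids_down %in% up_called)
  expect_lte(flips / (length(ex$truth$diff_site_ids_up) +
                        length(ex$truth$diff_site_ids_down)), 0.01)
})

test_that("protein aggregation categorises up-only, down-only, both and none", {
  res <- data.frame(
    site_id = paste0("s", 1:6),
    direction = c("up", "down", "up", "ns", "ns", "down"),
    stringsAsFactors = FALSE)
  map <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B", s5 = "C", s6 = "D")
  agg <- aggregate_proteins(res, map)
  expect_identical(agg$category[agg$protein_accession == "A"], "both")
  expect_identical(agg$category[agg$protein_accession == "B"], "up-only")
  expect_identical(agg$category[agg$protein_accession == "C"], "none")
  expect_identical(agg$category[agg$protein_accession == "D"], "down-only")
  expect_identical(agg$n_up_sites[agg$protein_accession == "A"], 1L)
  expect_error(aggregate_proteins(res, map[-1]), "unmapped")
})

test_that("overlap fractions reproduce printed-percentage arithmetic", {
  a <- paste0("s", 1:870)
  b <- c(paste0("s", 1:185), paste0("x", 1:50))
  ov <- overlap_fraction(a, b)
  expect_identical(ov$intersection, 185L)
  expect_equal(ov$percentage, 21.3)
  expect_equal(overlap_fraction(letters, LETTERS)$percentage, 0)
  expect_equal(overlap_fraction(letters[1:5], letters)$percentage, 100)
  expect_error(overlap_fraction(character(0), letters), "nonempty")
})

test_that("proteome overlap reports all four intersection counts", {
  pu <- paste0("p", 1:20)
  pd <- paste0("q", 1:30)
  prot_up <- c(paste0("p", 1:7), "z1")
  prot_down <- c(paste0("q", 1:3), paste0("p", 8:9))
  ov <- overlap_with_proteome(pu, pd, prot_up, prot_down)
  expect_identical(ov$up_up, 7L)
  expect_identical(ov$down_down, 3L)
  expect_identical(ov$up_down, 2L)
  expect_identical(ov$down_up, 0L)
  full <- overlap_with_proteome(pu, pd, pu, pd)
  expect_identical(full$up_up, 20L)
  expect_identical(full$down_up, 0L)
})
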