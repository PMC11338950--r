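# Two-group differential phosphorylation: pooled-variance Student's t-test,
# linear-scale fold change, up/down/ns classification, protein-level
# aggregation and set-overlap statistics.

#' Pooled-variance two-sample Student's t-test
#'
#' Two-sided independent t-test with pooled (equal) variance on
#' optionally log2-transformed values, with the degenerate cases made
#' explicit: two zero-variance groups with equal means give `t = 0,
#' p = 1`; zero pooled variance with unequal means gives `p = 0` and a
#' signed-infinity t statistic.
#'
#' @param a,b numeric vectors (missing values dropped), each with >= 2
#'   non-missing values.
#' @param log_scale test on log2-transformed values (requires positive
#'   data). Ratio-scale TMT data is tested on the log scale by default so
#'   up- and down-regulation are treated symmetrically.
#' @return list with `t_stat`, `p_value`, `df`, `n_a`, `n_b`.
#' @export
ttest_two_group <- function(a, b, log_scale = TRUE) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 non-missing values")
  if (log_scale) {
    if (any(a <= 0) || any(b <= 0))
      stop("log_scale = TRUE requires positive values")
    a <- log2(a)
    b <- log2(b)
  }
  df <- length(a) + length(b) - 2L
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t_stat = 0, p_value = 1, df = df,
                  n_a = length(a), n_b = length(b)))
    return(list(t_stat = sign(mean(b) - mean(a)) * Inf, p_value = 0, df = df,
                n_a = length(a), n_b = length(b)))
  }
  tt <- stats::t.test(b, a, var.equal = TRUE)
  list(t_stat = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), n_a = length(a), n_b = length(b))
}

#' Linear-scale fold change
#'
#' Ratio of group means on the linear (unlogged) calibrated scale,
#' comparison group over reference group.
#'
#' @param mean_a reference-group mean (> 0).
#' @param mean_b comparison-group mean (> 0).
#' @return `mean_b / mean_a`.
#' @export
fold_change <- function(mean_a, mean_b) {
  if (any(!is.finite(c(mean_a, mean_b))) || any(c(mean_a, mean_b) <= 0))
    stop("group means must be positive and finite")
  mean_b / mean_a
}

#' Classify differential phosphorylation sites between two groups
#'
#' Per site: pooled t-test (on log2 values by default) and linear-scale
#' fold change of group means; a site is called `up` if `p < alpha` and
#' `FC >= fc_threshold`, `down` if `p < alpha` and `FC <= 1/fc_threshold`,
#' else `ns`. The fold-change boundary is inclusive. Sites with fewer
#' than 2 usable values in either group are reported as `ns` with a
#' reason code rather than dropped. Benjamini-Hochberg q-values are
#' reported as an extra column but play no part in the direction call
#' (site-level significance uses the raw p-value).
#'
#' @param calibrated calibrated (or normalized) quant matrix.
#' @param design study design.
#' @param group_a reference group label (e.g. `"caput"`).
#' @param group_b comparison group label (e.g. `"cauda"`).
#' @param alpha significance level for the raw p-value.
#' @param fc_threshold fold-change threshold (inclusive).
#' @param log_scale passed to [ttest_two_group()].
#' @return `data.frame` with columns `site_id`, `mean_a`, `mean_b`,
#'   `fold_change`, `log2fc`, `t_stat`, `p_value`, `q_value`,
#'   `direction`, `n_a`, `n_b`, `reason`.
#' @export
classify_sites <- function(calibrated, design, group_a, group_b,
                           alpha = 0.05, fc_threshold = 1.5,
                           log_scale = TRUE) {
  for (g in c(group_a, group_b))
    if (!g %in% design$group) stop("unknown group label: ", g)
  cha <- design$channel[design$group == group_a]
  chb <- design$channel[design$group == group_b]
  if (length(cha) < 2 || length(chb) < 2)
    stop("both groups need at least 2 channels in the design")
  n <- nrow(calibrated)
  res <- data.frame(
    site_id = rownames(calibrated),
    mean_a = NA_real_, mean_b = NA_real_, fold_change = NA_real_,
    log2fc = NA_real_, t_stat = NA_real_, p_value = NA_real_,
    q_value = NA_real_, direction = "ns", n_a = NA_integer_,
    n_b = NA_integer_, reason = "", stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    va <- calibrated[i, cha]
    va <- va[!is.na(va)]
    vb <- calibrated[i, chb]
    vb <- vb[!is.na(vb)]
    res$n_a[i] <- length(va)
    res$n_b[i] <- length(vb)
    if (length(va) < 2 || length(vb) < 2) {
      res$reason[i] <- "insufficient_values"
      next
    }
    if (log_scale && (any(va <= 0) || any(vb <= 0))) {
      res$reason[i] <- "nonpositive_values"
      next
    }
    res$mean_a[i] <- mean(va)
    res$mean_b[i] <- mean(vb)
    res$fold_change[i] <- fold_change(res$mean_a[i], res$mean_b[i])
    res$log2fc[i] <- log2(res$fold_change[i])
    tt <- ttest_two_group(va, vb, log_scale = log_scale)
    res$t_stat[i] <- tt$t_stat
    res$p_value[i] <- tt$p_value
  }
  tested <- !is.na(res$p_value)
  res$q_value[tested] <- stats::p.adjust(res$p_value[tested], method = "BH")
  sig <- tested & res$p_value < alpha
  res$direction[sig & res$fold_change >= fc_threshold] <- "up"
  res$direction[sig & res$fold_change <= 1 / fc_threshold] <- "down"
  res
}

#' Aggregate site-level direction calls to proteins
#'
#' Counts up- and down-regulated sites per protein and assigns a
#' category: `up-only`, `down-only`, `both` (at least one site in each
#' direction -- proteins under complex phosphoregulation), or `none`.
#'
#' @param results output of [classify_sites()].
#' @param site_to_protein named character vector, site id -> accession.
#' @return `data.frame(protein_accession, n_up_sites, n_down_sites,
#'   category)`.
#' @export
aggregate_proteins <- function(results, site_to_protein) {
  acc <- site_to_protein[results$site_id]
  if (anyNA(acc))
    stop("unmapped site id(s): ",
         paste(utils::head(results$site_id[is.na(acc)], 5), collapse = ", "))
  up <- tapply(results$direction == "up", acc, sum)
  down <- tapply(results$direction == "down", acc, sum)
  out <- data.frame(protein_accession = names(up),
                    n_up_sites = as.integer(up),
                    n_down_sites = as.integer(down),
                    stringsAsFactors = FALSE)
  out$category <- ifelse(out$n_up_sites > 0 & out$n_down_sites > 0, "both",
                  ifelse(out$n_up_sites > 0, "up-only",
                  ifelse(out$n_down_sites > 0, "down-only", "none")))
  rownames(out) <- NULL
  out[order(out$protein_accession), , drop = FALSE]
}

#' Overlap of one id set with another
#'
#' @param set_a nonempty reference id set (the denominator).
#' @param set_b id set to intersect with.
#' @return list with `intersection` (count), `fraction` (`|A n B| / |A|`)
#'   and `percentage` (rounded to 1 decimal).
#' @export
overlap_fraction <- function(set_a, set_b) {
  set_a <- unique(set_a)
  if (!length(set_a)) stop("set_a must be nonempty")
  inter <- sum(set_a %in% set_b)
  frac <- inter / length(set_a)
  list(intersection = inter, fraction = frac,
       percentage = round(100 * frac, 1))
}

#' Cross-tabulate phosphorylation-level and protein-expression changes
#'
#' Intersections between proteins with up/down-regulated phosphosites and
#' proteins up/down-regulated at the expression level, quantifying how
#' far phosphorylation regulation is independent of abundance.
#'
#' @param phospho_up,phospho_down accessions with up/down phosphosites.
#' @param prot_up,prot_down accessions up/down at the protein level.
#' @return named list of the four intersection counts.
#' @export
overlap_with_proteome <- function(phospho_up, phospho_down, prot_up, prot_down) {
  list(
    up_up = length(intersect(phospho_up, prot_up)),
    down_down = length(intersect(phospho_down, prot_down)),
    up_down = length(intersect(phospho_up, prot_down)),
    down_up = length(intersect(phospho_down, prot_up))
  )
}
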