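# End-to-end orchestration: filter -> normalize -> calibrate -> differential
# statistics -> protein aggregation -> kinase enrichment -> ORA, with a JSON
# summary and an output manifest; plus the inhibitor-vs-maturation overlap.

.load_if_path <- function(x, loader, ...) {
  if (is.character(x) && length(x) == 1) loader(x, ...) else x
}

#' Run the full phosphoproteomics analysis pipeline
#'
#' Executes the analysis chain on a site table, protein table and study
#' design: class-I filtering, row-mean normalization of sites and
#' proteins, protein-abundance calibration (with fallback for sites whose
#' protein was not quantified), QC (channel correlations, PCA),
#' differential classification between two groups, protein-level
#' aggregation, optional motif-based kinase enrichment and optional
#' over-representation analysis of regulated proteins. Inputs may be
#' in-memory tables or file paths. Identical inputs and `seed` reproduce
#' an identical summary.
#'
#' @param sites site table or TSV path.
#' @param proteins protein table or TSV path.
#' @param design study design or TSV path.
#' @param group_a,group_b reference and comparison group labels.
#' @param kinases optional named list of [kinase_spec()] or reference TSV
#'   path; enables kinase enrichment.
#' @param gene_sets optional gene-set list or GMT path; enables ORA.
#' @param loc_threshold class-I localization-probability threshold.
#' @param alpha site-level significance threshold (raw p).
#' @param fc_threshold fold-change threshold (inclusive).
#' @param log_scale run the t-test on log2 values.
#' @param fpr nominal background false-positive rate for kinase cutoffs.
#' @param n_background number of residue-shuffled background windows for
#'   cutoff calibration.
#' @param mat substitution matrix for motif scoring.
#' @param ora_alpha q-value threshold counted as an ORA hit.
#' @param seed integer seed (drives background-window shuffling).
#' @param out_dir optional output directory; when given, all stage
#'   outputs are written as TSV plus `summary.json` and `manifest.json`.
#' @return list with `summary` (counts and headline results), `diff`,
#'   `proteins_by_direction`, `calibrated`, `flags`, `correlation`,
#'   `pca`, and when enabled `kinase_enrichment`, `family_summary`,
#'   `ora`.
#' @export
run_pipeline <- function(sites, proteins, design,
                         group_a = "caput", group_b = "cauda",
                         kinases = NULL, gene_sets = NULL,
                         loc_threshold = 0.75, alpha = 0.05,
                         fc_threshold = 1.5, log_scale = TRUE,
                         fpr = 0.02, n_background = 1000,
                         mat = default_substitution_matrix(),
                         ora_alpha = 0.05, seed = 1L, out_dir = NULL) {
  design <- .load_if_path(design, read_design)
  sites <- .load_if_path(sites, read_site_table, design = design)
  proteins <- .load_if_path(proteins, read_protein_table, design = design)
  kinases <- .load_if_path(kinases, read_kinase_reference)
  gene_sets <- .load_if_path(gene_sets, read_gmt)

  n_total <- nrow(sites)
  class1 <- filter_class1(sites, threshold = loc_threshold, quiet = TRUE)
  message("pipeline: ", n_total, " sites -> ", nrow(class1), " class I")

  site_m <- normalize_rows(quant_matrix(class1, design))
  prot_m <- normalize_rows(quant_matrix(proteins, design))
  site2prot <- stats::setNames(class1$protein_accession, class1$site_id)
  class1 <- class1[class1$site_id %in% rownames(site_m), , drop = FALSE]
  cal <- calibrate_sites(site_m, prot_m, site2prot)

  corr <- sample_correlation(cal$matrix)
  pca <- pca_project(cal$matrix, k = min(2L, ncol(cal$matrix)))

  diff <- classify_sites(cal$matrix, design, group_a, group_b,
                         alpha = alpha, fc_threshold = fc_threshold,
                         log_scale = log_scale)
  tested <- diff[!is.na(diff$p_value), , drop = FALSE]
  message("pipeline: ", nrow(tested), " tested, ",
          sum(diff$direction == "up"), " up / ",
          sum(diff$direction == "down"), " down at p<", alpha,
          " & FC>=", fc_threshold)

  prot_sum <- aggregate_proteins(diff, site2prot)

  universe <- tested$site_id
  up_ids <- diff$site_id[diff$direction == "up"]
  down_ids <- diff$site_id[diff$direction == "down"]

  enrich <- NULL
  fam <- NULL
  if (!is.null(kinases) && length(kinases)) {
    bg <- shuffle_background(class1$window, n_background, seed = seed)
    kinases <- lapply(kinases, calibrate_cutoff, background_windows = bg,
                      fpr = fpr, mat = mat)
    rel <- predict_substrates(class1[class1$site_id %in% universe, ,
                                     drop = FALSE], kinases, mat = mat)
    enrich <- kinase_enrichment(rel, kinases, up_ids, down_ids, universe)
    fam <- family_summary(enrich, alpha = alpha)
  }

  ora <- NULL
  if (!is.null(gene_sets) && length(gene_sets)) {
    bg_prot <- unique(site2prot[universe])
    hit_prot <- unique(site2prot[c(up_ids, down_ids)])
    ora <- ora_test(hit_prot, bg_prot, gene_sets)
  }

  top_kinases <- if (!is.null(enrich)) {
    lapply(c(up = "up", down = "down"), function(d) {
      e <- enrich[enrich$direction_set == d, ]
      utils::head(e$kinase[order(e$p_value, -e$n_substrates)], 5)
    })
  } else NULL

  summary <- list(
    n_sites_total = n_total,
    n_class1 = nrow(class1),
    n_tested = nrow(tested),
    n_p05_up = sum(tested$p_value < alpha & tested$fold_change > 1),
    n_p05_down = sum(tested$p_value < alpha & tested$fold_change < 1),
    n_p05 = sum(tested$p_value < alpha),
    n_up = length(up_ids), n_down = length(down_ids),
    n_ns = sum(diff$direction == "ns"),
    n_proteins_up_only = sum(prot_sum$category == "up-only"),
    n_proteins_down_only = sum(prot_sum$category == "down-only"),
    n_proteins_both = sum(prot_sum$category == "both"),
    top_kinases = top_kinases,
    n_ora_hits = if (!is.null(ora)) sum(ora$q_value < ora_alpha) else NULL,
    parameters = list(group_a = group_a, group_b = group_b,
                      loc_threshold = loc_threshold, alpha = alpha,
                      fc_threshold = fc_threshold, log_scale = log_scale,
                      fpr = fpr, n_background = n_background, seed = seed)
  )

  out <- list(summary = summary, diff = diff,
              proteins_by_direction = prot_sum,
              calibrated = cal$matrix, flags = cal$flags,
              correlation = corr, pca = pca,
              kinase_enrichment = enrich, family_summary = fam, ora = ora)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) {
      write_table_tsv(x, file.path(out_dir, f))
      f
    }
    files <- c(
      w(cbind(site_id = rownames(cal$matrix),
              as.data.frame(cal$matrix)), "calibrated.tsv"),
      w(cal$flags, "flags.tsv"),
      w(cbind(channel = rownames(corr), as.data.frame(corr)),
        "correlation.tsv"),
      w(cbind(channel = rownames(pca$scores),
              as.data.frame(pca$scores)), "pca_scores.tsv"),
      w(diff, "diff.tsv"),
      w(prot_sum, "proteins_by_direction.tsv"))
    if (!is.null(enrich)) files <- c(files, w(enrich, "kinase_enrichment.tsv"),
                                     w(fam, "family_summary.tsv"))
    if (!is.null(ora)) files <- c(files, w(ora, "ora.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- list(files = c(files, "summary.json"),
                     parameters = summary$parameters)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Compare inhibitor-induced and maturation-associated phosphosite sets
#'
#' Intersects the maturation-upregulated site set (`p < alpha`, any fold
#' change) with the inhibitor-downregulated site set (`p < alpha`) and
#' reports the overlap as a fraction of the maturation-up set. Both set
#' definitions deliberately use the p-value only, without the fold-change
#' filter, matching how inhibitor-response sets are defined; the
#' FC-filtered sets remain available from [classify_sites()] output.
#'
#' @param maturation_diff [classify_sites()] output for the maturation
#'   contrast (reference = caput, comparison = cauda, so up means higher
#'   in cauda).
#' @param inhibitor_diff [classify_sites()] output for the inhibitor
#'   contrast (reference = control, comparison = treated).
#' @param alpha significance threshold applied to both sets.
#' @return list with `n_maturation_up`, `n_inhibitor_down`,
#'   `intersection`, `fraction` and `percentage` (of the maturation-up
#'   set, 1 decimal).
#' @export
run_inhibitor_comparison <- function(maturation_diff, inhibitor_diff,
                                     alpha = 0.05) {
  mat_up <- maturation_diff$site_id[
    !is.na(maturation_diff$p_value) & maturation_diff$p_value < alpha &
      maturation_diff$fold_change > 1]
  inh_down <- inhibitor_diff$site_id[
    !is.na(inhibitor_diff$p_value) & inhibitor_diff$p_value < alpha &
      inhibitor_diff$fold_change < 1]
  if (!length(mat_up))
    stop("no maturation-upregulated sites at alpha = ", alpha)
  ov <- overlap_fraction(mat_up, inh_down)
  list(n_maturation_up = length(mat_up),
       n_inhibitor_down = length(inh_down),
       intersection = ov$intersection,
       fraction = ov$fraction,
       percentage = ov$percentage)
}
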