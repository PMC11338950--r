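# Synthetic TMT phosphoproteomics experiments with planted ground truth.
#
# The generator starts at the site-quantification table level (no spectra,
# isotopic impurity or peptide-to-site rollup) and emulates a 15-channel
# experiment: three epididymal regions (caput, corpus, cauda) x five
# biological replicates, ~10^3 phosphosites on ~10^2 proteins, an S/T/Y
# residue mix matching sperm phosphoproteomes, localization probabilities
# with a low-confidence tail, a fraction of sites whose parent protein is
# absent from the protein table, and group effects planted on sites --
# optionally driven by kinase recognition motifs.

#' Simulation configuration
#'
#' Validates and fills the parameters of the synthetic experiment
#' generator. Intensities follow a multiplicative (log-normal) error
#' model: `value = base * group_effect * 2^N(0, noise_sd_log2)`, so a
#' planted `effect_log2fc` is exact in expectation on the log2 scale.
#' The middle group receives half the planted effect, reproducing the
#' intermediate corpus phenotype between caput and cauda.
#'
#' @param n_proteins number of quantified proteins.
#' @param n_sites number of phosphosites.
#' @param n_channels_per_group replicates per group (default 5).
#' @param groups ordered group labels; the planted effect is the log2
#'   difference between the last and first group.
#' @param residue_props named proportions for S/T/Y, summing to 1. The
#'   default mix (89.1% pS, 10.24% pT, 0.66% pY) matches the class-I site
#'   composition observed in maturing mouse sperm.
#' @param frac_diff_sites fraction of sites with a planted group effect.
#' @param effect_log2fc planted log2 effect magnitude (last vs first group).
#' @param frac_protein_unquantified fraction of sites whose parent protein
#'   is absent from the protein table (triggering the calibration fallback).
#' @param noise_sd_log2 channel noise standard deviation on the log2 scale.
#' @param frac_low_localization fraction of null sites drawn from the
#'   low-confidence localization component (< 0.75); planted sites always
#'   receive probabilities > 0.9 so ground truth lies in the class-I
#'   (testable) fraction.
#' @param planted_kinases list of planted kinase activities; each element
#'   a list with `name`, `family`, `consensus` (15-char motif, `X` =
#'   wildcard, S/T/Y at center) and `direction` (`"up"` or `"down"`).
#' @param decoy_kinases like `planted_kinases` but without `direction`;
#'   included in the kinase reference with no planted substrate sites.
#' @param sites_per_kinase planted motif sites per active kinase, drawn
#'   from the matching-direction differential sites.
#' @param n_reference_windows reference substrate windows per kinase in
#'   the emitted kinase reference.
#' @param couple_protein_effect if `TRUE`, parent proteins of planted
#'   sites receive the same group effect as the site, so the phospho
#'   signal is explained by abundance and must vanish after calibration.
#' @param frac_missing fraction of intensity cells set missing at random.
#' @param seed integer seed; identical config + seed reproduces
#'   byte-identical outputs.
#' @return a validated `sim_config` list.
#' @export
simulation_config <- function(n_proteins = 200,
                              n_sites = 2000,
                              n_channels_per_group = 5,
                              groups = c("caput", "corpus", "cauda"),
                              residue_props = c(S = 0.891, T = 0.1024, Y = 0.0066),
                              frac_diff_sites = 0.1,
                              effect_log2fc = 1.5,
                              frac_protein_unquantified = 0.2,
                              noise_sd_log2 = 0.25,
                              frac_low_localization = 0.15,
                              planted_kinases = list(),
                              decoy_kinases = list(),
                              sites_per_kinase = 30,
                              n_reference_windows = 8,
                              couple_protein_effect = FALSE,
                              frac_missing = 0,
                              seed = 1L) {
  stopifnot_config <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg)
  stopifnot_config(length(n_proteins) == 1 && n_proteins >= 1, "n_proteins must be positive")
  stopifnot_config(length(n_sites) == 1 && n_sites >= 1, "n_sites must be positive")
  stopifnot_config(n_channels_per_group >= 1, "n_channels_per_group must be positive")
  stopifnot_config(length(groups) >= 2, "need at least two groups")
  stopifnot_config(length(residue_props) == 3 && all(residue_props >= 0),
                   "residue_props must be three nonnegative proportions")
  stopifnot_config(abs(sum(residue_props) - 1) <= 1e-9, "residue_props must sum to 1")
  stopifnot_config(frac_diff_sites >= 0 && frac_diff_sites <= 1,
                   "frac_diff_sites must be in [0, 1]")
  stopifnot_config(frac_protein_unquantified >= 0 && frac_protein_unquantified <= 1,
                   "frac_protein_unquantified must be in [0, 1]")
  stopifnot_config(frac_missing >= 0 && frac_missing < 1, "frac_missing must be in [0, 1)")
  stopifnot_config(effect_log2fc > 0, "effect_log2fc must be positive")
  stopifnot_config(noise_sd_log2 > 0, "noise_sd_log2 must be positive")
  if (is.null(names(residue_props))) names(residue_props) <- c("S", "T", "Y")
  for (pk in c(planted_kinases, decoy_kinases)) {
    stopifnot_config(nchar(pk$consensus) == 15, paste0("consensus of ", pk$name,
                                                       " must have length 15"))
    stopifnot_config(substr(pk$consensus, 8, 8) %in% c("S", "T", "Y"),
                     paste0("consensus of ", pk$name, " must center on S/T/Y"))
  }
  for (pk in planted_kinases)
    stopifnot_config(pk$direction %in% c("up", "down"),
                     paste0("direction of ", pk$name, " must be up or down"))
  structure(list(
    n_proteins = as.integer(n_proteins), n_sites = as.integer(n_sites),
    n_channels_per_group = as.integer(n_channels_per_group),
    groups = as.character(groups), residue_props = residue_props,
    frac_diff_sites = frac_diff_sites, effect_log2fc = effect_log2fc,
    frac_protein_unquantified = frac_protein_unquantified,
    noise_sd_log2 = noise_sd_log2,
    frac_low_localization = frac_low_localization,
    planted_kinases = planted_kinases, decoy_kinases = decoy_kinases,
    sites_per_kinase = as.integer(sites_per_kinase),
    n_reference_windows = as.integer(n_reference_windows),
    couple_protein_effect = couple_protein_effect,
    frac_missing = frac_missing, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate flanking windows matching a motif consensus
#'
#' @param consensus 15-character motif: fixed amino acids at constrained
#'   positions, `X` at wildcard positions, S/T/Y at the center (position 8).
#' @param n number of windows.
#' @param seed integer seed.
#' @return character vector of `n` 15-mers; wildcard positions are drawn
#'   uniformly from the 20 amino acids.
#' @export
generate_windows <- function(consensus, n, seed) {
  if (nchar(consensus) != 15)
    stop("consensus must have length 15")
  if (!substr(consensus, 8, 8) %in% c("S", "T", "Y"))
    stop("consensus center (position 8) must be S, T or Y")
  if (n == 0) return(character(0))
  set.seed(as.integer(seed))
  cons <- strsplit(consensus, "")[[1]]
  wild <- cons == "X"
  out <- matrix(rep(cons, n), nrow = n, byrow = TRUE)
  out[, wild] <- sample(AA20, n * sum(wild), replace = TRUE)
  apply(out, 1, paste, collapse = "")
}

#' A small kinase motif panel for simulations
#'
#' Stylised consensus motifs for common serine/threonine kinase families:
#' basophilic CAMK/AGC motifs (arginines upstream), proline-directed CMGC
#' motifs (+1 proline), and an acidophilic CK2-like motif. Intended as
#' planted activities and decoys for recovery experiments, not as curated
#' biological references.
#'
#' @return list of lists with `name`, `family`, `consensus`.
#' @export
default_kinase_panel <- function() {
  list(
    list(name = "CAMK2A", family = "CAMK", consensus = "XXXXRXXSXXXXXXX"),
    list(name = "CAMK4",  family = "CAMK", consensus = "XXXXRXXSXXDXXXX"),
    list(name = "TSSK2",  family = "CAMK", consensus = "XXXXRXXSXXXFXXX"),
    list(name = "PKACA",  family = "AGC",  consensus = "XXXXRRXSXXXXXXX"),
    list(name = "AKT1",   family = "AGC",  consensus = "XXRXRXXSXXXXXXX"),
    list(name = "CDK1",   family = "CMGC", consensus = "XXXXXXXSPXKXXXX"),
    list(name = "MAPK1",  family = "CMGC", consensus = "XXXXXPXSPXXXXXX"),
    list(name = "GSK3B",  family = "CMGC", consensus = "XXXXXXXSXXXSXXX"),
    list(name = "CSNK2A1", family = "Other", consensus = "XXXXXXXSXXEXEXX"),
    list(name = "CSNK1A1", family = "Other", consensus = "XXXXXXXSXXXEXXX"),
    list(name = "PLK1",   family = "Other", consensus = "XXDXEXXSXXXXXXX"),
    list(name = "ATM",    family = "Atypical", consensus = "XXXXXXXSQXXXXXX")
  )
}

.random_windows <- function(residues) {
  n <- length(residues)
  m <- matrix(sample(AA20, n * 15L, replace = TRUE), nrow = n)
  m[, 8L] <- residues
  apply(m, 1, paste, collapse = "")
}

#' Generate a complete synthetic TMT phosphoproteomics experiment
#'
#' Produces a site table, protein table, study design, kinase reference
#' and the ground-truth labels needed for recovery testing. Differential
#' sites carry a noiseless group-mean log2 difference of exactly
#' `effect_log2fc` between the last and first group (half that in the
#' middle group); protein intensities are generated independently of
#' their sites' effects unless `couple_protein_effect` is set.
#'
#' @param config a `sim_config` from [simulation_config()].
#' @return list with elements `sites`, `proteins`, `design`, `kinases`
#'   (named list of [kinase_spec()]) and `truth` (lists of planted up /
#'   down site ids, active kinase directions, per-kinase planted site
#'   ids, and unquantified protein ids).
#' @export
generate_experiment <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(simulation_config, config)
  set.seed(config$seed)
  ng <- length(config$groups)
  npg <- config$n_channels_per_group
  channels <- sprintf("C%02d", seq_len(ng * npg))
  design <- study_design(channels,
                         rep(config$groups, each = npg),
                         rep(seq_len(npg), times = ng))

  n_sites <- config$n_sites
  n_unq_sites <- round(config$frac_protein_unquantified * n_sites)
  acc_quant <- sprintf("P%05d", seq_len(config$n_proteins))
  n_unq_prot <- if (n_unq_sites > 0)
    max(1L, round(config$frac_protein_unquantified * config$n_proteins)) else 0L
  acc_unq <- if (n_unq_prot > 0) sprintf("U%05d", seq_len(n_unq_prot)) else character(0)

  # parent protein per site: a fixed count of sites point at proteins that
  # are absent from the protein table (calibration fallback path)
  parent <- character(n_sites)
  unq_idx <- if (n_unq_sites > 0) sort(sample.int(n_sites, n_unq_sites)) else integer(0)
  parent[unq_idx] <- sample(acc_unq, n_unq_sites, replace = TRUE)
  parent[setdiff(seq_len(n_sites), unq_idx)] <-
    sample(acc_quant, n_sites - n_unq_sites, replace = TRUE)

  residue <- sample(names(config$residue_props), n_sites, replace = TRUE,
                    prob = config$residue_props)

  # planted differential sites, split equally between up and down
  n_diff <- round(config$frac_diff_sites * n_sites)
  n_up <- ceiling(n_diff / 2)
  n_down <- n_diff - n_up
  shuffled <- sample.int(n_sites)
  up_idx <- shuffled[seq_len(n_up)]
  down_idx <- shuffled[n_up + seq_len(n_down)]

  # planted kinase activities claim motif sites among the matching-direction
  # differential sites
  kin_sites <- list()
  window <- .random_windows(residue)
  avail <- list(up = up_idx, down = down_idx)
  for (pk in config$planted_kinases) {
    take <- min(config$sites_per_kinase, length(avail[[pk$direction]]))
    idx <- avail[[pk$direction]][seq_len(take)]
    avail[[pk$direction]] <- setdiff(avail[[pk$direction]], idx)
    residue[idx] <- substr(pk$consensus, 8, 8)
    window[idx] <- generate_windows(pk$consensus, length(idx),
                                    seed = sample.int(.Machine$integer.max, 1))
    kin_sites[[pk$name]] <- idx
  }

  position <- sample.int(3000L, n_sites, replace = TRUE)
  site_id <- paste0(parent, "_", residue, position)
  while (anyDuplicated(site_id)) {
    dup <- duplicated(site_id)
    position[dup] <- sample.int(3000L, sum(dup), replace = TRUE)
    site_id <- paste0(parent, "_", residue, position)
  }

  # localization probabilities: high-confidence mass above 0.9, a tail of
  # null sites below the 0.75 class-I threshold
  is_diff <- logical(n_sites)
  is_diff[c(up_idx, down_idx)] <- TRUE
  loc <- 0.901 + 0.099 * stats::runif(n_sites)
  low <- !is_diff & stats::runif(n_sites) < config$frac_low_localization
  loc[low] <- 0.2 + 0.549 * stats::runif(sum(low))

  # group effect profile per site: linear in log2 from first to last group
  grade <- seq(0, 1, length.out = ng)
  eff_log2 <- numeric(n_sites)
  eff_log2[up_idx] <- config$effect_log2fc
  eff_log2[down_idx] <- -config$effect_log2fc
  group_of_channel <- match(design$group, config$groups)

  base_site <- 2^stats::rnorm(n_sites, mean = 20, sd = 1.5)
  noise <- matrix(2^stats::rnorm(n_sites * length(channels),
                                 sd = config$noise_sd_log2),
                  nrow = n_sites)
  effect_mat <- 2^(outer(eff_log2, grade[group_of_channel]))
  site_int <- base_site * effect_mat * noise

  if (config$frac_missing > 0) {
    drop <- stats::runif(length(site_int)) < config$frac_missing
    site_int[drop] <- NA_real_
  }
  colnames(site_int) <- channels

  sites <- data.frame(
    site_id = site_id, protein_accession = parent, position = position,
    residue = residue, localization_prob = round(loc, 4), window = window,
    stringsAsFactors = FALSE
  )
  sites <- cbind(sites, as.data.frame(site_int))

  base_prot <- 2^stats::rnorm(config$n_proteins, mean = 22, sd = 1.5)
  pnoise <- matrix(2^stats::rnorm(config$n_proteins * length(channels),
                                  sd = config$noise_sd_log2),
                   nrow = config$n_proteins)
  prot_int <- base_prot * pnoise
  if (config$couple_protein_effect && length(c(up_idx, down_idx))) {
    peff <- numeric(config$n_proteins)
    for (i in c(up_idx, down_idx)) {
      j <- match(parent[i], acc_quant)
      if (!is.na(j) && peff[j] == 0) peff[j] <- eff_log2[i]
    }
    prot_int <- prot_int * 2^(outer(peff, grade[group_of_channel]))
  }
  colnames(prot_int) <- channels
  proteins <- cbind(data.frame(protein_accession = acc_quant,
                               stringsAsFactors = FALSE),
                    as.data.frame(prot_int))

  all_kin <- c(config$planted_kinases, config$decoy_kinases)
  kinases <- list()
  for (pk in all_kin) {
    refs <- generate_windows(pk$consensus, config$n_reference_windows,
                             seed = sample.int(.Machine$integer.max, 1))
    kinases[[pk$name]] <- kinase_spec(pk$name, pk$family, refs)
  }

  truth <- list(
    diff_site_ids_up = site_id[up_idx],
    diff_site_ids_down = site_id[down_idx],
    active_kinases = stats::setNames(
      vapply(config$planted_kinases, `[[`, "", "direction"),
      vapply(config$planted_kinases, `[[`, "", "name")),
    kinase_site_ids = lapply(kin_sites, function(i) site_id[i]),
    unquantified_protein_ids = unique(parent[unq_idx])
  )
  list(sites = sites, proteins = proteins, design = design,
       kinases = kinases, truth = truth)
}

#' Write a generated experiment to a directory
#'
#' Emits the same TSV dialects the readers consume (`sites.tsv`,
#' `proteins.tsv`, `design.tsv`, `kinases.tsv`) plus the ground truth as
#' `ground_truth.json`.
#'
#' @param experiment output of [generate_experiment()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_tsv(experiment$sites, file.path(dir, "sites.tsv"))
  write_table_tsv(experiment$proteins, file.path(dir, "proteins.tsv"))
  write_design(experiment$design, file.path(dir, "design.tsv"))
  if (length(experiment$kinases))
    write_kinase_reference(experiment$kinases, file.path(dir, "kinases.tsv"))
  jsonlite::write_json(experiment$truth, file.path(dir, "ground_truth.json"))
  invisible(dir)
}
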