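# Filtering, normalization and protein-level calibration of TMT reporter
# intensities, plus sample-level QC (correlation matrix, PCA).

#' Build a quant matrix from a site or protein table
#'
#' @param x table from [read_site_table()] / [read_protein_table()] or the
#'   generator.
#' @param design study design giving channel order.
#' @param id_col column holding row ids (`site_id` or `protein_accession`).
#' @return numeric matrix (rows = ids, columns = design channels) with a
#'   `level_tag` attribute (`"raw"`).
#' @export
quant_matrix <- function(x, design, id_col = if ("site_id" %in% names(x))
  "site_id" else "protein_accession") {
  miss <- setdiff(design$channel, names(x))
  if (length(miss))
    stop("table lacks intensity column(s): ", paste(miss, collapse = ", "))
  m <- as.matrix(x[, design$channel, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x[[id_col]]
  attr(m, "level_tag") <- "raw"
  m
}

#' Filter to class-I phosphosites
#'
#' Retains sites whose phosphate-localization probability meets the
#' class-I threshold (0.75 by default). The boundary is inclusive,
#' following the standard class-I definition; set `inclusive = FALSE`
#' for a strict `>` cut.
#'
#' @param sites a site table.
#' @param threshold localization-probability threshold in \[0, 1\].
#' @param inclusive whether sites exactly at the threshold are retained.
#' @param quiet suppress the retained/removed message.
#' @return the retained rows of `sites`, input order preserved.
#' @export
filter_class1 <- function(sites, threshold = 0.75, inclusive = TRUE,
                          quiet = FALSE) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  keep <- if (inclusive) sites$localization_prob >= threshold
          else sites$localization_prob > threshold
  keep[is.na(keep)] <- FALSE
  if (!quiet)
    message("filter_class1: retained ", sum(keep), " of ", length(keep),
            " sites (removed ", sum(!keep), ")")
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Row-mean normalization
#'
#' Divides each row by the mean of its non-missing values, so every
#' complete row has mean exactly 1 across channels. Rows that are all
#' missing or have no positive values cannot be normalized and are
#' dropped with a warning.
#'
#' @param m a quant matrix.
#' @return the normalized matrix, `level_tag = "normalized"`.
#' @export
normalize_rows <- function(m) {
  mu <- rowMeans(m, na.rm = TRUE)
  bad <- !is.finite(mu) | mu <= 0
  if (any(bad)) {
    warning("normalize_rows: dropped ", sum(bad),
            " row(s) with no positive non-missing values")
    m <- m[!bad, , drop = FALSE]
    mu <- mu[!bad]
  }
  out <- m / mu
  attr(out, "level_tag") <- "normalized"
  out
}

#' Calibrate phosphosite levels by protein abundance
#'
#' Divides each normalized site value by the normalized expression of its
#' parent protein at the same channel, removing the contribution of
#' protein-abundance changes to apparent phosphorylation changes. For
#' sites whose parent protein was not quantified, the normalized site
#' level is carried through unchanged and flagged. Division by a missing
#' or nonpositive protein value yields a missing value (the fallback
#' applies only when the protein row is absent altogether).
#'
#' @param site_m normalized site quant matrix.
#' @param prot_m normalized protein quant matrix.
#' @param site_to_protein named character vector mapping site ids to
#'   parent protein accessions (e.g. from the site table).
#' @return list with `matrix` (`level_tag = "calibrated"`) and `flags`, a
#'   `data.frame(site_id, protein_quantified)`.
#' @export
calibrate_sites <- function(site_m, prot_m, site_to_protein) {
  if (!identical(colnames(site_m), colnames(prot_m)))
    stop("site and protein matrices must share the same channel columns")
  acc <- site_to_protein[rownames(site_m)]
  if (anyNA(acc))
    stop("no parent accession for site(s): ",
         paste(utils::head(rownames(site_m)[is.na(acc)], 5), collapse = ", "))
  j <- match(acc, rownames(prot_m))
  quantified <- !is.na(j)
  out <- site_m
  if (any(quantified)) {
    denom <- prot_m[j[quantified], , drop = FALSE]
    denom[!is.na(denom) & denom <= 0] <- NA_real_
    out[quantified, ] <- site_m[quantified, , drop = FALSE] / denom
  }
  attr(out, "level_tag") <- "calibrated"
  list(matrix = out,
       flags = data.frame(site_id = rownames(site_m),
                          protein_quantified = quantified,
                          stringsAsFactors = FALSE))
}

#' Channel-channel Pearson correlation
#'
#' Pairwise-complete Pearson correlations between channels; pairs with
#' fewer than 3 complete rows are set missing with a warning.
#'
#' @param m a quant matrix (rows = features, columns = channels).
#' @return symmetric channel x channel correlation matrix, diagonal 1.
#' @export
sample_correlation <- function(m) {
  r <- stats::cor(m, use = "pairwise.complete.obs")
  ok <- !is.na(m)
  npair <- crossprod(ok)
  few <- npair < 3
  if (any(few & upper.tri(few))) {
    warning("sample_correlation: ", sum(few & upper.tri(few)),
            " channel pair(s) with < 3 complete rows set to NA")
    r[few] <- NA_real_
  }
  diag(r) <- 1
  r
}

#' Project channels onto principal components
#'
#' Channels (samples) are the observations and sites/proteins the
#' features; features are centered but not scaled (values are already
#' ratio-normalized to a common scale). Rows with any missing value are
#' excluded.
#'
#' @param m a quant matrix.
#' @param k number of components to return.
#' @return list with `scores` (channels x k) and `variance_explained`
#'   (length-k fractions, nonincreasing, summing to <= 1).
#' @export
pca_project <- function(m, k = 2) {
  if (k > ncol(m)) stop("k exceeds the number of channels")
  complete <- stats::complete.cases(m)
  if (sum(complete) < 2) stop("need at least 2 complete rows for PCA")
  p <- stats::prcomp(t(m[complete, , drop = FALSE]), center = TRUE,
                     scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  k <- min(k, ncol(p$x))
  list(scores = p$x[, seq_len(k), drop = FALSE],
       variance_explained = ve[seq_len(k)])
}
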