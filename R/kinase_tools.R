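# Motif-based kinase-substrate prediction over +/-7 flanking windows
# (GPS-style substitution-matrix similarity with FPR-calibrated cutoffs)
# and Fisher's-exact kinase enrichment with family rollup.

#' Construct a kinase specification
#'
#' A kinase's known substrate flanking windows, family label, and (after
#' [calibrate_cutoff()]) its score cutoff. The residue class is inferred
#' from the reference window centers: `ST` for serine/threonine kinases,
#' `Y` for tyrosine kinases.
#'
#' @param name kinase name.
#' @param family kinase family label (e.g. CAMK, CMGC, AGC).
#' @param reference_windows nonempty character vector of 15-mer substrate
#'   windows with S/T/Y centers.
#' @param cutoff optional precalibrated score cutoff.
#' @return a `kinase_spec` list.
#' @export
kinase_spec <- function(name, family, reference_windows, cutoff = NA_real_) {
  if (!length(reference_windows)) stop("kinase ", name,
                                       " needs at least one reference window")
  centres <- .check_window(reference_windows,
                           where = paste0("kinase ", name))
  if (!all(centres %in% c("S", "T", "Y")))
    stop("kinase ", name, ": reference windows must center on S/T/Y")
  residue_class <- if (all(centres == "Y")) "Y" else "ST"
  structure(list(name = name, family = family,
                 reference_windows = reference_windows,
                 residue_class = residue_class, cutoff = cutoff),
            class = "kinase_spec")
}

.window_codes <- function(windows, mat) {
  alph <- rownames(mat)
  m <- matrix(match(unlist(strsplit(windows, "")), c(alph, "_")),
              ncol = 15L, byrow = TRUE)
  if (anyNA(m))
    stop("window contains character(s) outside the substitution alphabet")
  m  # padding "_" encoded as length(alph) + 1
}

# Substitution matrix augmented with a zero-scoring padding row/column, so
# any position involving the "_" terminus padding contributes 0.
.pad_matrix <- function(mat) {
  n <- nrow(mat)
  out <- rbind(cbind(mat, 0), 0)
  dimnames(out) <- list(c(rownames(mat), "_"), c(colnames(mat), "_"))
  out
}

#' Similarity of two flanking windows
#'
#' Position-summed substitution-matrix similarity over the 15 aligned
#' positions; positions involving the terminus-padding character `_`
#' contribute 0.
#'
#' @param w1,w2 15-character windows.
#' @param mat substitution matrix (default BLOSUM62).
#' @return numeric similarity score.
#' @export
window_similarity <- function(w1, w2, mat = default_substitution_matrix()) {
  pm <- .pad_matrix(mat)
  c1 <- .window_codes(w1, mat)
  c2 <- .window_codes(w2, mat)
  sum(pm[cbind(as.vector(c1), as.vector(c2))])
}

# Vectorised scoring: windows (n x 15 codes) against one kinase's
# reference windows; returns the mean over references per window.
.score_windows <- function(codes, ref_codes, pm) {
  n <- nrow(codes)
  total <- numeric(n)
  for (r in seq_len(nrow(ref_codes))) {
    s <- 0
    for (p in 1:15) total <- total + pm[cbind(codes[, p], ref_codes[r, p])]
  }
  total / nrow(ref_codes)
}

#' Score a site's window against a kinase
#'
#' Mean of [window_similarity()] between the query window and each of the
#' kinase's reference substrate windows.
#'
#' @param window 15-character query window.
#' @param kinase a [kinase_spec()].
#' @param mat substitution matrix.
#' @return numeric score.
#' @export
score_site <- function(window, kinase, mat = default_substitution_matrix()) {
  mean(vapply(kinase$reference_windows, window_similarity, 0,
              w1 = window, mat = mat))
}

#' Calibrate a kinase's score cutoff to a background false-positive rate
#'
#' Chooses the lowest cutoff such that the fraction of background windows
#' scoring at or above it does not exceed `fpr` (ties resolved upward: a
#' tied block that would overshoot the budget pushes the cutoff up). For
#' `fpr` below `1/n` the cutoff exceeds every background score.
#'
#' @param kinase a [kinase_spec()].
#' @param background_windows nonempty character vector of background
#'   15-mers (e.g. residue-shuffled experimental windows).
#' @param fpr nominal false-positive rate in (0, 1].
#' @param mat substitution matrix.
#' @return the kinase spec with its `cutoff` field set.
#' @export
calibrate_cutoff <- function(kinase, background_windows, fpr = 0.02,
                             mat = default_substitution_matrix()) {
  if (fpr <= 0 || fpr > 1) stop("fpr must be in (0, 1]")
  if (!length(background_windows)) stop("background must be nonempty")
  pm <- .pad_matrix(mat)
  codes <- .window_codes(background_windows, mat)
  refs <- .window_codes(kinase$reference_windows, mat)
  scores <- .score_windows(codes, refs, pm)
  n <- length(scores)
  allowed <- floor(fpr * n)
  u <- sort(unique(scores), decreasing = TRUE)
  counts <- cumsum(tabulate(match(scores, u), nbins = length(u)))
  ok <- which(counts <= allowed)
  kinase$cutoff <- if (length(ok)) u[max(ok)] else
    u[1] + max(1e-9, abs(u[1]) * 1e-9)
  kinase
}

#' Predict kinase substrates among quantified sites
#'
#' For each calibrated kinase, the set of class-I sites whose center
#' residue matches the kinase's residue class (S/T for serine/threonine
#' kinases, Y for tyrosine kinases) and whose window scores at or above
#' the kinase's cutoff.
#'
#' @param sites site table (class-I filtered).
#' @param kinases named list of calibrated [kinase_spec()] objects.
#' @param mat substitution matrix.
#' @return named list: per kinase, the character vector of predicted
#'   substrate site ids.
#' @export
predict_substrates <- function(sites, kinases,
                               mat = default_substitution_matrix()) {
  pm <- .pad_matrix(mat)
  codes <- .window_codes(sites$window, mat)
  out <- list()
  for (k in kinases) {
    if (is.na(k$cutoff))
      stop("kinase ", k$name, " has no calibrated cutoff")
    gate <- if (k$residue_class == "Y") sites$residue == "Y"
            else sites$residue %in% c("S", "T")
    refs <- .window_codes(k$reference_windows, mat)
    sc <- .score_windows(codes, refs, pm)
    out[[k$name]] <- sites$site_id[gate & sc >= k$cutoff]
  }
  out
}

#' Fisher's exact kinase enrichment
#'
#' Builds the 2x2 table contrasting regulated sites against the remainder
#' of the tested site universe, split by predicted-substrate status, and
#' computes the one-sided (enrichment) Fisher exact p-value via the
#' hypergeometric upper tail.
#'
#' @param predicted predicted substrate site ids (subset of `universe`).
#' @param regulated regulated (e.g. significantly up) site ids, a subset
#'   of `universe`.
#' @param universe all tested site ids.
#' @return list with counts `a` (regulated substrates), `b` (regulated
#'   non-substrates), `c` (non-regulated substrates), `d` (the rest),
#'   `odds_ratio` (`ad/bc`, `Inf` when `bc = 0` and `a > 0`) and
#'   `p_value`.
#' @export
fisher_enrich <- function(predicted, regulated, universe) {
  universe <- unique(universe)
  regulated <- unique(regulated)
  predicted <- unique(predicted)
  if (!all(regulated %in% universe))
    stop("regulated sites must be a subset of the universe")
  predicted <- intersect(predicted, universe)
  a <- length(intersect(regulated, predicted))
  b <- length(regulated) - a
  c_ <- length(predicted) - a
  d <- length(universe) - a - b - c_
  # P(X >= a) with X ~ Hypergeom(N = a+b+c+d, K = a+c, n = a+b)
  p <- stats::phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
  or <- if (b * c_ == 0) {
    if (a > 0 && d >= 0) Inf else 0
  } else (a * d) / (b * c_)
  if (a == 0) or <- 0
  list(a = a, b = b, c = c_, d = d, odds_ratio = or, p_value = p)
}

#' Run kinase enrichment for up- and down-regulated site sets
#'
#' Up-set and down-set enrichment are two separate analyses sharing the
#' same universe (all tested class-I sites).
#'
#' @param relations named list of predicted substrate id sets, as from
#'   [predict_substrates()].
#' @param kinases named list of [kinase_spec()] objects (for families).
#' @param up_sites,down_sites regulated site id sets.
#' @param universe all tested site ids.
#' @return `data.frame` with one row per kinase x direction-set:
#'   `kinase`, `family`, `direction_set`, `a`,`b`,`c`,`d`, `odds_ratio`,
#'   `p_value`, `n_substrates`, ordered by p-value with substrate count
#'   as tiebreak.
#' @export
kinase_enrichment <- function(relations, kinases, up_sites, down_sites,
                              universe) {
  rows <- list()
  for (nm in names(relations)) {
    if (is.null(kinases[[nm]])) stop("unknown kinase in relations: ", nm)
    for (dir in c("up", "down")) {
      reg <- if (dir == "up") up_sites else down_sites
      fe <- fisher_enrich(relations[[nm]], reg, universe)
      rows[[length(rows) + 1L]] <- data.frame(
        kinase = nm, family = kinases[[nm]]$family, direction_set = dir,
        a = fe$a, b = fe$b, c = fe$c, d = fe$d,
        odds_ratio = fe$odds_ratio, p_value = fe$p_value,
        n_substrates = length(relations[[nm]]), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$direction_set, out$p_value, -out$n_substrates), ]
  rownames(out) <- NULL
  out
}

#' Family rollup of kinase enrichment results
#'
#' Counts, per kinase family, the kinases significantly enriched in the
#' up-set analysis and in the down-set analysis.
#'
#' @param enrichment output of [kinase_enrichment()].
#' @param alpha significance level on the enrichment p-value.
#' @return `data.frame(family, n_enriched_up, n_enriched_down)`.
#' @export
family_summary <- function(enrichment, alpha = 0.05) {
  fams <- sort(unique(enrichment$family))
  sig <- enrichment$p_value < alpha
  up <- vapply(fams, function(f)
    sum(sig & enrichment$family == f & enrichment$direction_set == "up"), 0L)
  down <- vapply(fams, function(f)
    sum(sig & enrichment$family == f & enrichment$direction_set == "down"), 0L)
  data.frame(family = fams, n_enriched_up = up, n_enriched_down = down,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Residue-shuffled background windows
#'
#' Shuffles the flanking positions of the experiment's own quantified
#' windows while keeping the center residue fixed, giving a background
#' that matches the experiment's amino-acid composition without external
#' data.
#'
#' @param windows observed 15-mer windows.
#' @param n number of background windows to generate.
#' @param seed integer seed.
#' @return character vector of `n` shuffled windows.
#' @export
shuffle_background <- function(windows, n, seed) {
  set.seed(as.integer(seed))
  chars <- matrix(unlist(strsplit(windows, "")), ncol = 15L, byrow = TRUE)
  flank <- as.vector(chars[, -8L])
  flank <- flank[flank != "_"]
  centres <- sample(chars[, 8L], n, replace = TRUE)
  m <- matrix(sample(flank, n * 14L, replace = TRUE), nrow = n)
  out <- cbind(m[, 1:7, drop = FALSE], centres, m[, 8:14, drop = FALSE])
  apply(out, 1, paste, collapse = "")
}
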