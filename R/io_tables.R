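# Standard column names of the minimal site-table dialect. Real MaxQuant
# "Phospho (STY)Sites.txt" exports can be ingested by passing `col_map`
# aliases, decoupling the pipeline from MaxQuant version drift.
.SITE_COLS <- c(
  site_id = "site_id", protein_accession = "protein_accession",
  position = "position", residue = "residue",
  localization_prob = "localization_prob", window = "window"
)

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "W", "Y", "V")

#' Construct a study design
#'
#' The channel-to-sample map that drives all grouping: one row per TMT
#' reporter channel, giving its group label and replicate index. Channel
#' order here is authoritative for every intensity matrix in the pipeline;
#' file column order never is.
#'
#' @param channels character vector of channel ids (ordered).
#' @param groups group label per channel.
#' @param replicates replicate index per channel.
#' @return A `data.frame` with columns `channel`, `group`, `replicate`.
#' @export
study_design <- function(channels, groups, replicates) {
  channels <- as.character(channels)
  groups <- as.character(groups)
  replicates <- as.integer(replicates)
  if (length(channels) != length(groups) || length(channels) != length(replicates))
    stop("channels, groups and replicates must have equal length")
  if (anyDuplicated(channels))
    stop("duplicate channel ids in design")
  key <- paste(groups, replicates)
  if (anyDuplicated(key))
    stop("each (group, replicate) pair must be unique")
  data.frame(channel = channels, group = groups, replicate = replicates,
             stringsAsFactors = FALSE)
}

#' Read a study design table
#'
#' @param path TSV with columns `channel`, `group`, `replicate`.
#' @return A design `data.frame` as from [study_design()].
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("channel", "group", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("design file missing column(s): ", paste(miss, collapse = ", "))
  study_design(d$channel, d$group, d$replicate)
}

#' @rdname read_design
#' @param design a design `data.frame`.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.check_window <- function(window, residue = NULL, where = "window") {
  bad <- nchar(window) != 15L
  if (any(bad))
    stop(where, ": windows must be exactly 15 characters (rows ",
         paste(utils::head(which(bad), 5), collapse = ", "), ")")
  centre <- substr(window, 8L, 8L)
  if (!is.null(residue) && any(centre != residue))
    stop(where, ": window center must equal the site residue")
  invisible(centre)
}

.parse_intensities <- function(d, design, path) {
  miss_ch <- setdiff(design$channel, names(d))
  if (length(miss_ch))
    stop("missing intensity column(s): ", paste(miss_ch, collapse = ", "))
  # channel order always taken from the design, never from the file
  m <- as.matrix(d[, design$channel, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  m
}

#' Read a phosphosite quantification table
#'
#' A minimal named-column TSV dialect of the MaxQuant site table: one row
#' per phosphosite with identity, residue, localization probability, the
#' +/-7 flanking sequence window, and one reporter-intensity column per
#' design channel. Missing intensities are encoded as empty cells or `NA`
#' and parsed to `NA`, never to 0 (0 would be a legitimate-looking but
#' wrong denominator downstream).
#'
#' @param path path to the TSV file.
#' @param design study design (see [study_design()]); channel order is taken
#'   from here, not from file column order.
#' @param col_map optional named character vector aliasing standard column
#'   names (names) to the file's column names (values), e.g.
#'   `c(localization_prob = "Localization prob")`.
#' @return `data.frame` with the standard site columns followed by one
#'   numeric intensity column per channel.
#' @export
read_site_table <- function(path, design, col_map = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("NA", ""))
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      j <- match(col_map[[std]], names(d))
      if (!is.na(j)) names(d)[j] <- std
    }
  }
  miss <- setdiff(unname(.SITE_COLS), names(d))
  if (length(miss))
    stop("site table missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$site_id))
    stop("duplicate site_id in site table: ",
         paste(utils::head(unique(d$site_id[duplicated(d$site_id)]), 5),
               collapse = ", "))
  bad_res <- !d$residue %in% c("S", "T", "Y")
  if (any(bad_res))
    stop("residue must be one of S/T/Y (rows ",
         paste(utils::head(which(bad_res), 5), collapse = ", "), ")")
  .check_window(d$window, d$residue, where = "site table")
  lp <- suppressWarnings(as.numeric(d$localization_prob))
  n_bad <- sum(is.na(lp) & !is.na(d$localization_prob))
  if (n_bad > 0)
    message("read_site_table: skipped ", n_bad,
            " row(s) with unparseable localization probability")
  keep <- !(is.na(lp))
  if (any(lp[keep] < 0 | lp[keep] > 1))
    stop("localization probability outside [0, 1]")
  m <- .parse_intensities(d, design, path)
  out <- data.frame(
    site_id = as.character(d$site_id),
    protein_accession = as.character(d$protein_accession),
    position = as.integer(d$position),
    residue = as.character(d$residue),
    localization_prob = lp,
    window = as.character(d$window),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(m))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a protein quantification table
#'
#' @param path TSV with `protein_accession` plus one intensity column per
#'   design channel.
#' @inheritParams read_site_table
#' @return `data.frame` with `protein_accession` and per-channel intensities.
#' @export
read_protein_table <- function(path, design, col_map = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("NA", ""))
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      j <- match(col_map[[std]], names(d))
      if (!is.na(j)) names(d)[j] <- std
    }
  }
  if (!"protein_accession" %in% names(d))
    stop("protein table missing required column(s): protein_accession")
  if (anyDuplicated(d$protein_accession))
    stop("duplicate protein_accession in protein table")
  m <- .parse_intensities(d, design, path)
  out <- data.frame(protein_accession = as.character(d$protein_accession),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(m))
}

#' Write a site or protein table
#'
#' Inverse of [read_site_table()] / [read_protein_table()]: missing
#' intensities are written as `NA`.
#'
#' @param x table as returned by the readers (or the generator).
#' @param path output TSV path.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members. Duplicate members within a line are collapsed.
#'
#' @param path path to a `.gmt` file.
#' @return named list of gene sets; each element a list with `name`,
#'   `description` and character vector `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop("GMT line ", i, " has no members")
    out[[i]] <- list(name = f[[1]], description = f[[2]], members = members)
  }
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' @rdname read_gmt
#' @param sets a list of gene sets as returned by `read_gmt`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$description, s$members), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a kinase reference of substrate flanking windows
#'
#' TSV with columns `kinase`, `family`, `window` (one 15-mer reference
#' substrate window per row); rows are grouped per kinase into a
#' `kinase_spec`. The residue class each kinase phosphorylates (`ST` or
#' `Y`) is inferred from the centers of its reference windows.
#'
#' @param path path to the reference TSV.
#' @return named list of `kinase_spec` objects (see [kinase_spec()]).
#' @export
read_kinase_reference <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("kinase", "family", "window")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("kinase reference missing column(s): ", paste(miss, collapse = ", "))
  .check_window(d$window, where = "kinase reference")
  specs <- lapply(split(d, d$kinase), function(g) {
    fam <- unique(g$family)
    if (length(fam) > 1L)
      stop("kinase ", g$kinase[[1]], " has conflicting family labels")
    kinase_spec(g$kinase[[1]], fam, g$window)
  })
  specs[order(names(specs))]
}

#' @rdname read_kinase_reference
#' @param specs named list of `kinase_spec` objects.
#' @export
write_kinase_reference <- function(specs, path) {
  d <- do.call(rbind, lapply(specs, function(s)
    data.frame(kinase = s$name, family = s$family, window = s$reference_windows,
               stringsAsFactors = FALSE)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix layout used by NCBI BLAST (`#` comment
#' lines, a header row of residue letters, one labelled row per residue).
#' The default scoring matrix used elsewhere in the package is BLOSUM62 as
#' distributed with Biostrings; this reader admits user-supplied matrices.
#'
#' @param path path to the matrix file.
#' @return numeric matrix with residue dimnames.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a substitution matrix: ", path)
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  lab <- vapply(rows, `[[`, "", 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(header))))
  dimnames(vals) <- list(lab, header)
  if (!identical(sort(lab), sort(header)))
    stop("substitution matrix rows and columns disagree")
  vals
}

#' Default substitution matrix (BLOSUM62)
#'
#' @return the BLOSUM62 scoring matrix.
#' @export
default_substitution_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}
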