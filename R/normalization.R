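#' Row-mean normalize an intensity matrix
#'
#' Divides every row by its own mean over non-missing entries, so each
#' normalized row has mean 1. Applied to both the protein and the
#' phosphosite matrix before calibration.
#'
#' @param matrix numeric matrix (rows = proteins or sites, cols = samples);
#'   missing values allowed.
#' @return matrix of the same shape; row means over non-missing entries are 1.
#' @export
rowmean_normalize <- function(matrix) {
  stopifnot(is.matrix(matrix))
  rm <- rowMeans(matrix, na.rm = TRUE)
  bad <- !is.finite(rm)
  if (any(bad)) {
    stop("row(s) with no non-missing values: ",
         paste(rownames(matrix)[bad], collapse = ", "), call. = FALSE)
  }
  matrix / rm
}

#' Replace zeros in a raw protein matrix
#'
#' A protein intensity of exactly zero in any sample would make the
#' calibration ratio undefined, so every zero cell is replaced by the lowest
#' non-zero value of the whole protein matrix before normalization. Must be
#' applied to the raw (pre-normalization) protein matrix; the site matrix is
#' never zero-replaced (site zeros are treated as missing upstream).
#'
#' @param matrix raw protein intensity matrix.
#' @return matrix with all exact zeros replaced by the global minimum
#'   non-zero value.
#' @export
replace_zeros <- function(matrix) {
  stopifnot(is.matrix(matrix))
  nz <- matrix[!is.na(matrix) & matrix > 0]
  if (!length(nz)) {
    stop("protein matrix has no non-zero values", call. = FALSE)
  }
  matrix[!is.na(matrix) & matrix == 0] <- min(nz)
  matrix
}

#' Calibrate phosphosite levels against protein abundance
#'
#' Separates phosphorylation changes from protein-level changes by dividing
#' each row-mean-normalized site value by the row-mean-normalized level of
#' its parent protein in the same sample. Sites whose protein was not
#' quantified keep their normalized site level and are flagged
#' `"site_only"`; all others are flagged `"calibrated"`. Missing values
#' propagate pairwise (a missing site or protein cell gives a missing
#' calibrated cell).
#'
#' @param site_norm row-mean-normalized site matrix (rownames = site ids).
#' @param protein_norm row-mean-normalized protein matrix with zeros already
#'   replaced before normalization (an exact zero here is an error).
#' @param site_to_protein named character vector site_id -> protein_id.
#' @return object of class `calibrated_matrix`: list with `values` (matrix)
#'   and `provenance` (named character, `"calibrated"` or `"site_only"`).
#' @export
calibrate_sites <- function(site_norm, protein_norm, site_to_protein) {
  stopifnot(is.matrix(site_norm), is.matrix(protein_norm),
            identical(colnames(site_norm), colnames(protein_norm)))
  if (any(protein_norm == 0, na.rm = TRUE)) {
    stop("protein matrix contains exact zeros; run replace_zeros() on the ",
         "raw matrix before normalization", call. = FALSE)
  }
  sites <- rownames(site_norm)
  prot <- unname(site_to_protein[sites])
  if (anyNA(prot)) {
    stop("site(s) missing from the site-to-protein map: ",
         paste(sites[is.na(prot)], collapse = ", "), call. = FALSE)
  }
  have_prot <- prot %in% rownames(protein_norm)
  values <- site_norm
  if (any(have_prot)) {
    values[have_prot, ] <- site_norm[have_prot, , drop = FALSE] /
      protein_norm[prot[have_prot], , drop = FALSE]
  }
  provenance <- stats::setNames(
    ifelse(have_prot, "calibrated", "site_only"), sites)
  structure(list(values = values, provenance = provenance),
            class = "calibrated_matrix")
}

#' @export
print.calibrated_matrix <- function(x, ...) {
  cat("Calibrated phosphosite matrix:", nrow(x$values), "sites x",
      ncol(x$values), "samples;",
      sum(x$provenance == "site_only"), "site-only fallback rows\n")
  invisible(x)
}

#' Run the full calibration chain
#'
#' Fixed order of operations: protein zero replacement, row-mean
#' normalization of proteins and sites, then site-by-protein calibration.
#'
#' @param site_raw raw site intensity matrix.
#' @param protein_raw raw protein intensity matrix.
#' @param site_to_protein named character vector site_id -> protein_id.
#' @param site_zero_as_missing treat exact zeros in the site matrix as
#'   missing values (default TRUE).
#' @return a `calibrated_matrix` (see [calibrate_sites()]).
#' @export
calibrate_pipeline <- function(site_raw, protein_raw, site_to_protein,
                               site_zero_as_missing = TRUE) {
  if (site_zero_as_missing) site_raw[site_raw == 0] <- NA_real_
  protein_raw <- replace_zeros(protein_raw)
  calibrate_sites(rowmean_normalize(site_raw),
                  rowmean_normalize(protein_raw),
                  site_to_protein)
}

#' Write / read a calibrated matrix as TSV
#'
#' The TSV carries a `provenance` column after `site_id`.
#'
#' @param calibrated a `calibrated_matrix`.
#' @param path TSV path.
#' @export
write_calibrated <- function(calibrated, path) {
  out <- data.frame(site_id = rownames(calibrated$values),
                    provenance = unname(calibrated$provenance),
                    as.data.frame(calibrated$values, check.names = FALSE),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibrated
#' @export
read_calibrated <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  stopifnot(all(c("site_id", "provenance") %in% names(raw)))
  m <- as.matrix(raw[, setdiff(names(raw), c("site_id", "provenance")),
                     drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- raw$site_id
  structure(list(values = m,
                 provenance = stats::setNames(raw$provenance, raw$site_id)),
            class = "calibrated_matrix")
}
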