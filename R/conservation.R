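#' Extract the sequence window around a phosphosite
#'
#' Returns the residue at `position` with `flank` residues on either side
#' (13-mer for the default flank of 6). Positions beyond the protein termini
#' are padded with `"_"`.
#'
#' @param sequence protein sequence string.
#' @param position 1-based residue index within the sequence.
#' @param flank residues on each side of the site.
#' @return character window of length `2 * flank + 1`.
#' @export
extract_window <- function(sequence, position, flank = 6L) {
  n <- nchar(sequence)
  if (position < 1 || position > n) {
    stop("position ", position, " out of range for sequence of length ", n,
         call. = FALSE)
  }
  lo <- position - flank
  hi <- position + flank
  core <- substr(sequence, max(1L, lo), min(n, hi))
  paste0(strrep("_", max(0L, 1L - lo)), toupper(core),
         strrep("_", max(0L, hi - n)))
}

#' Count identical residues between two windows
#'
#' Position-wise identity on equal-length windows; the terminal pad
#' character `"_"` never matches anything, including another pad.
#'
#' @param w1,w2 windows of equal length (13 by default usage).
#' @return integer match count.
#' @export
count_matches <- function(w1, w2) {
  if (nchar(w1) != nchar(w2)) {
    stop("windows must have equal length", call. = FALSE)
  }
  a <- strsplit(w1, "")[[1]]
  b <- strsplit(w2, "")[[1]]
  sum(a == b & a != "_")
}

#' Window similarity rule
#'
#' Two windows are similar when they share at least `min_matches` identical
#' residues. The default of 9 on a 13-mer is the smallest integer count whose
#' fraction exceeds 69% (9/13 ~= 0.692).
#'
#' @param w1,w2 windows.
#' @param min_matches required identical residues.
#' @return logical.
#' @export
is_similar <- function(w1, w2, min_matches = 9L) {
  count_matches(w1, w2) >= min_matches
}

#' Screen for cross-species conserved phosphosites
#'
#' For every reference (mouse) site, finds the best-matching window in each
#' other species (maximal match count, ties broken by first occurrence). A
#' species counts as matched when its best window reaches `min_matches`
#' identical residues; a site is conserved when the number of matched
#' species, the reference included, reaches `min_species`.
#'
#' @param sites site data.frame with a `window` column.
#' @param species_sets named list of species window sets, each a data.frame
#'   with `window_id` and `window` columns (or a character vector of
#'   windows).
#' @param min_matches identical-residue threshold (default 9 of 13).
#' @param min_species minimum species including the reference (default 3).
#' @param require_center_match also require the center residue to be
#'   identical (off by default; the permissive literal reading).
#' @return list with `summary` (data.frame: site_id, n_species_matched,
#'   conserved) and `detail` (data.frame: site_id, species, best_window_id,
#'   match_count, similar), both sorted by site then species.
#' @export
screen_conserved <- function(sites, species_sets, min_matches = 9L,
                             min_species = 3L, require_center_match = FALSE) {
  stopifnot(length(species_sets) >= 1)
  if (nrow(sites) == 0) {
    return(list(
      summary = data.frame(site_id = character(), n_species_matched = integer(),
                           conserved = logical(), stringsAsFactors = FALSE),
      detail = data.frame(site_id = character(), species = character(),
                          best_window_id = character(),
                          match_count = integer(), similar = logical(),
                          stringsAsFactors = FALSE)))
  }
  wl <- nchar(sites$window[1])
  center <- (wl + 1L) %/% 2L
  site_chars <- t(vapply(strsplit(sites$window, ""), identity,
                         character(wl)))
  detail <- list()
  for (sp in names(species_sets)) {
    set <- species_sets[[sp]]
    if (is.character(set)) {
      set <- data.frame(window_id = paste0(sp, "_w", seq_along(set)),
                        window = set, stringsAsFactors = FALSE)
    }
    if (any(nchar(set$window) != wl)) {
      stop("species ", sp, " contains windows of the wrong length",
           call. = FALSE)
    }
    sp_chars <- t(vapply(strsplit(set$window, ""), identity, character(wl)))
    # match counts for all (site, window) pairs, one species column at a time
    counts <- matrix(0L, nrow(sites), nrow(set))
    for (k in seq_len(wl)) {
      counts <- counts + (outer(site_chars[, k], sp_chars[, k], "==") &
                            site_chars[, k] != "_")
    }
    if (require_center_match) {
      center_ok <- outer(site_chars[, center], sp_chars[, center], "==")
      counts[!center_ok] <- -1L
    }
    best_j <- max.col(counts, ties.method = "first")
    best_n <- counts[cbind(seq_len(nrow(sites)), best_j)]
    detail[[sp]] <- data.frame(
      site_id = sites$site_id, species = sp,
      best_window_id = set$window_id[best_j],
      match_count = as.integer(best_n),
      similar = best_n >= min_matches,
      stringsAsFactors = FALSE
    )
  }
  detail <- do.call(rbind, detail)
  detail <- detail[order(detail$site_id, detail$species), , drop = FALSE]
  rownames(detail) <- NULL
  n_matched <- tapply(detail$similar, detail$site_id, sum)
  summary <- data.frame(
    site_id = names(n_matched),
    n_species_matched = as.integer(n_matched) + 1L,  # the reference counts
    stringsAsFactors = FALSE
  )
  summary$conserved <- summary$n_species_matched >= min_species
  summary <- summary[order(summary$site_id), , drop = FALSE]
  rownames(summary) <- NULL
  list(summary = summary, detail = detail)
}

#' Novelty screen against reference site catalogs
#'
#' A site is novel when its (protein, position, residue) key is absent from
#' every supplied catalog (e.g. a multi-tissue phosphoproteome atlas and a
#' public phosphosite database).
#'
#' @param sites site data.frame (`protein_id`, `position`, `residue`).
#' @param catalogs list of data.frames with columns `protein_id`, `position`,
#'   `residue`.
#' @return list with `novel` (named logical per site_id), `n_novel`,
#'   `n_total`, `pct_novel` (rounded percent).
#' @export
novel_sites <- function(sites, catalogs) {
  key <- function(df) paste(df$protein_id, df$position, df$residue)
  known <- unique(unlist(lapply(catalogs, key), use.names = FALSE))
  novel <- !(key(sites) %in% known)
  names(novel) <- sites$site_id
  list(novel = novel, n_novel = sum(novel), n_total = length(novel),
       pct_novel = rounded_percent(sum(novel), length(novel)))
}
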