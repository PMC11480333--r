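#' Classify phosphosites by localization probability
#'
#' Search engines report, for every candidate phosphosite, the probability
#' that the phosphate is localized on the stated residue rather than on a
#' neighbouring S/T/Y. Sites are conventionally binned into three confidence
#' classes: class I (probability > 0.75), class II (0.50 to 0.75, both ends
#' included), and class III (< 0.50). Downstream quantification keeps class I
#' sites; the class also drives deduplication priority (see
#' [dedupe_by_class()]).
#'
#' @param loc_prob numeric vector of localization probabilities in \[0, 1\].
#' @return character vector of the same length with values `"I"`, `"II"` or
#'   `"III"`.
#' @examples
#' classify_site(c(0.9, 0.75, 0.1))
#' @export
classify_site <- function(loc_prob) {
  if (!is.numeric(loc_prob)) {
    stop("loc_prob must be numeric", call. = FALSE)
  }
  if (anyNA(loc_prob) || any(loc_prob < 0) || any(loc_prob > 1)) {
    stop("loc_prob must lie in [0, 1] with no missing values", call. = FALSE)
  }
  ifelse(loc_prob > 0.75, "I", ifelse(loc_prob >= 0.5, "II", "III"))
}

#' Construct a study design
#'
#' A study design maps sample identifiers to (stage, replicate). Stages are
#' ordered: the default is the oocyte maturation series GV (germinal
#' vesicle), GVBD (germinal vesicle breakdown), MII (metaphase II).
#'
#' @param stages ordered character vector of stage labels.
#' @param replicates number of replicates per stage (recycled), or a named
#'   vector giving the count per stage. Every stage needs at least 2 samples
#'   for variance-based testing.
#' @param sample_ids optional explicit sample identifiers; default
#'   `"<stage>_<replicate>"`.
#' @return a `study_design` data.frame with columns `sample`, `stage`
#'   (factor with the stage ordering), `replicate`.
#' @examples
#' design <- study_design()
#' table(design$stage)
#' @export
study_design <- function(stages = c("GV", "GVBD", "MII"), replicates = 5,
                         sample_ids = NULL) {
  stopifnot(is.character(stages), length(stages) >= 1, !anyDuplicated(stages))
  if (length(replicates) == 1) {
    replicates <- stats::setNames(rep(replicates, length(stages)), stages)
  }
  replicates <- replicates[stages]
  if (anyNA(replicates) || any(replicates < 2)) {
    stop("every stage needs >= 2 replicates", call. = FALSE)
  }
  stage <- rep(stages, times = replicates)
  repl <- unlist(lapply(replicates, seq_len), use.names = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste(stage, repl, sep = "_")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  out <- data.frame(
    sample = sample_ids,
    stage = factor(stage, levels = stages),
    replicate = as.integer(repl),
    stringsAsFactors = FALSE
  )
  class(out) <- c("study_design", class(out))
  out
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", nlevels(x$stage), "stages x",
      nrow(x), "samples\n")
  print(table(stage = x$stage))
  invisible(x)
}

#' Analysis thresholds
#'
#' Bundles the cutoffs used throughout the pipeline, with the study's
#' published defaults: class I requires localization probability > 0.75;
#' a TMT phosphosite (or protein) is significant at BH-adjusted p < 0.05 and
#' fold change > 1.5; DIA proteins at raw p < 0.05 and fold change > 1.2;
#' conservation windows use 6 flanking residues and require at least 9 of 13
#' identical residues in at least 3 species (mouse included); temporal
#' clustering uses 5 clusters.
#'
#' @param class_min_prob minimum localization probability for class I.
#' @param padj_max BH-adjusted p-value cutoff for TMT significance.
#' @param fc_min_phospho fold-change cutoff (> 1) for TMT significance,
#'   applied symmetrically as |log2 FC| > log2(fc_min_phospho).
#' @param dia_p_max raw p-value cutoff for DIA protein significance.
#' @param dia_fc_min fold-change cutoff for DIA protein significance.
#' @param flank flanking residues on each side of the phosphosite window.
#' @param min_matches minimum identical residues of the 2*flank+1 window.
#' @param min_species minimum number of species (including the reference)
#'   for a site to count as conserved.
#' @param n_clusters number of fuzzy c-means clusters.
#' @return a named list of class `analysis_thresholds`.
#' @export
analysis_thresholds <- function(class_min_prob = 0.75, padj_max = 0.05,
                                fc_min_phospho = 1.5, dia_p_max = 0.05,
                                dia_fc_min = 1.2, flank = 6, min_matches = 9,
                                min_species = 3, n_clusters = 5) {
  th <- list(
    class_min_prob = class_min_prob, padj_max = padj_max,
    fc_min_phospho = fc_min_phospho, dia_p_max = dia_p_max,
    dia_fc_min = dia_fc_min, flank = as.integer(flank),
    min_matches = as.integer(min_matches),
    min_species = as.integer(min_species),
    n_clusters = as.integer(n_clusters)
  )
  if (any(vapply(th, function(v) v <= 0, logical(1)))) {
    stop("all thresholds must be strictly positive", call. = FALSE)
  }
  if (th$fc_min_phospho <= 1 || th$dia_fc_min <= 1) {
    stop("fold-change thresholds must exceed 1", call. = FALSE)
  }
  if (th$min_matches > 2L * th$flank + 1L) {
    stop("min_matches cannot exceed the window length 2*flank + 1",
         call. = FALSE)
  }
  class(th) <- "analysis_thresholds"
  th
}

#' Smallest match count exceeding a similarity fraction
#'
#' The conservation screen's integer threshold: the smallest k such that
#' k / window_length strictly exceeds `min_similarity`. With a 13-mer window
#' and similarity > 0.69 this is 9 (9/13 ~= 0.692).
#'
#' @param min_similarity required similarity fraction (strict).
#' @param window_length window length (default 13).
#' @return integer match count.
#' @export
similarity_match_threshold <- function(min_similarity = 0.69,
                                       window_length = 13L) {
  stopifnot(min_similarity >= 0, min_similarity < 1, window_length >= 1)
  k <- ceiling(min_similarity * window_length)
  # strict inequality: bump when k/len equals the fraction exactly
  if (k / window_length <= min_similarity) k <- k + 1
  as.integer(k)
}

#' Read/write a study design as YAML
#'
#' @param path file path.
#' @return `read_study_design` returns a `study_design`;
#'   `write_study_design` returns `path` invisibly.
#' @export
read_study_design <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$stages), !is.null(y$samples))
  smp <- do.call(rbind, lapply(y$samples, function(s) {
    data.frame(sample = s$sample, stage = s$stage,
               replicate = as.integer(s$replicate),
               stringsAsFactors = FALSE)
  }))
  if (!all(smp$stage %in% y$stages)) {
    stop("design contains samples mapped to unknown stages", call. = FALSE)
  }
  if (any(table(factor(smp$stage, levels = y$stages)) < 2)) {
    stop("every stage needs >= 2 samples", call. = FALSE)
  }
  smp$stage <- factor(smp$stage, levels = y$stages)
  class(smp) <- c("study_design", class(smp))
  smp
}

#' @rdname read_study_design
#' @param design a `study_design`.
#' @export
write_study_design <- function(design, path) {
  y <- list(
    stages = levels(design$stage),
    samples = lapply(seq_len(nrow(design)), function(i) {
      list(sample = design$sample[i],
           stage = as.character(design$stage[i]),
           replicate = design$replicate[i])
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Parse a phosphosite quantification table
#'
#' Reads a TSV site export into a site table plus an intensity matrix. Two
#' dialects are supported: `generic` (columns `protein_id`, `position`,
#' `residue`, `loc_prob`, one intensity column per design sample) and
#' `maxquant` (columns `Protein`, `Position`, `Amino acid`,
#' `Localization prob`, and `Reporter intensity <sample>` columns).
#'
#' Empty cells and the token `NA` in intensity columns become missing values
#' (the site row is retained). Rows whose position or localization
#' probability cannot be parsed, or with other unparseable numerics, are
#' dropped with a warning listing the offending rows. Duplicate
#' (protein, position) pairs are an error; run search-engine level
#' deduplication (see [dedupe_by_class()]) before export, or use
#' `allow_duplicates = TRUE` and deduplicate with [dedupe_site_table()].
#'
#' @param path TSV file path.
#' @param design a `study_design`; intensity columns are aligned to
#'   `design$sample`.
#' @param dialect `"generic"` or `"maxquant"`.
#' @param allow_duplicates keep duplicate (protein, position) rows instead of
#'   erroring (needed as input to [dedupe_site_table()]).
#' @return list with `sites` (data.frame: site_id, protein_id, position,
#'   residue, loc_prob, site_class) and `intensities` (numeric matrix,
#'   rownames = site_id, colnames = design samples).
#' @export
parse_site_table <- function(path, design, dialect = c("generic", "maxquant"),
                             allow_duplicates = FALSE) {
  dialect <- match.arg(dialect)
  # read everything as character: type inference would turn a residue
  # column holding only "T" into a logical vector
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), colClasses = "character")
  cols <- switch(dialect,
    generic = c(protein_id = "protein_id", position = "position",
                residue = "residue", loc_prob = "loc_prob"),
    maxquant = c(protein_id = "Protein", position = "Position",
                 residue = "Amino acid", loc_prob = "Localization prob")
  )
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  intensity_cols <- switch(dialect,
    generic = design$sample,
    maxquant = paste("Reporter intensity", design$sample)
  )
  missing_int <- setdiff(intensity_cols, names(raw))
  if (length(missing_int)) {
    stop("missing intensity column(s): ", paste(missing_int, collapse = ", "),
         call. = FALSE)
  }

  suppress_to_na <- function(x) suppressWarnings(as.numeric(x))
  position <- suppress_to_na(raw[[cols["position"]]])
  loc_prob <- suppress_to_na(raw[[cols["loc_prob"]]])
  intens <- vapply(intensity_cols, function(cn) suppress_to_na(raw[[cn]]),
                   numeric(nrow(raw)))
  if (nrow(raw) == 1L) intens <- matrix(intens, nrow = 1L)
  # a cell is unparseable (not merely missing) if the source was non-empty
  src_missing <- vapply(intensity_cols, function(cn) is.na(raw[[cn]]),
                        logical(nrow(raw)))
  if (nrow(raw) == 1L) src_missing <- matrix(src_missing, nrow = 1L)
  bad_int <- rowSums(is.na(intens) & !src_missing) > 0
  bad <- is.na(position) | is.na(loc_prob) | bad_int
  if (any(bad)) {
    warning(sum(bad), " row(s) dropped for unparseable numerics: rows ",
            paste(which(bad), collapse = ", "), call. = FALSE)
    raw <- raw[!bad, , drop = FALSE]
    position <- position[!bad]
    loc_prob <- loc_prob[!bad]
    intens <- intens[!bad, , drop = FALSE]
  }
  if (!nrow(raw)) stop("no parseable rows in ", path, call. = FALSE)

  sites <- data.frame(
    protein_id = as.character(raw[[cols["protein_id"]]]),
    position = as.integer(position),
    residue = toupper(as.character(raw[[cols["residue"]]])),
    loc_prob = loc_prob,
    stringsAsFactors = FALSE
  )
  if (!all(sites$residue %in% c("S", "T", "Y"))) {
    stop("residue column must contain only S, T or Y", call. = FALSE)
  }
  sites$site_class <- classify_site(sites$loc_prob)
  sites$site_id <- paste0(sites$protein_id, ":", sites$residue, sites$position)
  key <- paste(sites$protein_id, sites$position)
  if (anyDuplicated(key) && !allow_duplicates) {
    dups <- unique(key[duplicated(key)])
    stop("duplicate (protein, position) entries: ",
         paste(dups, collapse = "; "), call. = FALSE)
  }
  if (allow_duplicates && anyDuplicated(sites$site_id)) {
    sites$site_id <- make.unique(sites$site_id, sep = ".dup")
  }
  colnames(intens) <- design$sample
  rownames(intens) <- sites$site_id
  if (any(intens < 0, na.rm = TRUE)) {
    stop("negative intensities are not allowed", call. = FALSE)
  }
  sites <- sites[, c("site_id", "protein_id", "position", "residue",
                     "loc_prob", "site_class")]
  list(sites = sites, intensities = intens)
}

#' Write a site table in the generic dialect
#'
#' Inverse of [parse_site_table()] (`dialect = "generic"`): parse -> write ->
#' parse round-trips to the same sites and intensities.
#'
#' @param sites site data.frame as returned by [parse_site_table()].
#' @param intensities matching intensity matrix.
#' @param path output TSV path.
#' @export
write_site_table <- function(sites, intensities, path) {
  stopifnot(identical(rownames(intensities), sites$site_id))
  out <- cbind(
    sites[, c("protein_id", "position", "residue", "loc_prob")],
    as.data.frame(intensities, check.names = FALSE)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a protein quantification table
#'
#' Generic TSV with a `protein_id` column and one intensity column per design
#' sample. Duplicate accessions are an error.
#'
#' @inheritParams parse_site_table
#' @return numeric matrix (rownames = protein_id, colnames = samples).
#' @export
parse_protein_table <- function(path, design) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  if (!"protein_id" %in% names(raw)) {
    stop("missing required column(s): protein_id", call. = FALSE)
  }
  missing_int <- setdiff(design$sample, names(raw))
  if (length(missing_int)) {
    stop("missing intensity column(s): ", paste(missing_int, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(raw$protein_id)) {
    stop("duplicate protein accessions: ",
         paste(unique(raw$protein_id[duplicated(raw$protein_id)]),
               collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(raw[, design$sample, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- raw$protein_id
  if (any(m < 0, na.rm = TRUE)) {
    stop("negative intensities are not allowed", call. = FALSE)
  }
  m
}

#' @rdname parse_protein_table
#' @param matrix protein intensity matrix.
#' @export
write_protein_table <- function(matrix, path) {
  out <- data.frame(protein_id = rownames(matrix),
                    as.data.frame(matrix, check.names = FALSE),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Deduplicate phosphosite entries sharing (protein, position)
#'
#' When a site is reported several times (e.g. from different peptide forms),
#' the entry with the highest localization class is kept, following the
#' priority Class I > Class II > Class III. Ties are broken by higher
#' localization probability, then by larger total intensity. The result is
#' invariant to the order of the input rows.
#'
#' @param sites data.frame of site rows all sharing (protein_id, position).
#' @param intensities optional intensity matrix (rownames = site_id) used
#'   for the total-intensity tie-break.
#' @return the selected single row of `sites`.
#' @export
dedupe_by_class <- function(sites, intensities = NULL) {
  if (is.null(sites) || nrow(sites) == 0) {
    stop("dedupe_by_class: empty input", call. = FALSE)
  }
  if (nrow(unique(sites[, c("protein_id", "position")])) != 1L) {
    stop("all rows must share (protein_id, position)", call. = FALSE)
  }
  if (nrow(sites) == 1L) return(sites)
  class_rank <- c(I = 3, II = 2, III = 1)[sites$site_class]
  total <- if (is.null(intensities)) rep(0, nrow(sites)) else
    rowSums(intensities[sites$site_id, , drop = FALSE], na.rm = TRUE)
  ord <- order(-class_rank, -sites$loc_prob, -total)
  sites[ord[1L], , drop = FALSE]
}

#' Deduplicate a whole site table by localization class
#'
#' Applies [dedupe_by_class()] to every (protein, position) group of a site
#' table parsed with `allow_duplicates = TRUE`.
#'
#' @param sites site data.frame.
#' @param intensities intensity matrix (rownames = site_id).
#' @return list with deduplicated `sites` and `intensities`.
#' @export
dedupe_site_table <- function(sites, intensities) {
  key <- paste(sites$protein_id, sites$position)
  keep <- unlist(lapply(split(seq_len(nrow(sites)), key), function(idx) {
    chosen <- dedupe_by_class(sites[idx, , drop = FALSE], intensities)
    idx[match(chosen$site_id, sites$site_id[idx])]
  }), use.names = FALSE)
  keep <- sort(keep)
  list(sites = sites[keep, , drop = FALSE],
       intensities = intensities[sites$site_id[keep], , drop = FALSE])
}

#' Parse a FASTA file of protein sequences
#'
#' The accession is the header token before the first whitespace. Sequences
#' are uppercased. Duplicate accessions and empty files are errors.
#'
#' @param path FASTA file path.
#' @return named character vector accession -> sequence.
#' @export
parse_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path, call. = FALSE)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) stop("FASTA must start with a '>' header", call. = FALSE)
  rec <- cumsum(is_hdr)
  ids <- sub("^>(\\S+).*$", "\\1", lines[is_hdr])
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA accessions: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- vapply(split(lines[!is_hdr], rec[!is_hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  # records with no sequence lines yield missing entries in the split
  out <- stats::setNames(rep("", length(ids)), ids)
  out[as.integer(names(seqs))] <- seqs
  names(out) <- ids
  out
}

#' Write protein sequences as FASTA
#'
#' @param sequences named character vector accession -> sequence.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(sequences)) {
    writeLines(paste0(">", id), con)
    s <- sequences[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
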