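#' Enzyme-class accounting (kinases and phosphatases)
#'
#' Annotates each enzyme of the supplied kinase and phosphatase lists with
#' its status in the dataset: detected (present in the proteome or the
#' phosphoproteome), phosphorylated (carries at least one quantified
#' phosphosite), and regulated (at least one regulated phosphosite). The
#' three statuses are nested: regulated implies phosphorylated implies
#' detected.
#'
#' @param proteome_ids protein accessions quantified in the proteome.
#' @param sites site data.frame (`site_id`, `protein_id`).
#' @param regulated data.frame from [call_regulated()].
#' @param kinase_list,phosphatase_list character vectors of accessions.
#' @return list with `status` (data.frame: enzyme_id, class, detected,
#'   phosphorylated, regulated) and `counts` (data.frame per class: n_total,
#'   n_detected, n_phosphorylated, n_regulated).
#' @export
annotate_enzymes <- function(proteome_ids, sites, regulated,
                             kinase_list, phosphatase_list) {
  reg_sites <- regulated$site_id[regulated$regulated]
  phospho_prot <- unique(sites$protein_id)
  reg_prot <- unique(sites$protein_id[sites$site_id %in% reg_sites])
  one_class <- function(ids, cls) {
    detected <- ids %in% proteome_ids | ids %in% phospho_prot
    phosphorylated <- ids %in% phospho_prot
    reg <- ids %in% reg_prot
    data.frame(enzyme_id = ids, class = cls, detected = detected,
               phosphorylated = phosphorylated, regulated = reg,
               stringsAsFactors = FALSE)
  }
  status <- rbind(one_class(kinase_list, "kinase"),
                  one_class(phosphatase_list, "phosphatase"))
  counts <- do.call(rbind, lapply(split(status, status$class), function(s) {
    data.frame(class = s$class[1], n_total = nrow(s),
               n_detected = sum(s$detected),
               n_phosphorylated = sum(s$phosphorylated),
               n_regulated = sum(s$regulated), stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  list(status = status, counts = counts)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test conditional on the table margins: the p-value is the
#' sum of hypergeometric probabilities of all tables (with the observed
#' margins) whose probability does not exceed that of the observed table.
#' The odds ratio is the sample odds ratio `ad / bc`. A zero margin makes
#' every conditional table identical, so p = 1 (with a `degenerate`
#' diagnostic flag).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list with `odds_ratio`, `p`, `degenerate`.
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2),
            all(table >= 0), all(table == round(table)))
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  or <- (a * d) / (b * c_)
  r1 <- a + b; c1 <- a + c_; n <- sum(table)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) {
    return(list(odds_ratio = or, p = 1, degenerate = TRUE))
  }
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(odds_ratio = or, p = min(p, 1), degenerate = FALSE)
}

#' Kinase enrichment of upregulated phosphosites
#'
#' For one stage comparison, tests every kinase of the network for
#' enrichment of its substrates among the significantly upregulated sites,
#' against the rest of the quantified site universe, with a two-sided
#' Fisher's exact test on the 2x2 table (substrate membership) x
#' (upregulated vs rest). P-values are BH-adjusted across kinases. Kinases
#' with no substrate in the universe are excluded (their ids are attached as
#' the `"excluded"` attribute).
#'
#' @param calls rows of [differential_sites()] output for one comparison.
#' @param edges kinase-substrate edge data.frame (`kinase_id`, `site_id`).
#' @param site_universe character vector of quantified site ids; defaults to
#'   the sites present in `calls`.
#' @return data.frame, one row per kinase: `kinase_id`, `n_sub_up`,
#'   `n_sub_not_up`, `n_nonsub_up`, `n_nonsub_not_up`, `odds_ratio`, `p`,
#'   `p_adj`, sorted by p.
#' @export
kinase_enrichment <- function(calls, edges,
                              site_universe = unique(calls$site_id)) {
  stopifnot(length(unique(calls$comparison)) == 1)
  up <- unique(calls$site_id[calls$significant & calls$direction == "up"])
  up <- intersect(up, site_universe)
  n_up <- length(up)
  n_uni <- length(site_universe)
  all_kinases <- unique(edges$kinase_id)
  edges <- edges[edges$site_id %in% site_universe, , drop = FALSE]
  kinases <- unique(edges$kinase_id)
  excluded <- setdiff(all_kinases, kinases)
  if (length(excluded)) {
    message(length(excluded), " kinase(s) without substrates in the universe",
            " excluded")
  }
  rows <- lapply(kinases, function(k) {
    subs <- unique(edges$site_id[edges$kinase_id == k])
    a <- length(intersect(subs, up))
    b <- length(subs) - a
    c_ <- n_up - a
    d <- (n_uni - length(subs)) - c_
    tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    # margins must reconcile with the global counts
    stopifnot(a + c_ == n_up, sum(tab) == n_uni)
    ft <- fisher_exact_2x2(tab)
    data.frame(kinase_id = k, n_sub_up = a, n_sub_not_up = b,
               n_nonsub_up = c_, n_nonsub_not_up = d,
               odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Substrate-based kinase activity profiles
#'
#' Estimates each kinase's activity trajectory from the phosphorylation
#' changes of its known substrates: every substrate site's stage-mean
#' profile is standardized to a z-profile (mean 0, population SD 1 across
#' stages), and the kinase profile is the per-stage mean of its substrates'
#' z-profiles (optionally weighted by edge scores). The trend label compares
#' consecutive stage differences against `trend_threshold` (in z units):
#' `increasing` / `decreasing` when all non-flat steps share a sign,
#' `transient` when steps change sign, `flat` otherwise. Kinases with fewer
#' than `min_substrates` usable substrate profiles are reported with a
#' missing profile.
#'
#' @param edges kinase-substrate edge data.frame (`kinase_id`, `site_id`,
#'   optional `score`).
#' @param profiles sites x stages matrix of calibrated stage means (see
#'   [stage_means()]).
#' @param min_substrates minimum usable substrates (default 3).
#' @param trend_threshold z-scale threshold for a non-flat step
#'   (default 0.25).
#' @param weight_by_score weight the substrate mean by edge scores.
#' @return data.frame: `kinase_id`, one `act_<stage>` column per stage,
#'   `n_substrates`, `trend`.
#' @export
infer_activity <- function(edges, profiles, min_substrates = 3L,
                           trend_threshold = 0.25, weight_by_score = FALSE) {
  z <- standardize_profiles(profiles)
  stages <- colnames(profiles)
  kinases <- unique(edges$kinase_id)
  rows <- lapply(kinases, function(k) {
    e <- edges[edges$kinase_id == k, , drop = FALSE]
    e <- e[!duplicated(e$site_id), , drop = FALSE]
    e <- e[e$site_id %in% rownames(z), , drop = FALSE]
    ns <- nrow(e)
    if (ns < min_substrates) {
      prof <- rep(NA_real_, length(stages))
      trend <- NA_character_
    } else {
      zi <- z[e$site_id, , drop = FALSE]
      w <- if (weight_by_score && !is.null(e$score)) e$score else rep(1, ns)
      prof <- colSums(zi * w) / sum(w)
      trend <- trend_label(prof, trend_threshold)
    }
    out <- data.frame(kinase_id = k, n_substrates = ns, trend = trend,
                      stringsAsFactors = FALSE)
    out[paste0("act_", stages)] <- as.list(prof)
    out
  })
  out <- do.call(rbind, rows)
  out[, c("kinase_id", paste0("act_", stages), "n_substrates", "trend")]
}

trend_label <- function(profile, threshold) {
  d <- diff(profile)
  s <- ifelse(d > threshold, 1L, ifelse(d < -threshold, -1L, 0L))
  if (any(s > 0) && any(s < 0)) return("transient")
  if (any(s > 0)) return("increasing")
  if (any(s < 0)) return("decreasing")
  "flat"
}

#' Read kinase-substrate edge tables and enzyme lists
#'
#' Edge TSV columns: `kinase_id`, `site_id`, optional `score`. Enzyme lists
#' are plain text, one accession per line.
#'
#' @param path file path.
#' @return data.frame (edges) or character vector (list).
#' @export
read_edge_table <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("kinase_id", "site_id") %in% names(raw)))
  if (anyDuplicated(raw[, c("kinase_id", "site_id")])) {
    stop("duplicate kinase-substrate edges", call. = FALSE)
  }
  raw
}

#' @rdname read_edge_table
#' @export
read_enzyme_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}
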