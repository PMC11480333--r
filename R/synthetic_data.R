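#' Synthetic phosphoproteome study configuration
#'
#' Defines the conditions of a simulated stage-resolved phosphoproteome
#' study with known ground truth. Defaults emulate the statistical structure
#' of a 3-stage x 5-replicate TMT-like oocyte maturation design: ~75% of
#' sites regulated, five planted temporal archetypes, residue composition
#' 86.5/13.0/0.5 % S/T/Y, and a long-tailed sites-per-protein distribution
#' (zero-truncated geometric, mean 3).
#'
#' The five archetype templates give the true stage means (GV, GVBD, MII) of
#' regulated sites, before noise:
#' A1 monotone down (1, 0.7, 0.3); A2 transient up (0.6, 1, 0.3);
#' A3 (0.3, 0.5, 1), A4 (0.3, 0.9, 1), A5 (0.5, 0.6, 1) up-shapes with
#' differing onset. Unregulated sites use a flat template (1, 1, 1).
#' Noise is multiplicative log-normal with `sdlog` sigma; a fraction of
#' proteins additionally drift 1.5-2x across stages, so that only calibrated
#' (protein-corrected) site levels classify sites correctly.
#'
#' @param n_proteins number of simulated proteins.
#' @param mean_sites_per_protein mean of the zero-truncated geometric
#'   sites-per-protein distribution.
#' @param residue_freqs named numeric (S, T, Y) frequencies summing to 1.
#' @param stages ordered stage labels.
#' @param n_replicates replicates per stage.
#' @param fraction_regulated fraction of sites carrying a temporal archetype.
#' @param archetypes numeric matrix (archetype x stage) of template means.
#' @param sdlog sigma of the multiplicative log-normal noise (natural log).
#' @param drift_fraction fraction of proteins with a protein-level drift.
#' @param drift_range range of the drift fold change.
#' @param protein_coverage fraction of proteins quantified in the proteome
#'   table (sites on the remainder exercise the site-only fallback).
#' @param seed integer seed governing all draws.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_proteins = 500,
                       mean_sites_per_protein = 3,
                       residue_freqs = c(S = 0.865, T = 0.130, Y = 0.005),
                       stages = c("GV", "GVBD", "MII"),
                       n_replicates = 5,
                       fraction_regulated = 0.75,
                       archetypes = default_archetypes(),
                       sdlog = 0.15,
                       drift_fraction = 0.1,
                       drift_range = c(1.5, 2),
                       protein_coverage = 0.9,
                       seed = 1L) {
  stopifnot(abs(sum(residue_freqs) - 1) < 1e-9,
            all(c("S", "T", "Y") %in% names(residue_freqs)),
            sdlog >= 0, mean_sites_per_protein > 1,
            fraction_regulated >= 0, fraction_regulated <= 1,
            ncol(archetypes) == length(stages),
            nrow(unique(archetypes)) == nrow(archetypes))
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    mean_sites_per_protein = mean_sites_per_protein,
    residue_freqs = residue_freqs[c("S", "T", "Y")],
    stages = stages,
    n_replicates = as.integer(n_replicates),
    fraction_regulated = fraction_regulated,
    archetypes = archetypes,
    sdlog = sdlog,
    drift_fraction = drift_fraction,
    drift_range = drift_range,
    protein_coverage = protein_coverage,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_archetypes <- function() {
  m <- rbind(
    A1 = c(1, 0.7, 0.3),
    A2 = c(0.6, 1, 0.3),
    A3 = c(0.3, 0.5, 1),
    A4 = c(0.3, 0.9, 1),
    A5 = c(0.5, 0.6, 1)
  )
  colnames(m) <- c("GV", "GVBD", "MII")
  m
}

# zero-truncated geometric on {1, 2, ...} with mean mu (= 1/p)
rztgeom <- function(n, mu) stats::rgeom(n, prob = 1 / mu) + 1L

amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Simulate a phosphoproteome study with ground truth
#'
#' Generates protein sequences, phosphosites with 13-mer windows, a site
#' intensity matrix and a protein intensity matrix under the configured
#' design, plus a truth object recording which sites are regulated, their
#' archetype, the true stage means and the protein drift profiles.
#'
#' The intensity of site i in sample s of stage t is
#' `base_i * protein_profile(t) * template_i(t) * exp(N(0, sdlog^2))`;
#' the protein intensity is `base_p * protein_profile(t) * exp(N(0, sdlog^2))`
#' with independent noise. With `sdlog = 0` the generated matrices are exact
#' and downstream differential calling recovers the planted regulated set.
#'
#' @param config a [sim_config()].
#' @return list with `sites`, `site_intensities`, `protein_intensities`
#'   (covered proteins only), `sequences`, `design`, and `truth` (list with
#'   `site_truth`, `protein_truth` data.frames).
#' @export
simulate_phosphoproteome <- function(config = sim_config()) {
  set.seed(config$seed)
  n_arch <- nrow(config$archetypes)
  design <- study_design(config$stages, config$n_replicates)
  stage_of_sample <- as.integer(design$stage)

  # proteins: sequences long enough to host all sites
  n_sites_per_prot <- rztgeom(config$n_proteins, config$mean_sites_per_protein)
  protein_ids <- sprintf("P%04d", seq_len(config$n_proteins))
  seq_len_aa <- pmax(50L, n_sites_per_prot * 12L) +
    stats::rpois(config$n_proteins, 30L)
  aa <- amino_acids()
  sequences <- vapply(seq_len_aa, function(L) {
    paste(sample(aa, L, replace = TRUE), collapse = "")
  }, character(1))
  names(sequences) <- protein_ids

  # sites: positions unique within protein, residue drawn from the S/T/Y mix
  site_rows <- lapply(seq_len(config$n_proteins), function(i) {
    k <- n_sites_per_prot[i]
    pos <- sort(sample.int(seq_len_aa[i], k))
    data.frame(protein_id = protein_ids[i], position = pos,
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_rows)
  n_sites <- nrow(sites)
  sites$residue <- sample(names(config$residue_freqs), n_sites,
                          replace = TRUE, prob = config$residue_freqs)
  # overwrite the sequence character so windows are consistent
  for (pid in protein_ids) {
    idx <- which(sites$protein_id == pid)
    if (!length(idx)) next
    s <- strsplit(sequences[[pid]], "")[[1]]
    s[sites$position[idx]] <- sites$residue[idx]
    sequences[[pid]] <- paste(s, collapse = "")
  }
  # localization probability mix: mostly class I
  cls_draw <- sample.int(3L, n_sites, replace = TRUE,
                         prob = c(0.90, 0.07, 0.03))
  sites$loc_prob <- c(
    stats::runif(n_sites, 0.751, 1),
    stats::runif(n_sites, 0.5, 0.75),
    stats::runif(n_sites, 0, 0.499)
  )[(cls_draw - 1L) * n_sites + seq_len(n_sites)]
  sites$site_class <- classify_site(sites$loc_prob)
  sites$site_id <- paste0(sites$protein_id, ":", sites$residue, sites$position)
  sites$window <- vapply(seq_len(n_sites), function(i) {
    extract_window(sequences[[sites$protein_id[i]]], sites$position[i])
  }, character(1))
  sites <- sites[, c("site_id", "protein_id", "position", "residue",
                     "loc_prob", "site_class", "window")]

  # planted regulation
  regulated <- stats::runif(n_sites) < config$fraction_regulated
  archetype <- rep(NA_character_, n_sites)
  archetype[regulated] <- rownames(config$archetypes)[
    sample.int(n_arch, sum(regulated), replace = TRUE)]
  template <- matrix(1, n_sites, length(config$stages))
  template[regulated, ] <- config$archetypes[archetype[regulated], ,
                                             drop = FALSE]

  # protein-level drift
  drifting <- stats::runif(config$n_proteins) < config$drift_fraction
  prot_profile <- matrix(1, config$n_proteins, length(config$stages),
                         dimnames = list(protein_ids, config$stages))
  if (any(drifting)) {
    n_d <- sum(drifting)
    fold <- stats::runif(n_d, config$drift_range[1], config$drift_range[2])
    up <- stats::runif(n_d) < 0.5
    # linear drift from 1 at GV to fold (or 1/fold) at the last stage
    k <- length(config$stages)
    ramp <- seq(0, 1, length.out = k)
    prof <- t(vapply(seq_len(n_d), function(j) {
      f <- if (up[j]) fold[j] else 1 / fold[j]
      f ^ ramp
    }, numeric(k)))
    prot_profile[drifting, ] <- prof
  }

  base_prot <- stats::setNames(
    stats::rlnorm(config$n_proteins, meanlog = log(1e6), sdlog = 0.5),
    protein_ids)
  base_site <- stats::rlnorm(n_sites, meanlog = log(1e5), sdlog = 0.5)

  n_samp <- nrow(design)
  site_noise <- if (config$sdlog > 0) {
    matrix(stats::rnorm(n_sites * n_samp, 0, config$sdlog), n_sites, n_samp)
  } else matrix(0, n_sites, n_samp)
  prot_noise <- if (config$sdlog > 0) {
    matrix(stats::rnorm(config$n_proteins * n_samp, 0, config$sdlog),
           config$n_proteins, n_samp)
  } else matrix(0, config$n_proteins, n_samp)

  prot_idx <- match(sites$protein_id, protein_ids)
  site_mat <- base_site *
    prot_profile[prot_idx, stage_of_sample, drop = FALSE] *
    template[, stage_of_sample, drop = FALSE] * exp(site_noise)
  dimnames(site_mat) <- list(sites$site_id, design$sample)
  prot_mat <- base_prot * prot_profile[, stage_of_sample, drop = FALSE] *
    exp(prot_noise)
  dimnames(prot_mat) <- list(protein_ids, design$sample)

  covered <- stats::runif(config$n_proteins) < config$protein_coverage
  prot_mat <- prot_mat[covered, , drop = FALSE]

  true_means <- template
  colnames(true_means) <- config$stages
  site_truth <- data.frame(
    site_id = sites$site_id, protein_id = sites$protein_id,
    regulated = regulated, archetype = archetype,
    stringsAsFactors = FALSE
  )
  site_truth <- cbind(site_truth,
                      stats::setNames(as.data.frame(true_means),
                                      paste0("mean_", config$stages)))
  protein_truth <- data.frame(
    protein_id = protein_ids, drifting = drifting,
    covered = covered, stringsAsFactors = FALSE
  )
  protein_truth <- cbind(protein_truth,
                         stats::setNames(as.data.frame(prot_profile),
                                         paste0("profile_", config$stages)))

  list(sites = sites, site_intensities = site_mat,
       protein_intensities = prot_mat, sequences = sequences,
       design = design,
       truth = list(site_truth = site_truth, protein_truth = protein_truth,
                    config = config))
}

#' Simulate cross-species phosphopeptide window sets
#'
#' For each non-reference species, selects mouse sites with pad-free 13-mer
#' windows and emits, per selected site, a window at a planted Hamming
#' distance drawn from `dist_probs` (substitutions never at the center
#' position, always to a different amino acid). Only pad-free windows are
#' used so the planted distance d maps exactly to 13 - d matches under the
#' pad-never-matches rule of [count_matches()].
#'
#' @param sites site data.frame with a `window` column.
#' @param species character vector of non-reference species names.
#' @param dist_probs named numeric: probability of each planted Hamming
#'   distance (names = distances, integers >= 0).
#' @param site_fraction fraction of eligible mouse sites covered per species.
#' @param seed integer seed.
#' @return list with `species_sets` (named list of data.frames: window_id,
#'   window) and `truth` (data.frame: site_id, species, distance) restricted
#'   to emitted windows.
#' @export
simulate_species_sets <- function(sites,
                                  species = c("sea_star", "drosophila",
                                              "xenopus"),
                                  dist_probs = c("0" = 0.15, "2" = 0.2,
                                                 "4" = 0.25, "5" = 0.2,
                                                 "7" = 0.2),
                                  site_fraction = 0.8,
                                  seed = 1L) {
  set.seed(seed)
  stopifnot(abs(sum(dist_probs) - 1) < 1e-9)
  eligible <- sites[!grepl("_", sites$window, fixed = TRUE), , drop = FALSE]
  if (!nrow(eligible)) stop("no pad-free windows available", call. = FALSE)
  dists <- as.integer(names(dist_probs))
  aa <- amino_acids()
  center <- 7L
  truth <- list()
  species_sets <- list()
  for (sp in species) {
    take <- which(stats::runif(nrow(eligible)) < site_fraction)
    d <- dists[sample.int(length(dists), length(take), replace = TRUE,
                          prob = dist_probs)]
    w <- vapply(seq_along(take), function(j) {
      chars <- strsplit(eligible$window[take[j]], "")[[1]]
      if (d[j] > 0) {
        pos <- sample(setdiff(1:13, center), d[j])
        for (p in pos) chars[p] <- sample(setdiff(aa, chars[p]), 1)
      }
      paste(chars, collapse = "")
    }, character(1))
    species_sets[[sp]] <- data.frame(
      window_id = sprintf("%s_w%05d", sp, seq_along(take)),
      window = w, stringsAsFactors = FALSE
    )
    truth[[sp]] <- data.frame(
      site_id = eligible$site_id[take], species = sp, distance = d,
      stringsAsFactors = FALSE
    )
  }
  list(species_sets = species_sets, truth = do.call(rbind, truth))
}

#' Simulate a kinase-substrate network with planted structure
#'
#' Designates a subset of simulated proteins as kinases (and another as
#' phosphatases) and assigns each kinase a substrate set drawn
#' preferentially (with probability `purity`) from the regulated sites of
#' one temporal archetype; `n_neutral` kinases draw substrates uniformly from
#' all sites and serve as enrichment null controls.
#'
#' @param sim output of [simulate_phosphoproteome()].
#' @param n_kinases number of archetype-preferring kinases (cycled over the
#'   archetypes of the generating config).
#' @param n_neutral number of non-preferential kinases.
#' @param n_phosphatases number of proteins labelled phosphatases.
#' @param substrates_per_kinase substrate set size.
#' @param purity probability that a substrate is drawn from the preferred
#'   archetype.
#' @param seed integer seed.
#' @return list with `edges` (kinase_id, site_id, score), `kinases`,
#'   `phosphatases` (character vectors of protein ids), and `truth`
#'   (data.frame: kinase_id, preferred_archetype with NA for neutral).
#' @export
simulate_ks_network <- function(sim, n_kinases = 15, n_neutral = 3,
                                n_phosphatases = 6,
                                substrates_per_kinase = 15,
                                purity = 0.9, seed = 1L) {
  set.seed(seed)
  stopifnot(n_kinases + n_neutral >= 1)
  st <- sim$truth$site_truth
  arch_names <- rownames(sim$truth$config$archetypes)
  protein_ids <- unique(sim$sites$protein_id)
  n_enz <- n_kinases + n_neutral + n_phosphatases
  stopifnot(n_enz <= length(protein_ids))
  enz <- sample(protein_ids, n_enz)
  kin_ids <- enz[seq_len(n_kinases + n_neutral)]
  pp_ids <- enz[n_kinases + n_neutral + seq_len(n_phosphatases)]
  pref <- c(rep_len(arch_names, n_kinases), rep(NA_character_, n_neutral))

  edges <- list()
  for (i in seq_along(kin_ids)) {
    if (is.na(pref[i])) {
      subs <- sample(st$site_id, substrates_per_kinase)
    } else {
      pool <- st$site_id[!is.na(st$archetype) & st$archetype == pref[i]]
      other <- setdiff(st$site_id, pool)
      from_pool <- stats::rbinom(1, substrates_per_kinase, purity)
      from_pool <- min(from_pool, length(pool))
      subs <- c(sample(pool, from_pool),
                sample(other, substrates_per_kinase - from_pool))
    }
    edges[[i]] <- data.frame(kinase_id = kin_ids[i], site_id = subs,
                             score = round(stats::runif(length(subs)), 3),
                             stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges)
  list(edges = edges, kinases = kin_ids, phosphatases = pp_ids,
       truth = data.frame(kinase_id = kin_ids, preferred_archetype = pref,
                          stringsAsFactors = FALSE))
}

#' Write a simulated study to disk
#'
#' Emits the same TSV/FASTA/YAML formats the parsers read, plus a
#' `truth.json` with the generator's ground truth.
#'
#' @param sim output of [simulate_phosphoproteome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_site_table(sim$sites[, setdiff(names(sim$sites), "window")],
                   sim$site_intensities, file.path(dir, "sites.tsv"))
  write_protein_table(sim$protein_intensities,
                      file.path(dir, "proteins.tsv"))
  write_fasta(sim$sequences, file.path(dir, "proteome.fasta"))
  write_study_design(sim$design, file.path(dir, "design.yaml"))
  jsonlite::write_json(sim$truth[c("site_truth", "protein_truth")],
                       file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
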