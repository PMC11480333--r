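#' Two-sample t test (Student or Welch)
#'
#' Classical two-sided two-sample t test on the supplied values: pooled
#' variance with df = n1 + n2 - 2 (`student`) or Satterthwaite degrees of
#' freedom (`welch`). Degenerate inputs are handled explicitly: with fewer
#' than 2 non-missing values in either group the result is untestable
#' (missing p with reason code); with zero variance in both groups the
#' statistic is 0 (p = 1) for equal means and +/-Inf (p = 0) otherwise.
#'
#' @param x,y numeric vectors (missing values dropped).
#' @param variant `"student"` or `"welch"`.
#' @return list with `t`, `df`, `p`, and `reason` (`NA` or `"untestable"`).
#' @export
two_group_test <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                reason = "untestable"))
  }
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (variant == "student") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- if (se > 0) {
      (v1 / n1 + v2 / n2)^2 /
        ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    } else NA_real_
  }
  if (!is.finite(se) || se == 0) {
    if (m1 == m2) return(list(t = 0, df = df, p = 1, reason = NA_character_))
    return(list(t = sign(m1 - m2) * Inf, df = df, p = 0,
                reason = NA_character_))
  }
  t <- (m1 - m2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), reason = NA_character_)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false discovery rate adjustment: sort the m p-values ascending,
#' compute p_(i) * m / i, enforce monotone non-decreasing adjusted values
#' from the largest rank down, cap at 1, and return in input order. Missing
#' values are skipped (they do not count towards m) and returned missing.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (!m) return(out)
  ord <- order(p[ok])
  adj <- p[ok][ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out[ok[ord]] <- pmin(adj, 1)
  out
}

# vectorized row-wise two-group t test: x, y are matrices (rows = features)
row_two_group_test <- function(x, y, variant = "student") {
  n1 <- rowSums(!is.na(x)); n2 <- rowSums(!is.na(y))
  m1 <- rowMeans(x, na.rm = TRUE); m2 <- rowMeans(y, na.rm = TRUE)
  v1 <- rowSums((x - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((y - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  testable <- n1 >= 2 & n2 >= 2
  if (variant == "student") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / pmax(n1 - 1, 1) + (v2 / n2)^2 / pmax(n2 - 1, 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  zero_se <- testable & (!is.finite(se) | se == 0)
  t[zero_se] <- ifelse(m1[zero_se] == m2[zero_se], 0,
                       sign(m1[zero_se] - m2[zero_se]) * Inf)
  p[zero_se] <- ifelse(m1[zero_se] == m2[zero_se], 1, 0)
  t[!testable] <- NA_real_
  p[!testable] <- NA_real_
  list(t = t, p = p, testable = testable)
}

#' Differential phosphosite calling across stage comparisons
#'
#' For each (test, reference) stage pair, tests every site on
#' log2-transformed calibrated values with a two-sample t test, adjusts
#' p-values per comparison with Benjamini-Hochberg, and applies the
#' significance rule: BH-adjusted p below `padj_max` and fold change beyond
#' `fc_min_phospho` (symmetric, |log2 FC| > log2 threshold). The fold change
#' is the ratio of arithmetic stage means of the calibrated values. A site
#' needs at least 2 non-missing values per compared stage to be testable.
#'
#' @param calibrated a `calibrated_matrix` (or plain positive matrix).
#' @param design a `study_design`.
#' @param comparisons list of `c(test, reference)` stage pairs; default all
#'   later-vs-earlier pairs of the design's stage order.
#' @param thresholds an [analysis_thresholds()].
#' @param variant t-test variant, `"student"` (default) or `"welch"`.
#' @return data.frame with one row per site per comparison: `site_id`,
#'   `comparison`, `log2fc`, `p_raw`, `p_adj`, `significant`, `direction`
#'   (`"up"`, `"down"` or `"none"`).
#' @export
differential_sites <- function(calibrated, design,
                               comparisons = default_comparisons(design),
                               thresholds = analysis_thresholds(),
                               variant = c("student", "welch")) {
  variant <- match.arg(variant)
  values <- if (inherits(calibrated, "calibrated_matrix")) {
    calibrated$values
  } else calibrated
  stages <- levels(design$stage)
  out <- lapply(comparisons, function(cmp) {
    if (!all(cmp %in% stages)) {
      stop("unknown stage label(s): ",
           paste(setdiff(cmp, stages), collapse = ", "), call. = FALSE)
    }
    test_cols <- design$sample[design$stage == cmp[1]]
    ref_cols <- design$sample[design$stage == cmp[2]]
    xt <- values[, test_cols, drop = FALSE]
    xr <- values[, ref_cols, drop = FALSE]
    lt <- log2(xt); lr <- log2(xr)
    lt[!is.finite(lt)] <- NA_real_
    lr[!is.finite(lr)] <- NA_real_
    tt <- row_two_group_test(lt, lr, variant)
    fc_num <- rowMeans(xt, na.rm = TRUE)
    fc_den <- rowMeans(xr, na.rm = TRUE)
    log2fc <- log2(fc_num / fc_den)
    p_adj <- bh_adjust(tt$p)
    significant <- !is.na(p_adj) & p_adj < thresholds$padj_max &
      is.finite(log2fc) & abs(log2fc) > log2(thresholds$fc_min_phospho)
    direction <- ifelse(significant, ifelse(log2fc > 0, "up", "down"), "none")
    data.frame(site_id = rownames(values),
               comparison = paste0(cmp[1], "_vs_", cmp[2]),
               log2fc = log2fc, p_raw = tt$p, p_adj = p_adj,
               significant = significant, direction = direction,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' @rdname differential_sites
#' @export
default_comparisons <- function(design) {
  stages <- levels(design$stage)
  cmp <- list()
  for (j in seq_along(stages)) {
    for (i in seq_along(stages)) {
      if (i < j) cmp[[length(cmp) + 1L]] <- c(stages[j], stages[i])
    }
  }
  cmp
}

#' Flag regulated sites across comparisons
#'
#' A site is regulated when it is significant in at least one of the
#' configured stage comparisons (the union rule).
#'
#' @param calls output of [differential_sites()].
#' @return data.frame with `site_id` and logical `regulated`.
#' @export
call_regulated <- function(calls) {
  reg <- tapply(calls$significant, calls$site_id, any)
  data.frame(site_id = names(reg), regulated = as.logical(reg),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential protein calling for label-free (DIA) two-group designs
#'
#' Student t test on log2 values with raw (unadjusted) p-values; a protein
#' is significant at raw p < `dia_p_max` and fold change beyond
#' `dia_fc_min` (symmetric on |log2 FC|).
#'
#' @param matrix protein intensity matrix.
#' @param design a two-stage `study_design`.
#' @param thresholds an [analysis_thresholds()].
#' @return data.frame: `protein_id`, `log2fc`, `p_raw`, `significant`,
#'   `direction`.
#' @export
differential_proteins_dia <- function(matrix, design,
                                      thresholds = analysis_thresholds()) {
  stages <- levels(design$stage)
  if (length(stages) != 2) {
    stop("DIA differential calling expects a two-group design", call. = FALSE)
  }
  xt <- matrix[, design$sample[design$stage == stages[2]], drop = FALSE]
  xr <- matrix[, design$sample[design$stage == stages[1]], drop = FALSE]
  lt <- log2(xt); lr <- log2(xr)
  lt[!is.finite(lt)] <- NA_real_
  lr[!is.finite(lr)] <- NA_real_
  tt <- row_two_group_test(lt, lr, "student")
  log2fc <- log2(rowMeans(xt, na.rm = TRUE) / rowMeans(xr, na.rm = TRUE))
  significant <- !is.na(tt$p) & tt$p < thresholds$dia_p_max &
    is.finite(log2fc) & abs(log2fc) > log2(thresholds$dia_fc_min)
  data.frame(protein_id = rownames(matrix), log2fc = log2fc, p_raw = tt$p,
             significant = significant,
             direction = ifelse(significant,
                                ifelse(log2fc > 0, "up", "down"), "none"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-stage mean profiles
#'
#' @param calibrated a `calibrated_matrix` or plain matrix.
#' @param design a `study_design`.
#' @return matrix sites x stages of arithmetic means over non-missing
#'   samples.
#' @export
stage_means <- function(calibrated, design) {
  values <- if (inherits(calibrated, "calibrated_matrix")) {
    calibrated$values
  } else calibrated
  stages <- levels(design$stage)
  out <- vapply(stages, function(st) {
    rowMeans(values[, design$sample[design$stage == st], drop = FALSE],
             na.rm = TRUE)
  }, numeric(nrow(values)))
  colnames(out) <- stages
  out
}

#' Standardize temporal profiles for clustering
#'
#' Scales each row of a sites x stages matrix to mean 0 and population
#' standard deviation 1 (divisor n, not n-1), the conventional preprocessing
#' before fuzzy c-means on temporal profiles. Constant rows carry no shape
#' information and are dropped; their ids are attached as the
#' `"dropped"` attribute.
#'
#' @param profiles numeric matrix (rows = sites, cols = stages).
#' @return standardized matrix, possibly with fewer rows.
#' @export
standardize_profiles <- function(profiles) {
  stopifnot(is.matrix(profiles), ncol(profiles) >= 2)
  mu <- rowMeans(profiles)
  sd_pop <- sqrt(rowMeans((profiles - mu)^2))
  keep <- sd_pop > 0 & is.finite(sd_pop)
  if (any(!keep)) {
    message(sum(!keep), " constant or non-finite profile(s) dropped")
  }
  out <- (profiles[keep, , drop = FALSE] - mu[keep]) / sd_pop[keep]
  attr(out, "dropped") <- rownames(profiles)[!keep]
  out
}

#' Fuzzy c-means clustering
#'
#' Minimizes the fuzzy objective J = sum_i sum_j u_ij^m ||x_i - c_j||^2 by
#' alternating updates: centers c_j = sum_i u_ij^m x_i / sum_i u_ij^m and
#' memberships u_ij = 1 / sum_k (d_ij / d_ik)^(2/(m-1)). Memberships are
#' initialized from a seeded uniform Dirichlet. Convergence when the largest
#' absolute membership change falls below `tol` or `max_iter` is reached. A
#' profile coincident with one or more centers gets its membership split
#' equally over those centers (1 when unique). With `nstart > 1`, the run
#' with the lowest final objective is returned (restarts are derived
#' deterministically from `seed`).
#'
#' @param profiles numeric matrix (rows = observations); typically
#'   standardized stage profiles.
#' @param c number of clusters.
#' @param m fuzzifier (> 1).
#' @param tol convergence tolerance on memberships.
#' @param max_iter iteration cap.
#' @param seed integer seed for the membership initialization.
#' @param nstart number of random restarts.
#' @return object of class `cluster_model`: list with `centers` (c x k),
#'   `memberships` (n x c, rows sum to 1), `hard_assignment` (argmax
#'   membership, ties to the lowest cluster index), `objective` (final
#'   value), `objective_trace` (per-iteration values, non-increasing),
#'   `iterations`, `c`, `m`, `seed`.
#' @export
fuzzy_cmeans <- function(profiles, c = 5, m = 2, tol = 1e-6, max_iter = 1000,
                         seed = 1L, nstart = 8L) {
  stopifnot(is.matrix(profiles), c >= 1, m > 1, nstart >= 1)
  n <- nrow(profiles)
  if (nrow(unique(profiles)) < c) {
    stop("fewer distinct profiles than clusters", call. = FALSE)
  }
  best <- NULL
  for (run in seq_len(nstart)) {
    set.seed(seed + (run - 1L) * 1009L)
    fit <- fcm_once(profiles, c, m, tol, max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  best$seed <- as.integer(seed)
  best
}

fcm_once <- function(x, c, m, tol, max_iter) {
  n <- nrow(x)
  # uniform Dirichlet initialization of memberships
  u <- matrix(stats::rgamma(n * c, shape = 1), n, c)
  u <- u / rowSums(u)
  trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    um <- u^m
    centers <- crossprod(um, x) / colSums(um)
    # squared Euclidean distances, n x c
    d2 <- outer(rowSums(x^2), rep(1, c)) - 2 * x %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    d2[d2 < 0] <- 0
    u_new <- fcm_memberships(d2, m)
    trace <- c(trace, sum(u_new^m * d2))
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol || iter >= max_iter) break
  }
  hard <- max.col(u, ties.method = "first")
  structure(list(centers = centers, memberships = u, hard_assignment = hard,
                 objective = trace[length(trace)], objective_trace = trace,
                 iterations = iter, c = c, m = m),
            class = "cluster_model")
}

fcm_memberships <- function(d2, m) {
  n <- nrow(d2); c <- ncol(d2)
  u <- matrix(0, n, c)
  zero <- d2 <= .Machine$double.eps
  has_zero <- rowSums(zero) > 0
  if (any(has_zero)) {
    u[has_zero, ] <- zero[has_zero, , drop = FALSE] /
      rowSums(zero[has_zero, , drop = FALSE])
  }
  if (any(!has_zero)) {
    e <- 1 / (m - 1)
    inv <- d2[!has_zero, , drop = FALSE]^(-e)
    u[!has_zero, ] <- inv / rowSums(inv)
  }
  u
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("Fuzzy c-means model: c =", x$c, ", m =", x$m, ",",
      nrow(x$memberships), "profiles,", x$iterations,
      "iterations, objective", format(x$objective, digits = 6), "\n")
  print(table(cluster = x$hard_assignment))
  invisible(x)
}

#' Cluster regulated sites on their temporal profiles
#'
#' Convenience wrapper: restrict the calibrated matrix to regulated sites,
#' compute per-stage means, standardize, and run [fuzzy_cmeans()].
#'
#' @param calibrated a `calibrated_matrix`.
#' @param design a `study_design`.
#' @param regulated data.frame from [call_regulated()].
#' @param c clusters (default from thresholds: 5).
#' @param ... passed to [fuzzy_cmeans()].
#' @return a `cluster_model` with `site_ids` naming the clustered rows.
#' @export
cluster_regulated <- function(calibrated, design, regulated, c = 5, ...) {
  ids <- regulated$site_id[regulated$regulated]
  values <- if (inherits(calibrated, "calibrated_matrix")) {
    calibrated$values
  } else calibrated
  prof <- stage_means(values[ids, , drop = FALSE], design)
  z <- standardize_profiles(prof)
  fit <- fuzzy_cmeans(z, c = c, ...)
  fit$site_ids <- rownames(z)
  fit
}

#' Integer percentage, rounded half away from zero
#'
#' Matches conventional manuscript rounding: `rounded_percent(26, 29)` is 90.
#'
#' @param numerator,denominator counts; denominator must be positive.
#' @return integer percentage.
#' @export
rounded_percent <- function(numerator, denominator) {
  stopifnot(denominator > 0)
  x <- 100 * numerator / denominator
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Phosphosite multiplicity per protein
#'
#' Counts phosphosites per protein and reports the rounded percentages of
#' phosphoproteins carrying at least two sites and more than six sites.
#'
#' @param sites site data.frame (needs `protein_id`).
#' @return list with `counts` (named integer vector per protein),
#'   `n_proteins`, `n_ge2`, `n_gt6`, `pct_ge2`, `pct_gt6`.
#' @export
summarize_multiplicity <- function(sites) {
  stopifnot(nrow(sites) > 0)
  counts <- table(sites$protein_id)
  n <- length(counts)
  n_ge2 <- sum(counts >= 2)
  n_gt6 <- sum(counts > 6)
  list(counts = c(counts), n_proteins = n, n_ge2 = n_ge2, n_gt6 = n_gt6,
       pct_ge2 = rounded_percent(n_ge2, n),
       pct_gt6 = rounded_percent(n_gt6, n))
}

#' Residue-type distribution of phosphosites
#'
#' @param sites site data.frame (needs `residue`).
#' @return named numeric fractions (S, T, Y) summing to 1.
#' @export
residue_distribution <- function(sites) {
  stopifnot(nrow(sites) > 0)
  tab <- table(factor(sites$residue, levels = c("S", "T", "Y")))
  c(tab) / nrow(sites)
}

#' Direction summary for one comparison
#'
#' @param calls rows of [differential_sites()] output for one comparison.
#' @return list with `n_significant`, `n_up`, `pct_up` (NA when nothing is
#'   significant).
#' @export
direction_summary <- function(calls) {
  stopifnot(length(unique(calls$comparison)) <= 1)
  n_sig <- sum(calls$significant)
  n_up <- sum(calls$direction == "up")
  list(n_significant = n_sig, n_up = n_up,
       pct_up = if (n_sig > 0) rounded_percent(n_up, n_sig) else NA_integer_)
}
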