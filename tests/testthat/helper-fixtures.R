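# shared fixtures; the default simulation is built once per test run
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_phosphoproteome(sim_config(seed = 1))
    cache
  }
})

site_to_protein_map <- function(sim) {
  stats::setNames(sim$sites$protein_id, sim$sites$site_id)
}

calibrated_for <- function(sim) {
  calibrate_pipeline(sim$site_intensities, sim$protein_intensities,
                     site_to_protein_map(sim))
}

tiny_design <- function(n_rep = 3) study_design(c("GV", "GVBD", "MII"), n_rep)

# write a generic-dialect site TSV and return the path
write_tmp_site_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# independent brute-force BH step-up (kept deliberately naive)
bh_bruteforce <- function(p) {
  m <- length(p)
  out <- numeric(m)
  for (i in seq_len(m)) {
    cands <- vapply(seq_len(m), function(j) {
      rj <- sum(p <= p[j])
      if (p[j] >= p[i]) p[j] * m / rj else Inf
    }, numeric(1))
    out[i] <- min(1, min(cands))
  }
  out
}

# independent hand-rolled adjusted Rand index
ari_bruteforce <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# independent Fisher two-sided p by explicit choose() enumeration over the
# conditional support, with the conventional relative tie tolerance
fisher_bruteforce <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- sum(tab)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- choose(c1, ks) * choose(n - c1, r1 - ks) / choose(n, r1)
  p_obs <- choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

hamming <- function(w1, w2) {
  sum(strsplit(w1, "")[[1]] != strsplit(w2, "")[[1]])
}
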