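test_that("two-group t test matches the closed form and handles degeneracy", {
  # identical nonconstant groups: no mean difference
  r <- two_group_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  # frozen closed-form case: means 2 and 3, pooled var 1, se = sqrt(2/3)
  r2 <- two_group_test(c(1, 2, 3), c(2, 3, 4), "student")
  expect_equal(r2$t, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r2$df, 4)
  expect_equal(r2$p, 2 * stats::pt(-abs(r2$t), 4), tolerance = 1e-12)
  expect_equal(round(r2$p, 4), 0.2879)

  # welch reduces to student for equal variances and sizes
  rw <- two_group_test(c(1, 2, 3), c(2, 3, 4), "welch")
  expect_equal(rw$p, r2$p, tolerance = 1e-12)
  expect_equal(rw$df, 4)

  # degenerate inputs
  expect_identical(two_group_test(c(1, 2), 5)$reason, "untestable")
  expect_equal(two_group_test(c(2, 2), c(2, 2))$p, 1)
  expect_equal(two_group_test(c(3, 3), c(2, 2))$p, 0)
  expect_equal(two_group_test(c(3, 3), c(2, 2))$t, Inf)
})

test_that("both t variants agree with the reference implementation", {
  set.seed(123)
  for (i in 1:50) {
    x <- stats::rnorm(sample(3:8, 1), sd = stats::runif(1, 0.5, 2))
    y <- stats::rnorm(sample(3:8, 1), mean = stats::runif(1, -1, 1))
    s <- two_group_test(x, y, "student")
    ref_s <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(s$t, unname(ref_s$statistic), tolerance = 1e-12)
    expect_equal(s$p, ref_s$p.value, tolerance = 1e-12)
    w <- two_group_test(x, y, "welch")
    ref_w <- stats::t.test(x, y)
    expect_equal(w$df, unname(ref_w$parameter), tolerance = 1e-12)
    expect_equal(w$p, ref_w$p.value, tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.5, 1.0)), c(1.0, 1.0))
  expect_equal(bh_adjust(c(0.2, NA, 0.01)), c(0.2, NA, 0.02))
  expect_error(bh_adjust(c(0.1, 1.3)), "\\[0, 1\\]")
})

test_that("BH adjustment agrees with brute force and the stats reference", {
  set.seed(7)
  for (i in 1:100) {
    p <- stats::runif(sample(1:40, 1))^sample(1:3, 1)
    a <- bh_adjust(p)
    expect_equal(a, bh_bruteforce(p), tolerance = 1e-12)
    expect_equal(a, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(a - p >= -1e-12 & a <= 1))
  }
})

test_that("differential calling applies the BH + fold-change gate", {
  # zero-noise simulation: planted effects are called exactly
  cfg <- sim_config(n_proteins = 40, sdlog = 0, protein_coverage = 1, seed = 2)
  sim <- simulate_phosphoproteome(cfg)
  cal <- calibrate_pipeline(sim$site_intensities, sim$protein_intensities,
                            site_to_protein_map(sim))
  calls <- differential_sites(cal, sim$design)
  reg <- call_regulated(calls)
  truth <- sim$truth$site_truth
  expect_setequal(reg$site_id[reg$regulated],
                  truth$site_id[truth$regulated])

  # a 1.2x effect fails the FC > 1.5 gate even at p ~ 0
  design <- tiny_design(5)
  m <- matrix(1, 2, 15, dimnames = list(c("x", "y"), design$sample))
  m["x", design$stage == "MII"] <- 1.2
  m["y", design$stage == "MII"] <- 2.0
  m <- m * matrix(exp(stats::rnorm(30, 0, 1e-6)), 2, 15)  # break constancy
  calls2 <- differential_sites(m, design,
                               comparisons = list(c("MII", "GV")))
  expect_false(calls2$significant[calls2$site_id == "x"])
  expect_true(calls2$significant[calls2$site_id == "y"])
  expect_identical(calls2$direction[calls2$site_id == "y"], "up")

  expect_error(differential_sites(m, design, list(c("M9", "GV"))), "unknown")
})

test_that("calls are invariant to permuting samples within a stage", {
  sim <- simulate_phosphoproteome(sim_config(n_proteins = 30, seed = 5))
  cal <- calibrated_for(sim)
  calls <- differential_sites(cal, sim$design)
  perm <- sim$design
  set.seed(1)
  for (st in levels(perm$stage)) {
    idx <- which(perm$stage == st)
    perm$sample[idx] <- sample(perm$sample[idx])
  }
  calls_perm <- differential_sites(cal, perm)
  expect_equal(calls$p_raw, calls_perm$p_raw, tolerance = 1e-12)
  expect_identical(calls$significant, calls_perm$significant)
})

test_that("DIA protein calling uses raw p and the 1.2x gate", {
  design <- study_design(c("ctrl", "mut"), 4)
  set.seed(2)
  m <- matrix(exp(stats::rnorm(4 * 8, 0, 1e-6)), 4, 8,
              dimnames = list(paste0("P", 1:4), design$sample))
  mut <- design$stage == "mut"
  m["P1", mut] <- m["P1", mut] * 1.3
  m["P2", mut] <- m["P2", mut] * 1.1
  res <- differential_proteins_dia(m, design)
  expect_true(res$significant[res$protein_id == "P1"])
  expect_false(res$significant[res$protein_id == "P2"])  # FC gate
  expect_false(res$significant[res$protein_id == "P3"])  # null
  expect_identical(res$direction[res$protein_id == "P1"], "up")
})

test_that("profile standardization uses population SD and drops constants", {
  m <- rbind(a = c(1, 2, 3), b = c(4, 4, 4))
  expect_message(z <- standardize_profiles(m), "constant")
  expect_equal(unname(z["a", ]), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_identical(attr(z, "dropped"), "b")
  # affine invariance
  z2 <- standardize_profiles(rbind(a = 100 + 7 * c(1, 2, 3)))
  expect_equal(unname(z2["a", ]), unname(z["a", ]), tolerance = 1e-12)
})

test_that("fuzzy c-means satisfies its optimisation contracts", {
  set.seed(31)
  x <- matrix(stats::rnorm(60), 20, 3)
  # c = 1: the single centre is the profile mean, memberships all 1
  f1 <- fuzzy_cmeans(x, c = 1, seed = 1, nstart = 1)
  expect_equal(unname(f1$centers[1, ]), unname(colMeans(x)), tolerance = 1e-6)
  expect_true(all(f1$memberships == 1))

  # two tight well-separated 1-D groups: centres near the group means
  g <- matrix(c(stats::rnorm(25, -5, 0.01), stats::rnorm(25, 5, 0.01)), ncol = 1)
  f2 <- fuzzy_cmeans(g, c = 2, m = 2, seed = 2)
  expect_equal(sort(f2$centers[, 1]), c(-5, 5), tolerance = 1e-2)
  expect_equal(sort(f2$centers[, 1]),
               sort(c(mean(g[1:25, 1]), mean(g[26:50, 1]))), tolerance = 1e-3)

  # objective non-increasing, memberships sum to one, determinism
  f3 <- fuzzy_cmeans(x, c = 3, seed = 5)
  expect_true(all(diff(f3$objective_trace) <= 1e-9))
  expect_equal(rowSums(f3$memberships), rep(1, 20), tolerance = 1e-9)
  f3b <- fuzzy_cmeans(x, c = 3, seed = 5)
  expect_identical(f3$memberships, f3b$memberships)

  # a profile coincident with a centre gets membership 1 there
  u <- phosphodyn:::fcm_memberships(rbind(c(0, 4), c(2, 3)), m = 2)
  expect_equal(u[1, ], c(1, 0))
  expect_equal(sum(u[2, ]), 1)

  expect_error(fuzzy_cmeans(matrix(1, 5, 2), c = 2), "distinct")
})

test_that("fuzzy c-means matches an independent implementation's objective", {
  skip_if_not_installed("e1071")
  set.seed(17)
  x <- rbind(matrix(stats::rnorm(40, -2, 0.3), ncol = 2),
             matrix(stats::rnorm(40, 2, 0.3), ncol = 2))
  mine <- fuzzy_cmeans(x, c = 2, m = 2, seed = 4)
  set.seed(4)
  ref <- e1071::cmeans(x, 2, m = 2, iter.max = 500)
  d2 <- vapply(1:2, function(j) colSums((t(x) - ref$centers[j, ])^2),
               numeric(nrow(x)))
  ref_obj <- sum(ref$membership^2 * d2)
  expect_equal(mine$objective, ref_obj, tolerance = 1e-3)
  # same hard partition up to label permutation
  expect_equal(ari_bruteforce(mine$hard_assignment, ref$cluster), 1)
})

test_that("descriptive summaries reproduce printed-style ratios", {
  expect_identical(rounded_percent(26, 29), 90L)
  expect_identical(rounded_percent(1, 2), 50L)
  expect_identical(rounded_percent(2268, 6700), 34L)

  sites <- data.frame(
    protein_id = c("A", "B", "B", rep("C", 7)),
    residue = c("S", "S", "T", rep("S", 6), "Y"))
  ms <- summarize_multiplicity(sites)
  expect_equal(ms$pct_ge2, 67L)   # 2 of 3 proteins
  expect_equal(ms$pct_gt6, 33L)   # 1 of 3 proteins
  expect_identical(rounded_percent(1508, 2604), 58L)
  expect_identical(rounded_percent(250, 2604), 10L)

  rd <- residue_distribution(data.frame(residue = c("S", "S", "T", "Y")))
  expect_equal(unname(rd), c(0.5, 0.25, 0.25))
  expect_equal(sum(rd), 1)

  calls <- data.frame(comparison = "MII_vs_GV",
                      significant = c(TRUE, TRUE, FALSE),
                      direction = c("up", "down", "none"))
  ds <- direction_summary(calls)
  expect_equal(ds$n_significant, 2)
  expect_identical(ds$pct_up, 50L)
  expect_identical(rounded_percent(168, 197), 85L)
  none <- direction_summary(calls[calls$significant == FALSE, ])
  expect_true(is.na(none$pct_up))
})
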