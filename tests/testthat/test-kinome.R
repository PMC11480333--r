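test_that("enzyme annotation is nested: regulated within phosphorylated within detected", {
  sites <- data.frame(site_id = c("K1:S5", "K1:S9", "P9:T2"),
                      protein_id = c("K1", "K1", "P9"))
  regulated <- data.frame(site_id = sites$site_id,
                          regulated = c(TRUE, FALSE, FALSE))
  ann <- annotate_enzymes(proteome_ids = c("K1", "K2", "PP1"),
                          sites = sites, regulated = regulated,
                          kinase_list = c("K1", "K2", "K3"),
                          phosphatase_list = c("PP1", "PP2"))
  st <- ann$status
  k1 <- st[st$enzyme_id == "K1", ]
  expect_true(k1$detected && k1$phosphorylated && k1$regulated)
  k2 <- st[st$enzyme_id == "K2", ]
  expect_true(k2$detected && !k2$phosphorylated)
  expect_false(any(st[st$enzyme_id %in% c("K3", "PP2"),
                      c("detected", "phosphorylated", "regulated")]))
  # nesting holds row-wise
  expect_true(all(st$regulated <= st$phosphorylated))
  expect_true(all(st$phosphorylated <= st$detected))
  counts <- ann$counts
  expect_true(all(counts$n_regulated <= counts$n_phosphorylated &
                    counts$n_phosphorylated <= counts$n_detected &
                    counts$n_detected <= counts$n_total))
})

test_that("Fisher exact p matches frozen enumerations and is symmetric", {
  # margins (1,1)/(1,1): both tables have probability 1/2
  expect_equal(fisher_exact_2x2(rbind(c(1, 0), c(0, 1)))$p, 1)
  # C(10,5) = 252; the two extreme tables have probability 1/252 each
  expect_equal(fisher_exact_2x2(rbind(c(5, 0), c(0, 5)))$p, 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(rbind(c(5, 0), c(0, 5)))$odds_ratio, Inf)
  # zero margin: degenerate, p = 1
  deg <- fisher_exact_2x2(rbind(c(0, 0), c(3, 4)))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
  # transpose symmetry on random tables
  set.seed(21)
  for (i in 1:25) {
    tab <- matrix(sample(0:12, 4, TRUE), 2)
    expect_equal(fisher_exact_2x2(tab)$p, fisher_exact_2x2(t(tab))$p,
                 tolerance = 1e-12)
  }
})

test_that("Fisher exact p agrees with the reference implementation", {
  set.seed(8)
  for (i in 1:60) {
    tab <- matrix(sample(0:15, 4, TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab)$p,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("kinase enrichment builds reconciling tables and flags planted kinases", {
  sim <- default_sim()
  cal <- calibrated_for(sim)
  calls <- differential_sites(cal, sim$design)
  mii <- calls[calls$comparison == "MII_vs_GV", ]
  net <- simulate_ks_network(sim, seed = 1)
  enr <- kinase_enrichment(mii, net$edges)
  # margins reconcile with the global counts
  n_up <- sum(mii$significant & mii$direction == "up")
  expect_true(all(enr$n_sub_up + enr$n_nonsub_up == n_up))
  expect_true(all(rowSums(enr[, c("n_sub_up", "n_sub_not_up", "n_nonsub_up",
                                  "n_nonsub_not_up")]) ==
                    length(unique(mii$site_id))))
  # up-archetype kinases enrich; their odds ratios exceed 1
  up_kin <- net$truth$kinase_id[net$truth$preferred_archetype %in%
                                  c("A3", "A4", "A5")]
  expect_true(all(enr$odds_ratio[enr$kinase_id %in% up_kin] > 1))
  # a kinase with no substrates in the universe is excluded with a diagnostic
  edges2 <- rbind(net$edges,
                  data.frame(kinase_id = "KGHOST", site_id = "nope",
                             score = 1))
  expect_message(enr2 <- kinase_enrichment(mii, edges2), "excluded")
  expect_false("KGHOST" %in% enr2$kinase_id)
  expect_identical(attr(enr2, "excluded"), "KGHOST")
})

test_that("null kinases are rarely significant under random substrate draws", {
  # 200 draws of a 15-substrate kinase from a fixed universe with the
  # background up-rate: the Fisher test should reject at ~alpha
  set.seed(14)
  n_uni <- 400; n_up <- 180; n_sub <- 15
  p <- replicate(200, {
    a <- stats::rhyper(1, n_up, n_uni - n_up, n_sub)
    tab <- rbind(c(a, n_sub - a), c(n_up - a, n_uni - n_sub - (n_up - a)))
    fisher_exact_2x2(tab)$p
  })
  frac <- mean(p < 0.05)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("activity inference recovers substrate trends and is scale invariant", {
  stages <- c("GV", "GVBD", "MII")
  mk <- function(id, profile) matrix(profile, 1, 3,
                                     dimnames = list(id, stages))
  profs <- rbind(mk("s1", c(3, 2, 1)), mk("s2", c(6, 4, 2)),
                 mk("s3", c(10, 7, 4)),
                 mk("u1", c(1, 2, 3)), mk("u2", c(2, 4, 6)),
                 mk("u3", c(4, 7, 10)))
  edges <- data.frame(
    kinase_id = c(rep("Kdown", 3), rep("Kflat", 6)),
    site_id = c("s1", "s2", "s3", "s1", "s2", "s3", "u1", "u2", "u3"))
  act <- infer_activity(edges, profs)
  expect_identical(act$trend[act$kinase_id == "Kdown"], "decreasing")
  # symmetric up/down substrates cancel to a flat profile
  expect_identical(act$trend[act$kinase_id == "Kflat"], "flat")
  expect_true(all(abs(unlist(act[act$kinase_id == "Kflat",
                                 paste0("act_", stages)])) < 0.25))
  # scale invariance: multiplying a substrate row by a constant changes nothing
  profs2 <- profs
  profs2["s2", ] <- profs2["s2", ] * 37
  act2 <- infer_activity(edges, profs2)
  expect_equal(act2[paste0("act_", stages)], act[paste0("act_", stages)],
               tolerance = 1e-12)
  # too few substrates: missing profile
  few <- infer_activity(edges[1:2, ], profs, min_substrates = 3)
  expect_true(is.na(few$trend[few$kinase_id == "Kdown"]))
})

test_that("planted kinase archetypes map to the expected activity trends", {
  sim <- default_sim()
  cal <- calibrated_for(sim)
  net <- simulate_ks_network(sim, seed = 1)
  act <- infer_activity(net$edges, stage_means(cal, sim$design))
  merged <- merge(act, net$truth, by = "kinase_id")
  expected <- c(A1 = "decreasing", A2 = "transient", A3 = "increasing",
                A4 = "increasing", A5 = "increasing")
  planted <- merged[!is.na(merged$preferred_archetype), ]
  hit <- planted$trend == expected[planted$preferred_archetype]
  expect_gte(mean(hit), 0.95)
})

test_that("edge tables and enzyme lists parse with validation", {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(kinase_id = c("K1", "K1"),
                                site_id = c("a", "b"), score = c(0.5, 0.9)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  e <- read_edge_table(path)
  expect_equal(nrow(e), 2)
  utils::write.table(data.frame(kinase_id = "K1", site_id = c("a", "a")),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_edge_table(path), "duplicate")
  lp <- tempfile()
  writeLines(c("K1", "", "K2 ", "K1"), lp)
  expect_identical(read_enzyme_list(lp), c("K1", "K2"))
})
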