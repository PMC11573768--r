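test_that("simulator is deterministic given the seed", {
  dc1 <- demo_community(seed = 42)
  dc2 <- demo_community(seed = 42)
  s1 <- simulate_community(dc1$genomes, dc1$scenario)
  s2 <- simulate_community(dc2$genomes, dc2$scenario)
  expect_identical(s1$orfs, s2$orfs)
  expect_identical(s1$coverage, s2$coverage)
  dc3 <- demo_community(seed = 43)
  s3 <- simulate_community(dc3$genomes, dc3$scenario)
  expect_false(identical(s3$coverage$coverage, s1$coverage$coverage))
})

test_that("scenario validation rejects malformed worlds", {
  ab <- matrix(c(0.6, 0.5), nrow = 2, ncol = 3)  # columns sum to 1.1
  expect_error(bloom_scenario(ab, seed = 1), "sum to 1")
  ab_ok <- matrix(c(0.5, 0.5), nrow = 2, ncol = 3)
  expect_error(bloom_scenario(ab_ok, noise_sd = -0.1, seed = 1), "noise_sd")
  expect_error(bloom_scenario(ab_ok[, 1:2, drop = FALSE], seed = 1),
               "3 samples")
  expect_error(bloom_scenario(ab_ok), "seed")
  sc <- bloom_scenario(ab_ok, seed = 1)
  sc <- plant_correlated_family(sc, "GH81", "positive")
  expect_error(plant_correlated_family(sc, "GH81", "negative"),
               "already planted")
  expect_error(plant_correlated_family(sc, "GH99", "sideways"))
})

test_that("noiseless planted copies are recovered exactly", {
  sim <- noiseless_sim(copies1 = c(GH16 = 3L))
  sets <- default_function_sets()
  for (s in sim$samples$sample_id) {
    cn <- copy_number(sim$orfs, sim$coverage, "Bacteroidetes", "GH16", s,
                      sets)
    expect_equal(cn, 3, tolerance = 1e-12)
  }
})

test_that("community-wide copy number is the coverage-weighted mean of planted copies", {
  sim <- noiseless_sim(copies1 = c(GH16 = 2L), copies2 = c(GH16 = 7L),
                       ab = c(0.7, 0.3))
  sets <- default_function_sets()
  # brute-force oracle: sum planted coverages by hand from the manifest
  exp_cov <- sim$manifest$expected_coverage
  s <- "S02"
  gh_orfs <- grep("GH16", rownames(exp_cov), value = TRUE)
  num <- sum(exp_cov[gh_orfs, s])
  usicg_orfs_g1 <- grep("^ctg_g01_usicg", rownames(exp_cov), value = TRUE)
  usicg_orfs_g2 <- grep("^ctg_g02_usicg", rownames(exp_cov), value = TRUE)
  den <- median(exp_cov[usicg_orfs_g1[1], s] + exp_cov[usicg_orfs_g2[1], s] +
                  numeric(11))  # every USiCG aggregates both genomes equally
  expect_equal(copy_number(sim$orfs, sim$coverage, NULL, "GH16", s, sets),
               num / den, tolerance = 1e-12)
  # and equals the abundance-weighted mean of planted copies
  expect_equal(num / den, (0.7 * 2 + 0.3 * 7) / (0.7 + 0.3),
               tolerance = 1e-12)
})

test_that("planted correlated families give Spearman rho of exactly +/-1 without noise", {
  genomes <- list(genome_model(c(phylum = "Bacteroidetes"),
                               c(GH16 = 2L)))
  ab <- matrix(1, 1, 8)
  sc <- bloom_scenario(ab, noise_sd = 0, depth = 20, seed = 5)
  sc <- plant_correlated_family(sc, "GH81", "positive", effect = 2)
  sc <- plant_correlated_family(sc, "GH95", "negative", effect = 2)
  sim <- simulate_community(genomes, sc)
  sets <- default_function_sets()
  cn <- copy_number_matrix(sim$orfs, sim$coverage, sim$samples,
                           "Bacteroidetes", c("GH81", "GH95"), sets)
  chl <- sim$samples$chlorophyll
  pos <- cn$value[cn$fun == "GH81"]
  neg <- cn$value[cn$fun == "GH95"]
  expect_equal(spearman_cor(pos, chl)$rho, 1)
  expect_equal(spearman_cor(neg, chl)$rho, -1)
})

test_that("annotation-noise truth labels obey direct set arithmetic", {
  sim <- noiseless_sim(copies1 = c(GH16 = 4L, GH30 = 3L),
                       copies2 = c(PL7 = 2L))
  set.seed(99)
  noisy <- plant_annotation_noise(sim, n_false_cazymes = 15, p_true = 1,
                                  p_false = 0)
  sets <- default_function_sets()
  filt <- filter_cazymes(noisy$orfs, sets)
  survivors <- filt$orfs$orf_id[vapply(filt$orfs$cazy, nzchar, TRUE)]
  expect_setequal(survivors, noisy$manifest$true_cazymes)
  expect_length(noisy$manifest$spurious_cazymes, 15)
  expect_length(intersect(survivors, noisy$manifest$spurious_cazymes), 0)
})

test_that("plant_annotation_noise validates inputs and handles the no-op case", {
  sim <- noiseless_sim()
  expect_error(plant_annotation_noise(sim, n_false_cazymes = -1), ">= 0")
  expect_error(plant_annotation_noise(sim, 0, p_true = 1.2), "0, 1")
  noisy <- plant_annotation_noise(sim, n_false_cazymes = 0)
  filt <- filter_cazymes(noisy$orfs, default_function_sets())
  ev <- evaluate_annotation(
    data.frame(orf_id = filt$orfs$orf_id[nzchar(filt$orfs$cazy)],
               family = "GH16"),
    data.frame(orf_id = noisy$manifest$true_cazymes, family = "GH16"),
    by_class = FALSE)
  expect_equal(ev$accuracy, 100)
})

test_that("pul layout validation enforces structural invariants", {
  expect_error(pul_layout("x", c("susC", "susD", "susC", "susD"),
                          rep("+", 4), c(0, 50, 50, 50), TRUE),
               "exactly one")
  expect_error(pul_layout("x", c("susC", "other", "susD"),
                          rep("+", 3), c(0, 50, 50), TRUE), "exactly one")
  expect_error(pul_layout("x", c("susC", "susD"), rep("+", 2), c(0, -80),
                          FALSE), "-50")
  planted <- plant_pul_contigs(decoy_pul_layouts())
  validate_orfs(planted$orfs)
  # gaps honoured exactly: good layout genes 50 bp apart
  g <- planted$orfs[planted$orfs$contig_id == "pul_good", ]
  g <- g[order(g$start), ]
  expect_equal(g$start[-1] - g$end[-nrow(g)] - 1L, rep(50L, nrow(g) - 1))
})
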