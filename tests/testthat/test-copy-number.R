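sets <- default_function_sets()

test_that("usicg_median matches a sort-based brute-force recomputation", {
  sim <- noiseless_sim(seed = 31, copies1 = c(GH16 = 2L))
  # perturb coverages so the aggregates differ per USiCG
  set.seed(31)
  sim$coverage$coverage <- sim$coverage$coverage * runif(nrow(sim$coverage),
                                                         0.5, 2)
  s <- "S03"
  got <- usicg_median(sim$orfs, sim$coverage, "Bacteroidetes", s, sets)
  # oracle: explicit per-id sums, explicit sort, central pair by hand
  sub <- sim$orfs[sim$orfs$tax_phylum == "Bacteroidetes", ]
  covs <- sim$coverage[sim$coverage$sample_id == s, ]
  agg <- sapply(sets$usicg_ids, function(u) {
    ids <- sub$orf_id[grepl(u, sub$cog)]
    sum(covs$coverage[covs$orf_id %in% ids])
  })
  srt <- sort(agg)
  n <- length(srt)
  oracle <- unname(if (n %% 2 == 1) srt[(n + 1) / 2]
                   else (srt[n / 2] + srt[n / 2 + 1]) / 2)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("zero median flags the denominator instead of zeroing values", {
  orfs <- rbind(
    blank_orf("u1", "c1", 1, 900, cog = "COG0048"),
    blank_orf("g1", "c1", 1000, 1900, cazy = "GH16", pfam = "PF00128"))
  cov <- flat_coverage(orfs, "S01", coverage = 5)
  # only 1 of 11 USiCGs present -> aggregates (5, 0 x10) -> median 0
  expect_equal(usicg_median(orfs, cov, "Bacteroidetes", "S01", sets), 0)
  expect_true(is.na(copy_number(orfs, cov, "Bacteroidetes", "GH16", "S01",
                                sets)))
  cnm <- copy_number_matrix(orfs, cov, tiny_samples(1), "Bacteroidetes",
                            "GH16", sets)
  expect_equal(cnm$flag, "undefined_denominator")
  # skip_absent changes the convention: median over present ids only
  expect_equal(usicg_median(orfs, cov, "Bacteroidetes", "S01", sets,
                            skip_absent = TRUE), 5)
  expect_error(usicg_median(orfs, cov, "Archaea", "S01", sets), "empty")
})

test_that("copy numbers are invariant to per-sample coverage rescaling", {
  sim <- noiseless_sim(seed = 17, copies1 = c(GH16 = 3L, GH30 = 2L))
  s <- "S02"
  base <- copy_number(sim$orfs, sim$coverage, "Bacteroidetes", "GH16", s,
                      sets)
  scaled <- sim$coverage
  scaled$coverage[scaled$sample_id == s] <-
    scaled$coverage[scaled$sample_id == s] * 37.5
  expect_equal(copy_number(sim$orfs, scaled, "Bacteroidetes", "GH16", s,
                           sets), base, tolerance = 1e-12)
})

test_that("numerators are additive over disjoint taxon subsets", {
  sim <- noiseless_sim(seed = 23, copies1 = c(GH16 = 2L),
                       copies2 = c(GH16 = 5L))
  s <- "S01"
  num <- function(taxon) {
    mask <- taxon_mask(sim$orfs, taxon) &
      bloomloci:::function_hit_mask(sim$orfs, "GH16")
    sum(bloomloci:::coverage_vector(sim$coverage, sim$orfs$orf_id[mask], s))
  }
  expect_equal(num("Bacteroidetes") + num("Proteobacteria"), num(NULL),
               tolerance = 1e-12)
})

test_that("CAZy class copy number counts multi-family genes once", {
  orfs <- rbind(
    do.call(rbind, lapply(seq_along(sets$usicg_ids), function(i)
      blank_orf(paste0("u", i), "c1", i * 1000, i * 1000 + 900,
                cog = sets$usicg_ids[i]))),
    blank_orf("g1", "c1", 20000, 20900, cazy = "GH16;GH30",
              pfam = "PF00128"),
    blank_orf("g2", "c1", 21000, 21900, cazy = "GH92", pfam = "PF00128"))
  cov <- flat_coverage(orfs, "S01", coverage = 2)
  # class GH: genes g1 (once, despite two families) + g2 -> 2 genes * 2x / 2x
  expect_equal(copy_number(orfs, cov, NULL, "GH", "S01", sets), 2)
  expect_equal(copy_number(orfs, cov, NULL, "GH16", "S01", sets), 1)
  expect_equal(copy_number(orfs, cov, NULL, "GH99", "S01", sets), 0)
})

test_that("taxon read percentages match planted abundances and sum to 100", {
  sim <- noiseless_sim(seed = 41, copies1 = c(GH16 = 2L),
                       copies2 = c(GH16 = 2L), ab = c(0.7, 0.3))
  s <- "S01"
  # equal genome sizes (same gene count/lengths) -> percentages = abundances
  p_bact <- taxon_read_percentage(sim$orfs, sim$coverage, "Bacteroidetes", s)
  p_prot <- taxon_read_percentage(sim$orfs, sim$coverage, "Proteobacteria", s)
  expect_equal(p_bact, 70, tolerance = 0.5)  # read rounding only
  expect_equal(p_prot, 30, tolerance = 0.5)
  expect_equal(p_bact + p_prot, 100, tolerance = 1e-6)
  # single-taxon community -> 100%
  one <- noiseless_sim(seed = 42, copies1 = c(GH16 = 1L),
                       copies2 = c(GH16 = 1L), ab = c(1, 0))
  expect_equal(taxon_read_percentage(one$orfs, one$coverage,
                                     "Bacteroidetes", "S01"), 100)
})

test_that("unclassified ORFs are excluded from the rank denominator", {
  orfs <- rbind(
    blank_orf("a", "c1", 1, 900, phylum = "Bacteroidetes"),
    blank_orf("b", "c1", 1000, 1900, phylum = "Proteobacteria"),
    blank_orf("c", "c1", 2000, 2900, phylum = ""))
  cov <- flat_coverage(orfs, "S01", reads = 10L)
  expect_equal(taxon_read_percentage(orfs, cov, "Bacteroidetes", "S01",
                                     rank = "phylum"), 50)
})
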