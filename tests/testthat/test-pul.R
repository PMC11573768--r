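sets <- default_function_sets()

test_that("sus gene tagging follows the domain lists", {
  orfs <- rbind(
    blank_orf("c_plug", "c1", 1, 900, pfam = "PF07715"),
    blank_orf("c_tigr", "c1", 1000, 1900, tigrfam = "TIGR04056"),
    blank_orf("d_ragb", "c1", 2000, 2900, pfam = "PF12741"),
    blank_orf("none", "c1", 3000, 3900, pfam = "PF09999"),
    blank_orf("both", "c1", 4000, 4900, pfam = "PF00593;PF07980"))
  expect_warning(tagged <- tag_sus_genes(orfs, sets), "both")
  flags <- tagged[, c("is_susC", "is_susD")]
  rownames(flags) <- tagged$orf_id
  expect_true(flags["c_plug", "is_susC"])
  expect_true(flags["c_tigr", "is_susC"])
  expect_true(flags["d_ragb", "is_susD"])
  expect_false(any(unlist(flags["none", ])))
  expect_true(flags["both", "is_susC"])     # susC precedence
  expect_false(flags["both", "is_susD"])
  tagged2 <- suppressWarnings(tag_sus_genes(orfs, sets,
                                            both_precedence = "susD"))
  expect_true(tagged2$is_susD[tagged2$orf_id == "both"])
})

test_that("tandem finding enforces adjacency, strand and the gap rule", {
  mk <- function(id, start, end, strand, pfam)
    blank_orf(id, "c1", start, end, strand, pfam = pfam)
  # gap 50 same strand -> tandem
  g <- rbind(mk("c", 1, 1500, "+", "PF00593"),
             mk("d", 1551, 2800, "+", "PF07980"))
  t1 <- find_tandems(tag_sus_genes(g, sets))
  expect_equal(nrow(t1), 1)
  expect_equal(t1$susC, "c"); expect_equal(t1$susD, "d")
  # opposite strands -> none
  g2 <- g; g2$strand[2] <- "-"
  expect_equal(nrow(find_tandems(tag_sus_genes(g2, sets))), 0)
  # intervening gene -> none
  g3 <- rbind(mk("c", 1, 1500, "+", "PF00593"),
              mk("x", 1551, 1800, "+", "PF09999"),
              mk("d", 1851, 2800, "+", "PF07980"))
  expect_equal(nrow(find_tandems(tag_sus_genes(g3, sets))), 0)
  # gap exactly 102 -> none; 101 -> tandem (strictly-less-than rule)
  g4 <- rbind(mk("c", 1, 1500, "+", "PF00593"),
              mk("d", 1603, 2800, "+", "PF07980"))
  expect_equal(nrow(find_tandems(tag_sus_genes(g4, sets))), 0)
  g5 <- rbind(mk("c", 1, 1500, "+", "PF00593"),
              mk("d", 1602, 2800, "+", "PF07980"))
  expect_equal(nrow(find_tandems(tag_sus_genes(g5, sets))), 1)
  # reversed linear order accepted unless strict_order
  g6 <- rbind(mk("d", 1, 1500, "+", "PF07980"),
              mk("c", 1551, 2800, "+", "PF00593"))
  tg6 <- tag_sus_genes(g6, sets)
  expect_equal(nrow(find_tandems(tg6)), 1)
  expect_equal(nrow(find_tandems(tg6, strict_order = TRUE)), 0)
  expect_equal(nrow(find_tandems(tag_sus_genes(g6[c(2, 1), ], sets))), 1)
})

test_that("a shared susC yields one tandem per susD partner", {
  g <- rbind(
    blank_orf("d1", "c1", 1, 900, pfam = "PF07980"),
    blank_orf("c", "c1", 951, 2200, pfam = "PF00593"),
    blank_orf("d2", "c1", 2251, 3200, pfam = "PF07980"))
  t <- find_tandems(tag_sus_genes(g, sets))
  expect_equal(nrow(t), 2)
  expect_setequal(t$susD, c("d1", "d2"))
})

test_that("locus extension follows the gap-or-cazyme rule", {
  lay <- pul_layout("L", c("susC", "susD", "cazyme", "cazyme", "cazyme"),
                    rep("+", 5), c(0, 50, 20, 30, 40), TRUE)
  g <- tag_sus_genes(plant_pul_contigs(lay)$orfs, sets)
  td <- find_tandems(g)
  loc <- extend_locus(g, td[1, ], sets)
  expect_equal(nrow(loc$locus), 5)
  expect_equal(loc$cazyme_count, 3)
  # non-cazyme at gap 150 stops the walk
  lay2 <- pul_layout("L2", c("susC", "susD", "other", "cazyme"),
                     rep("+", 4), c(0, 50, 150, 50), FALSE)
  g2 <- tag_sus_genes(plant_pul_contigs(lay2)$orfs, sets)
  loc2 <- extend_locus(g2, find_tandems(g2)[1, ], sets)
  expect_equal(nrow(loc2$locus), 2)
  # cazyme at gap 500 included; non-cazyme at gap 150 beyond it excluded
  lay3 <- pul_layout("L3", c("susC", "susD", "cazyme", "other"),
                     rep("+", 4), c(0, 50, 500, 150), FALSE)
  g3 <- tag_sus_genes(plant_pul_contigs(lay3)$orfs, sets)
  loc3 <- extend_locus(g3, find_tandems(g3)[1, ], sets)
  expect_equal(nrow(loc3$locus), 3)
  expect_equal(loc3$locus$role, c("susC", "susD", "cazyme"))
})

test_that("the decoy library funnel matches its truth table exactly", {
  planted <- plant_pul_contigs(decoy_pul_layouts())
  puls <- call_puls(planted$orfs, sets)
  called <- setNames(vapply(puls, function(p) p$called, TRUE),
                     vapply(puls, `[[`, "", "contig_id"))
  expect_equal(called[planted$truth$contig_id],
               setNames(planted$truth$should_call, planted$truth$contig_id))
  # the two canonical rejections carry their reasons
  reasons <- setNames(vapply(puls, `[[`, "", "rejection_reason"),
                      names(called))
  expect_equal(unname(reasons["pul_opp_inside"]), "opposite_strand_cazyme")
  expect_equal(unname(reasons["pul_tandem_only"]), "small_contig")
})

test_that("funnel counts are monotone and taxonomy is majority-voted", {
  planted <- plant_pul_contigs(decoy_pul_layouts())
  puls <- call_puls(planted$orfs, sets)
  f <- summarize_funnel(puls)
  cnt <- f$counts
  expect_true(cnt["tandems"] >= cnt["big_contig"] &&
                cnt["big_contig"] >= cnt["enough_cazymes"] &&
                cnt["enough_cazymes"] >= cnt["called_pul"])
  expect_equal(unname(f$by_taxon["Bacteroidetes"]), length(puls))
  # empty input -> all-zero funnel
  f0 <- summarize_funnel(list())
  expect_true(all(f0$counts == 0))
})

test_that("output is invariant to input row order", {
  planted <- plant_pul_contigs(decoy_pul_layouts())
  set.seed(1)
  shuffled <- planted$orfs[sample.int(nrow(planted$orfs)), ]
  r1 <- pul_report(call_puls(planted$orfs, sets))
  r2 <- pul_report(call_puls(shuffled, sets))
  o1 <- r1[order(r1$contig, r1$susC), ]
  o2 <- r2[order(r2$contig, r2$susC), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o1, o2)
})

test_that("incremental extension agrees with the window oracle on random contigs", {
  # 200 random contigs here; the full 1000-contig sweep runs in
  # test-acceptance.R
  for (seed in 1:200) {
    rc <- random_pul_contig(seed)
    td <- find_tandems(rc$genes)
    if (nrow(td) == 0) next
    loc <- extend_locus(rc$genes, td[1, ], sets)
    orc <- oracle_locus(rc$genes, td$susC_index[1], td$susD_index[1])
    expect_identical(loc$locus$orf_id, orc$orf_ids)
    expect_identical(loc$cazyme_count, orc$cazyme_count)
  }
})
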