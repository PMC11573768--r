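# Fixture builders: all in code, no data files.

blank_orf <- function(orf_id, contig_id, start, end, strand = "+",
                      phylum = "Bacteroidetes", cazy = "", pfam = "",
                      kegg = "", cog = "", tigrfam = "") {
  data.frame(orf_id = orf_id, contig_id = contig_id,
             start = as.integer(start), end = as.integer(end),
             strand = strand,
             tax_superkingdom = "Bacteria", tax_phylum = phylum,
             tax_class = "", tax_order = "", tax_family = "", tax_genus = "",
             cazy = cazy, pfam = pfam, kegg = kegg, cog = cog,
             tigrfam = tigrfam, stringsAsFactors = FALSE)
}

# Random valid ORF table for round-trip property tests
random_orf_table <- function(n, seed) {
  set.seed(seed)
  pool_caz <- c("GH13", "GH30_1", "PL7", "GT2", "CE4", "CBM50", "AA3_2")
  pool_pf <- c("PF00128", "PF00593", "PF07980", "PF09999")
  draw <- function(pool)
    paste(sample(pool, sample(0:min(3, length(pool)), 1)), collapse = ";")
  starts <- sort(sample.int(100000, n))
  do.call(rbind, lapply(seq_len(n), function(i) {
    blank_orf(sprintf("orf%03d", i),
              sprintf("ctg%02d", 1 + (i %% 4)),
              starts[i], starts[i] + sample(200:2000, 1),
              sample(c("+", "-"), 1),
              phylum = sample(c("Bacteroidetes", "Proteobacteria", ""), 1),
              cazy = draw(pool_caz), pfam = draw(pool_pf),
              kegg = draw(c("K01176", "K05349")),
              cog = draw(c("COG0048", "COG0366")),
              tigrfam = draw(c("TIGR04056")))
  }))
}

flat_coverage <- function(orfs, sample_ids, coverage = 1, reads = 10L) {
  cov <- expand.grid(orf_id = orfs$orf_id, sample_id = sample_ids,
                     stringsAsFactors = FALSE)
  cov$coverage <- coverage
  cov$reads <- as.integer(reads)
  cov
}

tiny_samples <- function(n = 4) {
  make_samples(sprintf("S%02d", seq_len(n)),
               as.Date("2021-03-01") + 7 * (seq_len(n) - 1),
               seq(0.1, 2, length.out = n))
}

# A two-genome noiseless simulation used across modules
noiseless_sim <- function(seed = 11, copies1 = c(GH16 = 3L),
                          copies2 = c(GH16 = 7L), ab = c(0.7, 0.3),
                          n_samples = 4) {
  genomes <- list(
    genome_model(c(superkingdom = "Bacteria", phylum = "Bacteroidetes"),
                 copies1),
    genome_model(c(superkingdom = "Bacteria", phylum = "Proteobacteria"),
                 copies2))
  abm <- matrix(rep(ab, n_samples), nrow = 2)
  scenario <- bloom_scenario(abm, chlorophyll = seq(0.1, 2,
                                                    length.out = n_samples),
                             noise_sd = 0, depth = 10, seed = seed)
  simulate_community(genomes, scenario)
}
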