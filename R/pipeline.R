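#' Default demonstration community
#'
#' Three planted genomes (a Bacteroidetes flavobacterium rich in glycoside
#' hydrolases and PULs, a gammaproteobacterium, an alphaproteobacterium) over
#' a 12-sample late-winter-to-bloom series, with one positively and one
#' negatively chlorophyll-correlated GH family planted in the Bacteroidetes.
#'
#' @param seed RNG seed.
#' @param n_samples samples in the series (default 12).
#' @param noise_sd coverage noise (default 0.1).
#' @return list with `genomes` and `scenario`, ready for
#'   [simulate_community()].
#' @export
demo_community <- function(seed, n_samples = 12, noise_sd = 0.1) {
  genomes <- list(
    genome_model(c(superkingdom = "Bacteria", phylum = "Bacteroidetes",
                   class = "Flavobacteriia", order = "Flavobacteriales"),
                 c(GH16 = 4L, GH17 = 3L, GH30 = 2L, GH92 = 3L, GH13 = 2L,
                   PL7 = 2L, CE4 = 1L, GT2 = 5L,
                   PF00593 = 6L, PF07980 = 6L, PF00884 = 2L)),
    genome_model(c(superkingdom = "Bacteria", phylum = "Proteobacteria",
                   class = "Gammaproteobacteria"),
                 c(GH23 = 2L, GH36 = 1L, GT2 = 4L, PF00593 = 3L)),
    genome_model(c(superkingdom = "Bacteria", phylum = "Proteobacteria",
                   class = "Alphaproteobacteria"),
                 c(GH3 = 1L, GT2 = 3L)))
  chl <- default_chlorophyll(n_samples)
  w <- chl / max(chl)
  ab <- rbind(0.1 + 0.5 * w, 0.3 - 0.05 * w, 0.6 - 0.45 * w)
  ab <- sweep(ab, 2, colSums(ab), "/")
  scenario <- bloom_scenario(ab, chlorophyll = chl, noise_sd = noise_sd,
                             seed = seed)
  scenario <- plant_correlated_family(scenario, "GH81", "positive",
                                      effect = 3, genome = 1L, base = 1)
  scenario <- plant_correlated_family(scenario, "GH95", "negative",
                                      effect = 3, genome = 1L, base = 1)
  list(genomes = genomes, scenario = scenario)
}

#' Run the full analysis pipeline
#'
#' Either simulates a community (when `simulate = TRUE`) or loads
#' `orfs.tsv` / `coverage.tsv` / `samples.tsv` from `input_dir`, then runs
#' consensus CAZyme filtering, copy numbers, GH profile distances + MDS,
#' the chlorophyll correlation screen and PUL detection, writing every stage
#' artifact plus a machine-readable run manifest to `out_dir`. Deterministic
#' given `seed`.
#'
#' @param out_dir output directory (created).
#' @param seed integer seed.
#' @param simulate simulate the demo community instead of reading inputs.
#' @param input_dir directory holding the three input TSVs when
#'   `simulate = FALSE`.
#' @param sets function sets (default packaged).
#' @param max_gap,min_cazymes,alpha pipeline thresholds.
#' @param dry_run validate configuration and exit without computing.
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(out_dir, seed = 1, simulate = TRUE,
                         input_dir = NULL, sets = default_function_sets(),
                         max_gap = 102, min_cazymes = 3, alpha = 0.01,
                         dry_run = FALSE) {
  if (max_gap <= 0 || min_cazymes <= 0) stop("thresholds must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!simulate) {
    if (is.null(input_dir)) stop("input_dir required when simulate = FALSE")
    for (f in c("orfs.tsv", "coverage.tsv", "samples.tsv"))
      if (!file.exists(file.path(input_dir, f)))
        stop("missing input file: ", file.path(input_dir, f))
  }
  if (dry_run) return(invisible(list(valid = TRUE)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (simulate) {
    dc <- demo_community(seed)
    sim <- simulate_community(dc$genomes, dc$scenario, sets)
    sim <- plant_annotation_noise(sim, n_false_cazymes = 20, p_true = 0.95,
                                  p_false = 0.05, sets = sets)
    layouts <- decoy_pul_layouts()
    planted <- plant_pul_contigs(layouts)
    sim$orfs <- rbind(sim$orfs, planted$orfs)
    extra <- expand.grid(orf_id = planted$orfs$orf_id,
                         sample_id = sim$samples$sample_id,
                         stringsAsFactors = FALSE)
    extra$coverage <- 2; extra$reads <- 18L
    sim$coverage <- rbind(sim$coverage, extra)
    sim$manifest$pul_truth <- planted$truth
    orfs <- sim$orfs; coverage <- sim$coverage; samples <- sim$samples
    write_orf_table(orfs, file.path(out_dir, "orfs.tsv"))
    write_coverage_table(coverage, file.path(out_dir, "coverage.tsv"))
    write_samples_table(samples, file.path(out_dir, "samples.tsv"))
    jsonlite::write_json(
      sim$manifest[c("seed", "depth", "noise_sd", "true_cazymes",
                     "spurious_cazymes")],
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  } else {
    samples <- read_samples_table(file.path(input_dir, "samples.tsv"))
    coverage <- read_coverage_table(file.path(input_dir, "coverage.tsv"))
    orfs <- read_orf_table(file.path(input_dir, "orfs.tsv"), coverage,
                           samples)
  }

  filt <- filter_cazymes(orfs, sets)
  write_orf_table(filt$orfs, file.path(out_dir, "filtered.tsv"))
  write.table(filt$log, file.path(out_dir, "filter_log.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  taxa <- setdiff(unique(filt$orfs$tax_phylum), "")
  fams <- unique(unlist(split_column(filt$orfs$cazy)))
  fams <- fams[grepl("^GH", fams)]
  cn <- copy_number_matrix(filt$orfs, coverage, samples, taxa,
                           c(fams, "GH", "GT"), sets)
  write.table(cn, file.path(out_dir, "copynum.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  mds <- NULL
  pm <- try(profile_matrix(cn, cazy_class = "GH"), silent = TRUE)
  if (!inherits(pm, "try-error") && nrow(pm) >= 3) {
    d <- chisq_distance(pm)
    mds <- classical_mds(d, k = min(2, nrow(pm) - 1))
    write.table(as.data.frame(d), file.path(out_dir, "dist.tsv"),
                sep = "\t", quote = FALSE)
    mds_df <- data.frame(row_id = rownames(mds$points), mds$points,
                         stringsAsFactors = FALSE)
    write.table(mds_df, file.path(out_dir, "mds.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  screen <- screen_families(cn, samples, taxon = "Bacteroidetes",
                            cazy_class = "GH", alpha = alpha)
  if (!is.null(screen$results))
    write.table(screen$results, file.path(out_dir, "corr.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  puls <- call_puls(filt$orfs, sets, max_gap = max_gap,
                    min_cazymes = min_cazymes)
  funnel <- summarize_funnel(puls)
  write.table(pul_report(puls), file.path(out_dir, "puls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(stage = names(funnel$counts),
                         n = as.integer(funnel$counts)),
              file.path(out_dir, "funnel.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_pul_gff(Filter(function(p) p$called, puls),
                file.path(out_dir, "puls.gff3"))

  manifest <- list(
    package = "bloomloci",
    version = as.character(utils::packageVersion("bloomloci")),
    seed = seed, simulate = simulate,
    parameters = list(max_gap = max_gap, min_cazymes = min_cazymes,
                      alpha = alpha),
    n_orfs = nrow(orfs), n_samples = nrow(samples),
    funnel = as.list(funnel$counts))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(orfs = orfs, filtered = filt, copynum = cn, mds = mds,
                 screen = screen, puls = puls, funnel = funnel))
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands (`demo`, `run`, `simulate`).
#' Installed as `inst/cli/bloomloci.R`; invoke with
#' `Rscript -e 'bloomloci::bloomloci_cli()' <subcommand> ...` or via the
#' wrapper script.
#'
#' @param args command-line arguments (default from the session).
#' @return exit status, invisibly (0 on success).
#' @export
bloomloci_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: bloomloci <demo|run|simulate> [--seed N] [--out DIR]",
    "[--in DIR] [--max-gap N] [--min-cazymes N] [--alpha X] [--dry-run]")
  if (length(args) == 0) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(name, default) {
    i <- which(args == name)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  out <- opt("--out", "bloomloci_out")
  status <- tryCatch({
    switch(cmd,
      demo = run_pipeline(out, seed = seed, simulate = TRUE,
                          dry_run = "--dry-run" %in% args),
      run = run_pipeline(out, seed = seed, simulate = FALSE,
                         input_dir = opt("--in", "."),
                         max_gap = as.numeric(opt("--max-gap", "102")),
                         min_cazymes = as.integer(opt("--min-cazymes", "3")),
                         alpha = as.numeric(opt("--alpha", "0.01")),
                         dry_run = "--dry-run" %in% args),
      simulate = {
        dc <- demo_community(seed)
        sim <- simulate_community(dc$genomes, dc$scenario)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_orf_table(sim$orfs, file.path(out, "orfs.tsv"))
        write_coverage_table(sim$coverage, file.path(out, "coverage.tsv"))
        write_samples_table(sim$samples, file.path(out, "samples.tsv"))
      },
      { message("unknown subcommand: ", cmd); message(usage)
        return(invisible(1L)) })
    0L
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
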