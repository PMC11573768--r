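#' Describe a planted genome for the community simulator
#'
#' A genome model states, per clade, how many copies of each function one
#' genome carries. Every universal single-copy gene (USiCG) is planted at
#' exactly one copy, which is what makes the USiCG-median denominator recover
#' genome equivalents.
#'
#' @param taxon named character vector giving the lineage, names among
#'   `c("superkingdom","phylum","class","order","family","genus")`; ranks may
#'   be omitted (unclassified).
#' @param function_copies named integer vector: function identifier (CAZy
#'   family such as `"GH30"`, or a PFAM/KEGG/COG/TIGRFAM id) to copies per
#'   genome. Values must be >= 0.
#' @param mean_gene_length mean gene length in bp used for coordinates and
#'   the coverage-to-reads conversion.
#' @return a `genome_model` list.
#' @export
genome_model <- function(taxon, function_copies = integer(0),
                         mean_gene_length = 900) {
  bad_rank <- setdiff(names(taxon), TAX_RANKS)
  if (length(bad_rank) > 0) stop("unknown rank(s): ",
                                 paste(bad_rank, collapse = ", "))
  if (length(function_copies) > 0 &&
      (is.null(names(function_copies)) || any(!nzchar(names(function_copies)))))
    stop("function_copies must be a named vector")
  if (any(function_copies < 0)) stop("function copies must be >= 0")
  structure(list(taxon = taxon,
                 function_copies = function_copies,
                 mean_gene_length = mean_gene_length),
            class = "genome_model")
}

#' Default chlorophyll a trajectory
#'
#' Low late-winter plateau (~0.1 ug/L) over the first three samples followed
#' by a logistic rise towards an early-summer peak, mimicking an Arctic
#' under-ice-to-bloom season.
#'
#' @param n_samples number of samples (default 12).
#' @param peak peak chlorophyll a in ug/L.
#' @return numeric vector of length `n_samples`.
#' @export
default_chlorophyll <- function(n_samples = 12, peak = 8) {
  t <- seq_len(n_samples)
  plateau <- rep(0.1, min(3, n_samples))
  if (n_samples <= 3) return(plateau[seq_len(n_samples)])
  rise <- peak / (1 + exp(-1.2 * (seq_len(n_samples - 3) -
                                    (n_samples - 3) / 2)))
  c(plateau, 0.1 + rise)
}

#' Describe a bloom sampling scenario
#'
#' @param abundance matrix of per-taxon relative abundances, one row per
#'   genome model, one column per sample; columns must sum to 1.
#' @param chlorophyll chlorophyll a trajectory (ug/L), length = n samples.
#' @param dates sample dates; default weekly from 2021-03-15.
#' @param noise_sd standard deviation of the multiplicative coverage noise
#'   (truncated Gaussian, so coverage stays positive).
#' @param depth sequencing depth scale: expected fold coverage of a
#'   single-copy gene in a taxon at relative abundance 1.
#' @param seed RNG seed (mandatory: the simulator is deterministic given it).
#' @param noise_model `"gaussian"` (truncated at -0.99) or `"lognormal"`.
#' @return a `bloom_scenario` list.
#' @export
bloom_scenario <- function(abundance, chlorophyll = NULL, dates = NULL,
                           noise_sd = 0.1, depth = 50, seed,
                           noise_model = c("gaussian", "lognormal")) {
  noise_model <- match.arg(noise_model)
  abundance <- as.matrix(abundance)
  n_samples <- ncol(abundance)
  if (n_samples < 3) stop("need at least 3 samples")
  if (missing(seed)) stop("a seed is required")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(abundance < 0)) stop("abundances must be >= 0")
  csums <- colSums(abundance)
  if (any(abs(csums - 1) > 1e-9))
    stop("per-sample abundances must sum to 1 (tolerance 1e-9); got ",
         paste(signif(csums, 6), collapse = ", "))
  if (is.null(chlorophyll)) chlorophyll <- default_chlorophyll(n_samples)
  if (length(chlorophyll) != n_samples)
    stop("chlorophyll length must equal the number of samples")
  if (any(chlorophyll < 0)) stop("chlorophyll must be >= 0")
  if (is.null(dates))
    dates <- as.Date("2021-03-15") + 7 * (seq_len(n_samples) - 1)
  structure(list(abundance = abundance, chlorophyll = chlorophyll,
                 dates = as.Date(dates), noise_sd = noise_sd, depth = depth,
                 seed = as.integer(seed), noise_model = noise_model,
                 correlated = list()),
            class = "bloom_scenario")
}

#' Plant a chlorophyll-correlated family into a scenario
#'
#' Registers a function family whose per-sample effective copy number in one
#' planted genome is a strictly monotone transform of chlorophyll, so the
#' noiseless Spearman correlation downstream is exactly +1 or -1.
#' The transform is `base * (1 + effect * c)` with `c` the chlorophyll scaled
#' to \[0, 1\] (positive direction) or `1 - c` (negative).
#'
#' @param scenario a [bloom_scenario()].
#' @param family function identifier to plant (must not already be planted).
#' @param direction `"positive"` or `"negative"`.
#' @param effect monotone link strength (> 0).
#' @param genome index of the genome model the family lives in.
#' @param base baseline copies per genome.
#' @return the modified scenario.
#' @export
plant_correlated_family <- function(scenario, family,
                                    direction = c("positive", "negative"),
                                    effect = 1, genome = 1L, base = 1) {
  direction <- match.arg(direction)
  if (family %in% vapply(scenario$correlated, `[[`, "", "family"))
    stop("family '", family, "' is already planted")
  if (effect <= 0) stop("effect must be > 0")
  scenario$correlated <- c(scenario$correlated,
                           list(list(family = family, direction = direction,
                                     effect = effect, genome = as.integer(genome),
                                     base = base)))
  scenario
}

#' Classify an annotation identifier into its database column
#' @keywords internal
classify_id <- function(id) {
  if (grepl(CAZY_PATTERN, id)) return("cazy")
  if (grepl("^PF[0-9]+$", id)) return("pfam")
  if (grepl("^TIGR[0-9]+$", id)) return("tigrfam")
  if (grepl("^K[0-9]{5}$", id)) return("kegg")
  if (grepl("^COG[0-9]+$", id)) return("cog")
  stop("cannot classify annotation id '", id,
       "' into cazy/pfam/kegg/cog/tigrfam")
}

#' @keywords internal
empty_orf_row <- function(orf_id, contig_id, start, end, strand, taxon) {
  row <- as.list(setNames(rep("", length(ORF_COLS)), ORF_COLS))
  row$orf_id <- orf_id; row$contig_id <- contig_id
  row$start <- start; row$end <- end; row$strand <- strand
  for (r in names(taxon)) row[[paste0("tax_", r)]] <- unname(taxon[[r]])
  row
}

#' Simulate a bloom community
#'
#' Builds a merged-assembly-style ORF table, a long coverage table, a sample
#' series and a ground-truth manifest. For every gene of genome `g` in sample
#' `s`, fold coverage is `abundance(g, s) * depth * m * (1 + eps)` where `m`
#' is the per-sample copy multiplier (1 except for planted correlated
#' families) and `eps ~ Normal(0, noise_sd)` truncated at -0.99 (or
#' lognormal, matched mean 1). Read counts are
#' `round(coverage * gene_length / 100)` (100 bp reads; only relative counts
#' matter downstream). Each planted copy of a function is its own ORF, so the
#' summed function coverage over USiCG median recovers the planted copies
#' exactly when `noise_sd = 0`.
#'
#' Every run is deterministic given `scenario$seed`.
#'
#' @param genomes list of [genome_model()]s, one per row of
#'   `scenario$abundance`.
#' @param scenario a [bloom_scenario()].
#' @param sets function sets (for the USiCG panel and carbohydrate
#'   co-annotations of planted cazymes); default [default_function_sets()].
#' @return list with `orfs`, `coverage`, `samples`, `manifest`.
#' @export
simulate_community <- function(genomes, scenario,
                               sets = default_function_sets()) {
  if (length(genomes) < 1) stop("need at least one genome model")
  if (length(genomes) != nrow(scenario$abundance))
    stop("abundance matrix must have one row per genome model")
  n_samples <- ncol(scenario$abundance)
  sample_ids <- sprintf("S%02d", seq_len(n_samples))
  samples <- make_samples(sample_ids, scenario$dates, scenario$chlorophyll)

  set.seed(scenario$seed)
  chl <- scenario$chlorophyll
  chl_scaled <- if (max(chl) > 0) chl / max(chl) else chl

  rows <- list()
  gene_meta <- list()   # per ORF: genome index, per-sample multiplier id
  carb_pf <- if (length(sets$carb_related$pfam) > 0)
    sets$carb_related$pfam[1] else ""

  for (g in seq_along(genomes)) {
    gm <- genomes[[g]]
    contig <- sprintf("ctg_g%02d", g)
    len <- gm$mean_gene_length
    pos <- 1L
    add_gene <- function(orf_id, annots, mult = NULL) {
      row <- empty_orf_row(orf_id, contig, pos, pos + len - 1L, "+", gm$taxon)
      for (id in annots) {
        col <- classify_id(id)
        row[[col]] <- join_ids(union(split_ids(row[[col]]), id))
      }
      rows[[length(rows) + 1L]] <<- row
      gene_meta[[length(gene_meta) + 1L]] <<-
        list(genome = g, mult = mult, orf_id = orf_id)
      # 150 bp spacing keeps simulated genome contigs outside the PUL gap
      # rule: locus geometry is planted only via explicit layouts
      pos <<- pos + len + 150L
    }
    for (u in sets$usicg_ids)
      add_gene(sprintf("%s_usicg_%s", contig, u), u)
    fc <- gm$function_copies
    for (f in names(fc)) {
      if (fc[[f]] == 0) next
      is_caz <- grepl(CAZY_PATTERN, f)
      annots <- if (is_caz && nzchar(carb_pf)) c(f, carb_pf) else f
      for (k in seq_len(fc[[f]]))
        add_gene(sprintf("%s_%s_%d", contig, f, k), annots)
    }
    for (cr in scenario$correlated) {
      if (cr$genome != g) next
      is_caz <- grepl(CAZY_PATTERN, cr$family)
      annots <- if (is_caz && nzchar(carb_pf)) c(cr$family, carb_pf) else cr$family
      mult <- if (cr$direction == "positive")
        cr$base * (1 + cr$effect * chl_scaled)
      else cr$base * (1 + cr$effect * (1 - chl_scaled))
      add_gene(sprintf("%s_%s_corr", contig, cr$family), annots, mult = mult)
    }
  }

  orfs <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  orfs$start <- as.integer(orfs$start)
  orfs$end <- as.integer(orfs$end)

  n_orfs <- nrow(orfs)
  cov_list <- vector("list", n_orfs)
  expected <- matrix(0, n_orfs, n_samples,
                     dimnames = list(orfs$orf_id, sample_ids))
  for (i in seq_len(n_orfs)) {
    meta <- gene_meta[[i]]
    ab <- scenario$abundance[meta$genome, ]
    mult <- if (is.null(meta$mult)) rep(1, n_samples) else meta$mult
    mu <- ab * scenario$depth * mult
    eps <- if (scenario$noise_sd == 0) rep(0, n_samples) else {
      if (scenario$noise_model == "gaussian")
        pmax(rnorm(n_samples, 0, scenario$noise_sd), -0.99)
      else exp(rnorm(n_samples, -scenario$noise_sd^2 / 2, scenario$noise_sd)) - 1
    }
    covv <- mu * (1 + eps)
    glen <- orfs$end[i] - orfs$start[i] + 1L
    cov_list[[i]] <- data.frame(
      orf_id = orfs$orf_id[i], sample_id = sample_ids,
      coverage = covv, reads = as.integer(round(covv * glen / 100)),
      stringsAsFactors = FALSE)
    expected[i, ] <- mu
  }
  coverage <- do.call(rbind, cov_list)
  rownames(coverage) <- NULL

  planted <- lapply(seq_along(genomes), function(g) {
    cr_fams <- vapply(Filter(function(x) x$genome == g, scenario$correlated),
                      `[[`, "", "family")
    list(taxon = genomes[[g]]$taxon,
         function_copies = as.list(genomes[[g]]$function_copies),
         correlated_families = cr_fams)
  })
  true_caz <- orfs$orf_id[vapply(orfs$cazy, nzchar, TRUE)]
  manifest <- list(
    seed = scenario$seed,
    depth = scenario$depth, noise_sd = scenario$noise_sd,
    noise_model = scenario$noise_model,
    abundance = scenario$abundance,
    chlorophyll = chl,
    genomes = planted,
    correlated = scenario$correlated,
    expected_coverage = expected,
    true_cazymes = true_caz,
    spurious_cazymes = character(0))

  validate_orfs(orfs, coverage, samples)
  list(orfs = orfs, coverage = coverage, samples = samples,
       manifest = manifest)
}

#' Inject annotation noise and spurious cazymes
#'
#' Emulates the false-positive structure the consensus filter targets: each
#' TRUE cazyme ORF carries a carbohydrate-related PFAM co-annotation with
#' probability `p_true` (otherwise all carbohydrate-related ids are stripped
#' from its PFAM/KEGG/COG sets); `n_false_cazymes` spurious cazyme ORFs are
#' appended on decoy contigs, each carrying a carbohydrate co-annotation with
#' probability `p_false`.
#'
#' @param sim result of [simulate_community()] (list with `orfs`, `coverage`,
#'   `samples`, `manifest`), or a bare ORF data.frame.
#' @param n_false_cazymes number of spurious cazyme ORFs to append (>= 0).
#' @param p_true,p_false carbohydrate co-annotation probabilities in \[0, 1\].
#' @param sets function sets supplying the carbohydrate-related ids.
#' @param families pool of CAZy family labels for spurious ORFs.
#' @return same shape as `sim`, with `manifest$true_cazymes` /
#'   `manifest$spurious_cazymes` updated (truth labels).
#' @export
plant_annotation_noise <- function(sim, n_false_cazymes, p_true = 1,
                                   p_false = 0,
                                   sets = default_function_sets(),
                                   families = c("GH2", "GH3", "GH13", "GT2",
                                                "PL7", "CE4")) {
  if (n_false_cazymes < 0) stop("n_false_cazymes must be >= 0")
  if (p_true < 0 || p_true > 1 || p_false < 0 || p_false > 1)
    stop("p_true and p_false must lie in [0, 1]")
  bare <- is.data.frame(sim)
  orfs <- if (bare) sim else sim$orfs
  carb_pf <- sets$carb_related$pfam[1]
  strip_carb <- function(row) {
    for (db in c("pfam", "kegg", "cog")) {
      ids <- setdiff(split_ids(row[[db]]), sets$carb_related[[db]])
      row[[db]] <- join_ids(ids)
    }
    row
  }
  is_caz <- vapply(orfs$cazy, nzchar, TRUE)
  true_ids <- orfs$orf_id[is_caz]
  for (i in which(is_caz)) {
    if (runif(1) <= p_true) {
      orfs$pfam[i] <- join_ids(union(split_ids(orfs$pfam[i]), carb_pf))
    } else {
      row <- strip_carb(as.list(orfs[i, ]))
      orfs[i, names(row)] <- row
    }
  }
  if (n_false_cazymes > 0) {
    fake <- lapply(seq_len(n_false_cazymes), function(k) {
      fam <- families[1 + (k - 1) %% length(families)]
      row <- empty_orf_row(sprintf("spurious_%04d", k),
                           sprintf("spur_ctg_%04d", k),
                           1L, 900L, "+", character(0))
      row$cazy <- fam
      # a spurious cazyme still resembles some protein: give it a neutral id
      row$pfam <- "PF09999"
      if (runif(1) <= p_false)
        row$pfam <- join_ids(c(row$pfam, carb_pf))
      row
    })
    fake_df <- do.call(rbind, lapply(fake, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    fake_df$start <- as.integer(fake_df$start)
    fake_df$end <- as.integer(fake_df$end)
    orfs <- rbind(orfs, fake_df)
  }
  spurious_ids <- if (n_false_cazymes > 0)
    sprintf("spurious_%04d", seq_len(n_false_cazymes)) else character(0)
  if (bare) return(list(orfs = orfs,
                        truth = list(true_cazymes = true_ids,
                                     spurious_cazymes = spurious_ids)))
  if (n_false_cazymes > 0 && !is.null(sim$coverage)) {
    extra <- expand.grid(orf_id = spurious_ids,
                         sample_id = sim$samples$sample_id,
                         stringsAsFactors = FALSE)
    extra$coverage <- 1
    extra$reads <- 9L
    sim$coverage <- rbind(sim$coverage, extra)
  }
  sim$orfs <- orfs
  sim$manifest$true_cazymes <- true_ids
  sim$manifest$spurious_cazymes <- spurious_ids
  sim
}
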