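#' Median USiCG coverage of a taxon subset (the copy-number denominator)
#'
#' For each configured universal single-copy gene, the coverages of every
#' subset ORF annotated with it are summed (0 when the gene is absent from
#' the subset — skipping absentees would inflate denominators for poorly
#' covered clades; set `skip_absent = TRUE` to opt out). The denominator is
#' the median over the panel; with an even count the mean of the central pair.
#' A zero median signals an undefined denominator: downstream cells are
#' flagged, never silently zeroed.
#'
#' @param orfs ORF data.frame.
#' @param coverage long coverage table.
#' @param taxon taxon name (see [taxon_mask()]); `NULL` = whole community.
#' @param sample sample_id.
#' @param sets function sets (USiCG panel).
#' @param rank optional rank restriction for the taxon match.
#' @param skip_absent drop USiCGs absent from the subset instead of counting
#'   them as zero.
#' @return median coverage (numeric scalar, possibly 0 = undefined).
#' @export
usicg_median <- function(orfs, coverage, taxon, sample, sets, rank = NULL,
                         skip_absent = FALSE) {
  mask <- taxon_mask(orfs, taxon, rank)
  if (!any(mask)) stop("taxon subset is empty")
  sub <- orfs[mask, , drop = FALSE]
  ann <- Map(function(p, k, c, t) c(p, k, c, t),
             split_column(sub$pfam), split_column(sub$kegg),
             split_column(sub$cog), split_column(sub$tigrfam))
  agg <- vapply(sets$usicg_ids, function(u) {
    hit <- vapply(ann, function(a) u %in% a, TRUE)
    if (!any(hit)) return(0)
    sum(coverage_vector(coverage, sub$orf_id[hit], sample))
  }, 0)
  if (skip_absent) agg <- agg[agg > 0]
  if (length(agg) == 0) return(0)
  median(agg)
}

#' @keywords internal
function_hit_mask <- function(orfs, fun) {
  classes <- c("GH", "GT", "PL", "CE", "AA", "CBM")
  caz_sets <- split_column(orfs$cazy)
  if (fun %in% classes) {
    vapply(caz_sets, function(f) any(cazy_class_of(f) == fun), TRUE)
  } else if (grepl(CAZY_PATTERN, fun)) {
    vapply(caz_sets, function(f) fun %in% f, TRUE)
  } else {
    ann <- Map(function(p, k, c, t) c(p, k, c, t),
               split_column(orfs$pfam), split_column(orfs$kegg),
               split_column(orfs$cog), split_column(orfs$tigrfam))
    vapply(ann, function(a) fun %in% a, TRUE)
  }
}

#' Function copy number for a taxon subset and sample
#'
#' The ratio between the summed coverage of all subset genes carrying the
#' function and the median USiCG coverage of the same subset: the average
#' number of gene copies per genome of the clade. `fun` may be a CAZy family
#' (`"GH30_1"`), a whole CAZy class (`"GH"`: genes with at least one family
#' of the class are counted once), or any PFAM/KEGG/COG/TIGRFAM id (so susC,
#' susD, sulfatases and peptidases work through their domain ids).
#'
#' @inheritParams usicg_median
#' @param fun function identifier or CAZy class.
#' @param denominator optionally pass a precomputed [usicg_median()].
#' @return numeric copy number, or `NA` (flagged) when the denominator is
#'   undefined.
#' @export
copy_number <- function(orfs, coverage, taxon, fun, sample, sets,
                        rank = NULL, denominator = NULL) {
  if (is.null(denominator))
    denominator <- usicg_median(orfs, coverage, taxon, sample, sets, rank)
  if (denominator <= 0) return(NA_real_)
  mask <- taxon_mask(orfs, taxon, rank) & function_hit_mask(orfs, fun)
  if (!any(mask)) return(0)
  sum(coverage_vector(coverage, orfs$orf_id[mask], sample)) / denominator
}

#' Copy-number matrix over taxa, functions and samples
#'
#' Long-form table with the USiCG denominator used for every (taxon, sample)
#' and a flag for undefined cells (zero denominator).
#'
#' @inheritParams copy_number
#' @param samples sample series.
#' @param taxa character vector of taxon names (`NA` entries = whole
#'   community, labelled `"community"`).
#' @param functions character vector of function ids / CAZy classes.
#' @return data.frame `taxon`, `fun`, `sample_id`, `value`, `denominator`,
#'   `flag` (`"ok"` or `"undefined_denominator"`).
#' @export
copy_number_matrix <- function(orfs, coverage, samples, taxa, functions,
                               sets) {
  out <- list()
  for (tx in taxa) {
    tx_arg <- if (is.na(tx) || identical(tx, "community")) NULL else tx
    tx_lab <- if (is.null(tx_arg)) "community" else tx
    for (s in samples$sample_id) {
      den <- usicg_median(orfs, coverage, tx_arg, s, sets)
      for (f in functions) {
        v <- copy_number(orfs, coverage, tx_arg, f, s, sets,
                         denominator = den)
        out[[length(out) + 1L]] <- data.frame(
          taxon = tx_lab, fun = f, sample_id = s,
          value = v, denominator = den,
          flag = if (den > 0) "ok" else "undefined_denominator",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Percentage of reads assigned to a taxon
#'
#' `100 * reads(taxon) / reads(classified at the taxon's rank)` for one
#' sample. ORFs unclassified at that rank (empty string) are excluded from
#' the denominator, so sibling taxa at one rank sum to 100.
#'
#' @inheritParams usicg_median
#' @param rank rank of the comparison; inferred from the first rank at which
#'   `taxon` occurs when omitted.
#' @return percentage (numeric scalar).
#' @export
taxon_read_percentage <- function(orfs, coverage, taxon, sample,
                                  rank = NULL) {
  if (is.null(rank)) rank <- infer_rank(orfs, taxon)
  col <- paste0("tax_", rank)
  classified <- nzchar(orfs[[col]])
  if (!any(classified))
    stop("no reads classified at rank ", rank, " in sample ", sample)
  denom <- sum(coverage_vector(coverage, orfs$orf_id[classified], sample,
                               what = "reads"))
  if (denom == 0)
    stop("zero classified reads at rank ", rank, " in sample ", sample)
  in_tax <- classified & orfs[[col]] == taxon
  num <- if (any(in_tax))
    sum(coverage_vector(coverage, orfs$orf_id[in_tax], sample,
                        what = "reads")) else 0
  100 * num / denom
}
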