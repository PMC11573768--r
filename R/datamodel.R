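#' @keywords internal
TAX_RANKS <- c("superkingdom", "phylum", "class", "order", "family", "genus")

#' @keywords internal
TAX_COLS <- paste0("tax_", TAX_RANKS)

#' @keywords internal
ANNOT_COLS <- c("cazy", "pfam", "kegg", "cog", "tigrfam")

#' @keywords internal
ORF_COLS <- c("orf_id", "contig_id", "start", "end", "strand",
              TAX_COLS, ANNOT_COLS)

CAZY_PATTERN <- "^(GH|GT|PL|CE|AA|CBM)[0-9]+(_[A-Za-z0-9]+)?$"

#' Split a ";"-joined annotation cell into an identifier vector
#'
#' Empty strings and `NA` become `character(0)`. This is the inverse of
#' [join_ids()] and the only place the on-disk set encoding is interpreted.
#'
#' @param x character scalar (one cell of an annotation column).
#' @return character vector of identifiers (possibly empty).
#' @export
split_ids <- function(x) {
  if (length(x) != 1L) stop("split_ids() expects a single cell")
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Join identifiers into a ";"-separated cell
#' @param ids character vector of identifiers.
#' @return character scalar; `""` for an empty set.
#' @export
join_ids <- function(ids) paste(ids, collapse = ";")

#' Per-row list of identifier sets for an annotation column
#' @keywords internal
split_column <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  out[is.na(x) | !nzchar(x)] <- list(character(0))
  out
}

#' Validate an ORF table against the documented schema
#'
#' Checks column presence, coordinate sanity (1-based inclusive,
#' `start <= end`), strand encoding, CAZy family label syntax, and (when a
#' sample series is supplied) that every sample referenced by the companion
#' coverage table is known.
#'
#' @param orfs data.frame in the `orfs.tsv` schema.
#' @param coverage optional long coverage data.frame
#'   (`orf_id`, `sample_id`, `coverage`, `reads`).
#' @param samples optional sample series (see [make_samples()]).
#' @return `orfs`, invisibly, after validation.
#' @export
validate_orfs <- function(orfs, coverage = NULL, samples = NULL) {
  missing_cols <- setdiff(ORF_COLS, names(orfs))
  if (length(missing_cols) > 0)
    stop("ORF table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(orfs$orf_id))
    stop("orf_id values must be unique")
  if (!is.numeric(orfs$start) || !is.numeric(orfs$end))
    stop("start/end must be numeric")
  bad <- which(orfs$start < 1 | orfs$end < 1 | orfs$start > orfs$end)
  if (length(bad) > 0)
    stop("invalid coordinates (need 1 <= start <= end) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad_strand <- which(!orfs$strand %in% c("+", "-"))
  if (length(bad_strand) > 0)
    stop("strand must be '+' or '-'; offending row(s): ",
         paste(utils::head(bad_strand, 5), collapse = ", "))
  fams <- unique(unlist(split_column(orfs$cazy)))
  bad_fam <- fams[!grepl(CAZY_PATTERN, fams)]
  if (length(bad_fam) > 0)
    stop("malformed CAZy family label(s): ", paste(bad_fam, collapse = ", "))
  if (!is.null(coverage)) {
    if (any(coverage$coverage < 0)) stop("coverage values must be >= 0")
    if (any(coverage$reads < 0)) stop("read counts must be >= 0")
    unknown_orf <- setdiff(unique(coverage$orf_id), orfs$orf_id)
    if (length(unknown_orf) > 0)
      stop("coverage refers to unknown orf_id(s): ",
           paste(utils::head(unknown_orf, 5), collapse = ", "))
    if (!is.null(samples)) {
      unknown <- setdiff(unique(coverage$sample_id), samples$sample_id)
      if (length(unknown) > 0)
        stop("coverage refers to unknown sample_id(s): ",
             paste(unknown, collapse = ", "),
             "; known samples: ", paste(samples$sample_id, collapse = ", "))
    }
  }
  invisible(orfs)
}

#' Construct a sample series
#'
#' An ordered set of samples with collection dates and chlorophyll a
#' concentrations (the bloom proxy). Dates must be strictly increasing and
#' sample identifiers unique.
#'
#' @param sample_id character vector of unique identifiers.
#' @param date `Date` vector (or ISO-8601 strings), strictly increasing.
#' @param chlorophyll non-negative numeric, micrograms per litre.
#' @return data.frame with columns `sample_id`, `date`, `chlorophyll`.
#' @export
make_samples <- function(sample_id, date, chlorophyll) {
  date <- as.Date(date)
  if (anyDuplicated(sample_id)) stop("sample_id values must be unique")
  if (length(date) != length(sample_id) ||
      length(chlorophyll) != length(sample_id))
    stop("sample_id, date and chlorophyll must have equal length")
  if (any(diff(date) <= 0)) stop("dates must be strictly increasing")
  if (any(chlorophyll < 0)) stop("chlorophyll must be >= 0")
  data.frame(sample_id = as.character(sample_id), date = date,
             chlorophyll = as.numeric(chlorophyll),
             stringsAsFactors = FALSE)
}

#' Read an ORF annotation table
#'
#' Reads the tab-separated `orfs.tsv` schema (one row per predicted gene;
#' set-valued annotation columns ";"-separated) and validates it.
#'
#' @param path file path.
#' @param coverage,samples optional companion tables passed to
#'   [validate_orfs()].
#' @return validated ORF data.frame.
#' @export
read_orf_table <- function(path, coverage = NULL, samples = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  orfs <- read.delim(path, sep = "\t", colClasses = "character",
                     check.names = FALSE, na.strings = NULL)
  missing_cols <- setdiff(ORF_COLS, names(orfs))
  if (length(missing_cols) > 0)
    stop("ORF table ", path, " is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  orfs$start <- as.integer(orfs$start)
  orfs$end <- as.integer(orfs$end)
  validate_orfs(orfs, coverage, samples)
  orfs[ORF_COLS]
}

#' Write an ORF annotation table
#' @param orfs validated ORF data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orf_table <- function(orfs, path) {
  validate_orfs(orfs)
  write.table(orfs[ORF_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read / write the long-form coverage table
#'
#' `coverage.tsv` has one row per (gene, sample): fold coverage and mapped
#' read count. Missing combinations are an error downstream, never silent
#' zeros.
#'
#' @param path file path.
#' @return data.frame `orf_id`, `sample_id`, `coverage`, `reads`.
#' @export
read_coverage_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cov <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("orf_id", "sample_id", "coverage", "reads")
  missing_cols <- setdiff(need, names(cov))
  if (length(missing_cols) > 0)
    stop("coverage table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  cov$coverage <- as.numeric(cov$coverage)
  cov$reads <- as.integer(cov$reads)
  cov[need]
}

#' @rdname read_coverage_table
#' @param coverage coverage data.frame.
#' @export
write_coverage_table <- function(coverage, path) {
  write.table(coverage, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample series table
#' @param path file path.
#' @return sample series data.frame (see [make_samples()]).
#' @export
read_samples_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  s <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "date", "chlorophyll")
  missing_cols <- setdiff(need, names(s))
  if (length(missing_cols) > 0)
    stop("samples table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  make_samples(s$sample_id, s$date, s$chlorophyll)
}

#' @rdname read_samples_table
#' @param samples sample series data.frame.
#' @export
write_samples_table <- function(samples, path) {
  out <- samples
  out$date <- format(out$date, "%Y-%m-%d")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Logical mask of ORFs belonging to a taxon
#'
#' Membership means exact name match at any rank of the stored lineage
#' (e.g. `"Bacteroidetes"` selects every ORF whose lineage contains that name
#' at any rank), or at one specific rank when `rank` is given. Unclassified
#' ranks are empty strings and never match.
#'
#' @param orfs ORF data.frame.
#' @param taxon taxon name, or `NULL` for the whole community.
#' @param rank optional rank name in
#'   `c("superkingdom","phylum","class","order","family","genus")`.
#' @return logical vector along rows of `orfs`.
#' @export
taxon_mask <- function(orfs, taxon, rank = NULL) {
  if (is.null(taxon)) return(rep(TRUE, nrow(orfs)))
  cols <- if (is.null(rank)) TAX_COLS else {
    if (!rank %in% TAX_RANKS) stop("unknown rank: ", rank)
    paste0("tax_", rank)
  }
  Reduce(`|`, lapply(cols, function(cl) orfs[[cl]] == taxon))
}

#' Infer the rank at which a taxon name occurs
#' @keywords internal
infer_rank <- function(orfs, taxon) {
  for (r in TAX_RANKS) if (any(orfs[[paste0("tax_", r)]] == taxon)) return(r)
  stop("taxon '", taxon, "' not found at any rank")
}

#' Rows of the coverage table for one sample, keyed by orf_id
#'
#' Errors if any requested ORF lacks coverage for the sample: missing
#' coverage is a data defect, not a zero.
#' @keywords internal
coverage_vector <- function(coverage, orf_ids, sample, what = "coverage") {
  sub <- coverage[coverage$sample_id == sample, , drop = FALSE]
  idx <- match(orf_ids, sub$orf_id)
  if (anyNA(idx))
    stop("missing ", what, " for sample '", sample, "' on ORF(s): ",
         paste(utils::head(orf_ids[is.na(idx)], 5), collapse = ", "))
  setNames(sub[[what]][idx], orf_ids)
}
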