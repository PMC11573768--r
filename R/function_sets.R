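#' Load function/domain identifier sets from a YAML config
#'
#' The config groups the identifier lists the pipeline needs:
#' * `usicg_ids` — universal single-copy genes used as the copy-number
#'   denominator (one copy expected per genome);
#' * `carb_related` — per-database (`pfam`, `kegg`, `cog`)
#'   carbohydrate-related identifiers backing the consensus CAZyme filter;
#' * `susc_domains`, `susd_domains` — domains that flag SusC transporters and
#'   SusD binding proteins for PUL detection;
#' * `sulfatase_ids`, `peptidase_ids` — accessory-gene annotation only.
#'
#' The packaged default (`default_function_sets()`) ships the published
#' SusC/SusD domain lists (PF00593, PF07715, PF13715, TIGR04056 /
#' PF07980, PF12741, PF12771, PF14322) and, because the original
#' single-copy-gene panel is not public, 11 ribosomal-protein COG
#' identifiers as a clearly labelled stand-in.
#'
#' @param path YAML file path.
#' @return a `function_sets` list.
#' @export
load_function_sets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  make_function_sets(
    usicg_ids = cfg$usicg_ids,
    carb_related = lapply(cfg$carb_related, as.character),
    susc_domains = cfg$susc_domains,
    susd_domains = cfg$susd_domains,
    sulfatase_ids = cfg$sulfatase_ids,
    peptidase_ids = cfg$peptidase_ids
  )
}

#' @rdname load_function_sets
#' @param usicg_ids,susc_domains,susd_domains,sulfatase_ids,peptidase_ids
#'   character vectors of identifiers.
#' @param carb_related named list with elements `pfam`, `kegg`, `cog`.
#' @export
make_function_sets <- function(usicg_ids, carb_related,
                               susc_domains, susd_domains,
                               sulfatase_ids = character(0),
                               peptidase_ids = character(0)) {
  usicg_ids <- as.character(usicg_ids)
  if (length(usicg_ids) == 0 || all(is.na(usicg_ids)))
    stop("usicg_ids must contain at least one identifier")
  carb_related <- carb_related[c("pfam", "kegg", "cog")]
  names(carb_related) <- c("pfam", "kegg", "cog")
  carb_related <- lapply(carb_related, function(x)
    if (is.null(x)) character(0) else as.character(x))
  susc_domains <- as.character(susc_domains)
  susd_domains <- as.character(susd_domains)
  overlap <- intersect(susc_domains, susd_domains)
  if (length(overlap) > 0)
    stop("susC and susD domain sets overlap: ", paste(overlap, collapse = ", "))
  structure(
    list(usicg_ids = unique(usicg_ids),
         carb_related = carb_related,
         susc_domains = unique(susc_domains),
         susd_domains = unique(susd_domains),
         sulfatase_ids = unique(as.character(sulfatase_ids)),
         peptidase_ids = unique(as.character(peptidase_ids))),
    class = "function_sets")
}

#' @rdname load_function_sets
#' @export
default_function_sets <- function() {
  load_function_sets(system.file("extdata", "function_sets.yaml",
                                 package = "bloomloci", mustWork = TRUE))
}
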