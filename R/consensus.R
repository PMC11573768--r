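#' Consensus CAZyme annotation filter
#'
#' Homology-based CAZyme calls are noisy: a gene can resemble a CAZy family
#' while actually being a different protein. The consensus rule keeps an
#' ORF's CAZy families (all of them) only when at least one of its PFAM, KEGG
#' or COG annotations is carbohydrate-related; otherwise the CAZy set is
#' emptied. Non-cazyme ORFs pass through untouched. Filtering is ORF-level:
#' co-annotations are not family-resolved, so one satisfying hit keeps every
#' family on the ORF.
#'
#' An ORF with a CAZy hit but no PFAM/KEGG/COG annotation at all is dropped
#' (the rule demands positive evidence); set `keep_unannotated = TRUE` to
#' invert that for exploratory use.
#'
#' @param orfs ORF data.frame.
#' @param sets function sets with `carb_related` defined for pfam/kegg/cog.
#' @param keep_unannotated keep cazyme ORFs lacking any PFAM/KEGG/COG ids.
#' @return list with `orfs` (filtered) and `log`: data.frame
#'   `orf_id`, `families`, `kept`, `evidence_db` (first database satisfying
#'   the rule, or `""`).
#' @export
filter_cazymes <- function(orfs, sets, keep_unannotated = FALSE) {
  carb <- sets$carb_related
  if (all(lengths(carb) == 0))
    warning("all carb_related sets are empty: every cazyme will be dropped")
  is_caz <- vapply(orfs$cazy, nzchar, TRUE)
  idx <- which(is_caz)
  kept <- logical(length(idx))
  evidence <- character(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    pf <- split_ids(orfs$pfam[i])
    kg <- split_ids(orfs$kegg[i])
    cg <- split_ids(orfs$cog[i])
    if (length(intersect(pf, carb$pfam)) > 0) {
      kept[k] <- TRUE; evidence[k] <- "pfam"
    } else if (length(intersect(kg, carb$kegg)) > 0) {
      kept[k] <- TRUE; evidence[k] <- "kegg"
    } else if (length(intersect(cg, carb$cog)) > 0) {
      kept[k] <- TRUE; evidence[k] <- "cog"
    } else if (keep_unannotated &&
               length(pf) + length(kg) + length(cg) == 0) {
      kept[k] <- TRUE; evidence[k] <- "unannotated"
    }
  }
  log <- data.frame(orf_id = orfs$orf_id[idx],
                    families = orfs$cazy[idx],
                    kept = kept, evidence_db = evidence,
                    stringsAsFactors = FALSE)
  orfs$cazy[idx[!kept]] <- ""
  list(orfs = orfs, log = log)
}

#' @keywords internal
strip_subfamily <- function(fam) sub("_.*$", "", fam)

#' @keywords internal
cazy_class_of <- function(fam) sub("^((GH|GT|PL|CE|AA|CBM)).*$", "\\1", fam)

#' Round half away from zero (display convention for percentages)
#' @keywords internal
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Evaluate predicted CAZyme annotations against a reference
#'
#' Both inputs are (orf_id, family) pair sets; matching is at family level
#' (subfamily suffixes are stripped before comparison). Recall is
#' `100 * TP / n_ref` and accuracy — precision — is `100 * TP / n_pred`.
#' When a side is empty, the corresponding metric is undefined (`NA`).
#'
#' @param predicted,reference data.frames with columns `orf_id`, `family`.
#' @param by_class also break results down by CAZy class (GH/GT/PL/CE/AA/CBM).
#' @return data.frame `cazy_class` (`"all"` row first), `n_ref`, `n_pred`,
#'   `tp`, `recall`, `accuracy` (real-valued percentages; round only for
#'   display).
#' @export
evaluate_annotation <- function(predicted, reference, by_class = TRUE) {
  key <- function(df) unique(paste(df$orf_id, strip_subfamily(df$family),
                                   sep = "\r"))
  fam_of <- function(k) sub("^.*\r", "", k)
  p <- key(predicted)
  r <- key(reference)
  one <- function(p, r, label) {
    tp <- length(intersect(p, r))
    data.frame(cazy_class = label,
               n_ref = length(r), n_pred = length(p), tp = tp,
               recall = if (length(r) > 0) 100 * tp / length(r) else NA_real_,
               accuracy = if (length(p) > 0) 100 * tp / length(p) else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- one(p, r, "all")
  if (by_class) {
    classes <- sort(unique(cazy_class_of(fam_of(c(p, r)))))
    for (cl in classes)
      out <- rbind(out, one(p[cazy_class_of(fam_of(p)) == cl],
                            r[cazy_class_of(fam_of(r)) == cl], cl))
  }
  rownames(out) <- NULL
  out
}
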