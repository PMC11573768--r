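#' Flag SusC and SusD genes by their domain annotations
#'
#' A gene is flagged susC when its PFAM or TIGRFAM ids intersect the
#' configured SusC domain set (TonB-dependent receptor machinery), and susD
#' when its PFAM ids intersect the SusD set (glycan-binding lipoproteins,
#' exclusive to Bacteroidetes). A gene matching both sets is logged and
#' given susC precedence by default.
#'
#' @param orfs ORF data.frame.
#' @param sets function sets with `susc_domains` / `susd_domains`.
#' @param both_precedence `"susC"` or `"susD"`: role for double matches.
#' @return `orfs` with logical columns `is_susC`, `is_susD` appended.
#' @export
tag_sus_genes <- function(orfs, sets, both_precedence = c("susC", "susD")) {
  both_precedence <- match.arg(both_precedence)
  pf <- split_column(orfs$pfam)
  tg <- split_column(orfs$tigrfam)
  susC <- mapply(function(p, t)
    length(intersect(c(p, t), sets$susc_domains)) > 0, pf, tg)
  susD <- vapply(pf, function(p)
    length(intersect(p, sets$susd_domains)) > 0, TRUE)
  both <- susC & susD
  if (any(both)) {
    warning(sum(both), " gene(s) match both susC and susD domains; ",
            "assigning ", both_precedence)
    if (both_precedence == "susC") susD[both] <- FALSE else susC[both] <- FALSE
  }
  orfs$is_susC <- as.logical(susC)
  orfs$is_susD <- as.logical(susD)
  orfs
}

#' Intergenic gap between two genes (bases strictly between them)
#' @keywords internal
intergenic_gap <- function(end_prev, start_next) {
  max(start_next - end_prev - 1L, 0L)
}

#' Find susC-susD tandems
#'
#' A tandem is an adjacent (no intervening gene) susC-flagged and
#' susD-flagged pair on the same strand, in either linear order, with an
#' intergenic gap below `max_gap` (default 102 bp, exclusive: gap <= 101
#' bases between the genes). Uniqueness is by (contig, susC, susD); a susC
#' shared by two susDs yields two tandems. With `strict_order = TRUE` only
#' pairs with susC upstream in transcription direction are kept.
#'
#' @param orfs output of [tag_sus_genes()].
#' @param max_gap gap threshold in bp (exclusive).
#' @param strict_order require susC upstream of susD.
#' @return data.frame `contig_id`, `susC`, `susD`, `strand`,
#'   `susC_index`, `susD_index` (row indices into the coordinate-sorted
#'   contig), one row per tandem.
#' @export
find_tandems <- function(orfs, max_gap = 102, strict_order = FALSE) {
  if (is.null(orfs$is_susC)) stop("run tag_sus_genes() first")
  out <- list()
  for (ctg in unique(orfs$contig_id)) {
    g <- orfs[orfs$contig_id == ctg, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    if (nrow(g) < 2) next
    for (i in seq_len(nrow(g) - 1L)) {
      a <- i; b <- i + 1L
      if (g$strand[a] != g$strand[b]) next
      gap <- intergenic_gap(g$end[a], g$start[b])
      if (gap >= max_gap) next
      cd <- g$is_susC[a] && g$is_susD[b]
      dc <- g$is_susD[a] && g$is_susC[b]
      if (!cd && !dc) next
      if (strict_order) {
        ok <- if (g$strand[a] == "+") cd else dc
        if (!ok) next
      }
      susC_i <- if (cd) a else b
      susD_i <- if (cd) b else a
      out[[length(out) + 1L]] <- data.frame(
        contig_id = ctg, susC = g$orf_id[susC_i], susD = g$orf_id[susD_i],
        strand = g$strand[a], susC_index = susC_i, susD_index = susD_i,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(contig_id = character(0), susC = character(0),
                      susD = character(0), strand = character(0),
                      susC_index = integer(0), susD_index = integer(0),
                      stringsAsFactors = FALSE))
  unique(do.call(rbind, out))
}

#' @keywords internal
gene_role <- function(g, sets) {
  if (isTRUE(g$is_susC)) return("susC")
  if (isTRUE(g$is_susD)) return("susD")
  if (nzchar(g$cazy)) return("cazyme")
  ids <- c(split_ids(g$pfam), split_ids(g$tigrfam))
  if (length(intersect(ids, sets$sulfatase_ids)) > 0) return("sulfatase")
  if (length(intersect(ids, sets$peptidase_ids)) > 0) return("peptidase")
  if ("PF00165" %in% ids) return("regulator")
  "other"
}

#' Extend a tandem into its locus
#'
#' Starting from the susC-susD pair, genes are added outward one at a time in
#' both directions along the coordinate-sorted contig. The next gene is
#' included iff it lies on the tandem strand AND (its intergenic gap to the
#' previous locus gene is below `max_gap`, OR it is a cazyme — cazymes are
#' exempt from the gap limit). The walk stops at the first gene failing both
#' conditions, at a strand change, or at the contig edge. Overlapping genes
#' (negative gaps) count as contiguous. Loci never cross contigs.
#'
#' @param contig_genes genes of one contig, coordinate-sorted, from
#'   [tag_sus_genes()] (cazy column assumed post-consensus-filter).
#' @param tandem one row of [find_tandems()] output.
#' @param sets function sets (for accessory-gene role labels).
#' @param max_gap gap threshold in bp (exclusive).
#' @return a `pul_candidate` list: `contig_id`, `susC`, `susD`, `strand`,
#'   `locus` (data.frame `orf_id,start,end,strand,role`), `cazyme_count`,
#'   `span`, plus placeholders for the funnel fields.
#' @export
extend_locus <- function(contig_genes, tandem, sets, max_gap = 102) {
  g <- contig_genes[order(contig_genes$start, contig_genes$end), ,
                    drop = FALSE]
  lo <- min(tandem$susC_index, tandem$susD_index)
  hi <- max(tandem$susC_index, tandem$susD_index)
  strand <- tandem$strand
  admissible <- function(prev_end, next_i, gap) {
    if (g$strand[next_i] != strand) return(FALSE)
    gap < max_gap || nzchar(g$cazy[next_i])
  }
  while (hi < nrow(g)) {
    gap <- intergenic_gap(g$end[hi], g$start[hi + 1L])
    if (!admissible(g$end[hi], hi + 1L, gap)) break
    hi <- hi + 1L
  }
  while (lo > 1L) {
    gap <- intergenic_gap(g$end[lo - 1L], g$start[lo])
    if (!admissible(g$end[lo - 1L], lo - 1L, gap)) break
    lo <- lo - 1L
  }
  idx <- lo:hi
  locus <- data.frame(orf_id = g$orf_id[idx], start = g$start[idx],
                      end = g$end[idx], strand = g$strand[idx],
                      cazy = g$cazy[idx],
                      role = vapply(idx, function(i)
                        gene_role(as.list(g[i, ]), sets), ""),
                      stringsAsFactors = FALSE)
  structure(list(contig_id = tandem$contig_id, susC = tandem$susC,
                 susD = tandem$susD, strand = strand, locus = locus,
                 cazyme_count = sum(nzchar(g$cazy[idx])),
                 span = c(min(g$start[idx]), max(g$end[idx])),
                 funnel_stage = NA_character_,
                 rejection_reason = NA_character_,
                 taxonomy = contig_taxonomy(g)),
            class = "pul_candidate")
}

#' Majority-vote contig taxonomy (ties at a rank give "")
#' @keywords internal
contig_taxonomy <- function(g) {
  vapply(TAX_COLS, function(cl) {
    v <- g[[cl]][nzchar(g[[cl]])]
    if (length(v) == 0) return("")
    tab <- sort(table(v), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) return("")
    names(tab)[1]
  }, "")
}

#' Call PULs and assign funnel stages
#'
#' Runs the whole funnel on an ORF table whose cazy annotations have already
#' been consensus-filtered: tag sus genes, find tandems, extend loci, then
#' stage every candidate:
#' * `small_contig` — the contig holds fewer than 3 genes besides the pair;
#' * `big_contig` — large enough, but fewer than 3 post-filter cazymes on the
#'   contig;
#' * `enough_cazymes` — >= 3 cazymes on the contig, but the locus itself has
#'   fewer than 3, or an opposite-strand cazyme lies within the locus span;
#' * `called_pul` — >= 3 cazymes in the locus and every cazyme within the
#'   span on the tandem strand.
#'
#' @param orfs post-filter ORF data.frame (cazy column refined).
#' @param sets function sets.
#' @param max_gap gap threshold (bp, exclusive; default 102).
#' @param min_cazymes cazymes required in the locus (default 3).
#' @param strict_order passed to [find_tandems()].
#' @return list of `pul_candidate`s with `funnel_stage`,
#'   `rejection_reason` and `called` finalized.
#' @export
call_puls <- function(orfs, sets, max_gap = 102, min_cazymes = 3,
                      strict_order = FALSE) {
  tagged <- tag_sus_genes(orfs, sets)
  tandems <- find_tandems(tagged, max_gap = max_gap,
                          strict_order = strict_order)
  out <- list()
  for (t in seq_len(nrow(tandems))) {
    td <- tandems[t, ]
    g <- tagged[tagged$contig_id == td$contig_id, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    cand <- extend_locus(g, td, sets, max_gap = max_gap)
    n_other_genes <- nrow(g) - 2L
    contig_caz <- sum(nzchar(g$cazy))
    if (n_other_genes < min_cazymes) {
      cand$funnel_stage <- "small_contig"
      cand$rejection_reason <- "small_contig"
    } else if (contig_caz < min_cazymes) {
      cand$funnel_stage <- "big_contig"
      cand$rejection_reason <- "few_cazymes_in_contig"
    } else {
      cand$funnel_stage <- "enough_cazymes"
      in_span <- g$start <= cand$span[2] & g$end >= cand$span[1]
      opp_caz <- any(in_span & nzchar(g$cazy) & g$strand != cand$strand)
      if (cand$cazyme_count < min_cazymes) {
        cand$rejection_reason <- "few_cazymes_in_locus"
      } else if (opp_caz) {
        cand$rejection_reason <- "opposite_strand_cazyme"
      } else {
        cand$funnel_stage <- "called_pul"
        cand$rejection_reason <- NA_character_
      }
    }
    cand$called <- identical(cand$funnel_stage, "called_pul")
    out[[length(out) + 1L]] <- cand
  }
  out
}

#' Summarize the PUL detection funnel
#'
#' @param candidates list from [call_puls()].
#' @param rank taxonomic rank for the per-taxon tandem breakdown.
#' @return list with `counts` (named vector: `tandems`, `big_contig`,
#'   `enough_cazymes`, `called_pul` — cumulative, so the funnel is monotone)
#'   and `by_taxon` (tandem counts per taxon at `rank`; unclassified = `""`).
#' @export
summarize_funnel <- function(candidates, rank = "phylum") {
  stages <- vapply(candidates, `[[`, "", "funnel_stage")
  reached <- function(s) sum(stages %in% s)
  counts <- c(
    tandems = length(candidates),
    big_contig = reached(c("big_contig", "enough_cazymes", "called_pul")),
    enough_cazymes = reached(c("enough_cazymes", "called_pul")),
    called_pul = reached("called_pul"))
  tax <- vapply(candidates, function(p) p$taxonomy[[paste0("tax_", rank)]], "")
  by_taxon <- if (length(tax) > 0) table(tax) else table(character(0))
  list(counts = counts, by_taxon = by_taxon)
}

#' Tabular PUL report
#'
#' One row per candidate, mirroring the pipeline's `puls.tsv` layout.
#'
#' @param candidates list from [call_puls()].
#' @return data.frame `contig`, `susC`, `susD`, `strand`, `n_cazymes`,
#'   `families`, `span_start`, `span_end`, `taxonomy`, `stage`, `reason`.
#' @export
pul_report <- function(candidates) {
  if (length(candidates) == 0)
    return(data.frame(contig = character(0), susC = character(0),
                      susD = character(0), strand = character(0),
                      n_cazymes = integer(0), families = character(0),
                      span_start = integer(0), span_end = integer(0),
                      taxonomy = character(0), stage = character(0),
                      reason = character(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(candidates, function(p) {
    data.frame(
      contig = p$contig_id, susC = p$susC, susD = p$susD,
      strand = p$strand, n_cazymes = p$cazyme_count,
      families = join_ids(unique(unlist(split_column(p$locus$cazy)))),
      span_start = p$span[1], span_end = p$span[2],
      taxonomy = paste(p$taxonomy[nzchar(p$taxonomy)], collapse = ";"),
      stage = p$funnel_stage,
      reason = if (is.na(p$rejection_reason)) "" else p$rejection_reason,
      stringsAsFactors = FALSE)
  }))
}
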