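#' Describe a PUL-like gene layout for the simulator
#'
#' A layout is an ordered plan of genes on one contig: role, strand, gap to
#' the previous gene (bp strictly between the genes; small overlaps down to
#' -50 allowed), and optionally explicit annotation ids. Exactly one adjacent
#' susC-susD pair is required per layout. `should_call` records the ground
#' truth: whether the locus caller, applying the clustering rules
#' (same strand, intergenic gap < 102 bp except for cazymes, >= 3 cazymes in
#' the locus, no opposite-strand cazyme within the span), must call a PUL.
#'
#' @param contig_id contig name.
#' @param roles character vector, each in
#'   `c("susC","susD","cazyme","sulfatase","peptidase","regulator","other")`.
#' @param strands `"+"`/`"-"` per gene.
#' @param gaps integer gaps to the previous gene (first entry ignored);
#'   must be >= -50.
#' @param should_call logical ground truth.
#' @param reason short truth rationale (e.g. `"ok"`, `"too_few_cazymes"`).
#' @param annots optional character vector of ";"-joined annotation ids per
#'   gene overriding the role defaults.
#' @param taxon named lineage vector for the contig's ORFs.
#' @return a `pul_layout` list.
#' @export
pul_layout <- function(contig_id, roles, strands, gaps, should_call,
                       reason = "", annots = NULL,
                       taxon = c(superkingdom = "Bacteria",
                                 phylum = "Bacteroidetes")) {
  n <- length(roles)
  valid_roles <- c("susC", "susD", "cazyme", "sulfatase", "peptidase",
                   "regulator", "other")
  if (!all(roles %in% valid_roles))
    stop("unknown role(s): ", paste(setdiff(roles, valid_roles), collapse = ", "))
  if (length(strands) != n || length(gaps) != n)
    stop("roles, strands and gaps must have equal length")
  if (any(gaps[-1] < -50)) stop("gaps must be >= -50")
  pair <- (roles[-n] == "susC" & roles[-1] == "susD") |
          (roles[-n] == "susD" & roles[-1] == "susC")
  if (sum(pair) != 1)
    stop("layout must contain exactly one adjacent susC-susD pair (found ",
         sum(pair), ")")
  structure(list(contig_id = contig_id, roles = roles, strands = strands,
                 gaps = gaps, should_call = isTRUE(should_call),
                 reason = reason, annots = annots, taxon = taxon),
            class = "pul_layout")
}

#' @keywords internal
role_default_annots <- function(role, k) {
  switch(role,
    susC = "PF00593;TIGR04056",
    susD = "PF07980",
    cazyme = sprintf("GH%d;PF00128", 15 + k),   # distinct family per gene
    sulfatase = "PF00884",
    peptidase = "PF00082",
    regulator = "PF00165",
    other = "PF09999")
}

#' Materialize PUL layouts as ORF rows plus a truth table
#'
#' Gene coordinates honour the requested gaps and strands exactly (gene
#' length fixed at 1,200 bp for susC, 900 bp otherwise). Cazyme genes carry a
#' carbohydrate-related PFAM co-annotation so they survive the consensus
#' filter; `other` genes carry a non-carbohydrate domain.
#'
#' @param layouts list of [pul_layout()]s.
#' @return list with `orfs` (data.frame fragment) and `truth`
#'   (data.frame `contig_id`, `should_call`, `reason`).
#' @export
plant_pul_contigs <- function(layouts) {
  if (inherits(layouts, "pul_layout")) layouts <- list(layouts)
  rows <- list()
  for (lay in layouts) {
    n <- length(lay$roles)
    pos <- 1L
    caz_i <- 0L
    for (j in seq_len(n)) {
      len <- if (lay$roles[j] == "susC") 1200L else 900L
      if (j > 1) pos <- pos + lay$gaps[j]
      start <- max(pos, 1L)
      annot <- if (!is.null(lay$annots) && nzchar(lay$annots[j]))
        lay$annots[j]
      else {
        if (lay$roles[j] == "cazyme") caz_i <- caz_i + 1L
        role_default_annots(lay$roles[j], caz_i)
      }
      row <- empty_orf_row(sprintf("%s_g%02d", lay$contig_id, j),
                           lay$contig_id, start, start + len - 1L,
                           lay$strands[j], lay$taxon)
      for (id in split_ids(annot)) {
        col <- classify_id(id)
        row[[col]] <- join_ids(union(split_ids(row[[col]]), id))
      }
      rows[[length(rows) + 1L]] <- row
      pos <- start + len
    }
  }
  orfs <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  orfs$start <- as.integer(orfs$start)
  orfs$end <- as.integer(orfs$end)
  truth <- data.frame(
    contig_id = vapply(layouts, `[[`, "", "contig_id"),
    should_call = vapply(layouts, `[[`, TRUE, "should_call"),
    reason = vapply(layouts, `[[`, "", "reason"),
    stringsAsFactors = FALSE)
  list(orfs = orfs, truth = truth)
}

#' Packaged decoy library for the PUL caller
#'
#' One callable locus plus the canonical near-misses, each annotated with its
#' ground truth:
#' * `good` — susC-susD tandem followed by three same-strand cazymes at
#'   small gaps: called.
#' * `few_caz` — only two cazymes: not called.
#' * `opp_strand` — three cazymes adjacent but on the opposite strand: not
#'   called (extension stops at the strand change and the same-direction rule
#'   fails).
#' * `severed` — a non-cazyme gene at a gap >= 102 bp severs the locus before
#'   three downstream cazymes: not called.
#' * `far_cazyme` — one cazyme at a 500 bp gap plus two at 50 bp: called
#'   (cazymes are exempt from the gap limit).
#' * `tandem_only` — the pair alone on a two-gene contig: not called
#'   (contig too small).
#' * `reversed_pair` — susD upstream of susC, three cazymes: called (pair
#'   order is free by default).
#' * `opp_inside` — three same-strand cazymes in the locus but one
#'   opposite-strand cazyme inside the span: not called (direction veto).
#'
#' @return list of [pul_layout()]s.
#' @export
decoy_pul_layouts <- function() {
  fw <- function(n) rep("+", n)
  list(
    pul_layout("pul_good", c("susC", "susD", "cazyme", "cazyme", "cazyme"),
               fw(5), c(0, 50, 50, 50, 50), TRUE, "ok"),
    pul_layout("pul_few_caz", c("susC", "susD", "cazyme", "cazyme"),
               fw(4), c(0, 50, 50, 50), FALSE, "too_few_cazymes"),
    pul_layout("pul_opp_strand", c("susC", "susD", "cazyme", "cazyme", "cazyme"),
               c("+", "+", "-", "-", "-"), c(0, 50, 50, 50, 50),
               FALSE, "cazymes_on_opposite_strand"),
    pul_layout("pul_severed",
               c("susC", "susD", "other", "cazyme", "cazyme", "cazyme"),
               fw(6), c(0, 50, 150, 50, 50, 50), FALSE, "locus_severed"),
    pul_layout("pul_far_cazyme", c("susC", "susD", "cazyme", "cazyme", "cazyme"),
               fw(5), c(0, 50, 50, 50, 500), TRUE, "gap_exempt_cazyme"),
    pul_layout("pul_tandem_only", c("susC", "susD"),
               fw(2), c(0, 50), FALSE, "small_contig"),
    pul_layout("pul_reversed_pair",
               c("susD", "susC", "cazyme", "cazyme", "cazyme"),
               fw(5), c(0, 50, 50, 50, 50), TRUE, "ok_reversed_order"),
    # three forward cazymes make a valid locus; a reverse-strand cazyme
    # overlapping the last locus gene (gap -50) sits inside the span
    pul_layout("pul_opp_inside",
               c("susC", "susD", "cazyme", "cazyme", "cazyme", "cazyme"),
               c("+", "+", "+", "+", "+", "-"), c(0, 50, 50, 50, 50, -50),
               FALSE, "opposite_strand_cazyme_in_span")
  )
}
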