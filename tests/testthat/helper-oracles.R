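# Independent reference implementations used as oracles. These deliberately
# take different routes from the package code paths they check.

# Brute-force locus oracle: enumerate whole windows around the tandem and
# keep the widest one in which every added gene individually satisfies the
# clustering predicate (same strand; gap < max_gap unless cazyme).
oracle_locus <- function(g, susC_i, susD_i, max_gap = 102) {
  g <- g[order(g$start, g$end), , drop = FALSE]
  strand <- g$strand[susC_i]
  lo0 <- min(susC_i, susD_i)
  hi0 <- max(susC_i, susD_i)
  gap <- function(a, b) max(g$start[b] - g$end[a] - 1L, 0L)
  gene_ok <- function(i, prev)
    g$strand[i] == strand &&
      (gap(min(i, prev), max(i, prev)) < max_gap || nzchar(g$cazy[i]))
  right_ok <- vapply(seq_len(nrow(g)), function(hi) {
    if (hi < hi0) return(FALSE)
    all(vapply(seq_len(nrow(g))[seq_len(nrow(g)) > hi0 &
                                seq_len(nrow(g)) <= hi],
               function(i) gene_ok(i, i - 1L), TRUE))
  }, TRUE)
  left_ok <- vapply(seq_len(nrow(g)), function(lo) {
    if (lo > lo0) return(FALSE)
    all(vapply(seq_len(nrow(g))[seq_len(nrow(g)) >= lo &
                                seq_len(nrow(g)) < lo0],
               function(i) gene_ok(i, i + 1L), TRUE))
  }, TRUE)
  idx <- min(which(left_ok)):max(which(right_ok))
  list(idx = idx,
       orf_ids = g$orf_id[idx],
       cazyme_count = sum(nzchar(g$cazy[idx])),
       span = c(min(g$start[idx]), max(g$end[idx])))
}

# Direct predicate: should this tandem be called a PUL?
oracle_called <- function(g, susC_i, susD_i, max_gap = 102,
                          min_cazymes = 3) {
  g <- g[order(g$start, g$end), , drop = FALSE]
  if (nrow(g) - 2L < min_cazymes) return(FALSE)
  if (sum(nzchar(g$cazy)) < min_cazymes) return(FALSE)
  loc <- oracle_locus(g, susC_i, susD_i, max_gap)
  if (loc$cazyme_count < min_cazymes) return(FALSE)
  strand <- g$strand[susC_i]
  in_span <- g$start <= loc$span[2] & g$end >= loc$span[1]
  !any(in_span & nzchar(g$cazy) & g$strand != strand)
}

# Random contig with a guaranteed susC-susD tandem (plus random flanks),
# returning tagged, coordinate-sorted genes and the tandem row indices.
random_pul_contig <- function(seed) {
  set.seed(seed)
  n_left <- sample(0:5, 1)
  n_right <- sample(0:6, 1)
  n <- n_left + 2L + n_right
  tandem_strand <- sample(c("+", "-"), 1)
  roles <- c(sample(c("cazyme", "other", "sulfatase"), n_left, TRUE),
             sample(c("susC_t", "susD_t"), 2),  # adjacent pair, random order
             sample(c("cazyme", "other", "regulator"), n_right, TRUE))
  strands <- ifelse(seq_len(n) %in% (n_left + 1:2), tandem_strand,
                    sample(c(tandem_strand, tandem_strand, "+", "-"), n,
                           TRUE))
  gaps <- c(0, sample(c(0L, 10L, 50L, 101L, 102L, 150L, 500L), n - 1L,
                      TRUE, prob = c(3, 3, 3, 1, 1, 2, 1)))
  gaps[n_left + 2L] <- sample(c(0L, 50L, 101L), 1)  # keep the tandem valid
  pos <- 1L
  rows <- lapply(seq_len(n), function(i) {
    len <- sample(300:1500, 1)
    if (i > 1) pos <<- pos + gaps[i]
    start <- pos
    pos <<- start + len
    ann <- switch(roles[i],
      susC_t = list(pfam = "PF00593", cazy = ""),
      susD_t = list(pfam = "PF07980", cazy = ""),
      cazyme = list(pfam = "PF00128", cazy = sample(c("GH16", "GH30_1",
                                                      "PL7"), 1)),
      sulfatase = list(pfam = "PF00884", cazy = ""),
      regulator = list(pfam = "PF00165", cazy = ""),
      other = list(pfam = "PF09999", cazy = ""))
    blank_orf(sprintf("g%02d", i), "rc", start, pos - 1L, strands[i],
              cazy = ann$cazy, pfam = ann$pfam)
  })
  g <- do.call(rbind, rows)
  g <- tag_sus_genes(g, default_function_sets())
  list(genes = g, susC_i = which(g$is_susC)[1], susD_i = which(g$is_susD)[1],
       strand = tandem_strand)
}

# Independent exact permutation p-value for Spearman: generates permutations
# recursively (a different algorithm from the package's) and counts.
oracle_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  perms_list <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms_list(v[-i]), function(p) c(v[i], p)))
    out
  }
  rhos <- vapply(perms_list(ry), function(p) cor(rx, p), 0)
  mean(abs(rhos) >= abs(rho) - 1e-12)
}
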