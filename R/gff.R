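#' Export PUL candidates to GFF3
#'
#' Writes one `polysaccharide_utilization_locus` feature spanning each locus,
#' plus one child `gene` feature per locus member carrying a `role` attribute
#' (`cazyme`, `susC`, `susD`, `sulfatase`, `peptidase`, `regulator`, `other`).
#' Coordinates are written 1-based inclusive, unshifted — the package-wide
#' convention already matches GFF3.
#'
#' @param puls list of PUL candidates (see [call_puls()]); only entries with
#'   a populated locus are written. An empty list yields a header-only file.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pul_gff <- function(puls, path) {
  lines <- "##gff-version 3"
  esc <- function(x) gsub("[;=,\t]", "_", x)
  for (i in seq_along(puls)) {
    p <- puls[[i]]
    pid <- sprintf("PUL%04d", i)
    lines <- c(lines, paste(
      p$contig_id, "bloomloci", "polysaccharide_utilization_locus",
      p$span[1], p$span[2], ".", p$strand, ".",
      sprintf("ID=%s;Name=%s;cazyme_count=%d;stage=%s",
              pid, pid, p$cazyme_count, p$funnel_stage),
      sep = "\t"))
    loc <- p$locus
    for (j in seq_len(nrow(loc))) {
      lines <- c(lines, paste(
        p$contig_id, "bloomloci", "gene",
        loc$start[j], loc$end[j], ".", loc$strand[j], ".",
        sprintf("ID=%s;Parent=%s;role=%s",
                esc(loc$orf_id[j]), pid, loc$role[j]),
        sep = "\t"))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
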