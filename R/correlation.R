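#' All permutations of 1..n (internal, n <= 8)
#' @keywords internal
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                         drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation with exact small-sample p-values
#'
#' rho is the Pearson correlation of average-rank vectors (the tie-robust
#' formulation — with ties the `1 - 6*sum(d^2)/...` shortcut is not used).
#' The two-sided p-value is computed by full enumeration of all `n!`
#' permutations of one rank vector for `n <= 8` (exact even under ties),
#' and by the t-approximation with `n - 2` degrees of freedom otherwise.
#' Time series of around a dozen samples sit exactly where asymptotic
#' p-values are unreliable, hence the exact default.
#'
#' @param x,y numeric vectors of equal length `n >= 4`.
#' @param method `"auto"` (exact for n <= 8), `"exact"`, or `"approx"`.
#' @return list with `rho`, `p_value`, `n`, `method`. Constant input yields
#'   `rho = NA` (flagged, not an error).
#' @export
spearman_cor <- function(x, y, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4) stop("need at least 4 observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined_constant_input"))
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  use_exact <- method == "exact" || (method == "auto" && n <= 8)
  if (use_exact && n > 8) stop("exact enumeration limited to n <= 8")
  if (use_exact) {
    perms <- permutations_of(n)
    # Pearson of rx with permuted ry: precompute centered/scaled vectors
    cx <- (rx - mean(rx)) / sqrt(sum((rx - mean(rx))^2))
    cy <- (ry - mean(ry)) / sqrt(sum((ry - mean(ry))^2))
    rhos <- as.vector((matrix(cy[perms], nrow(perms)) %*% cx))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    list(rho = rho, p_value = p, n = n, method = "exact_permutation")
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * pt(-abs(tstat), df = n - 2))
    list(rho = rho, p_value = p, n = n, method = "t_approximation")
  }
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1, mapped back to the
#' input order. Adjusted values are monotone with the raw p-values.
#'
#' @param p_values numeric vector, all in (0, 1].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  q_sorted <- pmin(1, rev(cummin(rev(p_values[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Screen function families against chlorophyll
#'
#' For every family of the requested CAZy class present in the taxon, the
#' copy-number series is correlated with the chlorophyll a series by
#' Spearman's rho; p-values are BH-adjusted across the screened families and
#' a family is significant when its adjusted p (q) is at or below `alpha`
#' (default 0.01). All-zero copy-number series are skipped and logged.
#' Results are split into positively and negatively correlated tables,
#' each sorted by q then decreasing |rho|.
#'
#' @param cn long copy-number table from [copy_number_matrix()] (one taxon,
#'   or pre-filtered with the `taxon` argument).
#' @param samples sample series (supplies chlorophyll, in sample order).
#' @param taxon restrict to this taxon label of `cn` (`NULL` = use all rows).
#' @param cazy_class CAZy class to screen (e.g. `"GH"`); `NULL` screens every
#'   family present.
#' @param alpha significance level on the adjusted p-value.
#' @param method p-value method passed to [spearman_cor()].
#' @return list with `results` (data.frame `fun`, `rho`, `p_value`,
#'   `q_value`, `n`, `significant`), `positive`, `negative` (significant
#'   subsets), and `skipped` (all-zero families).
#' @export
screen_families <- function(cn, samples, taxon = NULL, cazy_class = NULL,
                            alpha = 0.01, method = "auto") {
  if (!is.null(taxon)) cn <- cn[cn$taxon == taxon, , drop = FALSE]
  keep <- grepl(CAZY_PATTERN, cn$fun)
  if (!is.null(cazy_class))
    keep <- keep & cazy_class_of(cn$fun) == cazy_class
  cn <- cn[keep, , drop = FALSE]
  usable <- cn$flag == "ok"
  cn <- cn[usable, , drop = FALSE]
  n_samp <- length(unique(cn$sample_id))
  if (n_samp < 4) stop("fewer than 4 usable samples")
  chl <- setNames(samples$chlorophyll, samples$sample_id)
  fams <- unique(cn$fun)
  rows <- list()
  skipped <- character(0)
  for (f in fams) {
    sub <- cn[cn$fun == f, , drop = FALSE]
    sub <- sub[match(samples$sample_id, sub$sample_id), , drop = FALSE]
    sub <- sub[!is.na(sub$value), , drop = FALSE]
    if (nrow(sub) < 4) { skipped <- c(skipped, f); next }
    if (all(sub$value == 0)) { skipped <- c(skipped, f); next }
    sc <- spearman_cor(sub$value, chl[sub$sample_id], method = method)
    if (is.na(sc$rho)) { skipped <- c(skipped, f); next }
    rows[[length(rows) + 1L]] <- data.frame(
      fun = f, rho = sc$rho, p_value = sc$p_value, n = sc$n,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(list(results = NULL, positive = NULL, negative = NULL,
                skipped = skipped))
  res <- do.call(rbind, rows)
  res$q_value <- bh_fdr(res$p_value)
  res$significant <- res$q_value <= alpha
  res <- res[order(res$q_value, -abs(res$rho)), , drop = FALSE]
  rownames(res) <- NULL
  res <- res[, c("fun", "rho", "p_value", "q_value", "n", "significant")]
  list(results = res,
       positive = res[res$significant & res$rho > 0, , drop = FALSE],
       negative = res[res$significant & res$rho < 0, , drop = FALSE],
       skipped = skipped)
}
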