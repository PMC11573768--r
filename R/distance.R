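#' Chi-squared distance between profiles
#'
#' The community-ecology chi-squared distance on a non-negative profile
#' matrix:
#' `d(i,j) = sqrt( N * sum_k (1/c_k) * (x_ik/r_i - x_jk/r_j)^2 )`
#' with `r_i` row sums, `c_k` column sums and `N` the grand total. Rows are
#' compared as proportions, so scaling a row leaves all its distances
#' unchanged. All-zero columns carry no information and are dropped with a
#' warning; an all-zero row has no profile and is an error.
#'
#' @param m numeric matrix (rows = profiles, columns = families), or a
#'   data.frame coercible to one. Row names label the output.
#' @return symmetric `dist`-like matrix of class `matrix` with zero diagonal.
#' @export
chisq_distance <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("profile values must be non-negative")
  zero_row <- rowSums(m) == 0
  if (any(zero_row))
    stop("all-zero profile row(s): ",
         paste(utils::head(rownames(m)[zero_row], 5), collapse = ", "))
  zero_col <- colSums(m) == 0
  if (any(zero_col)) {
    warning("dropping ", sum(zero_col), " all-zero column(s)")
    m <- m[, !zero_col, drop = FALSE]
  }
  r <- rowSums(m)
  ck <- colSums(m)
  N <- sum(m)
  prop <- sweep(m, 1, r, "/")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    d[i, j] <- d[j, i] <-
      sqrt(N * sum((prop[i, ] - prop[j, ])^2 / ck))
  }
  d
}

#' Classical (Torgerson) metric multidimensional scaling
#'
#' Double-centers the squared distance matrix, `B = -1/2 * J D^2 J`,
#' eigendecomposes `B`, and returns coordinates `v_i * sqrt(lambda_i)` for
#' the leading positive eigenvalues. Explained variance of axis `i` is
#' `100 * lambda_i / sum(positive lambdas)`. Negative eigenvalues (the
#' distance not being exactly Euclidean) are reported but never used. Axis
#' signs are fixed by forcing the largest-magnitude loading of each axis
#' positive, for reproducible output.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param k number of dimensions requested (>= 1); truncated with a warning
#'   when fewer positive eigenvalues exist.
#' @return list with `points` (n x k' matrix), `eigenvalues` (all, sorted
#'   decreasing), `explained` (percent per returned axis), `negative`
#'   (negative eigenvalues, if any).
#' @export
classical_mds <- function(d, k = 2) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12) ||
      any(abs(diag(d)) > 1e-12))
    stop("d must be symmetric with a zero diagonal")
  if (k < 1) stop("k must be >= 1")
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lambda <- e$values
  tol <- max(abs(lambda)) * 1e-9
  pos <- which(lambda > tol)
  if (length(pos) == 0) stop("no positive eigenvalues: degenerate input")
  k_eff <- min(k, length(pos))
  if (k_eff < k)
    warning("only ", k_eff, " positive eigenvalue(s); returning ",
            k_eff, " dimension(s)")
  idx <- pos[seq_len(k_eff)]
  pts <- e$vectors[, idx, drop = FALSE] %*%
    diag(sqrt(lambda[idx]), k_eff, k_eff)
  for (a in seq_len(k_eff)) {
    big <- which.max(abs(pts[, a]))
    if (pts[big, a] < 0) pts[, a] <- -pts[, a]
  }
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("axis", seq_len(k_eff))
  list(points = pts,
       eigenvalues = lambda,
       explained = 100 * lambda[idx] / sum(lambda[pos]),
       negative = lambda[lambda < -tol])
}

#' Per-taxon proportional family profiles from a copy-number table
#'
#' Builds the profile matrix fed to [chisq_distance()]: one row per taxon,
#' one column per family of the requested CAZy class, entries the
#' series-averaged copy numbers (undefined cells excluded from the mean).
#'
#' @param cn long copy-number table from [copy_number_matrix()].
#' @param cazy_class restrict to families of this class (`NULL` = all).
#' @param per_sample keep (taxon, sample) rows instead of averaging the
#'   series.
#' @return numeric matrix.
#' @export
profile_matrix <- function(cn, cazy_class = NULL, per_sample = FALSE) {
  keep <- grepl(CAZY_PATTERN, cn$fun)
  if (!is.null(cazy_class))
    keep <- keep & cazy_class_of(cn$fun) == cazy_class
  cn <- cn[keep & cn$flag == "ok", , drop = FALSE]
  if (nrow(cn) == 0) stop("no usable copy-number cells for the profile")
  row_key <- if (per_sample) paste(cn$taxon, cn$sample_id, sep = "|")
             else cn$taxon
  tab <- tapply(cn$value, list(row_key, cn$fun), mean)
  tab[is.na(tab)] <- 0
  as.matrix(tab)
}
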