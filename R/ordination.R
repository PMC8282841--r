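impute_locus_means <- function(x) {
  if (!anyNA(x)) return(x)
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  x[idx] <- mu[idx[, 2L]]
  x
}

#' Covariance PCA of a band matrix
#'
#' Principal component analysis of the 0/1 band profiles: loci (columns)
#' are mean-centred (missing scores imputed by the locus mean first) and
#' the individuals-space covariance (divisor n - 1) is
#' eigen-decomposed. Eigenvalues, percent and cumulative percent of
#' variation, case scores and locus loadings are returned. The sign of
#' each axis is fixed so that its largest-magnitude loading is positive.
#'
#' @param m a [band_matrix()] (or a plain numeric matrix).
#' @return list of class `band_pca`: `eigenvalues` (descending),
#'   `pct_variation`, `cum_pct`, `scores` (individuals x axes),
#'   `loadings` (loci x axes).
#' @export
pca <- function(m) {
  x <- if (inherits(m, "band_matrix")) m$data else as.matrix(m)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("PCA needs at least 2 individuals and 2 loci", call. = FALSE)
  x <- impute_locus_means(x)
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  if (sum(ev) <= 0)
    stop("constant band matrix: all eigenvalues are zero", call. = FALSE)
  # deterministic sign convention
  for (a in seq_len(ncol(pr$rotation))) {
    jmax <- which.max(abs(pr$rotation[, a]))
    if (pr$rotation[jmax, a] < 0) {
      pr$rotation[, a] <- -pr$rotation[, a]
      pr$x[, a] <- -pr$x[, a]
    }
  }
  pct <- 100 * ev / sum(ev)
  structure(list(eigenvalues = ev, pct_variation = pct,
                 cum_pct = cumsum(pct), scores = pr$x,
                 loadings = pr$rotation, center = pr$center),
            class = "band_pca")
}

#' @export
print.band_pca <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat("band-matrix PCA\n")
  print(round(data.frame(axis = seq_len(k),
                         eigenvalue = x$eigenvalues[seq_len(k)],
                         pct = x$pct_variation[seq_len(k)],
                         cum_pct = x$cum_pct[seq_len(k)]), 4),
        row.names = FALSE)
  invisible(x)
}

#' Per-accession Shannon diversity of a band profile
#'
#' Entropy of the equal-weight presence profile in log base 10: with
#' `p_j = x_ij / sum_j(x_ij)` over the bands present,
#' `H' = -sum p_j log10 p_j`, which for 0/1 data reduces to
#' `log10(number of bands present)`.
#'
#' @param m a [band_matrix()].
#' @param individual individual id or index; all individuals when `NULL`.
#' @return named numeric vector of H' values.
#' @export
accession_shannon <- function(m, individual = NULL) {
  x <- m$data
  if (!is.null(individual)) x <- x[individual, , drop = FALSE]
  counts <- rowSums(x == 1L, na.rm = TRUE)
  if (any(counts == 0))
    stop("individual(s) with zero bands present: ",
         paste(rownames(x)[counts == 0], collapse = ", "), call. = FALSE)
  stats::setNames(log10(counts), rownames(x))
}

#' PCA report in the published layout
#'
#' Eigenvalues, percent and cumulative percent of variation for the
#' leading axes plus per-individual case scores and Shannon H' indices.
#'
#' @param m a [band_matrix()].
#' @param n_axes number of leading axes to report.
#' @return list with `axes` (data frame) and `scores` (data frame with
#'   an `h_prime` column).
#' @export
pca_report <- function(m, n_axes = 9) {
  p <- pca(m)
  n_axes <- min(n_axes, length(p$eigenvalues))
  axes <- data.frame(axis = paste0("PC", seq_len(n_axes)),
                     eigenvalue = p$eigenvalues[seq_len(n_axes)],
                     pct_variation = p$pct_variation[seq_len(n_axes)],
                     cum_pct = p$cum_pct[seq_len(n_axes)])
  scores <- data.frame(individual = rownames(p$scores),
                       p$scores[, seq_len(n_axes), drop = FALSE],
                       h_prime = accession_shannon(m),
                       check.names = FALSE)
  rownames(scores) <- NULL
  list(axes = axes, scores = scores)
}
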