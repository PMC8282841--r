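#' Band bookkeeping for one primer
#'
#' Counts the primer's total scored bands (TSB = loci), polymorphic bands
#' (PB = loci where both states 0 and 1 occur among non-missing scores)
#' and the percent polymorphic bands (PPB = 100 PB / TSB). A minimum
#' minor-state frequency can be imposed via `min_freq` (off by default,
#' i.e. any second state makes a locus polymorphic).
#'
#' @param m a [band_matrix()].
#' @param primer primer name.
#' @param min_freq optional minor band-phenotype frequency below which a
#'   locus is treated as monomorphic (e.g. 0.05 for a 95% criterion).
#' @return list with `TSB`, `PB`, `PPB`, and logical `polymorphic` per
#'   locus of the primer.
#' @export
count_bands <- function(m, primer, min_freq = 0) {
  idx <- loci_of_primer(m, primer)
  x <- m$data[, idx, drop = FALSE]
  f1 <- colMeans(x == 1L, na.rm = TRUE)   # band frequency per locus
  nobs <- colSums(!is.na(x))
  poly <- nobs > 0 & pmin(f1, 1 - f1) > min_freq
  TSB <- length(idx)
  PB <- sum(poly)
  list(TSB = TSB, PB = PB, PPB = 100 * PB / TSB, polymorphic = poly)
}

#' Pooled band-allele phenotype frequency of a primer
#'
#' The fraction of 1 scores among all non-missing scores across the
#' primer's polymorphic loci. This single pooled frequency is the input
#' of the bi-allelic H and PIC formulas, matching the convention of
#' marker-efficiency calculators for dominant data.
#'
#' @inheritParams count_bands
#' @return pooled frequency in \[0, 1\].
#' @export
pooled_band_frequency <- function(m, primer, min_freq = 0) {
  cb <- count_bands(m, primer, min_freq)
  idx <- loci_of_primer(m, primer)[cb$polymorphic]
  if (!length(idx))
    stop(sprintf("primer '%s' has no polymorphic loci", primer),
         call. = FALSE)
  x <- m$data[, idx, drop = FALSE]
  nobs <- sum(!is.na(x))
  if (nobs == 0)
    stop("no non-missing scores for primer ", primer, call. = FALSE)
  sum(x == 1L, na.rm = TRUE) / nobs
}

#' Expected heterozygosity of a bi-allelic locus
#'
#' `H = 1 - p^2 - q^2 = 2 p (1 - p)` for band-phenotype frequency `p`.
#'
#' @param p_bar frequency in \[0, 1\] (vectorized).
#' @return H in \[0, 0.5\].
#' @export
expected_heterozygosity <- function(p_bar) {
  stopifnot(all(p_bar >= 0 & p_bar <= 1))
  2 * p_bar * (1 - p_bar)
}

#' Polymorphic information content (bi-allelic Botstein form)
#'
#' `PIC = 1 - p^2 - q^2 - 2 p^2 q^2`, which equals `H - H^2/2` with
#' `H = 2pq`. The general multi-allele form over a frequency vector is
#' available via [pic_multiallelic()].
#'
#' @inheritParams expected_heterozygosity
#' @return PIC in \[0, 0.375\].
#' @export
pic <- function(p_bar) {
  H <- expected_heterozygosity(p_bar)
  H - H^2 / 2
}

#' Multi-allele polymorphic information content
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i != j} p_i^2 p_j^2` over ordered pairs.
#'
#' @param p vector of allele frequencies summing to 1.
#' @return PIC value.
#' @export
pic_multiallelic <- function(p) {
  stopifnot(abs(sum(p) - 1) < 1e-8)
  s2 <- sum(p^2)
  1 - s2 - (s2^2 - sum(p^4))
}

#' Effective multiplex ratio of a primer
#'
#' `EMR = n * beta` where `n` is the mean number of bands an individual
#' shows across the primer's loci (missing scores excluded per
#' individual) and `beta = PB / TSB` is the polymorphic fraction.
#'
#' @inheritParams count_bands
#' @return EMR value.
#' @export
emr <- function(m, primer, min_freq = 0) {
  idx <- loci_of_primer(m, primer)
  x <- m$data[, idx, drop = FALSE]
  n_bands <- rowSums(x == 1L, na.rm = TRUE)
  cb <- count_bands(m, primer, min_freq)
  mean(n_bands) * cb$PB / cb$TSB
}

#' Resolving power of a primer
#'
#' `RP = sum(Ib)` over the primer's bands, with band informativeness
#' `Ib = 1 - 2 |0.5 - p|` and `p` the fraction of individuals showing the
#' band (non-missing scores only).
#'
#' @inheritParams count_bands
#' @return RP in \[0, TSB\].
#' @export
resolving_power <- function(m, primer) {
  idx <- loci_of_primer(m, primer)
  x <- m$data[, idx, drop = FALSE]
  p <- colMeans(x == 1L, na.rm = TRUE)
  sum(1 - 2 * abs(0.5 - p))
}

#' Discriminating power of a primer
#'
#' Groups the N individuals by their full multi-locus banding pattern at
#' the primer's loci; for pattern i with frequency `p_i` the confusion
#' contribution is `c_i = p_i (N p_i - 1) / (N - 1)` and
#' `D = 1 - sum(c_i)`: the probability that two distinct individuals
#' drawn at random differ in pattern.
#'
#' @inheritParams count_bands
#' @return D in \[0, 1\].
#' @export
discriminating_power <- function(m, primer) {
  idx <- loci_of_primer(m, primer)
  N <- nrow(m$data)
  if (N < 2) stop("discriminating power needs N >= 2", call. = FALSE)
  pat <- apply(m$data[, idx, drop = FALSE], 1L, paste, collapse = "/")
  counts <- table(pat)
  p_i <- as.numeric(counts) / N
  1 - sum(p_i * (N * p_i - 1) / (N - 1))
}

#' Mean heterozygosity of the polymorphic fraction
#'
#' `Havp = sum(Hn) / np` where `Hn = 2 p_l (1 - p_l)` is the per-locus
#' expected heterozygosity of each of the primer's np polymorphic loci.
#'
#' @inheritParams count_bands
#' @return Havp value; 0 with a warning when the primer has no
#'   polymorphic locus.
#' @export
havp <- function(m, primer, min_freq = 0) {
  cb <- count_bands(m, primer, min_freq)
  if (cb$PB == 0) {
    warning("primer '", primer, "' has no polymorphic loci; Havp = 0")
    return(0)
  }
  idx <- loci_of_primer(m, primer)[cb$polymorphic]
  x <- m$data[, idx, drop = FALSE]
  p <- colMeans(x == 1L, na.rm = TRUE)
  mean(2 * p * (1 - p))
}

#' Marker index
#'
#' `MI = PIC x EMR`.
#'
#' @param PIC polymorphic information content.
#' @param EMR effective multiplex ratio.
#' @return MI value.
#' @export
marker_index <- function(PIC, EMR) {
  stopifnot(all(is.finite(PIC)), all(is.finite(EMR)),
            all(PIC >= 0), all(EMR >= 0))
  PIC * EMR
}

#' Per-primer marker-efficiency table
#'
#' Computes, for every primer (or a subset), the full efficiency record:
#' TSB, PB, PPB, pooled band frequency, H, PIC, EMR, Havp, MI, D and RP.
#'
#' @param m a [band_matrix()].
#' @param primer_names primers to include, default all.
#' @param min_freq see [count_bands()].
#' @return data frame with one row per primer.
#' @export
primer_metrics <- function(m, primer_names = primers(m), min_freq = 0) {
  rows <- lapply(primer_names, function(pr) {
    cb <- count_bands(m, pr, min_freq)
    p_bar <- if (cb$PB > 0) pooled_band_frequency(m, pr, min_freq)
             else NA_real_
    H <- if (is.na(p_bar)) 0 else expected_heterozygosity(p_bar)
    PIC <- if (is.na(p_bar)) 0 else pic(p_bar)
    EMR <- emr(m, pr, min_freq)
    data.frame(primer = pr, tsb = cb$TSB, pb = cb$PB, ppb = cb$PPB,
               p_bar = p_bar, h = H, pic = PIC, emr = EMR,
               havp = suppressWarnings(havp(m, pr, min_freq)),
               mi = marker_index(PIC, EMR),
               d = discriminating_power(m, pr),
               rp = resolving_power(m, pr))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Column means over a per-primer metrics table
#'
#' Arithmetic mean of every numeric column (the "Mean" row of a
#' per-primer report), with the standard deviation row optionally
#' appended.
#'
#' @param metrics data frame of per-primer values, e.g. from
#'   [primer_metrics()].
#' @param sd_row also compute the standard deviation per column.
#' @return data frame with a `statistic` column and one row (`mean`) or
#'   two (`mean`, `sd`).
#' @export
aggregate_metrics <- function(metrics, sd_row = FALSE) {
  stopifnot(is.data.frame(metrics), nrow(metrics) >= 1)
  num <- vapply(metrics, is.numeric, logical(1))
  mu <- as.data.frame(lapply(metrics[num], mean, na.rm = TRUE))
  out <- cbind(statistic = "mean", mu)
  if (sd_row) {
    sdv <- as.data.frame(lapply(metrics[num], stats::sd, na.rm = TRUE))
    out <- rbind(out, cbind(statistic = "sd", sdv))
  }
  rownames(out) <- NULL
  out
}
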