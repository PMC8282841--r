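#' Dominant-marker allele frequency estimation
#'
#' Under Hardy-Weinberg equilibrium the band-absent phenotype is the
#' homozygous null genotype, so the null-allele frequency is estimated as
#' `q_hat = sqrt(1 - band_freq)` and the band allele as
#' `p_hat = 1 - q_hat`. The Lynch-Milligan small-sample adjustment
#' `q_hat = sqrt(x) / (1 - var(x)/(8 x^2))` with `x` the band-absent
#' frequency and `var(x) = x (1 - x) / n` is available via
#' `lynch_milligan = TRUE`.
#'
#' @param band_freq observed fraction of 1 scores (vectorized).
#' @param n number of non-missing individuals per locus (used only by the
#'   Lynch-Milligan correction).
#' @param lynch_milligan apply the small-sample correction.
#' @return list with `p_hat` and `q_hat`.
#' @export
estimate_allele_freq <- function(band_freq, n = NULL,
                                 lynch_milligan = FALSE) {
  stopifnot(all(band_freq >= 0 & band_freq <= 1))
  x <- 1 - band_freq
  q_hat <- sqrt(x)
  if (lynch_milligan) {
    if (is.null(n)) stop("n is required for the Lynch-Milligan correction",
                         call. = FALSE)
    vx <- x * (1 - x) / n
    ok <- x > 0
    q_hat[ok] <- sqrt(x[ok]) / (1 - vx[ok] / (8 * x[ok]^2))
    q_hat <- pmin(pmax(q_hat, 0), 1)
  }
  list(p_hat = 1 - q_hat, q_hat = q_hat)
}

#' Per-locus diversity statistics from an allele frequency
#'
#' For band-allele frequency `p` (with `q = 1 - p`): observed number of
#' alleles `Na` (2 when both alleles segregate, else 1), effective number
#' of alleles `Ne = 1 / (p^2 + q^2)`, Nei's gene diversity
#' `h = 1 - p^2 - q^2`, and Shannon's information index
#' `I = -p ln p - q ln q` (natural log; zero-frequency terms contribute
#' 0).
#'
#' @param p_hat band-allele frequency in \[0, 1\] (vectorized).
#' @return data frame with columns `na`, `ne`, `h`, `i`.
#' @export
locus_diversity <- function(p_hat) {
  stopifnot(all(p_hat >= 0 & p_hat <= 1))
  q <- 1 - p_hat
  plogp <- function(z) ifelse(z > 0, z * log(z), 0)
  data.frame(na = ifelse(p_hat > 0 & p_hat < 1, 2L, 1L),
             ne = 1 / (p_hat^2 + q^2),
             h = 1 - p_hat^2 - q^2,
             i = -(plogp(p_hat) + plogp(q)))
}

per_locus_band_freq <- function(m, individuals = NULL) {
  x <- if (is.null(individuals)) m$data else m$data[individuals, ,
                                                    drop = FALSE]
  list(freq = colMeans(x == 1L, na.rm = TRUE),
       n = colSums(!is.na(x)))
}

#' Diversity statistics for a band matrix
#'
#' Per-locus and mean Na, Ne, h and I plus PPB, computed for the whole
#' matrix or any subset of individuals, with frequencies estimated by
#' [estimate_allele_freq()].
#'
#' @param m a [band_matrix()].
#' @param individuals optional individual ids or indices defining the
#'   scope.
#' @param scope label for the report (default `"overall"`).
#' @param lynch_milligan see [estimate_allele_freq()].
#' @return list with `scope`, `per_locus` (data frame) and `mean`
#'   (one-row data frame with `na`, `ne`, `h`, `i`, `ppb`).
#' @export
diversity_stats <- function(m, individuals = NULL, scope = "overall",
                            lynch_milligan = FALSE) {
  bf <- per_locus_band_freq(m, individuals)
  est <- estimate_allele_freq(bf$freq, bf$n, lynch_milligan)
  per_locus <- cbind(data.frame(locus = colnames(m$data),
                                band_freq = bf$freq, n = bf$n,
                                p_hat = est$p_hat, q_hat = est$q_hat),
                     locus_diversity(est$p_hat))
  rownames(per_locus) <- NULL
  mean_row <- data.frame(na = mean(per_locus$na), ne = mean(per_locus$ne),
                         h = mean(per_locus$h), i = mean(per_locus$i),
                         ppb = 100 * mean(per_locus$na == 2L))
  list(scope = scope, per_locus = per_locus, mean = mean_row)
}

#' Per-primer diversity report
#'
#' Primer-wise means of Na, Ne, h and I together with band bookkeeping
#' (TSB, PB, PPB) and gene flow Nm from a chosen population partition,
#' mirroring the layout of a POPGENE per-primer summary.
#'
#' @param m a [band_matrix()].
#' @param partition optional individual-to-group assignment for the Gst
#'   behind Nm; defaults to the matrix's population labels.
#' @return data frame with one row per primer and a trailing mean row
#'   accessible via [aggregate_metrics()].
#' @export
primer_diversity <- function(m, partition = m$population_of) {
  ds <- diversity_stats(m)
  pl <- ds$per_locus
  pd <- partition_diversity(m, partition)
  rows <- lapply(primers(m), function(pr) {
    idx <- loci_of_primer(m, pr)
    cb <- count_bands(m, pr)
    gl <- pd$per_locus[idx, ]
    gst_pr <- mean_gst(gl)
    data.frame(primer = pr,
               na = mean(pl$na[idx]), ne = mean(pl$ne[idx]),
               h = mean(pl$h[idx]), i = mean(pl$i[idx]),
               tsb = cb$TSB, pb = cb$PB, ppb = cb$PPB,
               nm = gene_flow(gst_pr))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

mean_gst <- function(per_locus) {
  keep <- is.finite(per_locus$ht) & per_locus$ht > 0
  if (!any(keep)) return(NA_real_)
  ht <- mean(per_locus$ht[keep])
  hs <- mean(per_locus$hs[keep])
  (ht - hs) / ht
}

#' Gene diversity partition: Ht, Hs and Gst
#'
#' Per locus, the band-allele frequency is estimated within each group;
#' `Hs` is the unweighted mean over groups of `2 p_g q_g`, `Ht = 2 p q`
#' with `p` the unweighted mean of the group frequencies, and
#' `Gst = (Ht - Hs) / Ht`. The headline Gst is the ratio of means
#' `(mean Ht - mean Hs) / mean Ht` (Nei's definition); the mean of
#' per-locus Gst values is also reported. Loci monomorphic overall
#' (`Ht = 0`) are skipped in the Gst summaries.
#'
#' @param m a [band_matrix()].
#' @param partition individual-to-group assignment (vector in individual
#'   order or named by individual); default the matrix's populations.
#' @param size_weighted weight groups by sample size instead of equally.
#' @param lynch_milligan see [estimate_allele_freq()].
#' @return list with `per_locus` (data frame: `ht`, `hs`, `gst`), `Ht`,
#'   `Hs` (means over polymorphic loci), `Gst` (ratio of means),
#'   `Gst_locus_mean`, and `Nm`.
#' @export
partition_diversity <- function(m, partition = m$population_of,
                                size_weighted = FALSE,
                                lynch_milligan = FALSE) {
  partition <- as.factor(partition)
  if (length(partition) != nrow(m$data))
    stop("partition must assign every individual", call. = FALSE)
  groups <- levels(partition)
  if (length(groups) < 2)
    stop("Gst needs at least two groups", call. = FALSE)
  L <- ncol(m$data)
  pmat <- matrix(NA_real_, length(groups), L)
  nmat <- matrix(0, length(groups), L)
  for (g in seq_along(groups)) {
    rows <- which(partition == groups[g])
    bf <- per_locus_band_freq(m, rows)
    pmat[g, ] <- estimate_allele_freq(bf$freq, bf$n,
                                      lynch_milligan)$p_hat
    nmat[g, ] <- bf$n
  }
  w <- if (size_weighted) nmat / rep(colSums(nmat), each = length(groups))
       else matrix(1 / length(groups), length(groups), L)
  hs <- colSums(w * 2 * pmat * (1 - pmat))
  pbar <- colSums(w * pmat)
  ht <- 2 * pbar * (1 - pbar)
  gst <- ifelse(ht > 0, (ht - hs) / ht, NA_real_)
  per_locus <- data.frame(locus = colnames(m$data), ht = ht, hs = hs,
                          gst = gst)
  keep <- ht > 0
  Ht <- mean(ht[keep]); Hs <- mean(hs[keep])
  Gst <- (Ht - Hs) / Ht
  list(per_locus = per_locus, Ht = Ht, Hs = Hs, Gst = Gst,
       Gst_locus_mean = mean(gst[keep]), Nm = gene_flow(Gst))
}

#' Gene flow from Gst
#'
#' `Nm = 0.5 (1 - Gst) / Gst`, the effective number of migrants per
#' generation implied by the island model.
#'
#' @param Gst differentiation coefficient in \[0, 1\] (vectorized).
#' @return Nm; `Inf` with a warning at `Gst = 0`.
#' @export
gene_flow <- function(Gst) {
  if (any(Gst < 0, na.rm = TRUE) || any(Gst > 1, na.rm = TRUE))
    stop("Gst must lie in [0, 1]", call. = FALSE)
  if (any(Gst == 0, na.rm = TRUE))
    warning("Gst = 0 implies unbounded gene flow (Nm = Inf)")
  0.5 * (1 - Gst) / Gst
}
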