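#' Configuration of the Bayesian admixture sampler
#'
#' Desk-scale defaults (burn-in 2,000 sweeps, 10,000 sampling sweeps,
#' 5 runs per K) give stable posterior means on panels of tens of
#' individuals and a few hundred loci; all settings scale up for larger
#' problems.
#'
#' @param burnin burn-in sweeps discarded before accumulation.
#' @param sweeps post-burn-in sweeps accumulated into posterior means.
#' @param runs independent runs per K in [admixture_scan()].
#' @param alpha fixed symmetric Dirichlet concentration of the admixture
#'   prior.
#' @param freq_model `"correlated"` (Balding-Nichols prior around the
#'   sample-wide ancestral frequencies, per-cluster F sampled) or
#'   `"independent"` (flat Beta(1,1) prior).
#' @param genotype_model `"dominant-diploid"` (two latent allele copies,
#'   recessive null; the band is absent only when both copies are null)
#'   or `"haploid"` (each band scored as one allele).
#' @param f_init initial per-cluster F.
#' @param f_range support of the uniform prior on each F_k.
#' @param f_prop_sd standard deviation of the logit-scale random walk on
#'   F_k.
#' @return list of class `admixture_config`.
#' @export
admixture_config <- function(burnin = 2000, sweeps = 10000, runs = 5,
                             alpha = 1,
                             freq_model = c("correlated", "independent"),
                             genotype_model = c("dominant-diploid",
                                                "haploid"),
                             f_init = 0.1, f_range = c(0.001, 0.999),
                             f_prop_sd = 0.3) {
  stopifnot(burnin >= 1, sweeps >= 1, runs >= 1, alpha > 0,
            f_range[1] > 0, f_range[2] < 1)
  structure(list(burnin = as.integer(burnin),
                 sweeps = as.integer(sweeps), runs = as.integer(runs),
                 alpha = alpha, freq_model = match.arg(freq_model),
                 genotype_model = match.arg(genotype_model),
                 f_init = f_init, f_range = f_range,
                 f_prop_sd = f_prop_sd),
            class = "admixture_config")
}

ancestral_freq_estimate <- function(m) {
  bf <- per_locus_band_freq(m)
  p <- estimate_allele_freq(bf$freq)$p_hat
  n <- nrow(m$data)
  pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
}

#' Fit the dominant-marker admixture model at a given K
#'
#' Gibbs sampler over the latent allele copies of every individual and
#' locus: cluster-of-origin and allelic-state augmentation given the
#' observed dominant band, Beta full-conditional updates of the cluster
#' band-allele frequencies `P`, Dirichlet updates of the admixture
#' proportions `Q`, and (under the correlated model) Metropolis updates
#' of the per-cluster differentiation `F_k`. Posterior means over the
#' post-burn-in sweeps are returned. Missing scores are skipped.
#'
#' @param m a [band_matrix()].
#' @param K number of clusters (`1 <= K <=` individuals).
#' @param config an [admixture_config()].
#' @param seed optional integer seed for the run.
#' @return object of class `admixture_result`: `K`, `Q` (individuals x
#'   K posterior mean), `P` (K x loci), `F_k`, `lnL` (post-burn-in
#'   trace), `lnPD`, `cluster_het`, `net_distance`, `config`.
#' @examples
#' \donttest{
#' sim <- simulate_band_matrix(sim_config(n_pops = 4, n_primers = 6,
#'                                        pop_to_cluster = c(1, 1, 2, 3),
#'                                        seed = 7))
#' fit <- admixture_fit(sim$bands, K = 3,
#'                      config = admixture_config(burnin = 200,
#'                                                sweeps = 500),
#'                      seed = 7)
#' round(fit$F_k, 2)
#' }
#' @export
admixture_fit <- function(m, K, config = admixture_config(),
                          seed = NULL) {
  stopifnot(inherits(m, "band_matrix"),
            inherits(config, "admixture_config"))
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (K > nrow(m$data))
    stop("K must not exceed the number of individuals", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p_anc <- ancestral_freq_estimate(m)
  res <- gibbs_admixture_cpp(
    m$data, as.integer(K), config$burnin, config$sweeps, config$alpha,
    p_anc, config$freq_model == "correlated",
    config$genotype_model == "dominant-diploid",
    rep_len(config$f_init, K), config$f_range[1], config$f_range[2],
    config$f_prop_sd)
  rownames(res$Q) <- rownames(m$data)
  colnames(res$Q) <- paste0("cluster", seq_len(K))
  rownames(res$P) <- paste0("cluster", seq_len(K))
  colnames(res$P) <- colnames(m$data)
  div <- cluster_divergence(res$P)
  structure(list(K = K, Q = res$Q, P = res$P,
                 F_k = stats::setNames(res$F_k,
                                       paste0("cluster", seq_len(K))),
                 lnL = res$lnL, lnPD = lnpd(res$lnL),
                 cluster_het = div$within_het,
                 net_distance = div$net_distance,
                 config = config),
            class = "admixture_result")
}

#' @export
print.admixture_result <- function(x, ...) {
  cat(sprintf("admixture fit: K = %d, lnPD = %.1f\n", x$K, x$lnPD))
  cat("  F_k:", paste(sprintf("%.3f", x$F_k), collapse = ", "), "\n")
  invisible(x)
}

#' Model log-probability from a log-likelihood trace
#'
#' The harmonic-style approximation `lnPD = mean(lnL) - var(lnL) / 2`
#' (sample variance, divisor n - 1).
#'
#' @param lnL numeric trace of at least 2 post-burn-in log-likelihoods.
#' @return lnPD estimate (never above `mean(lnL)`).
#' @export
lnpd <- function(lnL) {
  stopifnot(length(lnL) >= 2)
  mean(lnL) - stats::var(lnL) / 2
}

#' Evanno delta-K table and best K
#'
#' From per-K replicate lnPD values: `L(K)` is the mean over runs,
#' `L'(K) = L(K) - L(K-1)`, `|L''(K)| = |L'(K+1) - L'(K)|`, and
#' `deltaK = |L''(K)| / sd(L(K))`, defined on the interior of the K
#' range. The best K is the argmax of deltaK.
#'
#' @param runs named list mapping each K (contiguous range of length >=
#'   3) to a numeric vector of lnPD values, at least 2 runs per K.
#' @return list with `table` (data frame: `K`, `mean_lnpd`, `sd_lnpd`,
#'   `lprime`, `lsecond_abs`, `delta_k`) and `best_k`.
#' @examples
#' evanno(list(`1` = c(-100, -101), `2` = c(-60, -61),
#'             `3` = c(-40, -41), `4` = c(-38, -39)))$best_k
#' @export
evanno <- function(runs) {
  ks <- sort(as.integer(names(runs)))
  if (length(ks) < 3) stop("need at least 3 K values", call. = FALSE)
  if (!all(diff(ks) == 1L))
    stop("K range must be contiguous", call. = FALSE)
  if (any(vapply(runs, length, 1L) < 2))
    stop("Evanno needs at least 2 runs per K", call. = FALSE)
  runs <- runs[as.character(ks)]
  mu <- vapply(runs, mean, numeric(1))
  sdev <- vapply(runs, stats::sd, numeric(1))
  nk <- length(ks)
  lprime <- c(NA, diff(mu))                      # L(K) - L(K-1)
  lsec <- c(NA, abs(diff(lprime[-1])), NA)       # |L'(K+1) - L'(K)|
  dk <- lsec / sdev
  if (any(sdev == 0 & !is.na(lsec)))
    warning("sd(L(K)) = 0 at some K; delta-K undefined there")
  dk[sdev == 0] <- NA
  tab <- data.frame(K = ks, mean_lnpd = mu, sd_lnpd = sdev,
                    lprime = lprime, lsecond_abs = lsec, delta_k = dk)
  rownames(tab) <- NULL
  best <- if (all(is.na(dk))) NA_integer_ else ks[which.max(dk)]
  list(table = tab, best_k = best)
}

#' Run the admixture model over a range of K with replicate runs
#'
#' Fits [admixture_fit()] `config$runs` times for every K in `k_range`
#' (seeds derived deterministically from `seed`), assembles the Evanno
#' table, and aligns the replicate Q matrices of each K.
#'
#' @param m a [band_matrix()].
#' @param k_range integer vector of K values (contiguous for Evanno).
#' @param config an [admixture_config()].
#' @param seed integer base seed.
#' @return list with `fits` (list of lists of `admixture_result` per K),
#'   `lnpd` (named list per K), `evanno` (when the range allows),
#'   `mean_Q` (aligned mean Q per K), `best_k`.
#' @export
admixture_scan <- function(m, k_range = 1:6,
                           config = admixture_config(), seed = 1L) {
  k_range <- sort(unique(as.integer(k_range)))
  fits <- list()
  lnpds <- list()
  for (K in k_range) {
    kf <- lapply(seq_len(config$runs), function(r) {
      admixture_fit(m, K, config,
                    seed = (seed * 1009L + K * 131L + r) %% 2147483647L)
    })
    fits[[as.character(K)]] <- kf
    lnpds[[as.character(K)]] <- vapply(kf, `[[`, numeric(1), "lnPD")
  }
  ev <- NULL
  best <- NA_integer_
  if (length(k_range) >= 3 && all(diff(k_range) == 1L) &&
      config$runs >= 2) {
    ev <- evanno(lnpds)
    best <- ev$best_k
  }
  mean_Q <- lapply(fits, function(kf) {
    align_runs(lapply(kf, `[[`, "Q"))$mean_Q
  })
  list(fits = fits, lnpd = lnpds, evanno = ev, mean_Q = mean_Q,
       best_k = best)
}

#' Cluster divergence summaries from point frequency estimates
#'
#' Within-cluster expected heterozygosity
#' `het_k = mean_l (1 - P_kl^2 - (1-P_kl)^2)` and the net nucleotide
#' distance between clusters A and B,
#' `d_AB = pi_AB - (het_A + het_B)/2` with
#' `pi_AB = mean_l (1 - P_Al P_Bl - (1-P_Al)(1-P_Bl))`.
#'
#' @param P K x loci matrix of cluster band-allele frequencies (or an
#'   `admixture_result`).
#' @return list with `within_het` (length K) and `net_distance` (K x K,
#'   symmetric, zero diagonal).
#' @export
cluster_divergence <- function(P) {
  if (inherits(P, "admixture_result")) P <- P$P
  P <- as.matrix(P)
  K <- nrow(P)
  het <- rowMeans(1 - P^2 - (1 - P)^2)
  net <- matrix(0, K, K, dimnames = list(rownames(P), rownames(P)))
  if (K > 1) {
    for (a in seq_len(K - 1)) for (b in (a + 1):K) {
      pi_ab <- mean(1 - P[a, ] * P[b, ] - (1 - P[a, ]) * (1 - P[b, ]))
      net[a, b] <- net[b, a] <- pi_ab - (het[a] + het[b]) / 2
    }
  }
  list(within_het = het, net_distance = net)
}

#' Classify individuals as pure or admixed from Q
#'
#' An individual is pure in cluster k iff `Q_ik > threshold` (strict, so
#' a membership of exactly the threshold counts as admixed).
#'
#' @param Q individuals x K matrix of membership coefficients (or an
#'   `admixture_result`).
#' @param threshold purity cut-off, default 0.60.
#' @return data frame with `individual`, `label` (`"pure"`/`"admixed"`),
#'   `cluster` (NA when admixed), `max_q`; the per-category counts are
#'   in attribute `"counts"`.
#' @export
classify_membership <- function(Q, threshold = 0.60) {
  if (inherits(Q, "admixture_result")) Q <- Q$Q
  Q <- as.matrix(Q)
  kmax <- max.col(Q, ties.method = "first")
  qmax <- Q[cbind(seq_len(nrow(Q)), kmax)]
  pure <- qmax > threshold
  out <- data.frame(
    individual = rownames(Q) %||% as.character(seq_len(nrow(Q))),
    label = ifelse(pure, "pure", "admixed"),
    cluster = ifelse(pure, kmax, NA_integer_), max_q = qmax)
  attr(out, "counts") <- c(pure = sum(pure), admixed = sum(!pure))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Qualitative interpretation of a fixation index
#'
#' The conventional bands: below 0.05 little, 0.05-0.15 moderate,
#' 0.15-0.25 great, above 0.25 very great genetic difference.
#'
#' @param fst numeric vector of fixation indices in \[0, 1\].
#' @return character vector of labels.
#' @export
fst_interpretation <- function(fst) {
  stopifnot(all(fst >= 0 & fst <= 1))
  cut(fst, breaks = c(-Inf, 0.05, 0.15, 0.25, Inf),
      labels = c("little", "moderate", "great", "very great"),
      right = FALSE) |> as.character()
}

#' Align replicate Q matrices across label switching
#'
#' Columns of every run are permuted to best match the first run: the
#' permutation maximizing the summed elementwise agreement
#' `sum(Q_run[, perm] * Q_ref)` is found exactly for `K <= 7`
#' (enumeration) and greedily otherwise.
#'
#' @param q_list list of individuals x K matrices with identical
#'   dimensions.
#' @return list with `aligned` (list of permuted matrices), `mean_Q`,
#'   and `permutations` (list of integer vectors).
#' @export
align_runs <- function(q_list) {
  stopifnot(length(q_list) >= 1)
  K <- ncol(q_list[[1]])
  if (!all(vapply(q_list, ncol, 1L) == K) ||
      !all(vapply(q_list, nrow, 1L) == nrow(q_list[[1]])))
    stop("all Q matrices must share dimensions", call. = FALSE)
  ref <- q_list[[1]]
  perms <- lapply(q_list, function(Q) best_column_match(Q, ref))
  aligned <- Map(function(Q, p) {
    out <- Q[, p, drop = FALSE]
    colnames(out) <- colnames(ref)
    out
  }, q_list, perms)
  mean_Q <- Reduce(`+`, aligned) / length(aligned)
  list(aligned = aligned, mean_Q = mean_Q, permutations = perms)
}

# permutation p maximizing sum(Q[, p] * ref)
best_column_match <- function(Q, ref) {
  K <- ncol(ref)
  score <- crossprod(Q, ref)            # score[j, k] = sum(Q_j * ref_k)
  if (K <= 7) {
    perms <- all_permutations(K)
    vals <- vapply(perms, function(p) {
      sum(score[cbind(p, seq_len(K))])
    }, numeric(1))
    perms[[which.max(vals)]]
  } else {
    p <- integer(K)
    used <- rep(FALSE, K)
    for (k in seq_len(K)) {
      j <- which.max(ifelse(used, -Inf, score[, k]))
      p[k] <- j
      used[j] <- TRUE
    }
    p
  }
}

all_permutations <- function(K) {
  if (K == 1) return(list(1L))
  sub <- all_permutations(K - 1L)
  out <- list()
  for (p in sub)
    for (pos in seq_len(K))
      out[[length(out) + 1L]] <- append(p, K, after = pos - 1L)
  out
}
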