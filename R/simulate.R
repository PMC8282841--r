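#' Balding-Nichols cluster allele frequencies
#'
#' Draws per-cluster band-allele frequencies around an ancestral
#' frequency vector under the correlated-frequencies (Balding-Nichols)
#' model: `p_kl ~ Beta(p_l (1-F_k)/F_k, (1-p_l)(1-F_k)/F_k)`, so each
#' cluster's frequencies have mean `p_l` and variance `F_k p_l (1-p_l)`.
#'
#' @param p_ancestral numeric vector of ancestral band-allele frequencies
#'   in (0, 1).
#' @param F_k numeric vector of per-cluster differentiation parameters in
#'   \[0, 1); `F_k = 0` copies the ancestral frequencies exactly.
#' @param seed optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @return a `length(F_k) x length(p_ancestral)` matrix of frequencies.
#' @examples
#' p <- simulate_cluster_freqs(rep(0.5, 1000), F_k = c(0.2, 0.4), seed = 1)
#' apply(p, 1, var)  # about F * p * (1 - p) = 0.05, 0.1
#' @export
simulate_cluster_freqs <- function(p_ancestral, F_k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(p_ancestral > 0 & p_ancestral < 1))
  if (any(F_k < 0) || any(F_k >= 1))
    stop("F_k must lie in [0, 1)", call. = FALSE)
  L <- length(p_ancestral)
  K <- length(F_k)
  out <- matrix(NA_real_, K, L)
  for (k in seq_len(K)) {
    if (F_k[k] == 0) {
      out[k, ] <- p_ancestral
    } else {
      lam <- (1 - F_k[k]) / F_k[k]
      out[k, ] <- stats::rbeta(L, p_ancestral * lam,
                               (1 - p_ancestral) * lam)
    }
  }
  out
}

#' Simulate admixture proportions
#'
#' Either symmetric Dirichlet draws (admixed mode) or one-hot rows from a
#' hard population-to-cluster assignment (pure mode).
#'
#' @param n number of individuals (ignored in pure mode when
#'   `pop_to_cluster` is given per individual).
#' @param K number of clusters.
#' @param alpha Dirichlet concentration (> 0) for admixed mode, or `NULL`
#'   for pure mode.
#' @param pop_to_cluster integer vector of cluster assignments (one per
#'   individual) for pure mode.
#' @param seed optional integer seed.
#' @return `n x K` matrix whose rows sum to 1.
#' @export
simulate_admixture <- function(n, K, alpha = NULL, pop_to_cluster = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (is.null(alpha) && is.null(pop_to_cluster))
    stop("give alpha (admixed mode) or pop_to_cluster (pure mode)",
         call. = FALSE)
  if (!is.null(pop_to_cluster)) {
    z <- as.integer(pop_to_cluster)
    stopifnot(all(z >= 1 & z <= K))
    Q <- matrix(0, length(z), K)
    Q[cbind(seq_along(z), z)] <- 1
    return(Q)
  }
  stopifnot(alpha > 0)
  g <- matrix(stats::rgamma(n * K, shape = alpha), n, K)
  # guard against all-zero rows at tiny alpha
  zero <- rowSums(g) == 0
  if (any(zero)) g[zero, ] <- 1
  g / rowSums(g)
}

#' Simulate a dominant band matrix from admixture ground truth
#'
#' For each individual and locus two allele copies are drawn: each copy's
#' cluster of origin is Categorical over the individual's admixture
#' proportions and its allelic state Bernoulli with that cluster's
#' band-allele frequency. The band (dominant phenotype) is present iff at
#' least one copy carries the presence allele, so
#' `P(band = 0) = (sum_k Q_ik (1 - p_kl))^2` under HWE.
#'
#' @param Q_true `n x K` admixture proportions.
#' @param p_cluster `K x L` cluster band-allele frequencies.
#' @param missing_rate probability in \[0, 1) that a score is masked.
#' @param primer_of optional primer assignment for the L loci.
#' @param population_of optional population labels for the n individuals.
#' @param seed optional integer seed.
#' @return a [band_matrix()].
#' @export
simulate_dominant_bands <- function(Q_true, p_cluster, missing_rate = 0,
                                    primer_of = NULL,
                                    population_of = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q_true <- as.matrix(Q_true)
  p_cluster <- as.matrix(p_cluster)
  stopifnot(ncol(Q_true) == nrow(p_cluster),
            missing_rate >= 0, missing_rate < 1)
  n <- nrow(Q_true)
  L <- ncol(p_cluster)
  # P(null copy) per individual x locus, copies iid given Q
  pnull <- Q_true %*% (1 - p_cluster)
  band <- matrix(stats::rbinom(n * L, 1L, 1 - pnull^2), n, L)
  if (missing_rate > 0)
    band[stats::runif(n * L) < missing_rate] <- NA_integer_
  if (is.null(primer_of))
    primer_of <- rep("P1", L)
  locus_ids <- paste0(primer_of, ":", stats::ave(seq_len(L), primer_of,
                                                 FUN = seq_along))
  band_matrix(band,
              individual_ids = sprintf("G%d", seq_len(n)),
              locus_ids = locus_ids, primer_of = primer_of,
              population_of = population_of)
}

#' Configuration for the synthetic band-matrix generator
#'
#' Defaults emulate a 44-accession Bambara groundnut ISSR panel: 11
#' labelled populations of 4 individuals, 32 primers amplifying 11-22
#' loci each (around 510 loci in total), three latent clusters with
#' Balding-Nichols differentiation F = (0.19, 0.37, 0.40), and ancestral
#' band-allele frequencies Uniform(0.1, 0.9).
#'
#' @param K number of latent clusters.
#' @param n_pops number of labelled populations.
#' @param n_per_pop individuals per population.
#' @param pop_to_cluster integer vector (length `n_pops`) assigning each
#'   population to a cluster, or `NULL` for fully admixed individuals.
#' @param alpha Dirichlet concentration used when `pop_to_cluster` is
#'   `NULL`.
#' @param n_primers number of primers.
#' @param loci_per_primer inclusive integer range of loci per primer.
#' @param F_k per-cluster differentiation in (0, 1), recycled to K.
#' @param ancestral_freq_range range of the uniform ancestral-frequency
#'   prior.
#' @param missing_rate missing-score rate in \[0, 1).
#' @param seed integer seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(K = 3, n_pops = 11, n_per_pop = 4,
                       pop_to_cluster = c(1, 1, 1, 1, 1, 1, 2, 2, 3, 3, 3),
                       alpha = 0.2,
                       n_primers = 32, loci_per_primer = c(11, 22),
                       F_k = c(0.19, 0.37, 0.40),
                       ancestral_freq_range = c(0.1, 0.9),
                       missing_rate = 0, seed = 1L) {
  stopifnot(K >= 1, n_pops >= 1, n_per_pop >= 1, n_primers >= 1,
            all(loci_per_primer >= 1), missing_rate >= 0,
            missing_rate < 1)
  F_k <- rep_len(F_k, K)
  if (!is.null(pop_to_cluster)) {
    pop_to_cluster <- rep_len(pop_to_cluster, n_pops)
    stopifnot(all(pop_to_cluster >= 1 & pop_to_cluster <= K))
  }
  structure(list(K = K, n_pops = n_pops, n_per_pop = n_per_pop,
                 pop_to_cluster = pop_to_cluster, alpha = alpha,
                 n_primers = n_primers,
                 loci_per_primer = sort(loci_per_primer),
                 F_k = F_k, ancestral_freq_range = ancestral_freq_range,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic band matrix with known structure
#'
#' Runs the full generative model in a fixed order under one seeded RNG
#' stream: panel layout, ancestral frequencies, Balding-Nichols cluster
#' frequencies, admixture proportions, then dominant band sampling.
#' Identical configurations (including seed) give bit-identical output.
#'
#' @param config a [sim_config()].
#' @return list with elements `bands` (a [band_matrix()]) and `truth`
#'   (list: `Q_true`, `p_ancestral`, `p_cluster`, `F_k`, `seed`).
#' @examples
#' sim <- simulate_band_matrix(sim_config(seed = 42))
#' sim$bands
#' @export
simulate_band_matrix <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_pops * config$n_per_pop
  loci_per <- if (length(config$loci_per_primer) == 1L ||
                  config$loci_per_primer[1L] == config$loci_per_primer[2L])
    rep(config$loci_per_primer[1L], config$n_primers)
  else
    sample(config$loci_per_primer[1L]:config$loci_per_primer[2L],
           config$n_primers, replace = TRUE)
  primer_names <- sprintf("P%02d", seq_len(config$n_primers))
  primer_of <- rep(primer_names, loci_per)
  L <- length(primer_of)

  p_anc <- stats::runif(L, config$ancestral_freq_range[1L],
                        config$ancestral_freq_range[2L])
  p_cluster <- simulate_cluster_freqs(p_anc, config$F_k)
  pop_labels <- rep(sprintf("Pop%02d", seq_len(config$n_pops)),
                    each = config$n_per_pop)
  if (!is.null(config$pop_to_cluster)) {
    assign_ind <- rep(config$pop_to_cluster, each = config$n_per_pop)
    Q <- simulate_admixture(n, config$K, pop_to_cluster = assign_ind)
  } else {
    Q <- simulate_admixture(n, config$K, alpha = config$alpha)
  }
  bands <- simulate_dominant_bands(Q, p_cluster,
                                   missing_rate = config$missing_rate,
                                   primer_of = primer_of,
                                   population_of = pop_labels)
  list(bands = bands,
       truth = list(Q_true = Q, p_ancestral = p_anc,
                    p_cluster = p_cluster, F_k = config$F_k,
                    seed = config$seed))
}
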