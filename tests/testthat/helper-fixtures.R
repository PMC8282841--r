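# Small band matrices built in code for the unit tests.

tiny_bm <- function() {
  band_matrix(matrix(c(1, 0,
                       0, 1), nrow = 2, byrow = TRUE),
              individual_ids = c("i1", "i2"),
              locus_ids = c("P1:1", "P1:2"),
              population_of = c("A", "B"))
}

random_bm <- function(n = 10, n_loci = 20, n_primers = 2,
                      missing_rate = 0, seed = 1) {
  set.seed(seed)
  x <- matrix(rbinom(n * n_loci, 1, runif(n_loci, 0.2, 0.8)[
    rep(seq_len(n_loci), each = n)]), n, n_loci)
  if (missing_rate > 0)
    x[runif(length(x)) < missing_rate] <- NA
  primer <- rep(sprintf("P%d", seq_len(n_primers)), length.out = n_loci)
  primer <- sort(primer)
  band_matrix(x,
              individual_ids = sprintf("i%02d", seq_len(n)),
              locus_ids = paste0(primer, ":", ave(seq_len(n_loci),
                                                  primer, FUN = seq_along)),
              population_of = rep(c("A", "B"), length.out = n))
}

# frequency matrix -> expected Gst computed directly from the true
# cluster frequencies (oracle for the dominant-data estimate)
gst_from_freqs <- function(pmat) {
  hs <- colMeans(2 * pmat * (1 - pmat))
  pbar <- colMeans(pmat)
  ht <- 2 * pbar * (1 - pbar)
  keep <- ht > 0
  (mean(ht[keep]) - mean(hs[keep])) / mean(ht[keep])
}
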