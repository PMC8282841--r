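test_that("band bookkeeping counts polymorphic loci correctly", {
  # 3 loci: polymorphic, monomorphic-present, polymorphic
  m <- band_matrix(matrix(c(1, 1, 0,
                            0, 1, 1,
                            1, 1, 0,
                            0, 1, 1), 4, 3, byrow = TRUE),
                   locus_ids = c("P1:1", "P1:2", "P1:3"))
  cb <- count_bands(m, "P1")
  expect_equal(cb$TSB, 3)
  expect_equal(cb$PB, 2)
  expect_equal(cb$PPB, 100 * 2 / 3)
  expect_equal(unname(cb$polymorphic), c(TRUE, FALSE, TRUE))
  expect_error(count_bands(m, "nope"), "unknown primer")

  # all-polymorphic primer reaches 100%
  m2 <- random_bm(n = 30, n_loci = 10, n_primers = 1, seed = 2)
  expect_equal(count_bands(m2, "P1")$PPB, 100)
})

test_that("H and PIC follow the bi-allelic closed forms", {
  expect_equal(expected_heterozygosity(0.5), 0.5)
  expect_equal(expected_heterozygosity(0), 0)
  expect_equal(pic(0), 0)
  # PIC = H - H^2/2 identity on a grid
  p <- seq(0, 1, by = 0.01)
  H <- expected_heterozygosity(p)
  expect_equal(pic(p), H - H^2 / 2, tolerance = 1e-12)
  # bi-allelic reduction of the general Botstein double sum
  expect_equal(pic_multiallelic(c(0.3, 0.7)), pic(0.3), tolerance = 1e-12)
})

test_that("pooled frequency, EMR and MI agree with direct enumeration", {
  m <- random_bm(n = 15, n_loci = 12, n_primers = 2,
                 missing_rate = 0.1, seed = 8)
  for (pr in primers(m)) {
    idx <- which(m$primer_of == pr)
    x <- m$data[, idx, drop = FALSE]
    f <- colMeans(x == 1, na.rm = TRUE)
    poly <- pmin(f, 1 - f) > 0
    xp <- x[, poly, drop = FALSE]
    expect_equal(pooled_band_frequency(m, pr),
                 sum(xp == 1, na.rm = TRUE) / sum(!is.na(xp)))
    n_i <- rowSums(x == 1, na.rm = TRUE)
    expect_equal(emr(m, pr), mean(n_i) * sum(poly) / length(idx))
    p_bar <- pooled_band_frequency(m, pr)
    expect_equal(marker_index(pic(p_bar), emr(m, pr)),
                 pic(p_bar) * emr(m, pr))
  }
  # degenerate primer: no polymorphic loci
  mono <- band_matrix(matrix(1, 3, 2), locus_ids = c("P1:1", "P1:2"))
  expect_error(pooled_band_frequency(mono, "P1"), "polymorphic")
  expect_equal(emr(mono, "P1"), 0)   # beta = 0
})

test_that("resolving power matches brute-force band informativeness", {
  m <- random_bm(n = 44, n_loci = 22, n_primers = 1, seed = 13)
  p <- colMeans(m$data == 1)
  expect_equal(resolving_power(m, "P1"), sum(1 - 2 * abs(0.5 - p)))
  # single band in half the individuals -> RP = 1
  half <- band_matrix(matrix(rep(c(1, 0), each = 4), 8, 1),
                      locus_ids = "P1:1")
  expect_equal(resolving_power(half, "P1"), 1)
  # fixed band contributes 0
  fixed <- band_matrix(matrix(c(1, 1, 1, 1, 1, 0, 0, 1), 4, 2),
                       locus_ids = c("P1:1", "P1:2"))
  expect_equal(resolving_power(fixed, "P1"),
               1 - 2 * abs(0.5 - mean(fixed$data[, 2])))
})

test_that("discriminating power matches the pattern-confusion formula", {
  # patterns {A, A, B, C}: C = 0.5 * (2 - 1) / 3 = 1/6, D = 5/6
  m <- band_matrix(matrix(c(1, 0,
                            1, 0,
                            0, 1,
                            1, 1), 4, 2, byrow = TRUE),
                   locus_ids = c("P1:1", "P1:2"))
  expect_equal(discriminating_power(m, "P1"), 5 / 6)
  # all identical -> 0; all distinct -> 1
  same <- band_matrix(matrix(rep(c(1, 0), 4), 4, 2, byrow = TRUE),
                      locus_ids = c("P1:1", "P1:2"))
  expect_equal(discriminating_power(same, "P1"), 0)
  m2 <- random_bm(n = 20, n_loci = 30, n_primers = 1, seed = 3)
  if (!anyDuplicated(apply(m2$data, 1, paste, collapse = "")))
    expect_equal(discriminating_power(m2, "P1"), 1)
})

test_that("Havp is the mean per-locus 2pq over polymorphic loci", {
  one <- band_matrix(matrix(c(1, 1, 0, 0), 4, 1), locus_ids = "P1:1")
  expect_equal(havp(one, "P1"), 0.5)
  m <- random_bm(n = 25, n_loci = 15, n_primers = 1,
                 missing_rate = 0.05, seed = 6)
  f <- colMeans(m$data == 1, na.rm = TRUE)
  poly <- pmin(f, 1 - f) > 0
  expect_equal(havp(m, "P1"), mean(2 * f[poly] * (1 - f[poly])))
  mono <- band_matrix(matrix(1, 3, 2), locus_ids = c("P1:1", "P1:2"))
  expect_warning(expect_equal(havp(mono, "P1"), 0), "Havp")
})

test_that("indices are invariant under individual and locus reordering", {
  m <- random_bm(n = 18, n_loci = 16, n_primers = 2, seed = 10)
  perm_i <- sample(nrow(m$data))
  perm_l <- order(m$primer_of, sample(ncol(m$data)))  # within-primer
  m_perm <- band_matrix(m$data[perm_i, perm_l],
                        primer_of = m$primer_of[perm_l],
                        population_of = m$population_of[perm_i])
  for (pr in primers(m)) {
    expect_equal(discriminating_power(m_perm, pr),
                 discriminating_power(m, pr))
    expect_equal(resolving_power(m_perm, pr), resolving_power(m, pr))
    expect_equal(emr(m_perm, pr), emr(m, pr))
    expect_equal(havp(m_perm, pr), havp(m, pr))
  }
})

test_that("adding a monomorphic locus lowers PPB and beta, not RP", {
  m <- random_bm(n = 12, n_loci = 8, n_primers = 1, seed = 5)
  aug <- band_matrix(cbind(m$data, `P1:extra` = 1L),
                     primer_of = c(m$primer_of, "P1"),
                     population_of = m$population_of)
  expect_lt(count_bands(aug, "P1")$PPB, count_bands(m, "P1")$PPB)
  expect_equal(resolving_power(aug, "P1"), resolving_power(m, "P1"))
})

test_that("primer_metrics table and its mean row are consistent", {
  m <- random_bm(n = 20, n_loci = 24, n_primers = 3, seed = 7)
  pm <- primer_metrics(m)
  expect_equal(nrow(pm), 3)
  expect_equal(pm$mi, pm$pic * pm$emr, tolerance = 1e-12)
  expect_equal(pm$pic, pm$h - pm$h^2 / 2, tolerance = 1e-12)
  agg <- aggregate_metrics(pm, sd_row = TRUE)
  expect_equal(agg$pic[1], mean(pm$pic))
  expect_equal(agg$rp[2], sd(pm$rp))
  # single primer: summary equals the row
  agg1 <- aggregate_metrics(pm[1, ])
  expect_equal(agg1$mi, pm$mi[1])
})
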