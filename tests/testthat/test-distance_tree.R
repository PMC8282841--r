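test_that("Nei identity and distance follow the normalized formulas", {
  p <- c(1, 0, 0.5)
  expect_equal(nei_identity(p, p), 1)
  # completely opposite fixation -> identity 0
  expect_equal(nei_identity(c(1, 1), c(0, 0)), 0)
  # hand-computed perturbation
  px <- c(1, 0, 0.5); py <- c(1, 0, 0.8)
  jxy <- mean(px * py + (1 - px) * (1 - py))
  jx <- mean(px^2 + (1 - px)^2); jy <- mean(py^2 + (1 - py)^2)
  expect_equal(nei_identity(px, py), jxy / sqrt(jx * jy))

  expect_equal(nei_distance(1), 0)
  expect_equal(nei_distance(exp(-0.14)), 0.14)
  expect_equal(nei_distance(0), Inf)
  expect_error(nei_distance(1.2), "identity")
  # symmetry
  for (s in 1:5) {
    set.seed(s)
    a <- runif(20); b <- runif(20)
    expect_equal(nei_identity(a, b), nei_identity(b, a))
  }
})

test_that("pairwise matrices are symmetric with the right extremes", {
  m <- random_bm(n = 10, n_loci = 30, seed = 2)
  pm <- pairwise_matrix(m, "individual")
  expect_equal(pm$distance, t(pm$distance))
  expect_equal(unname(diag(pm$distance)), rep(0, 10))
  expect_true(all(pm$identity <= 1 & pm$identity >= 0))

  # identical individuals -> GD = 0; full mismatch -> identity 0, Inf
  x <- rbind(c(1, 0, 1), c(1, 0, 1), c(0, 1, 0))
  m2 <- band_matrix(x, locus_ids = paste0("P1:", 1:3))
  pm2 <- pairwise_matrix(m2, "individual")
  expect_equal(pm2$distance["ind1", "ind2"], 0)
  expect_equal(pm2$identity["ind1", "ind3"], 0)
  expect_equal(pm2$distance["ind1", "ind3"], Inf)

  # population level uses estimated frequencies
  pmp <- pairwise_matrix(m, "population")
  expect_equal(dim(pmp$distance), c(2L, 2L))
  expect_true(pmp$distance[1, 2] >= 0)

  # report layout: distance below, identity above
  rep4 <- nei_report(pm2)
  expect_equal(rep4[2, 1], pm2$distance[2, 1])
  expect_equal(rep4[1, 2], pm2$identity[1, 2])
})

test_that("UPGMA reproduces the textbook merge and is ultrametric", {
  d <- matrix(c(0, 2, 6,
                2, 0, 6,
                6, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(d)
  expect_equal(attr(tr, "height"), c(1, 3))
  co <- ape::cophenetic.phylo(tr)
  expect_equal(co["A", "B"], 2)
  expect_equal(co["A", "C"], 6)

  # cophenetic distances of an ultrametric input are reproduced exactly
  base <- upgma(as.matrix(dist(matrix(rnorm(40), 10, 4))))
  ultra <- ape::cophenetic.phylo(base)
  again <- upgma(ultra)
  expect_equal(ape::cophenetic.phylo(again)[rownames(ultra),
                                            colnames(ultra)],
               ultra, tolerance = 1e-8)

  expect_error(upgma(matrix(c(0, Inf, Inf, 0), 2, 2)), "cap")
  expect_silent(upgma(matrix(c(0, Inf, Inf, 0), 2, 2,
                             dimnames = list(c("a", "b"), c("a", "b"))),
                      cap = 10))
})

test_that("UPGMA agrees with hclust average linkage on random inputs", {
  for (s in 1:10) {
    set.seed(s)
    x <- matrix(rnorm(50), 10, 5)
    d <- dist(x)
    mine <- upgma(as.matrix(d))
    ref <- ape::as.phylo(hclust(d, method = "average"))
    co_m <- ape::cophenetic.phylo(mine)
    co_r <- ape::cophenetic.phylo(ref)
    expect_equal(co_m[rownames(co_r), colnames(co_r)], co_r,
                 tolerance = 1e-7)
  }
})

test_that("Nei distance between populations grows with simulated F", {
  set.seed(77)
  pa <- runif(400, 0.1, 0.9)
  gd <- vapply(c(0.05, 0.1, 0.2, 0.4), function(F) {
    pc <- simulate_cluster_freqs(pa, c(F, F))
    Q <- simulate_admixture(120, 2, pop_to_cluster = rep(1:2, each = 60))
    m <- simulate_dominant_bands(Q, pc,
                                 population_of = rep(c("A", "B"),
                                                     each = 60))
    pairwise_matrix(m, "population")$distance["A", "B"]
  }, numeric(1))
  expect_true(all(diff(gd) > 0))
})

test_that("Ward linkage matches hclust ward.D and hand-computed merges", {
  # two identical rows merge first at height 0
  x <- rbind(a = c(1, 0, 1), b = c(1, 0, 1), c = c(0, 1, 0),
             d = c(0, 1, 1))
  wl <- ward_linkage(dist(x))
  expect_equal(wl$hclust$height[1], 0)
  expect_setequal(wl$order, rownames(x))

  # 3-point collinear configuration: Lance-Williams ward.D update
  # d(A,B)=1, d(B,C)=2, d(A,C)=3; merge A,B at 1, then
  # d(AB,C) = (2*3 + 2*2 - 1*1)/3 = 3
  d3 <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  wl3 <- ward_linkage(d3)
  expect_equal(wl3$hclust$height, c(1, 3))

  m <- random_bm(n = 12, n_loci = 20, seed = 9)
  ho <- heatmap_orders(m)
  expect_setequal(ho$rows, rownames(m$data))
  expect_setequal(ho$cols, colnames(m$data))
})

test_that("UPGMA recovers simulated clusters at the 3-cluster cut", {
  hits <- vapply(1:20, function(s) {
    sim <- simulate_band_matrix(sim_config(n_primers = 12, seed = 400 + s))
    true_k <- apply(sim$truth$Q_true, 1, which.max)
    names(true_k) <- rownames(sim$bands$data)
    tr <- upgma(pairwise_matrix(sim$bands, "individual")$distance,
                cap = 10)
    hc <- stats::cutree(stats::hclust(
      stats::as.dist(ape::cophenetic.phylo(tr)), "average"), k = 3)
    tab <- table(hc, true_k[names(hc)])
    sum(apply(tab, 1, max)) / length(true_k)
  }, numeric(1))
  expect_gte(mean(hits >= 0.9), 0.9)
})
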