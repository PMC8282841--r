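#' Nei's normalized gene identity between two frequency vectors
#'
#' For bi-allelic loci with band-allele frequencies `p_x`, `p_y` (and
#' null frequencies `q = 1 - p`): `Jxy = mean(p_x p_y + q_x q_y)`,
#' `Jx = mean(p_x^2 + q_x^2)`, `Jy` likewise, and
#' `I = Jxy / sqrt(Jx Jy)`.
#'
#' @param freq_x,freq_y band-allele frequency vectors over the same loci.
#' @return identity in \[0, 1\].
#' @export
nei_identity <- function(freq_x, freq_y) {
  stopifnot(length(freq_x) == length(freq_y),
            all(freq_x >= 0 & freq_x <= 1),
            all(freq_y >= 0 & freq_y <= 1))
  qx <- 1 - freq_x; qy <- 1 - freq_y
  jxy <- mean(freq_x * freq_y + qx * qy)
  jx <- mean(freq_x^2 + qx^2)
  jy <- mean(freq_y^2 + qy^2)
  jxy / sqrt(jx * jy)
}

#' Nei's standard genetic distance from an identity
#'
#' `GD = -ln(I)`; identity 0 maps to `Inf`.
#'
#' @param I_xy identity in \[0, 1\] (vectorized).
#' @param tol numerical tolerance for values marginally outside \[0, 1\].
#' @return genetic distance `>= 0`.
#' @export
nei_distance <- function(I_xy, tol = 1e-9) {
  if (any(I_xy > 1 + tol) || any(I_xy < -tol))
    stop("identity must lie in [0, 1]", call. = FALSE)
  I_xy <- pmin(pmax(I_xy, 0), 1)
  ifelse(I_xy == 0, Inf, -log(I_xy))
}

#' Pairwise Nei identity and distance matrices
#'
#' At `level = "individual"` each individual's 0/1 band states are used
#' directly as frequencies (the GenAlEx convention for dominant data,
#' where Nei's 1972 measure is applied between single-individual
#' profiles). At `level = "population"` band-allele frequencies are
#' estimated within each population by [estimate_allele_freq()], with
#' Nei's 1978 small-sample ("unbiased") correction of the within-unit
#' homozygosities available via `unbiased = TRUE`.
#'
#' @param m a [band_matrix()].
#' @param level `"individual"` or `"population"`.
#' @param unbiased apply the Nei (1978) correction (population level
#'   only).
#' @param lynch_milligan see [estimate_allele_freq()].
#' @return list of class `nei_matrices` with symmetric `identity` and
#'   `distance` matrices (zero diagonal; distance may contain `Inf`).
#' @export
pairwise_matrix <- function(m, level = c("individual", "population"),
                            unbiased = FALSE, lynch_milligan = FALSE) {
  level <- match.arg(level)
  if (level == "individual") {
    keep <- rowSums(!is.na(m$data)) > 0
    if (!all(keep))
      warning("excluding individuals with all-missing data: ",
              paste(rownames(m$data)[!keep], collapse = ", "))
    units <- rownames(m$data)[keep]
    fmat <- m$data[keep, , drop = FALSE]
    nmat <- NULL
  } else {
    units <- levels(m$population_of)
    fmat <- t(vapply(units, function(g) {
      rows <- which(m$population_of == g)
      bf <- per_locus_band_freq(m, rows)
      estimate_allele_freq(bf$freq, bf$n, lynch_milligan)$p_hat
    }, numeric(ncol(m$data))))
    nmat <- t(vapply(units, function(g) {
      per_locus_band_freq(m, which(m$population_of == g))$n
    }, numeric(ncol(m$data))))
  }
  nu <- length(units)
  if (nu < 2) stop("need at least 2 units", call. = FALSE)
  ident <- diag(1, nu)
  dimnames(ident) <- list(units, units)
  jwithin <- vapply(seq_len(nu), function(i) {
    p <- fmat[i, ]; j <- p^2 + (1 - p)^2
    if (unbiased && !is.null(nmat)) {
      nn <- 2 * nmat[i, ]
      j <- pmin(1, (nn * j - 1) / (nn - 1))
    }
    mean(j, na.rm = TRUE)
  }, numeric(1))
  for (i in seq_len(nu - 1)) for (j in (i + 1):nu) {
    ok <- !is.na(fmat[i, ]) & !is.na(fmat[j, ])
    px <- fmat[i, ok]; py <- fmat[j, ok]
    jxy <- mean(px * py + (1 - px) * (1 - py))
    ident[i, j] <- ident[j, i] <- jxy / sqrt(jwithin[i] * jwithin[j])
  }
  ident <- pmin(ident, 1)
  dist <- nei_distance(ident)
  diag(dist) <- 0
  structure(list(identity = ident, distance = dist,
                 kind = "nei", level = level),
            class = "nei_matrices")
}

#' Combined identity/distance report matrix
#'
#' Distance below the diagonal, identity above (the conventional layout
#' of published pairwise tables).
#'
#' @param pm a `nei_matrices` object from [pairwise_matrix()].
#' @return square numeric matrix.
#' @export
nei_report <- function(pm) {
  stopifnot(inherits(pm, "nei_matrices"))
  out <- pm$distance
  out[upper.tri(out)] <- pm$identity[upper.tri(pm$identity)]
  diag(out) <- NA_real_
  out
}

#' UPGMA clustering of a distance matrix
#'
#' Average-linkage agglomeration: the closest pair of clusters is merged
#' at node height `d_min / 2` and the distance from the merged cluster
#' to any other is the size-weighted arithmetic mean of its members'
#' distances. Ties are broken by the lexicographically smallest pair of
#' cluster labels (a cluster is labelled by its smallest leaf), so the
#' output is reproducible across platforms. The result is an ultrametric
#' rooted tree.
#'
#' @param d symmetric distance matrix with unit labels, or a
#'   [stats::dist] object, or the `distance` element of a
#'   `nei_matrices`.
#' @param cap optional finite ceiling substituted for infinite
#'   distances; by default infinite entries are an error.
#' @return an [ape::phylo] tree with an `height` attribute (named vector
#'   of internal node heights in merge order).
#' @export
upgma <- function(d, cap = NULL) {
  if (inherits(d, "nei_matrices")) d <- d$distance
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  if (is.null(rownames(d)))
    rownames(d) <- colnames(d) <- paste0("u", seq_len(nrow(d)))
  if (nrow(d) < 2) stop("need at least 2 units", call. = FALSE)
  if (any(!is.finite(d[upper.tri(d)]))) {
    if (is.null(cap))
      stop("distance matrix contains infinite entries; ",
           "supply a finite 'cap' to build the tree", call. = FALSE)
    d[!is.finite(d)] <- cap
  }
  labels <- rownames(d)
  n <- length(labels)
  # active clusters: list of leaf-newick fragments, member heights, sizes
  frag <- labels
  lab <- labels                 # representative = smallest member label
  size <- rep(1, n)
  height <- rep(0, n)
  heights_out <- numeric(0)
  active <- rep(TRUE, n)
  D <- d
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        i <- idx[a]; j <- idx[b]
        dij <- D[i, j]
        key <- paste(sort(c(lab[i], lab[j])), collapse = "\r")
        if (dij < best_d - 1e-12 ||
            (abs(dij - best_d) <= 1e-12 && !is.null(best_key) &&
             key < best_key)) {
          best_d <- dij; best <- c(i, j); best_key <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    h <- best_d / 2
    heights_out <- c(heights_out, h)
    new_frag <- sprintf("(%s:%.12g,%s:%.12g)",
                        frag[i], h - height[i], frag[j], h - height[j])
    # size-weighted average linkage update
    for (k in which(active)) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <-
        (size[i] * D[i, k] + size[j] * D[j, k]) / (size[i] + size[j])
    }
    frag[i] <- new_frag
    lab[i] <- min(lab[i], lab[j])
    size[i] <- size[i] + size[j]
    height[i] <- h
    active[j] <- FALSE
  }
  tr <- ape::read.tree(text = paste0(frag[which(active)], ";"))
  attr(tr, "height") <- heights_out
  tr
}

#' Ward-linkage clustering of binary profiles
#'
#' Euclidean distances over the 0/1 rows (or columns) clustered with the
#' classical Lance-Williams Ward update on unsquared distances
#' ([stats::hclust] `method = "ward.D"`), as used to order heatmap rows
#' and columns.
#'
#' @param d a [stats::dist] of Euclidean distances, or a
#'   [band_matrix()] (then distances are computed over `margin`).
#' @param margin `"individuals"` (rows) or `"loci"` (columns) when `d`
#'   is a band matrix; missing scores are mean-imputed per locus first.
#' @param cap finite ceiling for non-finite distances (see [upgma()]).
#' @return list with `hclust` (the merge structure), `tree` (an
#'   [ape::phylo]) and `order` (labels in dendrogram order).
#' @export
ward_linkage <- function(d, margin = c("individuals", "loci"),
                         cap = NULL) {
  margin <- match.arg(margin)
  if (inherits(d, "band_matrix")) {
    x <- impute_locus_means(d$data)
    if (margin == "loci") x <- t(x)
    d <- stats::dist(x, method = "euclidean")
  }
  if (!inherits(d, "dist")) d <- stats::as.dist(as.matrix(d))
  if (any(!is.finite(d))) {
    if (is.null(cap))
      stop("distances contain non-finite entries; supply 'cap'",
           call. = FALSE)
    d[!is.finite(d)] <- cap
  }
  hc <- stats::hclust(d, method = "ward.D")
  list(hclust = hc, tree = ape::as.phylo(hc),
       order = hc$labels[hc$order])
}

#' Heatmap row and column orders of a band matrix
#'
#' Ward linkage on Euclidean distances over individuals (rows) and loci
#' (columns).
#'
#' @param m a [band_matrix()].
#' @return list with `rows` and `cols` label vectors.
#' @export
heatmap_orders <- function(m) {
  list(rows = ward_linkage(m, "individuals")$order,
       cols = ward_linkage(m, "loci")$order)
}
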