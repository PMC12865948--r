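# Alpha diversity, Bray-Curtis dissimilarity, principal coordinates analysis
# and the three label-permutation community tests (PERMANOVA, ANOSIM,
# homogeneity of multivariate dispersion), implemented from first principles.

#' Shannon and Simpson alpha diversity
#'
#' Within-sample relative abundances `p_i` give Shannon `-sum(p log p)` in
#' nats and Simpson `1 - sum(p^2)`.
#'
#' @param profile Samples x features abundance matrix with positive row sums.
#' @return `data.frame` with `sample_id`, `shannon`, `simpson`.
#' @export
alpha_diversity <- function(profile) {
  tot <- rowSums(profile)
  if (any(tot <= 0)) {
    ftx_format_error(sprintf("sample '%s' is empty (zero total abundance)",
                             rownames(profile)[tot <= 0][1]))
  }
  p <- profile / tot
  shannon <- apply(p, 1L, function(v) { v <- v[v > 0]; -sum(v * log(v)) })
  simpson <- 1 - rowSums(p^2)
  data.frame(sample_id = rownames(profile) %||% seq_len(nrow(profile)),
             shannon = unname(shannon), simpson = unname(simpson),
             stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` between the non-negative
#' abundance rows of `profile`; symmetric with a zero diagonal, values in
#' \[0, 1\].
#'
#' @param profile Samples x features matrix of non-negative abundances.
#' @return Square dissimilarity matrix with sample dimnames.
#' @export
bray_curtis <- function(profile) {
  if (nrow(profile) < 2L) ftx_usage_error("need at least two samples")
  if (any(profile < 0)) ftx_format_error("negative abundances are not allowed")
  rs <- rowSums(profile)
  if (sum(rs == 0) >= 2L) {
    ftx_format_error("two all-zero samples make Bray-Curtis undefined for that pair")
  }
  manh <- as.matrix(stats::dist(profile, method = "manhattan"))
  denom <- outer(rs, rs, "+")
  d <- manh / denom
  diag(d) <- 0
  dimnames(d) <- list(rownames(profile), rownames(profile))
  d
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-0.5 * D^2` followed by an eigendecomposition.
#' Axes with eigenvalues above a numerical tolerance are retained and scaled
#' by the square root of their eigenvalue; all eigenvalues, including
#' negative ones from non-Euclidean dissimilarities, are reported (no
#' Lingoes/Cailliez correction is applied).
#'
#' @param D Square symmetric dissimilarity matrix with zero diagonal.
#' @param tol Relative tolerance for retaining eigenvalues (default
#'   `1e-8 * max(|eigenvalue|)`).
#' @return List of class `"pcoa"` with `points` (samples x retained axes),
#'   `eigenvalues` (all, sorted decreasing), `prop_explained` (per positive
#'   axis, relative to the positive-eigenvalue total), and
#'   `negative_eigenvalues` flag.
#' @export
pcoa <- function(D, tol = NULL) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) ftx_usage_error("D must be square")
  if (max(abs(D - t(D))) > 1e-8) ftx_usage_error("D must be symmetric")
  if (max(abs(diag(D))) > 1e-12) ftx_usage_error("D must have a zero diagonal")
  n <- nrow(D)
  A <- -0.5 * D^2
  rm_ <- rowMeans(A); gm <- mean(A)
  G <- A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  lambda <- e$values
  if (is.null(tol)) tol <- if (max(abs(lambda)) > 0) 1e-8 * max(abs(lambda)) else 0
  pos <- which(lambda > tol)
  pts <- if (length(pos)) {
    e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lambda[pos]), length(pos))
  } else {
    matrix(0, n, 0L)
  }
  rownames(pts) <- rownames(D)
  if (ncol(pts)) colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  pos_sum <- sum(lambda[lambda > 0])
  structure(list(points = pts,
                 eigenvalues = lambda,
                 prop_explained = if (length(pos) && pos_sum > 0)
                   lambda[pos] / pos_sum else numeric(),
                 negative_eigenvalues = any(lambda < -tol)),
            class = "pcoa")
}

# ---- shared machinery for the permutation tests ---------------------------

.beta_checks <- function(D, design) {
  D <- as.matrix(D)
  design <- validate_design(as.data.frame(design))
  if (is.null(rownames(D))) {
    if (nrow(D) != nrow(design)) ftx_design_error("design and D sizes differ")
    idx <- seq_len(nrow(D))
  } else {
    idx <- match(design$sample_id, rownames(D))
    if (anyNA(idx)) {
      ftx_design_error(sprintf("sample '%s' absent from the dissimilarity matrix",
                               design$sample_id[which(is.na(idx))[1]]))
    }
    D <- D[idx, idx, drop = FALSE]
  }
  groups <- unique(design$group)
  list(D = D, g1 = design$group == groups[1], n = nrow(D))
}

# n x n_perm 0/1 indicator matrix of group-1 membership under random label
# permutations.
.perm_indicators <- function(n, n1, n_perm, seed) {
  with_seed(seed, {
    U <- matrix(0, n, n_perm)
    for (j in seq_len(n_perm)) U[sample.int(n, n1), j] <- 1
    U
  })
}

.new_beta_test <- function(test, statistic, n_perm, p, extra = list()) {
  structure(c(list(test = test, statistic = statistic,
                   permutations = n_perm, p.value = p), extra),
            class = "beta_test")
}

#' PERMANOVA for a two-group design
#'
#' One-factor permutational multivariate analysis of variance on a
#' dissimilarity matrix: the total sum of squares `sum(d^2)/n` is partitioned
#' into among- and within-group components and the pseudo-F statistic is
#' referred to its permutation distribution over random relabelings of the
#' samples. P values use the `(1 + b) / (1 + n_perm)` convention.
#'
#' @param D Square dissimilarity matrix.
#' @param design `sample_design` (two groups, each with >= 2 samples).
#' @param n_perm Number of label permutations.
#' @param seed RNG seed for the permutations.
#' @return `beta_test` list with the pseudo-F `statistic`, `R2`,
#'   `permutations` and permutation `p.value`.
#' @export
permanova <- function(D, design, n_perm = 999, seed = 1) {
  bc <- .beta_checks(D, design)
  D2 <- bc$D^2
  n <- bc$n
  n1 <- sum(bc$g1); n2 <- n - n1
  sst <- sum(D2) / (2 * n)
  f_of <- function(U) {
    # U: n x m indicator of group-1 membership; returns pseudo-F per column
    V <- 1 - U
    s1 <- colSums(U * (D2 %*% U))
    s2 <- colSums(V * (D2 %*% V))
    ssw <- s1 / (2 * n1) + s2 / (2 * n2)
    ((sst - ssw) / 1) / (ssw / (n - 2))
  }
  u_obs <- matrix(as.numeric(bc$g1), n, 1)
  f_obs <- f_of(u_obs)
  fp <- f_of(.perm_indicators(n, n1, n_perm, seed))
  p <- (1 + sum(fp >= f_obs)) / (1 + n_perm)
  .new_beta_test("PERMANOVA", unname(f_obs), n_perm, p,
                 extra = list(R2 = unname((f_obs / (n - 2)) / (1 + f_obs / (n - 2)))))
}

#' ANOSIM for a two-group design
#'
#' Analysis of similarities on the ranks of all pairwise dissimilarities
#' (average ranks on ties): `R = (mean between-group rank - mean within-group
#' rank) / (n(n-1)/4)`, which confines R to \[-1, 1\] with R = 1 when every
#' between-group dissimilarity exceeds every within-group one. Permutation P
#' as in [permanova()].
#'
#' @inheritParams permanova
#' @return `beta_test` list with `statistic` (R), `permutations`, `p.value`.
#' @export
anosim <- function(D, design, n_perm = 999, seed = 1) {
  bc <- .beta_checks(D, design)
  n <- bc$n
  n1 <- sum(bc$g1); n2 <- n - n1
  R <- matrix(0, n, n)
  lw <- lower.tri(R)
  R[lw] <- rank(bc$D[lw])
  R <- R + t(R)
  m_pairs <- n * (n - 1) / 2
  rank_total <- m_pairs * (m_pairs + 1) / 2
  w_pairs <- choose(n1, 2) + choose(n2, 2)
  b_pairs <- n1 * n2
  denom <- n * (n - 1) / 4
  r_of <- function(U) {
    V <- 1 - U
    sw <- (colSums(U * (R %*% U)) + colSums(V * (R %*% V))) / 2
    rw <- sw / w_pairs
    rb <- (rank_total - sw) / b_pairs
    (rb - rw) / denom
  }
  u_obs <- matrix(as.numeric(bc$g1), n, 1)
  r_obs <- r_of(u_obs)
  rp <- r_of(.perm_indicators(n, n1, n_perm, seed))
  p <- (1 + sum(rp >= r_obs)) / (1 + n_perm)
  .new_beta_test("ANOSIM", unname(r_obs), n_perm, p)
}

#' Homogeneity of multivariate dispersion
#'
#' Samples are embedded by [pcoa()]; each sample's distance to its group
#' centroid combines the positive- and negative-eigenvalue parts of the
#' embedding (squared imaginary-part distances are subtracted and the result
#' floored at zero). A one-way F statistic on these distances is referred to
#' its permutation distribution, permuting the centroid distances across
#' groups (the one-way equivalent of permuting labels). Group centroids (not
#' spatial medians) are used.
#'
#' @inheritParams permanova
#' @return `beta_test` list with the dispersion F `statistic`,
#'   `permutations`, `p.value`, per-sample `distances` and a `degenerate`
#'   flag (all distances zero gives P = 1).
#' @export
dispersion_test <- function(D, design, n_perm = 999, seed = 1) {
  bc <- .beta_checks(D, design)
  n <- bc$n
  g1 <- bc$g1
  A <- -0.5 * bc$D^2
  rm_ <- rowMeans(A); gm <- mean(A)
  G <- A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  tol <- if (max(abs(e$values)) > 0) 1e-8 * max(abs(e$values)) else 0
  ip <- e$values > tol
  im <- e$values < -tol
  Xp <- e$vectors[, ip, drop = FALSE] %*% diag(sqrt(e$values[ip]), sum(ip))
  Xn <- e$vectors[, im, drop = FALSE] %*% diag(sqrt(-e$values[im]), sum(im))
  dist_to_centroid <- function(keep) {
    d2 <- rep(0, sum(keep))
    if (ncol(Xp)) {
      cp <- colMeans(Xp[keep, , drop = FALSE])
      d2 <- d2 + rowSums(sweep(Xp[keep, , drop = FALSE], 2L, cp)^2)
    }
    if (ncol(Xn)) {
      cn <- colMeans(Xn[keep, , drop = FALSE])
      d2 <- d2 - rowSums(sweep(Xn[keep, , drop = FALSE], 2L, cn)^2)
    }
    sqrt(pmax(d2, 0))
  }
  z <- numeric(n)
  z[g1] <- dist_to_centroid(g1)
  z[!g1] <- dist_to_centroid(!g1)
  if (all(z < 1e-12)) {
    return(.new_beta_test("dispersion", NA_real_, n_perm, 1,
                          extra = list(distances = z, degenerate = TRUE)))
  }
  n1 <- sum(g1); n2 <- n - n1
  f_on <- function(U) {
    V <- 1 - U
    s1 <- drop(crossprod(U, z)); s2 <- drop(crossprod(V, z))
    ssb <- s1^2 / n1 + s2^2 / n2 - (s1 + s2)^2 / n
    sst <- sum(z^2) - (s1 + s2)^2 / n
    ssw <- sst - ssb
    (ssb / 1) / (ssw / (n - 2))
  }
  u_obs <- matrix(as.numeric(g1), n, 1)
  f_obs <- f_on(u_obs)
  fp <- f_on(.perm_indicators(n, n1, n_perm, seed))
  p <- (1 + sum(fp >= f_obs)) / (1 + n_perm)
  .new_beta_test("dispersion", unname(f_obs), n_perm, p,
                 extra = list(distances = z, degenerate = FALSE))
}
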