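# diversity: alpha indices, Bray-Curtis, PCoA, permutation tests

test_that("alpha diversity matches closed forms", {
  prof <- rbind(u = rep(25, 4),          # uniform over 4 features
                s = c(100, 0, 0, 0),     # single feature
                m = c(50, 25, 25, 0))    # p = (0.5, 0.25, 0.25)
  colnames(prof) <- paste0("f", 1:4)
  res <- alpha_diversity(prof)
  expect_equal(res$shannon, c(log(4), 0, 1.039721), tolerance = 1e-6)
  expect_equal(res$simpson, c(0.75, 0, 1 - (0.25 + 2 * 0.0625)),
               tolerance = 1e-12)
  prof[2, ] <- 0
  expect_error(alpha_diversity(prof), "s", class = "ftx_format_error")
})

test_that("alpha diversity agrees with vegan", {
  prof <- random_profile(8, 30, seed = 21)
  res <- alpha_diversity(prof)
  expect_equal(res$shannon, unname(vegan::diversity(prof, "shannon")),
               tolerance = 1e-10)
  expect_equal(res$simpson, unname(vegan::diversity(prof, "simpson")),
               tolerance = 1e-10)
})

test_that("Bray-Curtis matches hand cases, bounds, and vegan", {
  x <- rbind(a = c(1, 2), b = c(2, 1), c = c(1, 2), d = c(0, 3))
  D <- bray_curtis(x)
  expect_equal(D["a", "b"], 2 / 6, tolerance = 1e-12)
  expect_equal(D["a", "c"], 0)
  # disjoint supports
  y <- rbind(p = c(5, 0), q = c(0, 7))
  expect_equal(bray_curtis(y)["p", "q"], 1)

  prof <- random_profile(10, 25, seed = 3)
  D2 <- bray_curtis(prof)
  expect_true(all(D2 >= 0 & D2 <= 1))
  expect_equal(D2, t(D2))
  expect_equal(unname(diag(D2)), rep(0, 10))
  expect_equal(D2, as.matrix(vegan::vegdist(prof, "bray")),
               ignore_attr = TRUE, tolerance = 1e-10)

  # scaling both samples of a pair equally leaves d unchanged; scaling one
  # sample alone changes it
  z <- rbind(u = c(1, 2, 3), v = c(3, 1, 1))
  expect_equal(bray_curtis(z * 7)["u", "v"], bray_curtis(z)["u", "v"])
  z2 <- z; z2["v", ] <- z2["v", ] * 7
  expect_false(isTRUE(all.equal(bray_curtis(z2)["u", "v"],
                                bray_curtis(z)["u", "v"])))

  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(0, 0))),
               class = "ftx_format_error")
  expect_error(bray_curtis(-x), class = "ftx_format_error")
})

test_that("PCoA reconstructs Euclidean distances and reports negative
           eigenvalues", {
  set.seed(8)
  pts <- matrix(rnorm(20 * 3), 20, 3)
  rownames(pts) <- sprintf("S%02d", 1:20)
  D <- as.matrix(dist(pts))
  ord <- pcoa(D)
  expect_lte(max(abs(as.matrix(dist(ord$points)) - D)), 1e-8)
  expect_false(ord$negative_eigenvalues)
  # coordinates are centered
  expect_lt(max(abs(colMeans(ord$points))), 1e-8)
  # proportion explained sums to 1 over positive axes
  expect_equal(sum(ord$prop_explained), 1, tolerance = 1e-10)

  # all points identical: no retained axes
  ord0 <- pcoa(matrix(0, 4, 4))
  expect_equal(ncol(ord0$points), 0L)
  expect_no_mismatch(ord0$eigenvalues, rep(0, 4), tol = 1e-12)

  # a 4-point non-Euclidean metric keeps its negative eigenvalue in the list
  Dn <- matrix(1, 4, 4) - diag(4)
  Dn[1, 2] <- Dn[2, 1] <- 1.99  # violates embeddability, still a metric
  ordn <- pcoa(Dn)
  expect_true(ordn$negative_eigenvalues)
  expect_true(min(ordn$eigenvalues) < 0)

  expect_error(pcoa(matrix(1:9, 3, 3)), class = "ftx_usage_error")
})

test_that("PERMANOVA matches vegan::adonis2 on statistic and R2", {
  prof <- random_profile(14, 40, seed = 77)
  design <- make_design(7, 7)
  rownames(prof) <- design$sample_id
  D <- bray_curtis(prof)
  got <- permanova(D, design, n_perm = 199, seed = 5)
  ref <- vegan::adonis2(as.dist(D) ~ group, data = design, permutations = 199)
  expect_equal(got$statistic, ref$F[1], tolerance = 1e-10)
  expect_equal(got$R2, ref$R2[1], tolerance = 1e-10)
  # sample order of the inputs does not change the observed statistic
  idx <- sample(14)
  got2 <- permanova(D[idx, idx], design, n_perm = 199, seed = 5)
  expect_equal(got2$statistic, got$statistic, tolerance = 1e-12)
})

test_that("ANOSIM matches vegan and its R stays within [-1, 1]", {
  prof <- random_profile(12, 30, seed = 31)
  design <- make_design(6, 6)
  rownames(prof) <- design$sample_id
  D <- bray_curtis(prof)
  got <- anosim(D, design, n_perm = 99, seed = 2)
  ref <- vegan::anosim(as.dist(D), grouping = factor(design$group),
                       permutations = 99)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)

  set.seed(55)
  for (i in 1:25) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    p <- random_profile(n1 + n2, 12, seed = 1000 + i)
    d <- make_design(n1, n2)
    rownames(p) <- d$sample_id
    r <- anosim(bray_curtis(p), d, n_perm = 99, seed = i)$statistic
    expect_gte(r, -1); expect_lte(r, 1)
  }
})

test_that("fully separated clusters reach R = 1 and the minimal permutation P", {
  # two clusters far apart in feature space, 13 + 13
  design <- make_design(13, 13)
  set.seed(6)
  prof <- rbind(matrix(rlnorm(13 * 20, 0, 0.1), 13, 20),
                matrix(rlnorm(13 * 20, 4, 0.1), 13, 20))
  rownames(prof) <- design$sample_id
  D <- bray_curtis(prof)
  pa <- permanova(D, design, n_perm = 999, seed = 11)
  an <- anosim(D, design, n_perm = 999, seed = 11)
  expect_equal(an$statistic, 1, tolerance = 1e-12)
  expect_equal(pa$p.value, 1 / 1000)
  expect_equal(an$p.value, 1 / 1000)
})

test_that("permutation tests are deterministic given a seed and bounded", {
  prof <- random_profile(10, 15, seed = 12)
  design <- make_design(5, 5)
  rownames(prof) <- design$sample_id
  D <- bray_curtis(prof)
  for (f in list(permanova, anosim, dispersion_test)) {
    r1 <- f(D, design, n_perm = 199, seed = 3)
    r2 <- f(D, design, n_perm = 199, seed = 3)
    expect_identical(r1$p.value, r2$p.value)
    expect_gte(r1$p.value, 1 / 200)
    expect_lte(r1$p.value, 1)
  }
  bad <- data.frame(sample_id = design$sample_id, group = "one")
  expect_error(permanova(D, bad, 99, 1), class = "ftx_design_error")
})

test_that("dispersion test distances match vegan::betadisper and degenerate
           input yields P = 1", {
  prof <- random_profile(12, 20, seed = 41)
  design <- make_design(6, 6)
  rownames(prof) <- design$sample_id
  D <- bray_curtis(prof)
  got <- dispersion_test(D, design, n_perm = 99, seed = 9)
  ref <- vegan::betadisper(as.dist(D), group = factor(design$group),
                           type = "centroid")
  expect_equal(got$distances, unname(ref$distances), tolerance = 1e-8)
  ref_f <- anova(ref)$`F value`[1]
  expect_equal(got$statistic, ref_f, tolerance = 1e-8)

  # identical samples -> all centroid distances zero -> degenerate, P = 1
  same <- matrix(5, 6, 3, dimnames = list(make_design(3, 3)$sample_id, NULL))
  d0 <- bray_curtis(same + 0)
  res0 <- dispersion_test(d0, make_design(3, 3), n_perm = 99, seed = 1)
  expect_true(res0$degenerate)
  expect_equal(res0$p.value, 1)
})

test_that("dispersion test detects a scaled spread difference with power", {
  # one group's within-spread scaled x5; reduced replicate count here (the
  # acceptance suite covers calibration at scale)
  design <- make_design(13, 13)
  hits <- 0L
  for (i in 1:40) {
    set.seed(7000 + i)
    base <- matrix(rlnorm(13 * 15, 0, 0.15), 13, 15)
    wide <- matrix(rlnorm(13 * 15, 0, 0.75), 13, 15)
    prof <- rbind(base, wide)
    rownames(prof) <- design$sample_id
    p <- dispersion_test(bray_curtis(prof), design, n_perm = 999,
                         seed = i)$p.value
    hits <- hits + (p <= 0.01)
  }
  expect_gte(hits / 40, 0.9)
})
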