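# attribution: genus deltas, contribution percentages, pooling/ranking

# a small function-by-taxon fixture with known group sums
make_ftm <- function(cells, design) {
  # cells: data.frame(feature_id, genus, per-sample tpm columns)
  long <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(feature_id = cells$feature_id[i], genus = cells$genus[i],
               sample_id = design$sample_id,
               tpm = as.numeric(cells[i, design$sample_id]),
               stringsAsFactors = FALSE)
  }))
  class(long) <- c("function_taxon_matrix", "data.frame")
  long
}

test_that("genus deltas implement the signed group-sum difference", {
  design <- make_design(2, 2)
  cells <- data.frame(feature_id = "K1",
                      genus = c("GenA", "GenB", "GenC"),
                      stringsAsFactors = FALSE)
  # LFCR sums: A 30, B 10, C 5; HFCR sums: A 10, B 20, C 5
  cells[design$sample_id] <- rbind(c(10, 20, 5, 5),
                                   c(4, 6, 12, 8),
                                   c(2, 3, 1, 4))
  ftm <- make_ftm(cells, design)
  d <- genus_deltas("K1", ftm, design)
  expect_equal(d[["GenA"]], 20)
  expect_equal(d[["GenB"]], -10)
  expect_false("GenC" %in% names(d))  # balanced genus dropped
  expect_equal(attr(d, "positive_group"), "LFCR")
  expect_error(genus_deltas("missing", ftm, design), "missing",
               class = "ftx_usage_error")
})

test_that("contribution percentages follow |delta| / total x 100 with sign
           direction", {
  d <- c(GenA = 20, GenB = -10)
  attr(d, "positive_group") <- "LFCR"; attr(d, "negative_group") <- "HFCR"
  res <- contribution_percentages(d)
  expect_equal(res$contribution_pct, c(200 / 3, 100 / 3), tolerance = 1e-12)
  expect_equal(res$direction, c("LFCR", "HFCR"))
  expect_equal(sum(res$contribution_pct), 100)

  # single genus -> 100%
  one <- c(G = -5)
  expect_equal(contribution_percentages(one)$contribution_pct, 100)
  # symmetric deltas -> 50/50 opposite directions
  sym <- c(A = 10, B = -10)
  rs <- contribution_percentages(sym)
  expect_equal(rs$contribution_pct, c(50, 50))
  expect_equal(length(unique(rs$direction)), 2L)
  # zero total change is an error
  expect_error(contribution_percentages(c(A = 0)), "no net change",
               class = "ftx_usage_error")
})

test_that("pool_and_rank pools < threshold, keeps top-k, conserves 100%", {
  mk <- function(pct, dir, genus = sprintf("G%02d", seq_along(pct))) {
    structure(data.frame(genus = genus,
                         delta_g = ifelse(dir == "LFCR", pct, -pct),
                         direction = dir, contribution_pct = pct,
                         stringsAsFactors = FALSE),
              positive_group = "LFCR", negative_group = "HFCR")
  }
  # contributions (40, 25, 15) one direction, 20 in the other
  rec <- mk(c(40, 25, 15, 20), c("LFCR", "LFCR", "LFCR", "HFCR"))
  out <- pool_and_rank(rec, pool_threshold = 0.20, top_k = 5)
  ret <- out[out$retained & out$genus != "Others", ]
  expect_equal(sort(ret$contribution_pct), c(20, 25, 40))
  oth <- out[out$genus == "Others", ]
  expect_equal(sum(oth$contribution_pct), 15)
  expect_equal(sum(ret$contribution_pct) + sum(oth$contribution_pct), 100)

  # 7 genera all >= 20% of their direction: only the largest 5 retained
  pct7 <- c(22, 21, 15, 11, 11, 10, 10)  # one direction, sums to 100
  rec7 <- mk(pct7, rep("LFCR", 7))
  out7 <- pool_and_rank(rec7, pool_threshold = 0.10, top_k = 5)
  ret7 <- out7[out7$retained & out7$genus != "Others", ]
  expect_equal(nrow(ret7), 5L)
  expect_equal(sum(out7$contribution_pct[out7$genus == "Others"]),
               sum(sort(pct7)[1:2]))
  # deterministic tie-break: contribution desc, then genus label asc
  expect_equal(ret7$genus, c("G01", "G02", "G03", "G04", "G05"))

  # label flag at >= 3%
  rec3 <- mk(c(90, 8, 2), rep("LFCR", 3))
  out3 <- pool_and_rank(rec3, pool_threshold = 0.01, top_k = 5,
                        label_threshold = 0.03)
  expect_equal(out3$labeled[match(c("G01", "G02", "G03"), out3$genus)],
               c(TRUE, TRUE, FALSE))

  # the unassigned pseudo-genus is never retained by name
  recu <- mk(c(60, 40), c("LFCR", "LFCR"), genus = c("unassigned", "GenA"))
  outu <- pool_and_rank(recu, pool_threshold = 0.20, top_k = 5)
  expect_false(any(outu$retained & outu$genus == "unassigned"))
  expect_equal(sum(outu$contribution_pct[outu$genus == "Others"]), 60)

  expect_error(pool_and_rank(rec, pool_threshold = 1.2),
               class = "ftx_usage_error")
})

test_that("attribution is conserved, scale-equivariant and composes the
           three steps", {
  ds <- generate_dataset(simulation_spec(n_per_group = 6, n_genera = 8,
                                         n_genes = 200, n_kos = 12,
                                         depth_mean = 1e5, seed = 19))
  tpm <- compute_tpm(ds$counts, ds$annotations)
  ko <- aggregate_by_function(tpm, ds$annotations, "KO")
  ftm <- build_function_taxon_matrix(tpm, ds$annotations, "KO")
  cfg <- analysis_config(trend_alpha = 0.5)  # attribute plenty of features
  diff <- differential_features(ko, ds$design, cfg)
  res <- attribute_differentials(diff, ftm, ds$design, cfg)
  feats <- unique(res$feature_id)
  expect_gt(length(feats), 2)

  for (f in feats) {
    sub <- res[res$feature_id == f, ]
    # conservation before pooling: named genus rows sum to 100
    expect_equal(sum(sub$contribution_pct[sub$genus != "Others"]), 100,
                 tolerance = 1e-9)
    # retained + Others = 100
    expect_equal(sum(sub$contribution_pct[sub$retained]), 100,
                 tolerance = 1e-9)
    # direction always matches the delta sign
    pos <- attr(diff, "positive_group")
    expect_true(all(sub$direction[sub$delta_g > 0] == pos))
    # composition oracle: equals the three steps run by hand
    hand <- pool_and_rank(contribution_percentages(
      genus_deltas(f, ftm, ds$design)),
      cfg$pool_threshold, cfg$top_k, cfg$label_threshold)
    expect_equal(sub$contribution_pct, hand$contribution_pct)
    expect_equal(sub$genus, hand$genus)
  }

  # scale equivariance: c * TPM leaves every contribution unchanged
  ftm_scaled <- ftm
  ftm_scaled$tpm <- ftm_scaled$tpm * 37.5
  res2 <- attribute_differentials(diff, ftm_scaled, ds$design, cfg)
  expect_equal(res2$contribution_pct, res$contribution_pct, tolerance = 1e-12)
  expect_equal(res2$direction, res$direction)

  # no differential features -> empty table
  none <- diff[0, ]
  res0 <- attribute_differentials(none, ftm, ds$design, cfg)
  expect_equal(nrow(res0), 0L)
})

test_that("a planted dominant genus is recovered as top contributor", {
  hits <- 0L
  nsim <- 25L
  for (i in seq_len(nsim)) {
    pf <- data.frame(feature_id = "K00900", feature_kind = "KO",
                     target_genus = "Genus_002", log2_effect = 1.5,
                     intended_dominant_contribution = 0.6,
                     stringsAsFactors = FALSE)
    ds <- generate_dataset(simulation_spec(
      n_per_group = 13, n_genera = 12, n_genes = 300, n_kos = 30,
      depth_mean = 2e5, planted_features = pf, seed = 5000 + i))
    tpm <- compute_tpm(ds$counts, ds$annotations)
    ko <- aggregate_by_function(tpm, ds$annotations, "KO")
    diff <- differential_features(ko, ds$design)
    ftm <- build_function_taxon_matrix(tpm, ds$annotations, "KO")
    res <- attribute_differentials(diff, ftm, ds$design)
    sub <- res[res$feature_id == "K00900" & res$retained &
                 res$genus != "Others", ]
    if (nrow(sub) && sub$genus[which.max(sub$contribution_pct)] == "Genus_002") {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, ceiling(0.9 * nsim))
})
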