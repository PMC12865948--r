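# Synthetic two-group metagenome cohort: an annotated gene catalog, an
# overdispersed count matrix, a sample design, animal phenotypes, and a
# ground-truth table for planted effects. Counts are simulated at the gene
# level (the pipeline consumes mapped-read counts, so read-level simulation
# adds nothing); library sizes are log-normal and counts negative-binomial
# with a shared dispersion. Group effects multiply the expected abundance of
# the planted (feature, target genus) gene sets in the positive group only,
# and per-sample compositions are renormalized afterwards so TPM closure is
# respected.

.default_phenotype_model <- function() {
  # trait = c(mean positive group (LFCR), mean negative group (HFCR), sd)
  list(FCR        = c(4.2, 5.6, 0.35),
       IBW        = c(22, 22, 1.8),
       FBW        = c(42, 38.5, 2.5),
       ADG        = c(0.29, 0.22, 0.025),
       ADFI       = c(1.32, 1.28, 0.09),
       CW         = c(21, 19, 1.6),
       LW         = c(0.78, 0.66, 0.07),
       total_VFA  = c(95, 93, 9),
       acetate    = c(60, 61, 6),
       propionate = c(23, 18.5, 3.5),
       butyrate   = c(10.5, 10, 1.6))
}

#' Specification of a synthetic cohort
#'
#' Defaults emulate the shape of a 13-vs-13 extreme-feed-efficiency cohort:
#' a gene catalog partitioned over genera whose mean relative abundances
#' follow a power-law rank-abundance curve, gene lengths uniform on
#' 300-3000 bp, roughly half of genes KO-annotated and ~7% CAZy-annotated,
#' log-normal library sizes and negative-binomial counts.
#'
#' @param n_per_group Samples per group (>= 2).
#' @param n_genera Number of genera in the catalog.
#' @param n_genes Catalog size.
#' @param n_kos,n_cazy Functional label pool sizes.
#' @param genus_base_abundance Dirichlet concentration vector (length
#'   `n_genera`, positive); default `150 * rank^-1.2` normalized means.
#' @param depth_mean,depth_cv Log-normal library-size model.
#' @param dispersion Negative-binomial overdispersion phi
#'   (variance `mu + phi mu^2`); 0 gives Poisson counts.
#' @param length_range Gene length range in bp.
#' @param ko_prob,cazy_prob,hydrogenase_prob Per-gene annotation probabilities.
#' @param unassigned_prob Probability that a gene's lineage is truncated at a
#'   random rank (taxonomically unassigned tail).
#' @param planted_features `data.frame` with columns `feature_id`,
#'   `feature_kind` (KO / CAZy / hydrogenase), `target_genus`, `log2_effect`
#'   (applied to the positive group), `intended_dominant_contribution` in
#'   (0, 1].
#' @param group_labels Two group labels, positive group first.
#' @param phenotype_model Named list `trait = c(mean_pos, mean_neg, sd)`.
#' @param seed RNG seed; identical specs and seeds give byte-identical output.
#' @return List of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_per_group = 13, n_genera = 50, n_genes = 5000,
                            n_kos = 300, n_cazy = 50,
                            genus_base_abundance = NULL,
                            depth_mean = 2e6, depth_cv = 0.25,
                            dispersion = 0.2,
                            length_range = c(300, 3000),
                            ko_prob = 0.5, cazy_prob = 0.07,
                            hydrogenase_prob = 0.002,
                            unassigned_prob = 0.10,
                            planted_features = NULL,
                            group_labels = c("LFCR", "HFCR"),
                            phenotype_model = NULL,
                            seed = 1) {
  if (n_per_group < 2) ftx_spec_error("n_per_group must be >= 2")
  if (n_genera < 2) ftx_spec_error("n_genera must be >= 2")
  if (n_genes < n_genera) ftx_spec_error("n_genes must be >= n_genera")
  if (is.null(genus_base_abundance)) {
    w <- (seq_len(n_genera))^(-1.2)
    genus_base_abundance <- 150 * w / sum(w)
  }
  if (length(genus_base_abundance) != n_genera ||
      any(genus_base_abundance <= 0)) {
    ftx_spec_error("genus_base_abundance must be a positive vector of length n_genera")
  }
  if (dispersion < 0) ftx_spec_error("dispersion must be >= 0")
  if (depth_mean <= 0 || depth_cv < 0) ftx_spec_error("invalid depth model")
  if (length(group_labels) != 2L || anyDuplicated(group_labels)) {
    ftx_spec_error("group_labels must be two distinct labels")
  }
  if (!is.null(planted_features)) {
    req <- c("feature_id", "feature_kind", "target_genus", "log2_effect",
             "intended_dominant_contribution")
    if (!all(req %in% names(planted_features))) {
      ftx_spec_error(sprintf("planted_features needs columns: %s",
                             paste(req, collapse = ", ")))
    }
    if (any(!is.finite(planted_features$log2_effect))) {
      ftx_spec_error("planted log2 effects must be finite")
    }
    idc <- planted_features$intended_dominant_contribution
    if (any(!(idc > 0 & idc <= 1))) {
      ftx_spec_error("intended_dominant_contribution must lie in (0, 1]")
    }
    if (!all(planted_features$feature_kind %in% c("KO", "CAZy", "hydrogenase"))) {
      ftx_spec_error("feature_kind must be KO, CAZy or hydrogenase")
    }
  }
  structure(list(
    n_per_group = as.integer(n_per_group), n_genera = as.integer(n_genera),
    n_genes = as.integer(n_genes), n_kos = as.integer(n_kos),
    n_cazy = as.integer(n_cazy),
    genus_base_abundance = genus_base_abundance,
    depth_mean = depth_mean, depth_cv = depth_cv, dispersion = dispersion,
    length_range = length_range, ko_prob = ko_prob, cazy_prob = cazy_prob,
    hydrogenase_prob = hydrogenase_prob, unassigned_prob = unassigned_prob,
    planted_features = planted_features, group_labels = group_labels,
    phenotype_model = phenotype_model %||% .default_phenotype_model(),
    seed = as.integer(seed)), class = "simulation_spec")
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  g / rowSums(g)
}

.genus_names <- function(n) sprintf("Genus_%03d", seq_len(n))

# Build the annotated catalog and the per-gene baseline relative weights b
# (summing to 1), including the planted-feature carrier designation and the
# within-genus weight rescaling that realizes the intended dominant
# contribution in expectation. Assumes the RNG is already seeded.
.build_catalog <- function(spec) {
  n_genera <- spec$n_genera
  genera <- .genus_names(n_genera)
  m <- spec$genus_base_abundance / sum(spec$genus_base_abundance)

  # genes per genus proportional to mean abundance, each genus >= 1 gene
  n_g <- pmax(1L, round(m * spec$n_genes))
  while (sum(n_g) != spec$n_genes) {
    d <- spec$n_genes - sum(n_g)
    j <- if (d > 0) which.max(m) else which.max(n_g * (n_g > 1L))
    n_g[j] <- n_g[j] + sign(d)
  }
  genus_of <- rep.int(seq_len(n_genera), n_g)

  # baseline gene weights: within-genus exponential stick lengths scaled to
  # the genus mean abundance
  b <- numeric(spec$n_genes)
  for (k in seq_len(n_genera)) {
    idx <- which(genus_of == k)
    w <- stats::rexp(length(idx))
    b[idx] <- m[k] * w / sum(w)
  }

  lengths_bp <- sample(spec$length_range[1]:spec$length_range[2],
                       spec$n_genes, replace = TRUE)

  # taxonomy: genera nested in synthetic higher ranks; domains weighted to a
  # bacteria-dominated community
  doms <- sample(c("Bacteria", "Eukaryota", "Viruses", "Archaea"),
                 n_genera, replace = TRUE, prob = c(0.92, 0.05, 0.02, 0.01))
  n_phyla <- max(2L, ceiling(n_genera / 6))
  phy_of <- sample.int(n_phyla, n_genera, replace = TRUE)
  lineage <- data.frame(
    domain = doms[genus_of],
    phylum = sprintf("Phylum_%02d", phy_of[genus_of]),
    class  = sprintf("Class_%02d", phy_of[genus_of]),
    order  = sprintf("Order_%02d", ((genus_of - 1L) %/% 3L) + 1L),
    family = sprintf("Family_%03d", genus_of),
    genus  = genera[genus_of],
    stringsAsFactors = FALSE)
  lineage_full <- lineage
  # truncate a fraction of lineages at a random rank (prefix rule holds)
  trunc_gene <- which(stats::runif(spec$n_genes) < spec$unassigned_prob)
  if (length(trunc_gene)) {
    cut_at <- sample.int(length(.RANKS), length(trunc_gene), replace = TRUE)
    for (i in seq_along(trunc_gene)) {
      lineage[trunc_gene[i], cut_at[i]:length(.RANKS)] <- .UNASSIGNED
    }
  }

  ko_pool <- sprintf("K%05d", seq_len(spec$n_kos))
  cls <- sample(.CAZY_CLASSES, spec$n_cazy, replace = TRUE,
                prob = c(140, 83, 33, 17, 90, 12))
  cazy_pool <- paste0(cls, seq_len(spec$n_cazy))

  ko <- rep(NA_character_, spec$n_genes)
  annotated <- which(stats::runif(spec$n_genes) < spec$ko_prob)
  if (length(annotated)) {
    # every KO in the pool is used at least once when enough genes exist,
    # remaining annotated genes draw uniformly from the pool
    labs <- if (length(annotated) >= spec$n_kos) {
      sample(c(ko_pool, sample(ko_pool, length(annotated) - spec$n_kos,
                               replace = TRUE)))
    } else {
      sample(ko_pool, length(annotated))
    }
    ko[annotated] <- labs
  }

  caz <- rep(NA_character_, spec$n_genes)
  caz_gene <- which(stats::runif(spec$n_genes) < spec$cazy_prob)
  if (length(caz_gene)) {
    nfam <- sample(1:2, length(caz_gene), replace = TRUE, prob = c(0.8, 0.2))
    caz[caz_gene] <- vapply(seq_along(caz_gene), function(i) {
      paste(unique(sample(cazy_pool, nfam[i])), collapse = ";")
    }, "")
  }

  hg <- rep(NA_character_, spec$n_genes)
  hc <- rep(NA_character_, spec$n_genes)
  hyd_gene <- which(stats::runif(spec$n_genes) < spec$hydrogenase_prob)
  if (length(hyd_gene)) {
    hg[hyd_gene] <- sample(.HYD_GROUPS, length(hyd_gene), replace = TRUE,
                           prob = c(0.045, 0.952, 0.003))
    hc[hyd_gene] <- sample(.HYD_CATEGORIES, length(hyd_gene), replace = TRUE)
  }

  ann <- data.frame(gene_id = sprintf("gene_%06d", seq_len(spec$n_genes)),
                    length_bp = as.integer(lengths_bp), lineage,
                    ko = ko, cazy_families = caz,
                    hydrogenase_group = hg, hydrogenase_category = hc,
                    stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")

  # planted features: designate carrier genes and rescale baseline weights so
  # the target genus holds the intended share of the feature's expected mass
  boosted <- rep(FALSE, spec$n_genes)   # genes receiving the group effect
  effect_log2 <- rep(0, spec$n_genes)
  pf <- spec$planted_features
  reserved <- rep(FALSE, spec$n_genes)  # carriers are never shared between
                                        # planted features
  if (!is.null(pf) && nrow(pf)) {
    for (i in seq_len(nrow(pf))) {
      tg <- pf$target_genus[i]
      k <- match(tg, genera)
      if (is.na(k)) {
        ftx_spec_error(sprintf("planted feature '%s' references absent genus '%s'",
                               pf$feature_id[i], tg))
      }
      in_tg <- which(genus_of == k & !reserved)
      if (!length(in_tg)) {
        ftx_spec_error(sprintf(
          "planted feature '%s': no unreserved genes left in genus '%s'",
          pf$feature_id[i], tg))
      }
      s_t <- in_tg[seq_len(min(3L, length(in_tg)))]
      idc <- pf$intended_dominant_contribution[i]
      s_o <- integer()
      if (idc < 1) {
        og <- setdiff(unique(genus_of), k)
        pick_g <- og[seq_len(min(6L, length(og)))]
        s_o <- unlist(lapply(pick_g, function(gg) {
          utils::head(which(genus_of == gg & !reserved), 1L)
        }))
      }
      # rescale target-genus carrier weights toward the intended share,
      # preserving the genus total
      if (length(s_o)) {
        b_t <- sum(b[s_t]); b_o <- sum(b[s_o])
        want <- idc / (1 - idc) * b_o
        cap <- 0.9 * m[k]
        if (want > cap) {
          warning(sprintf(
            "feature '%s': intended contribution %.2f not realizable within genus mass; capped",
            pf$feature_id[i], idc), call. = FALSE)
          want <- cap
        }
        rest <- setdiff(in_tg, s_t)
        if (length(rest) && (m[k] - want) > 0) {
          b[rest] <- b[rest] * (m[k] - want) / sum(b[rest])
        }
        b[s_t] <- b[s_t] * want / b_t
      }
      carriers <- c(s_t, s_o)
      reserved[carriers] <- TRUE
      # carriers must keep their genus assignment: the planted effect is a
      # statement about a (feature, genus) pair, so undo any lineage
      # truncation that hit a carrier gene
      ann[carriers, .RANKS] <- lineage_full[carriers, ]
      kind <- pf$feature_kind[i]
      fid <- pf$feature_id[i]
      if (kind == "KO") {
        ann$ko[carriers] <- fid
      } else if (kind == "CAZy") {
        if (!grepl("^(GH|GT|PL|CE|CBM|AA)[0-9]+$", fid)) {
          ftx_spec_error(sprintf("planted CAZy feature id '%s' is not a family label", fid))
        }
        ann$cazy_families[carriers] <- vapply(ann$cazy_families[carriers],
          function(cur) {
            if (is.na(cur)) return(fid)
            fams <- strsplit(cur, ";", fixed = TRUE)[[1]]
            paste(unique(c(fams, fid)), collapse = ";")
          }, "", USE.NAMES = FALSE)
      } else {
        if (!fid %in% .HYD_CATEGORIES) {
          ftx_spec_error(sprintf("planted hydrogenase feature '%s' is not a category", fid))
        }
        ann$hydrogenase_category[carriers] <- fid
        ann$hydrogenase_group[carriers] <- "[FeFe]"
      }
      boosted[s_t] <- TRUE
      effect_log2[s_t] <- effect_log2[s_t] + pf$log2_effect[i]
    }
    b <- b / sum(b)
  }

  list(annotations = ann, b = b, genus_of = genus_of, genus_means = m,
       genera = genera, boosted = boosted, effect_log2 = effect_log2)
}

#' Generate a synthetic cohort dataset
#'
#' Draws per-sample genus compositions from the Dirichlet model, applies the
#' planted group effects to the positive group, renormalizes (compositional
#' closure), samples log-normal library sizes and negative-binomial counts,
#' and draws phenotypes with the configured group differences (lower FCR and
#' higher ADG in the positive group by default). The same spec and seed
#' always reproduce identical output.
#'
#' @param spec A [simulation_spec()].
#' @return List with `annotations`, `counts` (samples x genes), `design`,
#'   `phenotypes`, `truth` (see [truth_contributions()]), and `expected`
#'   (noise-free expected per-group TPM used for the truth channel).
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "simulation_spec")) {
    spec <- do.call(simulation_spec, spec)
  }
  with_seed(spec$seed, {
    cat_ <- .build_catalog(spec)
    npg <- spec$n_per_group
    n_s <- 2L * npg
    g_lab <- spec$group_labels
    sample_ids <- c(sprintf("%s_%02d", g_lab[1], seq_len(npg)),
                    sprintf("%s_%02d", g_lab[2], seq_len(npg)))
    design <- data.frame(sample_id = sample_ids,
                         group = rep(g_lab, each = npg),
                         stringsAsFactors = FALSE)

    alpha <- spec$genus_base_abundance
    pi_s <- .rdirichlet(n_s, alpha)                       # samples x genera
    rel <- pi_s[, cat_$genus_of, drop = FALSE] *
      rep(cat_$b / cat_$genus_means[cat_$genus_of], each = n_s)
    mult <- 2^cat_$effect_log2
    if (any(cat_$boosted)) {
      rel[seq_len(npg), cat_$boosted] <-
        rel[seq_len(npg), cat_$boosted, drop = FALSE] *
        rep(mult[cat_$boosted], each = npg)
    }
    rel <- rel / rowSums(rel)

    sdlog <- sqrt(log(1 + spec$depth_cv^2))
    depth <- stats::rlnorm(n_s, meanlog = log(spec$depth_mean) - sdlog^2 / 2,
                           sdlog = sdlog)
    mu <- rel * depth
    counts <- if (spec$dispersion > 0) {
      matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                            size = 1 / spec$dispersion), nrow = n_s)
    } else {
      matrix(stats::rpois(length(mu), lambda = as.vector(mu)), nrow = n_s)
    }
    dimnames(counts) <- list(sample_ids, cat_$annotations$gene_id)
    # TPM needs at least one read per sample; at realistic depths this never
    # triggers, but guard tiny test configurations
    empty <- rowSums(counts) == 0
    if (any(empty)) counts[empty, which.max(cat_$b)] <- 1

    pm <- spec$phenotype_model
    phen <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
    for (tr in names(pm)) {
      mu_tr <- rep(pm[[tr]][1:2], each = npg)
      phen[[tr]] <- stats::rnorm(n_s, mean = mu_tr, sd = pm[[tr]][3])
    }

    expected <- .expected_group_tpm(spec, cat_)
    truth <- truth_contributions(spec, expected)

    list(annotations = cat_$annotations, counts = counts,
         design = validate_design(design), phenotypes = phen,
         truth = truth, expected = expected, spec = spec)
  })
}

# Noise-free expected per-group TPM: Dirichlet proportions at their means,
# planted effects applied to the positive group, closure to 1e6.
.expected_group_tpm <- function(spec, cat_) {
  base <- cat_$b
  pos <- base * 2^cat_$effect_log2
  tpm <- rbind(pos / sum(pos), base / sum(base)) * 1e6
  dimnames(tpm) <- list(spec$group_labels, cat_$annotations$gene_id)
  list(tpm = tpm, annotations = cat_$annotations,
       boosted = cat_$boosted, genus_of = cat_$genus_of,
       genera = cat_$genera)
}

#' Ground-truth contributions for planted features
#'
#' Applies the contribution decomposition (group-sum deltas, absolute
#' normalization) to the noise-free expected abundances of the generator:
#' per planted feature, the expected per-group TPM of each carrier gene is
#' summed over the `n_per_group` samples of each group and differenced, and
#' each genus's realized expected contribution is its share of the total
#' absolute change. This is the truth channel against which attribution on
#' simulated data is scored; realized contributions differ from the intended
#' ones because compositional renormalization spreads a planted boost across
#' all other genes.
#'
#' @param spec A [simulation_spec()] with planted features.
#' @param expected The `expected` element of [generate_dataset()] output.
#' @return `data.frame` with one row per (planted feature, genus):
#'   `feature_id`, `genus`, `expected_delta`, `direction`,
#'   `truth_contribution_pct`, `is_target`.
#' @export
truth_contributions <- function(spec, expected) {
  pf <- spec$planted_features
  if (is.null(pf) || !nrow(pf)) {
    return(data.frame(feature_id = character(), genus = character(),
                      expected_delta = numeric(), direction = character(),
                      truth_contribution_pct = numeric(), is_target = logical(),
                      stringsAsFactors = FALSE))
  }
  ann <- expected$annotations
  genus <- ann$genus
  genus[genus == .UNASSIGNED] <- .UNASSIGNED
  npg <- spec$n_per_group
  g_lab <- spec$group_labels
  out <- list()
  for (i in seq_len(nrow(pf))) {
    fid <- pf$feature_id[i]
    kind <- pf$feature_kind[i]
    carriers <- switch(kind,
      KO = which(!is.na(ann$ko) & ann$ko == fid),
      CAZy = which(!is.na(ann$cazy_families) &
                     vapply(strsplit(ann$cazy_families, ";", fixed = TRUE),
                            function(f) fid %in% f, TRUE)),
      hydrogenase = which(!is.na(ann$hydrogenase_category) &
                            ann$hydrogenase_category == fid))
    delta_gene <- npg * (expected$tpm[g_lab[1], carriers] -
                           expected$tpm[g_lab[2], carriers])
    dm <- rowsum(delta_gene, genus[carriers], reorder = TRUE)
    d <- drop(dm); names(d) <- rownames(dm)
    d <- d[d != 0]
    total <- sum(abs(d))
    if (total == 0) {
      warning(sprintf("planted feature '%s': effect cancels (Delta_total = 0)", fid),
              call. = FALSE)
      next
    }
    out[[fid]] <- data.frame(
      feature_id = fid, genus = names(d), expected_delta = unname(d),
      direction = ifelse(d > 0, g_lab[1], g_lab[2]),
      truth_contribution_pct = abs(unname(d)) / total * 100,
      is_target = names(d) == pf$target_genus[i],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, unname(out))
  rownames(res) <- NULL
  res
}
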