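# Genus-level contribution decomposition of differential functional features:
# for a feature, each genus's signed group-sum difference Delta_g =
# sum(TPM over group-1 samples) - sum(TPM over group-2 samples), the total
# change Delta_total = sum(|Delta_g|), and the proportional contribution
# |Delta_g| / Delta_total * 100 with direction from sign(Delta_g), followed
# by pooling (< pool_threshold into "Others") and top-k retention per
# direction.

#' Signed genus-level group-sum differences for one feature
#'
#' For every genus carrying the feature, TPM values are summed across all
#' samples of each group and differenced, oriented positive group minus
#' negative group (LFCR - HFCR when those labels are present). Group sums,
#' not means, are used; with unequal group sizes the sums bias the difference
#' toward the larger group, so a warning is emitted in that case. Genera with
#' an exactly zero difference are dropped.
#'
#' @param feature_id Feature to decompose.
#' @param ftm `function_taxon_matrix` from [build_function_taxon_matrix()].
#' @param design `sample_design`.
#' @param positive Optional name of the group taking the positive sign.
#' @return Named numeric vector of Delta_g per genus, with attributes
#'   `positive_group` and `negative_group`.
#' @export
genus_deltas <- function(feature_id, ftm, design, positive = NULL) {
  design <- validate_design(as.data.frame(design))
  rows <- ftm[ftm$feature_id == feature_id, , drop = FALSE]
  if (!nrow(rows)) {
    ftx_usage_error(sprintf("feature '%s' is absent from the function-by-taxon matrix",
                            feature_id))
  }
  pos <- positive_group(design, positive)
  sizes <- attr(design, "group_sizes")
  if (length(unique(sizes)) > 1L) {
    warning(sprintf(
      "unequal group sizes (%s): group sums bias Delta toward the larger group",
      paste(sizes, collapse = " vs ")), call. = FALSE)
  }
  grp <- design$group[match(rows$sample_id, design$sample_id)]
  if (anyNA(grp)) {
    ftx_design_error("function-by-taxon matrix contains samples absent from the design")
  }
  s_pos <- rowsum(rows$tpm * (grp == pos), rows$genus, reorder = TRUE)
  s_neg <- rowsum(rows$tpm * (grp != pos), rows$genus, reorder = TRUE)
  delta <- drop(s_pos - s_neg)
  names(delta) <- rownames(s_pos)
  delta <- delta[delta != 0]  # subsetting drops attributes; set them after
  attr(delta, "positive_group") <- pos
  attr(delta, "negative_group") <- setdiff(unique(design$group), pos)
  delta
}

#' Contribution percentages from genus deltas
#'
#' `Delta_total = sum(|Delta_g|)`; each genus contributes
#' `|Delta_g| / Delta_total * 100` percent, with enrichment direction given
#' by the sign of its delta. Before any pooling the percentages sum to 100.
#'
#' @param deltas Named vector from [genus_deltas()].
#' @return `data.frame` with `genus`, `delta_g`, `direction`,
#'   `contribution_pct`, sorted by contribution (descending, genus ascending
#'   on ties).
#' @export
contribution_percentages <- function(deltas) {
  pos_attr <- attr(deltas, "positive_group")
  neg_attr <- attr(deltas, "negative_group")
  deltas <- deltas[deltas != 0]
  total <- sum(abs(deltas))
  if (!length(deltas) || total == 0) {
    ftx_usage_error("no net change to attribute (Delta_total = 0)")
  }
  pos <- pos_attr %||% "group1"
  neg <- neg_attr %||% "group2"
  out <- data.frame(genus = names(deltas),
                    delta_g = unname(deltas),
                    direction = ifelse(deltas > 0, pos, neg),
                    contribution_pct = abs(unname(deltas)) / total * 100,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$contribution_pct, out$genus), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "positive_group") <- pos
  attr(out, "negative_group") <- neg
  out
}

#' Pool small contributions and retain the top genera per direction
#'
#' Within each enrichment direction, genera contributing strictly less than
#' `pool_threshold` (as a fraction of the feature's total change) are pooled
#' into "Others"; of the remainder at most `top_k` genera are retained
#' (contribution descending, genus label ascending on ties), and everything
#' not retained also folds into "Others". The pseudo-genus `"unassigned"`
#' (genes without a genus call) participates in the decomposition but is
#' never retained as a named contributor. Retained contributions of at least
#' `label_threshold` are flagged `labeled`. Retained mass plus the "Others"
#' rows always totals 100%.
#'
#' @param records Output of [contribution_percentages()] for one feature.
#' @param pool_threshold Pooling threshold as a fraction (default 0.20).
#' @param top_k Maximum genera retained per direction (default 5).
#' @param label_threshold Labelling threshold as a fraction (default 0.03).
#' @return `data.frame` of class `"contribution_table"`: all genus records
#'   with `retained`/`labeled` flags plus one `"Others"` row per direction
#'   holding the pooled remainder.
#' @export
pool_and_rank <- function(records, pool_threshold = 0.20, top_k = 5,
                          label_threshold = 0.03) {
  if (!(pool_threshold > 0 && pool_threshold < 1)) {
    ftx_usage_error("pool_threshold must lie in (0, 1)")
  }
  if (top_k < 1) ftx_usage_error("top_k must be >= 1")
  dirs <- unique(records$direction)
  records$retained <- FALSE
  records$labeled <- FALSE
  others <- list()
  for (d in dirs) {
    in_dir <- which(records$direction == d)
    cand <- in_dir[records$contribution_pct[in_dir] >= pool_threshold * 100 &
                     records$genus[in_dir] != .UNASSIGNED]
    cand <- cand[order(-records$contribution_pct[cand], records$genus[cand])]
    keep <- utils::head(cand, top_k)
    records$retained[keep] <- TRUE
    records$labeled[keep] <- records$contribution_pct[keep] >= label_threshold * 100
    rest <- setdiff(in_dir, keep)
    if (length(rest)) {
      others[[d]] <- data.frame(
        genus = "Others", delta_g = sum(records$delta_g[rest]), direction = d,
        contribution_pct = sum(records$contribution_pct[rest]),
        retained = TRUE,
        labeled = sum(records$contribution_pct[rest]) >= label_threshold * 100,
        stringsAsFactors = FALSE)
    }
  }
  out <- rbind(records, do.call(rbind, unname(others)))
  rownames(out) <- NULL
  attr(out, "positive_group") <- attr(records, "positive_group")
  attr(out, "negative_group") <- attr(records, "negative_group")
  class(out) <- c("contribution_table", "data.frame")
  out
}

#' Attribute differential features to genera
#'
#' Runs the full decomposition ([genus_deltas()],
#' [contribution_percentages()], [pool_and_rank()]) for every feature whose
#' differential tier is in `tiers` (by default significant and trend
#' features), in the order of the differential table. Features whose total
#' change is zero are skipped with a warning.
#'
#' @param diff `differential_table` from [differential_features()].
#' @param ftm `function_taxon_matrix` for the same scheme.
#' @param design `sample_design`.
#' @param config An [analysis_config()] supplying the pooling parameters.
#' @param tiers Tiers to attribute.
#' @return `data.frame` with a `feature_id` column followed by the
#'   [pool_and_rank()] columns; zero rows when nothing is differential.
#' @export
attribute_differentials <- function(diff, ftm, design,
                                    config = analysis_config(),
                                    tiers = c("significant", "trend")) {
  feats <- diff$feature_id[diff$tier %in% tiers]
  out <- list()
  for (f in feats) {
    deltas <- genus_deltas(f, ftm, design)
    if (!length(deltas) || sum(abs(deltas)) == 0) {
      warning(sprintf("feature '%s': no net change to attribute; skipped", f),
              call. = FALSE)
      next
    }
    tab <- pool_and_rank(contribution_percentages(deltas),
                         pool_threshold = config$pool_threshold,
                         top_k = config$top_k,
                         label_threshold = config$label_threshold)
    out[[f]] <- cbind(feature_id = f, tab, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(feature_id = character(), genus = character(),
               delta_g = numeric(), direction = character(),
               contribution_pct = numeric(), retained = logical(),
               labeled = logical(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("contribution_table", "data.frame")
  res
}
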