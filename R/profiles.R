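# TPM normalization and aggregation of gene-level abundances into taxon
# profiles, function profiles and function-by-taxon matrices, plus the
# display pooling rule ("Others").

#' Compute TPM abundances from mapped-read counts
#'
#' Per sample, each gene's count is divided by its length in kilobases and
#' the resulting rates are renormalized to sum to one million. Because of the
#' per-sample renormalization the choice of bp vs kb cancels; kilobases are
#' used by convention.
#'
#' @param counts Samples x genes matrix of non-negative integer counts.
#' @param annotations `gene_annotation` table covering every gene in `counts`.
#' @return Samples x genes matrix of TPM values (each row sums to 1e6).
#' @export
compute_tpm <- function(counts, annotations) {
  genes <- colnames(counts)
  if (is.null(genes)) ftx_usage_error("counts matrix must have gene column names")
  idx <- match(genes, annotations$gene_id)
  if (anyNA(idx)) {
    ftx_format_error(sprintf("gene '%s' in counts is absent from the annotation table",
                             genes[which(is.na(idx))[1]]))
  }
  len_kb <- annotations$length_bp[idx] / 1000
  if (any(len_kb <= 0)) ftx_format_error("non-positive gene length in annotations")
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    ftx_format_error(sprintf("sample '%s' has no mapped reads (all-zero column)",
                             rownames(counts)[zero][1]))
  }
  rate <- sweep(counts, 2L, len_kb, "/")
  tpm <- rate / rowSums(rate) * 1e6
  tpm
}

#' Aggregate TPM to a taxonomic rank
#'
#' Sums the TPM of all genes whose lineage is assigned at `rank`; genes
#' unassigned at that rank are excluded from the profile and their per-sample
#' TPM total is reported in the `"unassigned_tpm"` attribute. With
#' `renormalize_within_domain = TRUE` each gene's TPM is first divided by its
#' domain's per-sample total, yielding within-domain relative abundances.
#'
#' @param tpm Samples x genes TPM matrix.
#' @param annotations `gene_annotation` table.
#' @param rank One of domain, phylum, class, order, family, genus.
#' @param renormalize_within_domain Rescale abundances within each domain.
#' @return Samples x taxa matrix with attributes `rank_or_scheme` and
#'   `unassigned_tpm`.
#' @export
aggregate_by_taxon <- function(tpm, annotations, rank,
                               renormalize_within_domain = FALSE) {
  if (length(rank) != 1L || !rank %in% .RANKS) {
    ftx_usage_error(sprintf("unknown rank '%s' (use one of: %s)",
                            paste(rank, collapse = ","), paste(.RANKS, collapse = ", ")))
  }
  idx <- match(colnames(tpm), annotations$gene_id)
  if (anyNA(idx)) ftx_format_error("TPM matrix contains genes absent from annotations")
  labels <- annotations[[rank]][idx]
  assigned <- labels != .UNASSIGNED
  vals <- tpm
  if (renormalize_within_domain) {
    dom <- annotations$domain[idx]
    dom_ok <- dom != .UNASSIGNED
    dom_tot <- t(rowsum(t(tpm[, dom_ok, drop = FALSE]), dom[dom_ok]))
    scale <- matrix(NA_real_, nrow(tpm), ncol(tpm))
    scale[, dom_ok] <- dom_tot[, dom[dom_ok], drop = FALSE]
    vals <- ifelse(scale > 0, tpm / scale, 0)
    assigned <- assigned & dom_ok
  }
  sel <- which(assigned)
  if (!length(sel)) {
    out <- matrix(0, nrow(tpm), 0L, dimnames = list(rownames(tpm), character()))
  } else {
    out <- t(rowsum(t(vals[, sel, drop = FALSE]), labels[sel]))
  }
  attr(out, "rank_or_scheme") <- rank
  attr(out, "unassigned_tpm") <- rowSums(tpm[, !assigned, drop = FALSE])
  out
}

.SCHEMES <- c("KO", "CAZy_family", "CAZy_class", "hydrogenase_category",
              "hydrogenase_group")

# gene index -> functional label map for a scheme; a gene appears once per
# distinct label it carries (multi-family CAZy genes book their full TPM in
# each family; classes are deduplicated so a GH13;GH97 gene counts once in GH).
.function_gene_map <- function(annotations, idx, scheme) {
  if (length(scheme) != 1L || !scheme %in% .SCHEMES) {
    ftx_usage_error(sprintf("unknown scheme '%s' (use one of: %s)",
                            paste(scheme, collapse = ","),
                            paste(.SCHEMES, collapse = ", ")))
  }
  if (scheme == "KO") {
    lab <- annotations$ko[idx]
    keep <- which(!is.na(lab))
    return(list(gene = keep, label = lab[keep]))
  }
  if (scheme == "hydrogenase_category") {
    lab <- annotations$hydrogenase_category[idx]
    keep <- which(!is.na(lab))
    return(list(gene = keep, label = lab[keep]))
  }
  if (scheme == "hydrogenase_group") {
    lab <- annotations$hydrogenase_group[idx]
    keep <- which(!is.na(lab))
    return(list(gene = keep, label = lab[keep]))
  }
  caz <- annotations$cazy_families[idx]
  keep <- which(!is.na(caz))
  fams <- strsplit(caz[keep], ";", fixed = TRUE)
  if (scheme == "CAZy_class") {
    fams <- lapply(fams, function(f) unique(sub("[0-9]+$", "", f)))
  }
  list(gene = rep(keep, lengths(fams)), label = unlist(fams, use.names = FALSE))
}

# Shared cell computation: samples x (feature, genus) cell sums, cells sorted
# by feature then genus. Both the function profile and the long
# function-by-taxon table are marginals of this one object, which enforces an
# identical floating-point summation order for the conservation identity.
.ftm_cells <- function(tpm, annotations, scheme) {
  idx <- match(colnames(tpm), annotations$gene_id)
  if (anyNA(idx)) ftx_format_error("TPM matrix contains genes absent from annotations")
  map <- .function_gene_map(annotations, idx, scheme)
  genus <- annotations$genus[idx]
  genus[genus == .UNASSIGNED] <- .UNASSIGNED
  if (!length(map$gene)) {
    return(list(cells = matrix(0, nrow(tpm), 0L, dimnames = list(rownames(tpm), NULL)),
                feature = character(), genus = character()))
  }
  g <- genus[map$gene]
  key <- paste(map$label, g, sep = "\r")
  ord <- order(map$label, g, map$gene)
  sub <- tpm[, map$gene[ord], drop = FALSE]
  cells <- t(rowsum(t(sub), key[ord], reorder = TRUE))
  parts <- strsplit(colnames(cells), "\r", fixed = TRUE)
  list(cells = cells,
       feature = vapply(parts, `[`, "", 1L),
       genus = vapply(parts, `[`, "", 2L))
}

#' Aggregate TPM to a functional scheme
#'
#' Schemes: `"KO"` (single best KEGG Ortholog per gene), `"CAZy_family"`
#' (a multi-family gene contributes its full TPM to each family),
#' `"CAZy_class"` (families collapsed to GH/GT/PL/CE/CBM/AA; a gene counts
#' once per distinct class), `"hydrogenase_category"` and
#' `"hydrogenase_group"`. Profiles keep raw aggregated TPM; they are not
#' renormalized to the annotated fraction.
#'
#' @inheritParams aggregate_by_taxon
#' @param scheme Functional scheme name.
#' @return Samples x features matrix with attribute `rank_or_scheme`.
#' @export
aggregate_by_function <- function(tpm, annotations, scheme) {
  parts <- .ftm_cells(tpm, annotations, scheme)
  if (!ncol(parts$cells)) {
    out <- matrix(0, nrow(tpm), 0L, dimnames = list(rownames(tpm), character()))
  } else {
    out <- t(rowsum(t(parts$cells), parts$feature, reorder = TRUE))
  }
  attr(out, "rank_or_scheme") <- scheme
  out
}

#' Build a function-by-taxon abundance matrix
#'
#' Long-format table of TPM summed over genes sharing a (functional feature,
#' genus) pair. Genes lacking a genus assignment are booked under the genus
#' `"unassigned"` so that the genus marginal of this table reproduces the
#' function profile exactly.
#'
#' @inheritParams aggregate_by_function
#' @return A `data.frame` of class `"function_taxon_matrix"` with columns
#'   `feature_id`, `genus`, `sample_id`, `tpm`, sorted by feature, genus,
#'   sample.
#' @export
build_function_taxon_matrix <- function(tpm, annotations, scheme) {
  parts <- .ftm_cells(tpm, annotations, scheme)
  n_s <- nrow(tpm)
  out <- data.frame(
    feature_id = rep(parts$feature, each = n_s),
    genus = rep(parts$genus, each = n_s),
    sample_id = rep(rownames(tpm), times = length(parts$feature)),
    tpm = as.vector(parts$cells),
    stringsAsFactors = FALSE)
  attr(out, "rank_or_scheme") <- scheme
  class(out) <- c("function_taxon_matrix", "data.frame")
  out
}

#' Pool rare features into "Others" for display
#'
#' A feature is retained if its within-sample relative abundance reaches
#' `min_frac` in at least one sample; all other features are summed into an
#' `"Others"` column. Per-sample totals are unchanged and the operation is
#' idempotent at a fixed threshold (an existing `"Others"` column is treated
#' as the pooled bucket and merged, never re-tested).
#'
#' @param profile Samples x features abundance matrix.
#' @param min_frac Retention threshold as a fraction in (0, 1).
#' @return Pooled samples x features matrix.
#' @export
pool_for_display <- function(profile, min_frac) {
  if (!is.numeric(min_frac) || length(min_frac) != 1L ||
      !(min_frac > 0 && min_frac < 1)) {
    ftx_usage_error("min_frac must be a single value in (0, 1)")
  }
  if (!ncol(profile)) return(profile)
  tot <- rowSums(profile)
  if (any(tot <= 0)) {
    ftx_format_error(sprintf("sample '%s' has zero total abundance",
                             rownames(profile)[tot <= 0][1]))
  }
  feats <- colnames(profile)
  is_others <- feats == "Others"
  rel <- profile / tot
  keep <- apply(rel >= min_frac, 2L, any) & !is_others
  pooled <- rowSums(profile[, !keep, drop = FALSE])
  out <- profile[, keep, drop = FALSE]
  if (any(!keep)) {
    out <- cbind(out, Others = pooled)
  }
  attr(out, "rank_or_scheme") <- attr(profile, "rank_or_scheme")
  out
}
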