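# Readers, writers and configuration for the pipeline's TSV interchange
# formats. Dialect: tab-separated, UTF-8, mandatory header, "." or the empty
# string marks a missing value, ";" separates multiple CAZy families within
# one cell.

.read_tsv <- function(path) {
  if (!file.exists(path)) ftx_io_error(sprintf("file not found: %s", path))
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL, stringsAsFactors = FALSE)
}

.blank_to_na <- function(x) {
  x[x == "." | x == ""] <- NA_character_
  x
}

#' Analysis configuration
#'
#' Bundles the tunable thresholds shared by the profiling, testing and
#' attribution stages. Defaults follow the conventions of the study design
#' this pipeline targets: taxa are displayed individually when they reach 1%
#' relative abundance at the phylum level or 0.1% at the genus level in at
#' least one sample; features are called significant at `P < 0.05` and
#' reported as trends at `0.05 <= P < 0.10`; genera contributing less than
#' 20% of a feature's total change are pooled, at most the top five genera
#' per enrichment direction are retained, and contributions of at least 3%
#' are flagged for labelling.
#'
#' @param phylum_min_frac Display threshold for phylum-level pooling (fraction).
#' @param genus_min_frac Display threshold for genus-level pooling (fraction).
#' @param sig_alpha Significance level for the "significant" tier.
#' @param trend_alpha Upper bound for the "trend" tier.
#' @param pool_threshold Attribution pooling threshold (fraction of total change).
#' @param top_k Maximum number of named genera retained per direction.
#' @param label_threshold Labelling threshold for retained contributions (fraction).
#' @param n_perm Number of permutations for the community tests.
#' @param seed Integer seed controlling every randomized stage.
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(phylum_min_frac = 0.01, genus_min_frac = 0.001,
                            sig_alpha = 0.05, trend_alpha = 0.10,
                            pool_threshold = 0.20, top_k = 5,
                            label_threshold = 0.03, n_perm = 999, seed = 1) {
  cfg <- list(phylum_min_frac = phylum_min_frac,
              genus_min_frac = genus_min_frac,
              sig_alpha = sig_alpha, trend_alpha = trend_alpha,
              pool_threshold = pool_threshold, top_k = as.integer(top_k),
              label_threshold = label_threshold,
              n_perm = as.integer(n_perm), seed = as.integer(seed))
  if (!(cfg$sig_alpha > 0 && cfg$sig_alpha < cfg$trend_alpha &&
        cfg$trend_alpha < 1)) {
    ftx_usage_error("require 0 < sig_alpha < trend_alpha < 1")
  }
  for (nm in c("phylum_min_frac", "genus_min_frac", "pool_threshold",
               "label_threshold")) {
    if (!(cfg[[nm]] > 0 && cfg[[nm]] < 1)) {
      ftx_usage_error(sprintf("%s must lie in (0, 1)", nm))
    }
  }
  if (cfg$top_k < 1L) ftx_usage_error("top_k must be >= 1")
  if (cfg$n_perm < 99L) ftx_usage_error("permutations must be >= 99")
  structure(cfg, class = "analysis_config")
}

#' Read a flat `key = value` configuration file
#'
#' Lines are `key = value` pairs (`:` also accepted); `#` starts a comment.
#' Keys must match the fields of [analysis_config()]; unknown keys are
#' rejected so typos do not silently fall back to defaults.
#'
#' @param path Path to the configuration file.
#' @return An `analysis_config` with the file's overrides applied.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) ftx_io_error(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:]\\s*(.+)$", lines[i]))[[1]]
    if (length(m) != 3L) {
      ftx_format_error(sprintf("config line %d is not 'key = value': '%s'", i, lines[i]))
    }
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[m[2]]] <- if (is.na(num)) val else num
  }
  known <- names(formals(analysis_config))
  bad <- setdiff(names(out), known)
  if (length(bad)) {
    ftx_format_error(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  do.call(analysis_config, out)
}

#' Read a gene annotation table
#'
#' Expects a TSV with columns `gene_id`, `length_bp`, the six lineage ranks
#' `domain`, `phylum`, `class`, `order`, `family`, `genus`, and optionally
#' `ko` (single best KEGG Ortholog), `cazy_families` (semicolon-delimited
#' CAZy family labels from the classes GH/GT/PL/CE/CBM/AA),
#' `hydrogenase_group` and `hydrogenase_category`. Missing cells are `.` or
#' empty; an unassigned lineage rank is written `unassigned` (or left
#' missing). Lineages must be prefixes: a rank may be unassigned only if all
#' finer ranks are too.
#'
#' @param path Path to the annotation TSV.
#' @return A `data.frame` of class `"gene_annotation"`, one row per gene, in
#'   file order.
#' @export
read_gene_annotations <- function(path) {
  df <- .read_tsv(path)
  required <- c("gene_id", "length_bp", .RANKS)
  for (col in required) {
    if (!col %in% names(df)) {
      ftx_format_error(sprintf("annotation file is missing required column '%s'", col))
    }
  }
  ann <- data.frame(gene_id = df$gene_id, stringsAsFactors = FALSE)
  dup <- duplicated(ann$gene_id)
  if (any(dup)) {
    ftx_format_error(sprintf("duplicate gene_id '%s' at row %d",
                             ann$gene_id[dup][1], which(dup)[1]))
  }
  len <- suppressWarnings(as.numeric(df$length_bp))
  bad <- which(is.na(len) | !is_wholenumber(len) | len < 1)
  if (length(bad)) {
    ftx_format_error(sprintf(
      "length_bp must be a positive integer: row %d (gene '%s') has '%s'",
      bad[1], ann$gene_id[bad[1]], df$length_bp[bad[1]]))
  }
  ann$length_bp <- as.integer(round(len))

  for (r in .RANKS) {
    v <- .blank_to_na(df[[r]])
    v[is.na(v)] <- .UNASSIGNED
    ann[[r]] <- v
  }
  assigned <- ann[.RANKS] != .UNASSIGNED
  # prefix rule: once a rank is unassigned, all finer ranks must be too
  viol <- which(apply(assigned, 1L, function(a) any(!a[-length(a)] & a[-1]) ||
                        (!a[1] && any(a[-1]))))
  if (length(viol)) {
    ftx_format_error(sprintf(
      "row %d (gene '%s'): lineage has an assigned rank below an unassigned one",
      viol[1], ann$gene_id[viol[1]]))
  }

  ko <- if ("ko" %in% names(df)) .blank_to_na(df$ko) else rep(NA_character_, nrow(ann))
  multi <- which(grepl(";", ko))
  if (length(multi)) {
    ftx_format_error(sprintf(
      "row %d (gene '%s'): multiple KOs in one cell; the schema keeps a single best hit",
      multi[1], ann$gene_id[multi[1]]))
  }
  ann$ko <- ko

  caz <- if ("cazy_families" %in% names(df)) .blank_to_na(df$cazy_families) else rep(NA_character_, nrow(ann))
  for (i in which(!is.na(caz))) {
    fams <- unique(trimws(strsplit(caz[i], ";", fixed = TRUE)[[1]]))
    fams <- fams[nzchar(fams)]
    ok <- grepl("^(GH|GT|PL|CE|CBM|AA)[0-9]+$", fams)
    if (!all(ok)) {
      ftx_format_error(sprintf(
        "row %d (gene '%s'): unknown CAZy family label '%s' (classes are %s)",
        i, ann$gene_id[i], fams[!ok][1], paste(.CAZY_CLASSES, collapse = "/")))
    }
    caz[i] <- paste(fams, collapse = ";")
  }
  ann$cazy_families <- caz

  hg <- if ("hydrogenase_group" %in% names(df)) .blank_to_na(df$hydrogenase_group) else rep(NA_character_, nrow(ann))
  hc <- if ("hydrogenase_category" %in% names(df)) .blank_to_na(df$hydrogenase_category) else rep(NA_character_, nrow(ann))
  badg <- which(!is.na(hg) & !hg %in% .HYD_GROUPS)
  if (length(badg)) {
    ftx_format_error(sprintf("row %d: unknown hydrogenase group '%s'",
                             badg[1], hg[badg[1]]))
  }
  badc <- which(!is.na(hc) & !hc %in% .HYD_CATEGORIES)
  if (length(badc)) {
    ftx_format_error(sprintf("row %d: unknown hydrogenase category '%s'",
                             badc[1], hc[badc[1]]))
  }
  ann$hydrogenase_group <- hg
  ann$hydrogenase_category <- hc
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Read a per-sample gene count matrix
#'
#' TSV with first column `gene_id` and one column of non-negative integer
#' mapped-read counts per sample. Returned oriented samples x genes (rows are
#' samples) as used throughout the package.
#'
#' @param path Path to the counts TSV.
#' @return Numeric matrix, samples x genes, with dimnames.
#' @export
read_counts <- function(path) {
  df <- .read_tsv(path)
  if (names(df)[1] != "gene_id") {
    ftx_format_error("counts file must have 'gene_id' as its first column")
  }
  if (ncol(df) < 2L) ftx_format_error("counts file has no sample columns")
  genes <- df$gene_id
  dup <- duplicated(genes)
  if (any(dup)) {
    ftx_format_error(sprintf("duplicate gene_id '%s' at row %d",
                             genes[dup][1], which(dup)[1]))
  }
  samples <- names(df)[-1]
  if (anyDuplicated(samples)) ftx_format_error("duplicate sample column names")
  m <- matrix(NA_real_, nrow = length(samples), ncol = length(genes),
              dimnames = list(samples, genes))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) | !is_wholenumber(v) | v < 0)
    if (length(bad)) {
      ftx_format_error(sprintf(
        "counts must be non-negative integers: gene '%s', sample '%s' has '%s'",
        genes[bad[1]], samples[j], df[[j + 1L]][bad[1]]))
    }
    m[j, ] <- round(v)
  }
  m
}

#' Read a two-group sample design table
#'
#' TSV with columns `sample_id` and `group`. Exactly two distinct group
#' labels are required and, when `require_tests = TRUE`, each group must hold
#' at least two samples.
#'
#' @param path Path to the design TSV.
#' @param require_tests Enforce >= 2 samples per group (needed by every test
#'   in the pipeline).
#' @return A `data.frame` of class `"sample_design"` with attribute
#'   `group_sizes`.
#' @export
read_sample_design <- function(path, require_tests = TRUE) {
  df <- .read_tsv(path)
  for (col in c("sample_id", "group")) {
    if (!col %in% names(df)) {
      ftx_format_error(sprintf("design file is missing required column '%s'", col))
    }
  }
  design <- data.frame(sample_id = df$sample_id, group = df$group,
                       stringsAsFactors = FALSE)
  validate_design(design, require_tests = require_tests)
}

#' @rdname read_sample_design
#' @param design A data.frame with `sample_id` and `group` columns.
#' @export
validate_design <- function(design, require_tests = TRUE) {
  dup <- duplicated(design$sample_id)
  if (any(dup)) {
    ftx_design_error(sprintf("duplicated sample_id '%s'", design$sample_id[dup][1]))
  }
  sizes <- table(design$group)
  if (length(sizes) != 2L) {
    ftx_design_error(sprintf(
      "design must have exactly two groups, found %d (%s)",
      length(sizes), paste(names(sizes), collapse = ", ")))
  }
  if (require_tests && any(sizes < 2L)) {
    ftx_design_error(sprintf(
      "each group needs >= 2 samples for testing; group '%s' has %d",
      names(sizes)[which.min(sizes)], min(sizes)))
  }
  attr(design, "group_sizes") <- c(sizes)
  class(design) <- unique(c("sample_design", class(design)))
  design
}

# Which group plays the "positive" role in oriented differences
# (LFCR - HFCR when those labels are present, else first label in the file).
positive_group <- function(design, positive = NULL) {
  groups <- unique(design$group)
  if (!is.null(positive)) {
    if (!positive %in% groups) {
      ftx_design_error(sprintf("group '%s' not present in design", positive))
    }
    return(positive)
  }
  if ("LFCR" %in% groups) "LFCR" else groups[1]
}

#' Write a result table as TSV
#'
#' Deterministic serializer used for every tabular output: columns in the
#' order given, floating point values at a fixed significant-digit precision
#' (default 6), missing values written as `.`. Re-reading with
#' [read_results()] reproduces values to that precision, and identical
#' inputs always produce byte-identical files.
#'
#' @param table A data.frame (or matrix, written with an `id` column from its
#'   row names).
#' @param path Output path.
#' @param digits Significant digits for numeric columns.
#' @return Invisibly, `path`.
#' @export
write_results <- function(table, path, digits = 6) {
  if (is.matrix(table)) {
    table <- data.frame(id = rownames(table) %||% seq_len(nrow(table)),
                        table, check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(table)) ftx_usage_error("write_results expects a data.frame or matrix")
  out <- table
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (is.double(v)) {
      s <- formatC(v, digits = digits, format = "g")
      s[is.na(v)] <- "."
      out[[j]] <- s
    } else if (is.integer(v) || is.logical(v) || is.numeric(v)) {
      s <- as.character(v)
      s[is.na(v)] <- "."
      out[[j]] <- s
    } else {
      v <- as.character(v)
      v[is.na(v)] <- "."
      out[[j]] <- v
    }
  }
  ok <- tryCatch({
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(names(out), collapse = "\t"), con)
    if (nrow(out)) {
      writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
    }
    TRUE
  }, error = function(e) FALSE)
  if (!ok) ftx_io_error(sprintf("cannot write to '%s'", path))
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- .read_tsv(path)
  for (j in seq_along(df)) {
    v <- .blank_to_na(df[[j]])
    num <- suppressWarnings(as.numeric(v))
    if (all(is.na(num) == is.na(v))) {
      df[[j]] <- num
    } else {
      df[[j]] <- v
    }
  }
  df
}

# Profile matrices travel features-in-rows on disk (features x samples).
write_profile <- function(profile, path, digits = 6) {
  df <- data.frame(feature_id = colnames(profile) %||% seq_len(ncol(profile)),
                   t(profile), check.names = FALSE, stringsAsFactors = FALSE)
  write_results(df, path, digits = digits)
}

read_profile <- function(path) {
  df <- .read_tsv(path)
  feats <- df[[1]]
  m <- t(vapply(df[-1], function(col) suppressWarnings(as.numeric(col)),
                numeric(length(feats))))
  if (length(feats) == 1L) m <- matrix(m, ncol = 1L,
                                       dimnames = list(names(df)[-1], NULL))
  colnames(m) <- feats
  rownames(m) <- names(df)[-1]
  m
}

write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = colnames(counts), t(counts),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (j in 2:ncol(df)) df[[j]] <- as.integer(round(df[[j]]))
  write_results(df, path)
}
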