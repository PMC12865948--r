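# Small in-code fixtures shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A hand-written six-gene catalog exercising every annotation field.
tiny_annotations <- function() {
  df <- data.frame(
    gene_id = paste0("g", 1:6),
    length_bp = c(1000L, 2000L, 500L, 1500L, 800L, 1200L),
    domain = c("Bacteria", "Bacteria", "Bacteria", "Archaea", "Bacteria", "Bacteria"),
    phylum = c("P1", "P1", "P2", "P3", "P2", "unassigned"),
    class = c("C1", "C1", "C2", "C3", "C2", "unassigned"),
    order = c("O1", "O1", "O2", "O3", "O2", "unassigned"),
    family = c("F1", "F1", "F2", "F3", "F2", "unassigned"),
    genus = c("GenA", "GenA", "GenB", "GenC", "unassigned", "unassigned"),
    ko = c("K00001", "K00002", "K00001", NA, "K00003", NA),
    cazy_families = c("GH13;CBM27", NA, "GH13", "GT2", NA, "GH13;GH97"),
    hydrogenase_group = c(NA, "[FeFe]", NA, "[NiFe]", NA, NA),
    hydrogenase_category = c(NA, "fermentative", NA, "methanogenic", NA, NA),
    stringsAsFactors = FALSE)
  class(df) <- c("gene_annotation", "data.frame")
  df
}

# counts for the tiny catalog: 4 samples x 6 genes
tiny_counts <- function() {
  m <- rbind(s1 = c(10, 20, 5, 2, 8, 4),
             s2 = c(12, 18, 7, 1, 6, 5),
             s3 = c(30, 5, 15, 4, 2, 9),
             s4 = c(25, 8, 12, 3, 3, 7))
  colnames(m) <- paste0("g", 1:6)
  m
}

tiny_design <- function() {
  validate_design(data.frame(sample_id = paste0("s", 1:4),
                             group = c("LFCR", "LFCR", "HFCR", "HFCR"),
                             stringsAsFactors = FALSE))
}

make_design <- function(n1, n2, labels = c("LFCR", "HFCR")) {
  validate_design(data.frame(
    sample_id = c(sprintf("%s_%02d", labels[1], seq_len(n1)),
                  sprintf("%s_%02d", labels[2], seq_len(n2))),
    group = rep(labels, c(n1, n2)), stringsAsFactors = FALSE))
}

# write a data.frame as the package's TSV dialect
write_tsv_fixture <- function(df, path) {
  write_results(df, path)
  path
}

# random abundance matrix with sample rownames
random_profile <- function(n_samples, n_features, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rlnorm(n_samples * n_features), n_samples, n_features)
  rownames(m) <- sprintf("S%02d", seq_len(n_samples))
  colnames(m) <- sprintf("f%03d", seq_len(n_features))
  m
}

# full-enumeration oracle for the two-sided exact Wilcoxon P value:
# enumerate all C(n1+n2, n1) assignments of ranks to group 1.
oracle_exact_wilcoxon <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  sets <- utils::combn(n, n1)
  sums <- colSums(matrix(seq_len(n)[sets], nrow = n1))
  p_le <- mean(sums <= W)
  p_ge <- mean(sums >= W)
  min(1, 2 * min(p_le, p_ge))
}

expect_no_mismatch <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a - b)), tol)
}
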