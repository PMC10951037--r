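# Fixture builders: everything is constructed in code at test time.

# A minimal dataset: n_genes x (donors x structures), iid log-normal
# values, one cerebellar structure per donor. All genes exchangeable.
make_null_dataset <- function(n_genes = 20, n_donors = 4, n_other = 5,
                              seed = 1, meanlog = 0, sdlog = 1,
                              age_labels = NULL) {
  set.seed(seed)
  if (is.null(age_labels)) {
    age_labels <- paste(sample(c(8:38, 1:40), n_donors, replace = TRUE),
                        sample(c("pcw", "yrs"), n_donors, replace = TRUE))
  }
  donors <- sprintf("d%02d", seq_len(n_donors))
  columns <- do.call(rbind, lapply(seq_len(n_donors), function(d) {
    data.frame(donor_id = donors[d], age = age_labels[d],
               structure_acronym = c("CBC", sprintf("R%02d", seq_len(n_other))),
               stringsAsFactors = FALSE)
  }))
  values <- matrix(exp(rnorm(n_genes * nrow(columns), meanlog, sdlog)),
                   n_genes, nrow(columns))
  genes <- data.frame(gene_id = sprintf("g%04d", seq_len(n_genes)),
                      gene_symbol = sprintf("S%04d", seq_len(n_genes)),
                      stringsAsFactors = FALSE)
  relx_dataset(values, genes, columns)
}

# Hand-build a relz_matrix around a given z matrix (genes x donors).
make_relz <- function(z, ages_days = NULL) {
  donors <- colnames(z)
  if (is.null(donors)) {
    donors <- sprintf("d%02d", seq_len(ncol(z)))
    colnames(z) <- donors
  }
  if (is.null(ages_days)) ages_days <- seq(100, 5000, length.out = ncol(z))
  structure(list(
    z = z,
    n_other = matrix(10L, nrow(z), ncol(z), dimnames = dimnames(z)),
    specimens = data.frame(
      donor_id = donors,
      age = paste(seq_len(ncol(z)), "yrs"),
      days_post_conception = ages_days,
      is_prenatal = ages_days < 280,
      has_cerebellum = TRUE,
      n_other_regions = 10L,
      stringsAsFactors = FALSE),
    n_degenerate = 0L, log_transform = FALSE), class = "relz_matrix")
}

# Write a BrainSpan-dialect triplet from raw pieces (for reader tests).
write_triplet <- function(dir, values, genes, columns) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat <- cbind(seq_len(nrow(values)), values)
  write.table(mat, file.path(dir, "expression_matrix.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  write.csv(genes, file.path(dir, "rows_metadata.csv"), row.names = FALSE)
  write.csv(columns, file.path(dir, "columns_metadata.csv"), row.names = FALSE)
  file.path(dir, c("expression_matrix.csv", "rows_metadata.csv",
                   "columns_metadata.csv"))
}
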