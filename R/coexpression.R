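# Co-expression gene sets relative to the target's z profile. Two
# filters are applied in order before correlating: (1) genes whose mean
# RPKM across all samples falls strictly below the dataset's 25th
# percentile are dropped (near-silent genes cannot show differential
# regional expression and only dilute the multiple-testing correction);
# (2) genes with too many missing z-scores across the included
# specimens are dropped (their correlations would rest on too few
# pairs).

#' Expression and missingness gene filters
#'
#' Applies, in order: the lowest-quartile filter on per-gene mean RPKM
#' over all samples (strictly below the linear-interpolation 25th
#' percentile), then the missingness filter (more than `max_missing_z`
#' missing z cells across the specimens).
#'
#' @param ds the [relx_dataset()] the z matrix was computed from.
#' @param zm the matching [relative_z()] result.
#' @param max_missing_z maximum tolerated missing z cells per gene
#'   (default 5; with 30 specimens this is the "at least 25 z-scores"
#'   rule).
#' @return List with `retained_genes` (character) and `report` (one-row
#'   data frame: `n_input`, `quartile_threshold`,
#'   `n_low_expression_dropped`, `n_missingness_dropped`, `n_retained`).
#' @export
filter_genes <- function(ds, zm, max_missing_z = 5L) {
  stopifnot(inherits(ds, "relx_dataset"), inherits(zm, "relz_matrix"))
  mean_rpkm <- rowMeans(ds$values)
  thr <- quantile(mean_rpkm, 0.25, type = 7, names = FALSE)
  pass_expr <- mean_rpkm >= thr
  n_missing <- rowSums(is.na(zm$z[ds$genes$gene_id, , drop = FALSE]))
  pass_miss <- n_missing <= max_missing_z
  retained <- ds$genes$gene_id[pass_expr & pass_miss]
  report <- data.frame(
    n_input = nrow(ds$values),
    quartile_threshold = thr,
    n_low_expression_dropped = sum(!pass_expr),
    n_missingness_dropped = sum(pass_expr & !pass_miss),
    n_retained = length(retained))
  list(retained_genes = retained, report = report)
}

#' Correlate every gene's z profile with the target's
#'
#' Pairwise-complete Pearson correlation between each retained gene's
#' z-score profile (across specimens) and the target gene's, with a
#' two-sided t-based p-value. Genes with fewer than `min_pairs` complete
#' pairs get missing `r` and `p`.
#'
#' @param zm a [relative_z()] result.
#' @param target_gene gene id with a z profile in `zm`.
#' @param retained_genes genes to correlate (the target itself is
#'   skipped); default all genes in `zm`.
#' @param min_pairs minimum complete pairs (default 3).
#' @return Data frame `gene`, `n_pairs`, `r`, `p`.
#' @export
correlate_all <- function(zm, target_gene,
                          retained_genes = rownames(zm$z),
                          min_pairs = 3L) {
  stopifnot(inherits(zm, "relz_matrix"))
  if (!target_gene %in% rownames(zm$z)) {
    stop("target gene ", sQuote(target_gene), " not in z matrix",
         call. = FALSE)
  }
  genes <- setdiff(retained_genes, target_gene)
  missing <- setdiff(genes, rownames(zm$z))
  if (length(missing)) {
    stop("retained gene(s) absent from z matrix: ",
         paste(head(missing, 3L), collapse = ", "),
         if (length(missing) > 3L) ", ...", call. = FALSE)
  }
  tz <- zm$z[target_gene, ]
  zt <- t(zm$z[genes, , drop = FALSE])          # specimens x genes
  n_pairs <- colSums(!is.na(zt) & !is.na(tz))
  r <- suppressWarnings(as.vector(cor(zt, tz, use = "pairwise.complete.obs")))
  r[n_pairs < min_pairs] <- NA_real_
  tstat <- r * sqrt(pmax(n_pairs - 2, 0)) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * pt(-abs(tstat), df = n_pairs - 2)
  data.frame(gene = genes, n_pairs = as.integer(n_pairs), r = r, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Threshold a correlation table into gene sets
#'
#' Strict-inequality membership: positive set `r > upper`, negative set
#' `r < lower`; genes with missing `r` belong to neither.
#'
#' @param ct data frame from [correlate_all()].
#' @param upper,lower correlation thresholds (defaults 0.6 and -0.6).
#' @return List of class `gene_set_pair`: `positive`, `negative`
#'   (character vectors) and `thresholds`.
#' @export
build_sets <- function(ct, upper = 0.6, lower = -0.6) {
  stopifnot(is.data.frame(ct), all(c("gene", "r") %in% names(ct)))
  ok <- !is.na(ct$r)
  structure(list(positive = ct$gene[ok & ct$r > upper],
                 negative = ct$gene[ok & ct$r < lower],
                 thresholds = c(upper = upper, lower = lower)),
            class = "gene_set_pair")
}

#' @export
print.gene_set_pair <- function(x, ...) {
  cat("gene_set_pair: ", length(x$positive), " positive (r > ",
      x$thresholds[["upper"]], "), ", length(x$negative),
      " negative (r < ", x$thresholds[["lower"]], ")\n", sep = "")
  invisible(x)
}

#' Write a gene-set pair to disk
#'
#' One-gene-per-line text files plus a 2-entry GMT.
#' @param sets a [build_sets()] result.
#' @param dir output directory.
#' @param prefix file-name prefix (default `"target"`).
#' @return Invisibly, the paths written.
#' @export
write_gene_sets <- function(sets, dir, prefix = "target") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pos <- file.path(dir, paste0(prefix, "_positive.txt"))
  neg <- file.path(dir, paste0(prefix, "_negative.txt"))
  gmt <- file.path(dir, paste0(prefix, "_sets.gmt"))
  writeLines(sets$positive, pos)
  writeLines(sets$negative, neg)
  writeLines(c(paste(c(paste0(prefix, "_positive"),
                       "positively correlated genes", sets$positive),
                     collapse = "\t"),
               paste(c(paste0(prefix, "_negative"),
                       "negatively correlated genes", sets$negative),
                     collapse = "\t")), con = gmt)
  invisible(c(pos, neg, gmt))
}
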