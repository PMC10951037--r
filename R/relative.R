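# Region-relative z-scores: for each gene and specimen, the cerebellar
# RPKM is expressed in standard-deviation units of that specimen's
# non-cerebellar regional values. Degenerate cells (no cerebellar
# sample, fewer than 2 other regions, or zero spread across them)
# become missing rather than 0 or +/-Inf, so downstream correlations
# are not biased by sentinel values.

#' Drop genes never expressed anywhere
#'
#' Removes genes whose value is zero in every region of every specimen;
#' such genes carry no signal for any relative-expression contrast.
#'
#' @param ds a [relx_dataset()].
#' @return A list with `kept` (the restricted dataset) and
#'   `dropped_genes` (character vector of gene ids).
#' @export
drop_never_expressed <- function(ds) {
  stopifnot(inherits(ds, "relx_dataset"))
  expressed <- rowSums(ds$values > 0) > 0L
  kept <- relx_dataset(ds$values[expressed, , drop = FALSE],
                       ds$genes[expressed, , drop = FALSE],
                       ds$columns[, setdiff(names(ds$columns), "is_cerebellar"),
                                  drop = FALSE],
                       cerebellar_labels = ds$cerebellar_labels)
  list(kept = kept, dropped_genes = ds$genes$gene_id[!expressed])
}

#' Cerebellar-vs-rest z-score matrix
#'
#' For each gene g and specimen s with cerebellar value c and
#' non-cerebellar values x1..xk (k >= 2, sd > 0):
#' `z = (c - mean(x)) / sd(x)` with the sample standard deviation
#' (divisor k - 1). Cells that do not meet the conditions are missing.
#'
#' @param ds a [relx_dataset()], normally the `included` part of
#'   [select_specimens()].
#' @param log_transform if `TRUE`, values are `log2(x + 1)`-transformed
#'   before z-scoring (default `FALSE`: RPKM is z-scored directly).
#' @return An object of class `relz_matrix`: list with `z` (genes x
#'   donors matrix, NA = missing), `n_other` (integer matrix of
#'   non-cerebellar regions used per cell), `specimens` (donor metadata
#'   as in the dataset) and `n_degenerate` (count of cells missing due
#'   to zero spread).
#' @export
relative_z <- function(ds, log_transform = FALSE) {
  stopifnot(inherits(ds, "relx_dataset"))
  vals <- ds$values
  if (log_transform) vals <- log2(vals + 1)
  sp <- ds$specimens
  donors <- sp$donor_id
  n_gene <- nrow(vals)
  z <- matrix(NA_real_, n_gene, length(donors),
              dimnames = list(rownames(vals), donors))
  n_other <- matrix(0L, n_gene, length(donors),
                    dimnames = dimnames(z))
  n_degenerate <- 0L
  for (j in seq_along(donors)) {
    cb_col <- which(ds$columns$donor_id == donors[j] & ds$columns$is_cerebellar)
    ot_col <- which(ds$columns$donor_id == donors[j] & !ds$columns$is_cerebellar)
    k <- length(ot_col)
    if (length(cb_col) != 1L || k < 2L) next
    x <- vals[, ot_col, drop = FALSE]
    m <- rowMeans(x)
    s <- sqrt(rowSums((x - m)^2) / (k - 1L))
    ok <- s > 0
    n_degenerate <- n_degenerate + sum(!ok)
    z[ok, j] <- (vals[ok, cb_col] - m[ok]) / s[ok]
    n_other[, j] <- k
  }
  structure(list(z = z, n_other = n_other, specimens = sp,
                 n_degenerate = n_degenerate,
                 log_transform = log_transform),
            class = "relz_matrix")
}

#' @export
print.relz_matrix <- function(x, ...) {
  cat("relz_matrix: ", nrow(x$z), " genes x ", ncol(x$z), " specimens; ",
      sum(is.na(x$z)), " missing cells (", x$n_degenerate,
      " degenerate sd = 0)\n", sep = "")
  invisible(x)
}

#' Write a z-score matrix as TSV
#'
#' Genes x donors, missing cells as empty fields.
#' @param zm a [relative_z()] result.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_relz <- function(zm, path) {
  dt <- data.table::as.data.table(zm$z, keep.rownames = "gene")
  data.table::fwrite(dt, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Benchmark a target gene against the genome-wide z distribution
#'
#' Per specimen, ranks the target gene's z-score within the distribution
#' of all genes' z-scores for that specimen. The centile is the midrank
#' of the target within the pooled sample of background plus target:
#' `100 * (#below + 0.5 * #ties + 0.5) / (n_background + 1)`, so a
#' target above all of 99 background values sits at the 99.5th centile
#' and a target tied with every background value at the 50th. Background
#' quantiles use linear interpolation (type 7).
#'
#' @param zm a [relative_z()] result.
#' @param target_gene gene id present in `zm` (use [resolve_gene()] for
#'   symbols).
#' @param exclude_target if `TRUE` (default) the target gene is not part
#'   of its own background.
#' @return A data frame of class `centile_report`, one row per specimen
#'   with non-missing target z: `donor_id`, `age`,
#'   `days_post_conception`, `target_z`, `centile`,
#'   `n_background_genes`, background quantiles `q05`, `q25`, `q50`,
#'   `q75`, `q95`.
#' @export
centile_benchmark <- function(zm, target_gene, exclude_target = TRUE) {
  stopifnot(inherits(zm, "relz_matrix"))
  if (!target_gene %in% rownames(zm$z)) {
    stop("target gene ", sQuote(target_gene), " not in z matrix",
         call. = FALSE)
  }
  tz <- zm$z[target_gene, ]
  bg_all <- if (exclude_target) {
    zm$z[setdiff(rownames(zm$z), target_gene), , drop = FALSE]
  } else zm$z
  out <- lapply(which(!is.na(tz)), function(j) {
    bg <- bg_all[, j]
    bg <- bg[!is.na(bg)]
    if (!length(bg)) return(NULL)
    n_below <- sum(bg < tz[j])
    n_tie <- sum(bg == tz[j])
    centile <- 100 * (n_below + 0.5 * n_tie + 0.5) / (length(bg) + 1)
    q <- quantile(bg, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7, names = FALSE)
    data.frame(donor_id = zm$specimens$donor_id[j],
               age = zm$specimens$age[j],
               days_post_conception = zm$specimens$days_post_conception[j],
               target_z = tz[j], centile = centile,
               n_background_genes = length(bg),
               q05 = q[1], q25 = q[2], q50 = q[3], q75 = q[4], q95 = q[5],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("centile_report", "data.frame")
  out
}
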