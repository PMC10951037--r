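# Data model: an expression dataset is a genes x columns RPKM matrix
# where each column is one (donor, structure) sample, plus gene and
# column metadata. Absent samples are absent columns (never zeros):
# zeros are real measurements and would corrupt downstream z-score
# denominators if used as fill-in.

#' Cerebellar structure acronyms
#'
#' Default set of structure acronyms treated as cerebellar: `CB` (whole
#' cerebellum, used for early fetal specimens) and `CBC` (cerebellar
#' cortex). Overridable in every function that takes `cerebellar_labels`.
#' @export
cerebellar_labels_default <- c("CB", "CBC")

#' Construct an expression dataset
#'
#' Assembles the pipeline's central container from an RPKM matrix and
#' its metadata. Values must be non-negative; a structure can appear at
#' most once per donor; at most one cerebellar structure per donor.
#'
#' @param values numeric matrix, genes x samples, RPKM.
#' @param genes data frame with at least a `gene_id` column (unique);
#'   an optional `gene_symbol` column is used for symbol lookups.
#' @param columns data frame with columns `donor_id`, `age` (dialect
#'   label, see [parse_age()]) and `structure_acronym`, one row per
#'   matrix column.
#' @param cerebellar_labels acronyms counted as cerebellar.
#' @return An object of class `relx_dataset`: a list with elements
#'   `values`, `genes`, `columns` (with an added `is_cerebellar` flag)
#'   and `specimens` (one row per donor: `donor_id`, `age`,
#'   `days_post_conception`, `is_prenatal`, `has_cerebellum`,
#'   `n_other_regions`).
#' @export
relx_dataset <- function(values, genes, columns,
                         cerebellar_labels = cerebellar_labels_default) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != nrow(genes)) {
    stop("matrix has ", nrow(values), " rows but gene metadata has ",
         nrow(genes), call. = FALSE)
  }
  if (ncol(values) != nrow(columns)) {
    stop("matrix has ", ncol(values), " data columns but column metadata has ",
         nrow(columns), " rows", call. = FALSE)
  }
  if (anyNA(values) || any(values < 0)) {
    stop("RPKM values must be non-negative and present (absent samples are ",
         "absent columns, not NA cells)", call. = FALSE)
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene ids in gene metadata", call. = FALSE)
  }
  key <- paste(columns$donor_id, columns$structure_acronym, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (donor, structure) columns: ",
         paste(unique(sub("\r", "/", key[duplicated(key)])), collapse = ", "),
         call. = FALSE)
  }
  columns$is_cerebellar <- columns$structure_acronym %in% cerebellar_labels
  n_cb <- tapply(columns$is_cerebellar, columns$donor_id, sum)
  if (any(n_cb > 1L)) {
    stop("more than one cerebellar structure for donor(s): ",
         paste(names(n_cb)[n_cb > 1L], collapse = ", "), call. = FALSE)
  }
  rownames(values) <- genes$gene_id
  donors <- unique(columns$donor_id)
  idx <- match(donors, columns$donor_id)
  age <- parse_age(columns$age[idx])
  specimens <- data.frame(
    donor_id = donors,
    age = age$raw_label,
    days_post_conception = age$days_post_conception,
    is_prenatal = age$is_prenatal,
    has_cerebellum = as.logical(n_cb[donors] > 0L),
    n_other_regions = as.integer(
      tapply(!columns$is_cerebellar, columns$donor_id, sum)[donors]),
    stringsAsFactors = FALSE
  )
  structure(list(values = values, genes = genes, columns = columns,
                 specimens = specimens,
                 cerebellar_labels = cerebellar_labels),
            class = "relx_dataset")
}

#' @export
print.relx_dataset <- function(x, ...) {
  cat("relx_dataset: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", nrow(x$specimens), " donors)\n", sep = "")
  cat("  donors with cerebellar sample: ",
      sum(x$specimens$has_cerebellum), "\n", sep = "")
  cat("  age range: ", x$specimens$age[which.min(x$specimens$days_post_conception)],
      " to ", x$specimens$age[which.max(x$specimens$days_post_conception)],
      "\n", sep = "")
  invisible(x)
}

pick_col <- function(df, candidates, what, file) {
  hit <- intersect(candidates, names(df))
  if (!length(hit)) {
    stop("cannot find a ", what, " column in ", file,
         " (looked for: ", paste(candidates, collapse = ", "), ")",
         call. = FALSE)
  }
  hit[[1L]]
}

#' Read a BrainSpan-style expression triplet
#'
#' Loads the three-file dialect used by the BrainSpan "summarised to
#' genes" downloads: a header-less `expression_matrix.csv` whose first
#' field is the row number, a `rows_metadata.csv` describing genes and a
#' `columns_metadata.csv` describing (donor, structure) samples.
#'
#' Gene ids are taken from the first of `ensembl_gene_id`, `gene_id`,
#' `gene_symbol` that exists and is duplicate-free; `gene_symbol` (when
#' present) is kept for symbol lookups.
#'
#' @param matrix_path,rows_meta_path,columns_meta_path file paths.
#' @param cerebellar_labels acronyms counted as cerebellar.
#' @return A [relx_dataset()].
#' @export
read_brainspan <- function(matrix_path, rows_meta_path, columns_meta_path,
                           cerebellar_labels = cerebellar_labels_default) {
  for (p in c(matrix_path, rows_meta_path, columns_meta_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  mat <- data.table::fread(matrix_path, header = FALSE, sep = ",",
                           data.table = FALSE)
  rows <- data.table::fread(rows_meta_path, header = TRUE, sep = ",",
                            data.table = FALSE)
  cols <- data.table::fread(columns_meta_path, header = TRUE, sep = ",",
                            data.table = FALSE)

  values <- as.matrix(mat[, -1L, drop = FALSE])
  if (ncol(values) != nrow(cols)) {
    stop(matrix_path, ": ", ncol(values), " data columns but ",
         columns_meta_path, " describes ", nrow(cols), call. = FALSE)
  }
  if (nrow(values) != nrow(rows)) {
    stop(matrix_path, ": ", nrow(values), " rows but ", rows_meta_path,
         " describes ", nrow(rows), call. = FALSE)
  }
  if (anyNA(values) || any(values < 0)) {
    i <- which(is.na(values) | values < 0, arr.ind = TRUE)[1L, ]
    stop(matrix_path, ": negative or missing RPKM at matrix row ", i[1L],
         ", data column ", i[2L], call. = FALSE)
  }

  id_col <- NULL
  for (cand in c("ensembl_gene_id", "gene_id", "gene_symbol")) {
    if (cand %in% names(rows) && !anyDuplicated(rows[[cand]])) {
      id_col <- cand
      break
    }
  }
  if (is.null(id_col)) {
    stop(rows_meta_path, ": no duplicate-free gene identifier column ",
         "(ensembl_gene_id / gene_id / gene_symbol)", call. = FALSE)
  }
  genes <- data.frame(gene_id = as.character(rows[[id_col]]),
                      stringsAsFactors = FALSE)
  genes$gene_symbol <- if ("gene_symbol" %in% names(rows)) {
    as.character(rows$gene_symbol)
  } else genes$gene_id

  columns <- data.frame(
    donor_id = as.character(cols[[pick_col(cols, c("donor_id", "donor_name"),
                                           "donor id", columns_meta_path)]]),
    age = as.character(cols[[pick_col(cols, "age", "age", columns_meta_path)]]),
    structure_acronym = as.character(
      cols[[pick_col(cols, c("structure_acronym", "structure"),
                     "structure acronym", columns_meta_path)]]),
    stringsAsFactors = FALSE
  )
  relx_dataset(values, genes, columns, cerebellar_labels = cerebellar_labels)
}

#' Write a dataset back to the three-file dialect
#'
#' Emits `expression_matrix.csv`, `rows_metadata.csv` and
#' `columns_metadata.csv` under `dir`, such that [read_brainspan()] on
#' the result round-trips values and metadata.
#'
#' @param ds a [relx_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_brainspan <- function(ds, dir) {
  stopifnot(inherits(ds, "relx_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("expression_matrix.csv", "rows_metadata.csv",
                            "columns_metadata.csv"))
  # shortest decimal representation that parses back to the same double
  num_to_str <- function(x) {
    s <- sprintf("%.15g", x)
    bad <- as.numeric(s) != x
    if (any(bad)) s[bad] <- sprintf("%.17g", x[bad])
    s
  }
  sm <- matrix(num_to_str(ds$values), nrow(ds$values))
  cols <- c(list(seq_len(nrow(sm))),
            lapply(seq_len(ncol(sm)), function(j) sm[, j]))
  writeLines(do.call(paste, c(cols, sep = ",")), paths[1L])
  rows <- data.frame(row_num = seq_len(nrow(ds$genes)),
                     gene_id = ds$genes$gene_id,
                     gene_symbol = ds$genes$gene_symbol)
  data.table::fwrite(rows, paths[2L])
  cols <- data.frame(column_num = seq_len(nrow(ds$columns)),
                     donor_id = ds$columns$donor_id,
                     age = ds$columns$age,
                     structure_acronym = ds$columns$structure_acronym)
  data.table::fwrite(cols, paths[3L])
  invisible(paths)
}

#' Write a tidy long-format table of a dataset
#'
#' One row per (gene, donor, structure) with its RPKM value; the format
#' consumed by downstream spreadsheet inspection.
#'
#' @param ds a [relx_dataset()].
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_tidy_expression <- function(ds, path) {
  stopifnot(inherits(ds, "relx_dataset"))
  dt <- data.table::data.table(
    gene = rep(ds$genes$gene_id, times = ncol(ds$values)),
    donor = rep(ds$columns$donor_id, each = nrow(ds$values)),
    structure = rep(ds$columns$structure_acronym, each = nrow(ds$values)),
    rpkm = as.vector(ds$values))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Apply the specimen inclusion rule
#'
#' A specimen is analysable only if its cerebellum was sampled and it
#' has enough non-cerebellar regions to anchor the comparison
#' distribution: the rule keeps donors with a cerebellar sample and at
#' least `min_other_regions` other regions, and reports every excluded
#' donor with its reason.
#'
#' @param ds a [relx_dataset()].
#' @param min_other_regions minimum number of non-cerebellar regions
#'   (default 4).
#' @return A list with `included` (a [relx_dataset()] restricted to the
#'   kept donors' columns) and `excluded` (data frame `donor_id`,
#'   `reason`).
#' @export
select_specimens <- function(ds, min_other_regions = 4L) {
  stopifnot(inherits(ds, "relx_dataset"))
  sp <- ds$specimens
  keep <- sp$has_cerebellum & sp$n_other_regions >= min_other_regions
  reason <- ifelse(!sp$has_cerebellum, "no cerebellar sample",
                   "too few non-cerebellar regions")
  excluded <- data.frame(donor_id = sp$donor_id[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)
  col_keep <- ds$columns$donor_id %in% sp$donor_id[keep]
  included <- relx_dataset(ds$values[, col_keep, drop = FALSE],
                           ds$genes,
                           ds$columns[col_keep,
                                      setdiff(names(ds$columns), "is_cerebellar"),
                                      drop = FALSE],
                           cerebellar_labels = ds$cerebellar_labels)
  list(included = included, excluded = excluded)
}

#' Resolve a gene symbol or id to a dataset gene id
#'
#' Matches `gene` first against `gene_id`, then against `gene_symbol`.
#' Errors if absent or ambiguous.
#' @param ds a [relx_dataset()] (or its `genes` data frame).
#' @param gene character scalar.
#' @return The matching `gene_id`.
#' @export
resolve_gene <- function(ds, gene) {
  genes <- if (inherits(ds, "relx_dataset")) ds$genes else ds
  if (gene %in% genes$gene_id) return(gene)
  hit <- genes$gene_id[genes$gene_symbol == gene]
  if (length(hit) == 1L) return(hit)
  if (length(hit) > 1L) {
    stop("gene symbol ", sQuote(gene), " is ambiguous (",
         length(hit), " matches)", call. = FALSE)
  }
  stop("gene ", sQuote(gene), " not found in dataset", call. = FALSE)
}
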