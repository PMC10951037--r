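# Overrepresentation analysis: each annotation term is a 2x2 table
# (in/out of query x in/out of term) over a finite gene universe,
# tested with the exact two-sided hypergeometric (Fisher) probability.
# Fold enrichment (k/n)/(K/N) gives the direction: > 1 over-represented,
# otherwise under-represented. BH-FDR is applied across all tested
# terms.

#' Read a GMT annotation file
#'
#' Standard tab-separated GMT: term id, description, then member genes.
#' Duplicate members within a line are collapsed.
#'
#' @param path GMT file path.
#' @param universe optional explicit gene universe; default is the union
#'   of all term members.
#' @return Object of class `annotation_collection`: list with `terms`
#'   (named list of character vectors), `term_names` (named character)
#'   and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1L)) < 3L
  if (any(short)) {
    stop(path, ": line ", which(short)[1L],
         " has fewer than 3 tab-separated fields", call. = FALSE)
  }
  ids <- vapply(fields, `[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop(path, ": duplicate term id ", sQuote(ids[duplicated(ids)][1L]),
         call. = FALSE)
  }
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(members) <- ids
  if (is.null(universe)) {
    universe <- unique(unlist(members, use.names = FALSE))
  } else {
    members <- lapply(members, intersect, universe)
  }
  structure(list(terms = members,
                 term_names = setNames(vapply(fields, `[`, character(1L), 2L),
                                       ids),
                 universe = universe),
            class = "annotation_collection")
}

#' @export
print.annotation_collection <- function(x, ...) {
  cat("annotation_collection: ", length(x$terms), " terms over ",
      length(x$universe), " genes\n", sep = "")
  invisible(x)
}

#' Exact two-sided hypergeometric p-value
#'
#' Probability, under the hypergeometric null, of drawing an overlap at
#' least as extreme as `k`: the sum over the support of all point
#' probabilities not exceeding that of the observed table (the
#' two-sided Fisher exact convention, with a 1 + 1e-7 relative
#' tolerance for ties).
#'
#' @param k observed overlap(s) between query and term.
#' @param K term size(s) in the universe.
#' @param n query size.
#' @param N universe size.
#' @return Numeric vector of p-values in (0, 1].
#' @export
hyper_p_two_sided <- function(k, K, n, N) {
  K <- rep_len(K, length(k))
  stopifnot(length(n) == 1L, length(N) == 1L, n <= N, all(K <= N),
            all(k <= pmin(K, n)), all(k >= pmax(0, K + n - N)))
  vapply(seq_along(k), function(i) {
    lo <- max(0L, K[i] + n - N)
    hi <- min(K[i], n)
    d <- dhyper(lo:hi, K[i], N - K[i], n)
    min(1, sum(d[d <= d[k[i] - lo + 1L] * (1 + 1e-7)]))
  }, numeric(1L))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted values (monotone-enforced, capped at 1), input
#' order preserved. Inputs must lie in (0, 1].
#'
#' @param p_values numeric vector of raw p-values.
#' @return Adjusted values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Term over/under-representation of a query gene set
#'
#' For each annotation term, forms the 2x2 overlap counts of the query
#' against the universe, computes fold enrichment
#' `(k/n) / (K/N)`, the exact two-sided hypergeometric p-value, and
#' BH-FDR across all tested terms. Query genes outside the universe are
#' dropped with a warning.
#'
#' @param query character vector of genes.
#' @param ann an [read_gmt()] collection.
#' @param universe gene universe; defaults to the collection's. Term
#'   memberships are intersected with it.
#' @return Data frame of class `enrichment_table`, sorted by `fdr` then
#'   `term_id`, with columns `term_id`, `term_name`, `k`, `n`, `K`, `N`,
#'   `fold`, `p_raw`, `fdr`, `direction` (`"over"` iff `fold > 1`).
#' @export
enrich <- function(query, ann, universe = ann$universe) {
  stopifnot(inherits(ann, "annotation_collection"))
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (!length(query)) stop("empty query set", call. = FALSE)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  n <- length(query)
  N <- length(universe)
  terms <- lapply(ann$terms, intersect, universe)
  K <- vapply(terms, length, integer(1L))
  keep <- K > 0L
  terms <- terms[keep]
  K <- K[keep]
  k <- vapply(terms, function(m) length(intersect(m, query)), integer(1L))
  fold <- (k / n) / (K / N)
  p <- hyper_p_two_sided(k, K, n, N)
  out <- data.frame(term_id = names(terms),
                    term_name = unname(ann$term_names[names(terms)]),
                    k = k, n = n, K = K, N = N,
                    fold = fold, p_raw = p, fdr = bh_adjust(p),
                    direction = ifelse(fold > 1, "over", "under"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$fdr, out$term_id), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Write an enrichment table as TSV
#'
#' @param et an [enrich()] result.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(et, path) {
  data.table::fwrite(as.data.frame(et), path, sep = "\t")
  invisible(path)
}
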