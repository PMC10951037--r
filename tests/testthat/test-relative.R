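make_single_specimen <- function(cb, others) {
  columns <- data.frame(donor_id = "d1", age = "20 pcw",
                        structure_acronym = c("CBC",
                                              paste0("R", seq_along(others))))
  relx_dataset(matrix(c(cb, others), 1),
               data.frame(gene_id = "g1", gene_symbol = "g1"), columns)
}

test_that("z-score follows the cerebellar-vs-rest formula with sample SD", {
  zm <- relative_z(make_single_specimen(5, c(1, 2, 3)))
  expect_equal(unname(zm$z["g1", "d1"]), 3)   # mean 2, sample sd 1
  expect_equal(unname(zm$n_other["g1", "d1"]), 3L)
})

test_that("degenerate cells (sd = 0 or too few regions) are missing", {
  zm <- relative_z(make_single_specimen(2, c(2, 2, 2, 2)))
  expect_true(is.na(zm$z["g1", "d1"]))
  expect_equal(zm$n_degenerate, 1L)
  # a single other region cannot anchor an SD
  zm1 <- relative_z(make_single_specimen(2, 7))
  expect_true(is.na(zm1$z["g1", "d1"]))
})

test_that("vectorized z agrees with the per-cell loop oracle", {
  ds <- make_null_dataset(n_genes = 100, n_donors = 6, n_other = 7, seed = 3)
  zm <- relative_z(ds)
  expect_equal(zm$z, oracle_relative_z(ds), tolerance = 1e-12)
})

test_that("null genes give z-scores centred at zero", {
  # i.i.d. values per region from one (symmetric) distribution
  set.seed(11)
  base <- make_null_dataset(n_genes = 2, n_donors = 4, n_other = 10)
  values <- matrix(runif(10000 * ncol(base$values)), 10000)
  ds <- relx_dataset(values,
                     data.frame(gene_id = sprintf("g%05d", 1:10000),
                                gene_symbol = sprintf("g%05d", 1:10000)),
                     base$columns[, c("donor_id", "age", "structure_acronym")])
  zm <- relative_z(ds)
  expect_lt(abs(mean(zm$z, na.rm = TRUE)), 0.05)
})

test_that("z is invariant to specimen-wise scaling and region order", {
  ds <- make_null_dataset(n_genes = 30, n_donors = 4, n_other = 6, seed = 5)
  z0 <- relative_z(ds)$z
  # scale all of donor 2's samples by a positive constant
  ds2 <- ds
  sel <- ds$columns$donor_id == "d02"
  ds2$values[, sel] <- ds2$values[, sel] * 17.3
  expect_equal(relative_z(ds2)$z[, "d02"], z0[, "d02"], tolerance = 1e-12)
  expect_equal(relative_z(ds2)$z[, "d01"], z0[, "d01"])
  # permute column order
  perm <- sample(ncol(ds$values))
  ds3 <- relx_dataset(ds$values[, perm], ds$genes,
                      ds$columns[perm, c("donor_id", "age",
                                         "structure_acronym")])
  expect_equal(relative_z(ds3)$z[, colnames(z0)], z0, tolerance = 1e-12)
})

test_that("never-expressed genes are exactly the all-zero rows", {
  ds <- make_null_dataset(n_genes = 10, n_donors = 3, seed = 8)
  ds$values[c(2, 7), ] <- 0
  ds$values[4, ] <- 0
  ds$values[4, 5] <- 0.001   # one tiny value -> kept
  res <- drop_never_expressed(ds)
  expect_setequal(res$dropped_genes, ds$genes$gene_id[c(2, 7)])
  expect_true("g0004" %in% res$kept$genes$gene_id)
})

test_that("centile benchmark uses midrank within the pooled sample", {
  z <- matrix(c(10, sort(rnorm(99))), ncol = 1,
              dimnames = list(c("t", paste0("b", 1:99)), "d01"))
  zm <- make_relz(z)
  expect_equal(centile_benchmark(zm, "t")$centile, 99.5)
  # all ties -> 50th centile
  z2 <- matrix(rep(1, 100), ncol = 1,
               dimnames = list(c("t", paste0("b", 1:99)), "d01"))
  expect_equal(centile_benchmark(make_relz(z2), "t")$centile, 50)
  expect_error(centile_benchmark(zm, "absent"), "not in z matrix")
})

test_that("centile agrees with the sort-based oracle on 1000-gene matrices", {
  set.seed(21)
  for (rep in 1:3) {
    z <- matrix(rnorm(1000 * 5), 1000, 5,
                dimnames = list(paste0("g", 1:1000), NULL))
    z[sample(length(z), 200)] <- NA
    z <- round(z, 1)          # induce ties
    zm <- make_relz(z)
    target <- paste0("g", sample(1000, 1))
    rep_tab <- centile_benchmark(zm, target)
    for (i in seq_len(nrow(rep_tab))) {
      j <- match(rep_tab$donor_id[i], colnames(zm$z))
      bg <- z[setdiff(rownames(z), target), j]
      expect_equal(rep_tab$centile[i],
                   oracle_centile(z[target, j], bg[!is.na(bg)]))
    }
  }
})

test_that("centile report is consistent with its background quantiles", {
  set.seed(9)
  z <- matrix(rnorm(500 * 20), 500, 20,
              dimnames = list(paste0("g", 1:500), NULL))
  z[1, ] <- rnorm(20, mean = 2)   # push the target around the upper tail
  zm <- make_relz(z)
  tab <- centile_benchmark(zm, "g1")
  margin <- 100 / (tab$n_background_genes + 1)
  clear <- abs(tab$centile - 95) > margin
  expect_true(all((tab$centile[clear] > 95) ==
                    (tab$target_z[clear] > tab$q95[clear])))
})
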