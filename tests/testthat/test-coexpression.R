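test_that("quartile filter drops genes strictly below the 25th percentile", {
  # 8 genes with mean RPKM 1..8: type-7 25th percentile is 2.75,
  # so the genes at 1 and 2 are dropped
  columns <- data.frame(donor_id = rep(c("d1", "d2"), each = 3),
                        age = rep(c("20 pcw", "3 yrs"), each = 3),
                        structure_acronym = rep(c("CBC", "R1", "R2"), 2))
  values <- matrix(rep(1:8, 6), 8, 6)
  values[, 2] <- values[, 2] + 0.5   # break sd = 0 degeneracy
  values[, 5] <- values[, 5] - 0.5
  ds <- relx_dataset(values,
                     data.frame(gene_id = paste0("g", 1:8),
                                gene_symbol = paste0("g", 1:8)), columns)
  zm <- relative_z(ds)
  f <- filter_genes(ds, zm)
  expect_equal(f$report$quartile_threshold, 2.75)
  expect_equal(f$report$n_low_expression_dropped, 2)
  expect_setequal(f$retained_genes, paste0("g", 3:8))
  expect_equal(f$report$n_input,
               f$report$n_low_expression_dropped +
                 f$report$n_missingness_dropped + f$report$n_retained)
})

test_that("missingness filter is strict at more than max_missing_z", {
  set.seed(2)
  z <- matrix(rnorm(8 * 30), 8, 30, dimnames = list(paste0("g", 1:8), NULL))
  z[2, 1:6] <- NA   # 6 missing -> dropped
  z[3, 1:5] <- NA   # 5 missing -> kept
  zm <- make_relz(z)
  columns <- data.frame(donor_id = rep(c("d1", "d2"), each = 3),
                        age = rep(c("20 pcw", "3 yrs"), each = 3),
                        structure_acronym = rep(c("CBC", "R1", "R2"), 2))
  values <- matrix(10, 8, 6)
  values[1, ] <- 0.1   # the only gene under the quartile threshold
  ds <- relx_dataset(values,
                     data.frame(gene_id = paste0("g", 1:8),
                                gene_symbol = paste0("g", 1:8)), columns)
  f <- filter_genes(ds, zm, max_missing_z = 5)
  expect_false("g2" %in% f$retained_genes)
  expect_true("g3" %in% f$retained_genes)
  expect_equal(f$report$n_low_expression_dropped, 1)
  expect_equal(f$report$n_missingness_dropped, 1)
})

test_that("correlation hits the self and anti-self boundaries", {
  set.seed(3)
  base <- rnorm(12)
  z <- rbind(t = base, same = base, anti = 2 * mean(base) - base,
             noise = rnorm(12))
  ct <- correlate_all(make_relz(z), "t")
  expect_equal(ct$r[ct$gene == "same"], 1)
  expect_equal(ct$r[ct$gene == "anti"], -1)
  expect_equal(ct$n_pairs, rep(12L, 3))
})

test_that("pairwise-complete correlation matches the per-gene loop oracle", {
  set.seed(14)
  z <- matrix(rnorm(101 * 30), 101, 30,
              dimnames = list(c("t", paste0("g", 1:100)), NULL))
  z[sample(length(z), 250)] <- NA
  zm <- make_relz(z)
  ct <- correlate_all(zm, "t")
  expect_equal(ct$r, unname(oracle_correlate(zm, "t", ct$gene)),
               tolerance = 1e-12)
  # genes under the pair floor are reported missing
  z["g1", ] <- NA
  z["g1", 1:2] <- rnorm(2)
  ct2 <- correlate_all(make_relz(z), "t", min_pairs = 3)
  expect_true(is.na(ct2$r[ct2$gene == "g1"]))
  expect_equal(ct2$n_pairs[ct2$gene == "g1"], 2L)
})

test_that("set membership is strict and monotone in the thresholds", {
  ct <- data.frame(gene = paste0("g", 1:5),
                   r = c(0.6, 0.61, -0.6, -0.61, NA))
  sets <- build_sets(ct)
  expect_equal(sets$positive, "g2")    # r = 0.6 exactly is out
  expect_equal(sets$negative, "g4")    # r = -0.6 exactly is out
  set.seed(6)
  ct2 <- data.frame(gene = paste0("g", 1:200), r = runif(200, -1, 1))
  sizes <- sapply(c(0.2, 0.4, 0.6, 0.8), function(u) {
    length(build_sets(ct2, upper = u)$positive)
  })
  expect_true(all(diff(sizes) <= 0))
})

test_that("null correlations beyond the thresholds match the t-tail rate", {
  # analytic tail: P(|r| > 0.6) at n = 30 from the t transform of r
  r0 <- 0.6; n <- 30
  t0 <- r0 * sqrt(n - 2) / sqrt(1 - r0^2)
  p_tail <- pt(t0, df = n - 2, lower.tail = FALSE)
  set.seed(33)
  total <- 0L
  n_genes <- 5000L; reps <- 20L
  for (i in seq_len(reps)) {
    z <- matrix(rnorm((n_genes + 1) * n), n_genes + 1, n,
                dimnames = list(c("t", paste0("g", seq_len(n_genes))), NULL))
    sets <- build_sets(correlate_all(make_relz(z), "t"))
    total <- total + length(sets$positive) + length(sets$negative)
  }
  expected <- 2 * p_tail * n_genes * reps
  expect_lt(abs(total - expected), 4 * sqrt(expected) + 1)
})
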