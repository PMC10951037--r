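test_that("a perfectly linear trajectory gives r = 1 and strict elevation", {
  ages <- c(100, 200, 300, 400, 500)
  z <- matrix(seq(0.5, 2.5, by = 0.5), 1, dimnames = list("t", NULL))
  zm <- make_relz(z, ages_days = ages)
  fit <- fit_phase(zm, "t", data.frame(name = "all", lo = 0, hi = Inf))
  expect_equal(fit$r, 1)
  expect_lt(fit$p, 1e-10)
  expect_equal(fit$n, 5)
  expect_equal(sum(fit$specimens$elevated), 2)  # z = 2.0 and 2.5 exceed 1.96
  # threshold is strict: z exactly 1.96 is not elevated
  z2 <- matrix(c(1, 1.5, 1.96, 2, 2.5), 1, dimnames = list("t", NULL))
  fit2 <- fit_phase(make_relz(z2, ages), "t",
                    data.frame(name = "all", lo = 0, hi = Inf))
  expect_equal(fit2$specimens$elevated, c(FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("phases with fewer than 3 usable specimens are errors", {
  zm <- make_relz(matrix(rnorm(4), 1, dimnames = list("t", NULL)),
                  ages_days = c(100, 150, 400, 500))
  expect_error(fit_phase(zm, "t", data.frame(name = "early", lo = 0, hi = 280)),
               "early")
  expect_error(fit_phase(zm, "t", data.frame(name = "none", lo = 9e5, hi = Inf)),
               "0 usable")
  # all-prenatal input: the late phase has nothing
  zm2 <- make_relz(matrix(rnorm(5), 1, dimnames = list("t", NULL)),
                   ages_days = c(60, 100, 150, 200, 250))
  expect_error(two_phase_report(zm2, "t"), "late")
})

test_that("r and p are invariant to affine transforms of age and z", {
  set.seed(4)
  ages <- sort(runif(12, 60, 5000))
  z <- matrix(0.001 * ages + rnorm(12, sd = 0.8), 1,
              dimnames = list("t", NULL))
  win <- data.frame(name = "all", lo = 0, hi = Inf)
  f0 <- fit_phase(make_relz(z, ages), "t", win)
  f1 <- fit_phase(make_relz(3.7 * z - 2, ages * 2 + 100), "t", win)
  expect_equal(f1$r, f0$r)
  expect_equal(f1$p, f0$p)
})

test_that("the t-based p-value matches a permutation test", {
  set.seed(7)
  ages <- runif(10, 100, 4000)
  zvec <- 4e-4 * ages + rnorm(10, sd = 1)
  zm <- make_relz(matrix(zvec, 1, dimnames = list("t", NULL)), ages)
  fit <- fit_phase(zm, "t", data.frame(name = "all", lo = 0, hi = Inf))
  robs <- abs(fit$r)
  B <- 10000
  rperm <- replicate(B, abs(cor(ages, sample(zvec))))
  p_perm <- (1 + sum(rperm >= robs)) / (1 + B)
  expect_lt(abs(p_perm - fit$p), 0.03)
})

test_that("elevation count is non-increasing in the threshold", {
  set.seed(12)
  zm <- make_relz(matrix(rnorm(20, 1.5), 1, dimnames = list("t", NULL)),
                  ages_days = runif(20, 60, 9000))
  win <- data.frame(name = "all", lo = 0, hi = Inf)
  counts <- sapply(c(0.5, 1, 1.96, 3), function(th) {
    sum(fit_phase(zm, "t", win, elevation_threshold = th)$specimens$elevated)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("rise-then-fall data yields positive early and negative late r", {
  sim <- simulate_brainspan(sim_config(n_null_genes = 200L, seed = 31L))
  sel <- select_specimens(sim$dataset)
  zm <- relative_z(drop_never_expressed(sel$included)$kept)
  rep <- two_phase_report(zm, "ATM")
  expect_gt(rep$fits$early$r, 0)
  expect_lt(rep$fits$late$r, 0)
  # the combined table covers every specimen and tags phase membership
  expect_equal(nrow(rep$specimens), ncol(zm$z))
  expect_true(all(rep$specimens$in_early + rep$specimens$in_late >= 1 |
                    is.na(rep$specimens$z)))
  # convention switch: late phase starting at one year drops infants
  rep2 <- two_phase_report(zm, "ATM",
                           phases = default_phases(first_year_in_phase2 = FALSE))
  expect_lte(rep2$fits$late$n, rep$fits$late$n)
})
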