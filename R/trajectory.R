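# Two-phase age trajectory of a target gene's region-relative z-score.
# Phase windows are half-open intervals [lo, hi) on the
# days-post-conception scale. The defaults follow the common scheme of
# an early neurodevelopmental phase (conception through first postnatal
# year) and a postnatal phase through adulthood; because it is ambiguous
# whether first-year infants belong to the late phase as well, the
# default includes them in both and `default_phases(first_year_in_phase2
# = FALSE)` starts phase 2 at one year instead.

#' Default phase windows
#'
#' @param first_year_in_phase2 if `TRUE` (default) the late phase starts
#'   at birth so first-year specimens belong to both phases; if `FALSE`
#'   it starts at one postnatal year.
#' @param constants age-scale constants, see [age_constants].
#' @return A data frame with columns `name`, `lo`, `hi` (days post
#'   conception, half-open `[lo, hi)`).
#' @export
default_phases <- function(first_year_in_phase2 = TRUE,
                           constants = age_constants) {
  one_year <- constants[["birth"]] + constants[["year"]]
  data.frame(
    name = c("early", "late"),
    lo = c(0, if (first_year_in_phase2) constants[["birth"]] else one_year),
    hi = c(one_year, Inf),
    stringsAsFactors = FALSE
  )
}

#' Pearson trajectory fit within one phase window
#'
#' Correlates age (days post conception) with the target gene's
#' region-relative z-score over the specimens falling in the window.
#' The two-sided p-value uses the t reference distribution with n - 2
#' degrees of freedom, `t = r * sqrt(n - 2) / sqrt(1 - r^2)`. Specimens
#' with z strictly above `elevation_threshold` are flagged as elevated.
#'
#' @param zm a [relative_z()] result.
#' @param target_gene gene id present in `zm`.
#' @param phase single-row data frame (`name`, `lo`, `hi`) as one row of
#'   [default_phases()].
#' @param elevation_threshold z-score above which relative expression is
#'   called significantly elevated (default 1.96, the two-sided 5%
#'   normal critical value).
#' @return Object of class `trajectory_fit`: list with `phase`, `n`,
#'   `r`, `p`, and `specimens` (data frame `donor_id`, `age`,
#'   `days_post_conception`, `z`, `elevated`).
#' @export
fit_phase <- function(zm, target_gene, phase,
                      elevation_threshold = 1.96) {
  stopifnot(inherits(zm, "relz_matrix"))
  if (!target_gene %in% rownames(zm$z)) {
    stop("target gene ", sQuote(target_gene), " not in z matrix",
         call. = FALSE)
  }
  age <- zm$specimens$days_post_conception
  z <- zm$z[target_gene, ]
  in_win <- age >= phase$lo & age < phase$hi & !is.na(z)
  n <- sum(in_win)
  if (n < 3L) {
    stop("phase ", sQuote(phase$name), ": only ", n,
         " usable specimens (need >= 3)", call. = FALSE)
  }
  r <- cor(age[in_win], z[in_win])
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(tstat), df = n - 2)
  specimens <- data.frame(
    donor_id = zm$specimens$donor_id[in_win],
    age = zm$specimens$age[in_win],
    days_post_conception = age[in_win],
    z = z[in_win],
    elevated = z[in_win] > elevation_threshold,
    stringsAsFactors = FALSE)
  structure(list(phase = phase, n = n, r = r, p = p,
                 elevation_threshold = elevation_threshold,
                 specimens = specimens),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, digits = 3, ...) {
  cat("trajectory_fit [", x$phase$name, "): n = ", x$n,
      ", r = ", signif(x$r, digits), ", p = ", signif(x$p, digits),
      "; ", sum(x$specimens$elevated), " specimen(s) elevated (z > ",
      x$elevation_threshold, ")\n", sep = "")
  invisible(x)
}

#' Two-phase trajectory report
#'
#' Fits every phase window and assembles a combined per-specimen table
#' (age, z, phase membership, elevation flag).
#'
#' @inheritParams fit_phase
#' @param phases data frame of phase windows, default [default_phases()].
#' @return Object of class `trajectory_report`: list with `fits` (named
#'   list of [fit_phase()] results) and `specimens` (combined table with
#'   one logical column per phase).
#' @export
two_phase_report <- function(zm, target_gene, phases = default_phases(),
                             elevation_threshold = 1.96) {
  fits <- lapply(seq_len(nrow(phases)), function(i) {
    fit_phase(zm, target_gene, phases[i, , drop = FALSE],
              elevation_threshold = elevation_threshold)
  })
  names(fits) <- phases$name
  age <- zm$specimens$days_post_conception
  z <- zm$z[target_gene, ]
  tab <- data.frame(donor_id = zm$specimens$donor_id,
                    age = zm$specimens$age,
                    days_post_conception = age,
                    z = unname(z),
                    elevated = unname(z > elevation_threshold),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(phases))) {
    tab[[paste0("in_", phases$name[i])]] <-
      age >= phases$lo[i] & age < phases$hi[i] & !is.na(z)
  }
  structure(list(fits = fits, specimens = tab,
                 target_gene = target_gene),
            class = "trajectory_report")
}

#' @export
print.trajectory_report <- function(x, ...) {
  cat("trajectory_report for ", x$target_gene, ":\n", sep = "")
  for (f in x$fits) print(f, ...)
  invisible(x)
}

#' @export
plot.trajectory_report <- function(x, ...) {
  tab <- x$specimens[!is.na(x$specimens$z), ]
  plot(tab$days_post_conception, tab$z, log = "x",
       xlab = "age (days post conception)",
       ylab = paste("relative cerebellar z of", x$target_gene),
       pch = 19, ...)
  abline(h = 0)
  abline(h = c(-1.96, 1.96), lty = 2)
  abline(v = age_constants[["birth"]], lty = 3)
  invisible(x)
}

#' Write a trajectory report as TSV files
#'
#' @param report a [two_phase_report()] result.
#' @param fits_path TSV with one row per phase (`phase`, `n`, `r`, `p`).
#' @param specimens_path TSV of the combined per-specimen table.
#' @return Invisibly, the two paths.
#' @export
write_trajectory <- function(report, fits_path, specimens_path) {
  fits <- do.call(rbind, lapply(report$fits, function(f) {
    data.frame(phase = f$phase$name, n = f$n, r = f$r, p = f$p)
  }))
  data.table::fwrite(fits, fits_path, sep = "\t")
  data.table::fwrite(report$specimens, specimens_path, sep = "\t", na = "")
  invisible(c(fits_path, specimens_path))
}
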