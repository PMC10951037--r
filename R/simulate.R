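# Synthetic BrainSpan-like data with planted structure, so that every
# pipeline stage has a ground truth to be checked against. The
# generative model:
#   * null genes: log RPKM = gene baseline + donor effect + region
#     noise, all normal, exponentiated (log-normal RPKM, exchangeable
#     across regions, hence mean-zero relative z);
#   * the target gene carries a planted per-specimen z value (a
#     rise-to-peak / decline-from-peak trajectory in age plus noise);
#     the cerebellar RPKM is set to mean(others) + z * sd(others),
#     clamped at 0, so the planted z is recovered exactly by the
#     z-scoring stage;
#   * module genes are planted the same way with z profiles correlated
#     to the target's at a configured population correlation;
#   * a configured fraction of genes is all-zero ("never expressed");
#   * whole (donor, structure) samples drop out with a configured
#     probability, which is what produces <30-of-42 inclusion and
#     missing z cells.
# Values are rounded to 3 decimals like the public downloads; rounding
# is what turns near-silent genes into exact zeros and produces sd = 0
# degenerate z cells.

non_cerebellar_acronyms <- c("DFC", "VFC", "MFC", "OFC", "M1C", "S1C",
                             "IPC", "A1C", "STC", "ITC", "V1C", "HIP",
                             "AMY", "STR", "MD")

#' Simulation configuration
#'
#' Defaults emulate the BrainSpan developmental transcriptome: 42
#' donors with log-uniform ages from 8 post-conception weeks to 40
#' years, 16 grey-matter structures (one cerebellar; whole-cerebellum
#' `CB` for early fetal donors, cerebellar cortex `CBC` otherwise),
#' 28% per-sample dropout (so about 30 of 42 donors pass the inclusion
#' rule), 50,000 null genes with log-normal RPKM baselines of which
#' 3.6% are never expressed, a target gene whose relative cerebellar z
#' rises to a peak of 4 at one postnatal year and then declines slowly,
#' and 100-gene positive and negative modules at population correlation
#' 0.8 with the target profile.
#'
#' @param n_donors number of donors.
#' @param age_min_days,age_max_days age range, days post conception
#'   (defaults 8 pcw and 40 yrs); ages are sampled log-uniformly.
#' @param n_regions total structures per donor including one cerebellar.
#' @param dropout probability that a (donor, structure) sample is
#'   absent.
#' @param n_null_genes number of background genes.
#' @param fraction_never_expressed fraction of null genes set all-zero.
#' @param n_positive_module,n_negative_module module sizes.
#' @param r_mod population correlation (in absolute value) of module
#'   gene z profiles with the target's; must lie in (-1, 1).
#' @param target_gene id/symbol given to the target gene.
#' @param z_peak planted target z at `peak_age_days`.
#' @param peak_age_days age of the trajectory peak (default one
#'   postnatal year).
#' @param phase1_slope,phase2_slope planted slopes of the mean z
#'   trajectory, z units per year, before and after the peak. The
#'   phase-1 default rises from z = 0 at 8 pcw to the peak; the phase-2
#'   default declines to z = 1 at 40 years.
#' @param trajectory_noise_sd per-specimen noise SD on the planted z.
#' @param gene_meanlog_mean,gene_meanlog_sd distribution of per-gene
#'   log-RPKM baselines.
#' @param donor_sd,region_sd SDs of donor and region effects (natural
#'   log scale).
#' @param target_meanlog,module_meanlog_mean,module_meanlog_sd baselines
#'   for the target and module genes (kept well-expressed so they
#'   survive the quartile filter, as a gene must to be analysable).
#' @param module_z_scale SD-type scale applied to module z profiles
#'   (correlation-invariant; kept below 1 so planted cerebellar values
#'   rarely clamp at zero).
#' @param round_digits decimals kept in the written RPKM.
#' @param seed integer seed; the whole simulation is a deterministic
#'   function of the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_donors = 42L,
                       age_min_days = 56,
                       age_max_days = 280 + 40 * 365.25,
                       n_regions = 16L,
                       dropout = 0.28,
                       n_null_genes = 50000L,
                       fraction_never_expressed = 0.0363,
                       n_positive_module = 100L,
                       n_negative_module = 100L,
                       r_mod = 0.8,
                       target_gene = "ATM",
                       z_peak = 4,
                       peak_age_days = 280 + 365.25,
                       phase1_slope = NULL,
                       phase2_slope = (1 - 4) / 39,
                       trajectory_noise_sd = 0.5,
                       gene_meanlog_mean = 0,
                       gene_meanlog_sd = 2,
                       donor_sd = 0.3,
                       region_sd = 0.5,
                       target_meanlog = log(5),
                       module_meanlog_mean = 1,
                       module_meanlog_sd = 0.5,
                       module_z_scale = 0.6,
                       round_digits = 3L,
                       seed = 1L) {
  if (is.null(phase1_slope)) {
    phase1_slope <- z_peak / ((peak_age_days - age_min_days) / 365.25)
  }
  cfg <- as.list(environment())
  stopifnot(cfg$n_donors > 0, cfg$n_regions >= 3,
            cfg$dropout >= 0, cfg$dropout < 1,
            cfg$n_null_genes > 0,
            cfg$fraction_never_expressed >= 0,
            cfg$fraction_never_expressed < 1,
            cfg$age_min_days > 0, cfg$age_max_days > cfg$age_min_days)
  if (abs(cfg$r_mod) >= 1) {
    stop("infeasible module correlation: |r_mod| must be < 1", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

planted_mean_z <- function(age_days, cfg) {
  yr <- (age_days - cfg$peak_age_days) / 365.25
  ifelse(age_days <= cfg$peak_age_days,
         cfg$z_peak + cfg$phase1_slope * yr,
         cfg$z_peak + cfg$phase2_slope * yr)
}

#' Phase-1 slope that yields a requested population trajectory r
#'
#' Under log-uniform age sampling on `[age_min, age_max]` and
#' independent normal noise on the planted z, the population Pearson
#' correlation between age and z is
#' `beta * sd(age) / sqrt(beta^2 var(age) + noise_sd^2)`. This inverts
#' that relation for the slope.
#'
#' @param r target population correlation (0 < |r| < 1).
#' @param noise_sd planted z noise SD.
#' @param age_min,age_max age window, days post conception.
#' @return Slope in z units per year.
#' @export
slope_for_population_r <- function(r, noise_sd, age_min, age_max) {
  stopifnot(abs(r) < 1, abs(r) > 0, noise_sd > 0)
  L <- log(age_max / age_min)
  m1 <- (age_max - age_min) / L
  m2 <- (age_max^2 - age_min^2) / (2 * L)
  va <- m2 - m1^2
  sign(r) * sqrt(r^2 * noise_sd^2 / ((1 - r^2) * va)) * 365.25
}

#' Simulate a BrainSpan-like expression dataset with planted structure
#'
#' See [sim_config()] for the generative model. With `dir` supplied the
#' three-file dialect of [write_brainspan()] plus a `ground_truth.txt`
#' key-value sidecar are written; re-running with the same config gives
#' byte-identical files.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory.
#' @return List with `dataset` (a [relx_dataset()]) and `truth`: the
#'   target gene id, module memberships, never-expressed genes, donor
#'   ages and the planted per-donor z values (`NA` for donors whose
#'   cerebellar sample dropped out), plus the config.
#' @export
simulate_brainspan <- function(cfg = sim_config(), dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  donors <- sprintf("D%03d", seq_len(cfg$n_donors))
  ages <- exp(runif(cfg$n_donors, log(cfg$age_min_days), log(cfg$age_max_days)))
  ages <- round(ages, 1)
  age_labels <- ifelse(
    ages < 280, paste(round(ages / 7), "pcw"),
    ifelse(ages < 280 + 365.25,
           paste(pmax(1, round((ages - 280) / 30.44)), "mos"),
           paste(round((ages - 280) / 365.25), "yrs")))
  # labels are the coarse display form; exact ages live in the truth record

  n_other <- cfg$n_regions - 1L
  if (n_other > length(non_cerebellar_acronyms)) {
    extra <- sprintf("RX%02d", seq_len(n_other - length(non_cerebellar_acronyms)))
    other_acr <- c(non_cerebellar_acronyms, extra)
  } else {
    other_acr <- non_cerebellar_acronyms[seq_len(n_other)]
  }
  cb_label <- ifelse(ages < 17 * 7, "CB", "CBC")  # whole cerebellum early

  columns <- do.call(rbind, lapply(seq_along(donors), function(d) {
    data.frame(donor_id = donors[d], age = age_labels[d],
               structure_acronym = c(cb_label[d], other_acr),
               stringsAsFactors = FALSE)
  }))
  keep <- runif(nrow(columns)) >= cfg$dropout
  columns <- columns[keep, , drop = FALSE]
  rownames(columns) <- NULL

  n_mod <- cfg$n_positive_module + cfg$n_negative_module
  n_genes <- cfg$n_null_genes + n_mod + 1L
  gene_ids <- c(cfg$target_gene,
                sprintf("G%06d", seq_len(n_genes - 1L)))
  pos_module <- gene_ids[1L + seq_len(cfg$n_positive_module)]
  neg_module <- gene_ids[1L + cfg$n_positive_module +
                           seq_len(cfg$n_negative_module)]
  null_genes <- setdiff(gene_ids, c(cfg$target_gene, pos_module, neg_module))

  meanlog <- rnorm(n_genes, cfg$gene_meanlog_mean, cfg$gene_meanlog_sd)
  meanlog[1L] <- cfg$target_meanlog
  meanlog[1L + seq_len(n_mod)] <- rnorm(n_mod, cfg$module_meanlog_mean,
                                        cfg$module_meanlog_sd)

  donor_idx <- match(columns$donor_id, donors)
  u <- matrix(rnorm(n_genes * cfg$n_donors, 0, cfg$donor_sd),
              n_genes, cfg$n_donors)
  values <- exp(meanlog + u[, donor_idx, drop = FALSE] +
                  matrix(rnorm(n_genes * nrow(columns), 0, cfg$region_sd),
                         n_genes, nrow(columns)))

  n_never <- round(cfg$fraction_never_expressed * length(null_genes))
  never <- sample(null_genes, n_never)
  values[match(never, gene_ids), ] <- 0

  values <- round(values, cfg$round_digits)

  # keep non-planted genes out of the all-zero set after rounding
  acc <- setdiff(seq_len(n_genes), match(never, gene_ids))
  zeroed <- acc[rowSums(values[acc, , drop = FALSE] > 0) == 0L]
  if (length(zeroed)) {
    first_col <- max.col(matrix(runif(length(zeroed) * ncol(values)),
                                length(zeroed)), ties.method = "first")
    values[cbind(zeroed, first_col)] <- 10^(-cfg$round_digits)
  }

  # planted z values per donor (trajectory + noise), target and modules
  z_target <- planted_mean_z(ages, cfg) +
    rnorm(cfg$n_donors, 0, cfg$trajectory_noise_sd)
  is_cb <- columns$structure_acronym %in% c("CB", "CBC")
  planted <- rep(NA_real_, cfg$n_donors)
  names(planted) <- donors
  cb_donors <- which(donors %in% columns$donor_id[is_cb])
  usable <- integer(0)
  for (d in cb_donors) {
    ot <- which(donor_idx == d & !is_cb)
    if (length(ot) >= 2L) usable <- c(usable, d)
  }
  if (length(usable) >= 2L) {
    zt <- z_target[usable]
    z_std <- (zt - mean(zt)) / sd(zt)
    eps <- matrix(rnorm(n_mod * length(usable)), nrow = n_mod,
                  ncol = length(usable))
    sgn <- rep(c(1, -1), c(cfg$n_positive_module, cfg$n_negative_module))
    z_mod <- cfg$module_z_scale *
      (outer(sgn * cfg$r_mod, z_std) + sqrt(1 - cfg$r_mod^2) * eps)
    for (i in seq_along(usable)) {
      d <- usable[i]
      cb <- which(donor_idx == d & is_cb)
      ot <- which(donor_idx == d & !is_cb)
      rows <- c(1L, 1L + seq_len(n_mod))
      zz <- c(z_target[d], z_mod[, i])
      x <- values[rows, ot, drop = FALSE]
      m <- rowMeans(x)
      s <- sqrt(rowSums((x - m)^2) / (length(ot) - 1L))
      values[rows, cb] <- round(pmax(0, m + zz * s), cfg$round_digits)
      planted[d] <- z_target[d]
    }
  }

  genes <- data.frame(gene_id = gene_ids, gene_symbol = gene_ids,
                      stringsAsFactors = FALSE)
  ds <- relx_dataset(values, genes, columns)
  truth <- list(target_gene = cfg$target_gene,
                positive_module = pos_module,
                negative_module = neg_module,
                never_expressed = sort(never),
                donor_ages_days = setNames(ages, donors),
                planted_z = planted,
                config = cfg)
  if (!is.null(dir)) {
    write_brainspan(ds, dir)
    writeLines(c(
      paste0("target_gene=", cfg$target_gene),
      paste0("positive_module=", paste(pos_module, collapse = ",")),
      paste0("negative_module=", paste(neg_module, collapse = ",")),
      paste0("never_expressed=", paste(truth$never_expressed, collapse = ",")),
      paste0("donor_ages_days=",
             paste(sprintf("%s:%g", donors, ages), collapse = ",")),
      paste0("planted_z=",
             paste(sprintf("%s:%g", donors, planted), collapse = ",")),
      paste0("seed=", cfg$seed)),
      file.path(dir, "ground_truth.txt"))
  }
  list(dataset = ds, truth = truth)
}

#' Simulate a GMT annotation collection with one planted term
#'
#' Random terms are drawn uniformly from the universe; one planted term
#' overlaps a designated query set at the requested expected fold
#' enrichment `(k/n)/(K/N)` (overlap fixed at the rounded expected
#' count, members random).
#'
#' @param universe gene universe (character).
#' @param query designated query set (subset of `universe`).
#' @param planted_term_fold requested fold (>= 1).
#' @param planted_term_size planted term size (default 50).
#' @param n_random_terms number of null terms (default 99).
#' @param random_term_size_range size range of null terms.
#' @param seed integer seed.
#' @param path optional GMT output path (byte-identical under a fixed
#'   seed).
#' @return List with `collection` (an `annotation_collection`),
#'   `planted_term_id` (`"PLANTED"`), and `planted_overlap` (the fixed
#'   overlap count k).
#' @export
simulate_gmt <- function(universe, query, planted_term_fold,
                         planted_term_size = 50L, n_random_terms = 99L,
                         random_term_size_range = c(20L, 200L),
                         seed = 1L, path = NULL) {
  stopifnot(planted_term_fold >= 1, all(query %in% universe))
  set.seed(seed)
  N <- length(universe)
  n <- length(query)
  m <- planted_term_size
  k <- round(planted_term_fold * m * n / N)
  if (k > min(m, n) || (m - k) > (N - n)) {
    stop("infeasible planted fold: implied overlap ", k,
         " exceeds term/query capacity", call. = FALSE)
  }
  planted <- c(sample(query, k), sample(setdiff(universe, query), m - k))
  terms <- c(list(PLANTED = sort(planted)),
             setNames(lapply(seq_len(n_random_terms), function(i) {
               sort(sample(universe,
                           sample(random_term_size_range[1L]:
                                    random_term_size_range[2L], 1L)))
             }), sprintf("RAND%04d", seq_len(n_random_terms))))
  term_names <- setNames(c("planted enriched term",
                           sprintf("random term %d",
                                   seq_len(n_random_terms))), names(terms))
  coll <- structure(list(terms = terms, term_names = term_names,
                         universe = universe),
                    class = "annotation_collection")
  if (!is.null(path)) {
    writeLines(vapply(names(terms), function(id) {
      paste(c(id, term_names[[id]], terms[[id]]), collapse = "\t")
    }, character(1L)), path)
  }
  list(collection = coll, planted_term_id = "PLANTED", planted_overlap = k)
}
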