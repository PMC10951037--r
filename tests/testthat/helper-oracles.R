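# Independent oracles: deliberately naive re-derivations used to check
# the vectorized implementations.

# Per-cell z-score by direct looping with stats::sd().
oracle_relative_z <- function(ds) {
  sp <- ds$specimens
  z <- matrix(NA_real_, nrow(ds$values), nrow(sp),
              dimnames = list(ds$genes$gene_id, sp$donor_id))
  for (g in seq_len(nrow(ds$values))) {
    for (d in seq_len(nrow(sp))) {
      cb <- ds$columns$donor_id == sp$donor_id[d] & ds$columns$is_cerebellar
      ot <- ds$columns$donor_id == sp$donor_id[d] & !ds$columns$is_cerebellar
      if (sum(cb) != 1L || sum(ot) < 2L) next
      x <- ds$values[g, ot]
      if (sd(x) > 0) z[g, d] <- (ds$values[g, cb] - mean(x)) / sd(x)
    }
  }
  z
}

# Centile by explicit sorting of the pooled sample (target + background):
# midrank of the target within the pool, as a percentage of pool size.
oracle_centile <- function(target_z, background_z) {
  pool <- c(target_z, background_z)
  r <- unname(rank(pool)[1L])            # midrank handles ties
  100 * (r - 0.5) / length(pool)
}

# Two-sided Fisher probability by enumeration of the hypergeometric
# support with binomial-coefficient arithmetic.
oracle_fisher <- function(k, K, n, N) {
  supp <- max(0, K + n - N):min(K, n)
  pr <- choose(K, supp) * choose(N - K, n - supp) / choose(N, n)
  min(1, sum(pr[pr <= pr[supp == k] * (1 + 1e-7)]))
}

# BH step-up from its definition: sort, scale by m/i, enforce
# monotonicity from the largest down, cap at 1, restore input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  stepped <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(stepped)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# Per-gene pairwise-complete Pearson correlation by an explicit loop.
oracle_correlate <- function(zm, target_gene, genes, min_pairs = 3L) {
  tz <- zm$z[target_gene, ]
  sapply(genes, function(g) {
    ok <- !is.na(zm$z[g, ]) & !is.na(tz)
    if (sum(ok) < min_pairs) return(NA_real_)
    cor(zm$z[g, ok], tz[ok])
  })
}
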