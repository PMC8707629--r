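# Independent brute-force oracles. These deliberately avoid the package's
# code paths and the base-R shortcuts they are checking against.

# Spearman as Pearson on average (midrank) ranks, from first principles.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Kendall tau-b by explicit pair counting with tie corrections.
oracle_kendall_taub <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(sapply(table(x), function(t) t * (t - 1) / 2))
  ty <- sum(sapply(table(y), function(t) t * (t - 1) / 2))
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (tie-free data assumed).
oracle_mwu_exact_p <- function(g1, g0) {
  v <- c(g1, g0)
  n1 <- length(g1)
  u_of <- function(idx) {
    x <- v[idx]; y <- v[-idx]
    sum(outer(x, y, ">")) # tie-free
  }
  u_obs <- u_of(seq_len(n1))
  all_u <- apply(utils::combn(length(v), n1), 2, u_of)
  p_le <- mean(all_u <= u_obs)
  p_ge <- mean(all_u >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Benjamini-Hochberg step-up computed literally from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(o == i) # rank of p[i]
    q[i] <- min(1, min(p[o][seq(j, m)] * m / seq(j, m)))
  }
  q
}

# Naive Ward clustering that recomputes cluster means each step, using the
# merge cost D(A,B) = sqrt(2 |A||B| / (|A|+|B|) * ||mean_A - mean_B||^2).
# Returns merge heights and the cophenetic distance matrix.
oracle_ward <- function(X) {
  n <- nrow(X)
  members <- lapply(seq_len(n), identity)
  active <- seq_len(n)
  heights <- numeric(n - 1)
  coph <- matrix(0, n, n)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_d <- Inf
    for (ai in seq_along(active)) {
      for (bi in seq_along(active)) {
        if (bi <= ai) next
        A <- members[[active[ai]]]; B <- members[[active[bi]]]
        mA <- colMeans(X[A, , drop = FALSE])
        mB <- colMeans(X[B, , drop = FALSE])
        d <- sqrt(2 * length(A) * length(B) / (length(A) + length(B)) *
                    sum((mA - mB)^2))
        if (d < best_d) { best_d <- d; best <- c(ai, bi) }
      }
    }
    A <- members[[active[best[1]]]]; B <- members[[active[best[2]]]]
    heights[step] <- best_d
    coph[A, B] <- best_d; coph[B, A] <- best_d
    members[[active[best[1]]]] <- c(A, B)
    active <- active[-best[2]]
  }
  list(heights = heights, cophenetic = coph)
}

# Brute-force interval containment scan for variant -> gene assignment.
oracle_assign <- function(variants, panel, flank_bp = 500) {
  out <- list()
  for (i in seq_len(nrow(panel))) {
    for (j in seq_len(nrow(variants))) {
      lo <- max(panel$start[i] - flank_bp, 0)
      hi <- panel$end[i] + flank_bp
      if (variants$chrom[j] == panel$chrom[i] &&
          variants$pos[j] >= lo && variants$pos[j] < hi) {
        out[[length(out) + 1]] <- data.frame(gene_id = panel$gene_id[i],
                                             variant_id = variants$variant_id[j])
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(gene_id = character(), variant_id = character()))
  do.call(rbind, out)
}
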