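# Independent brute-force oracles used to validate the fast implementations.

# Exact HWE p-value by direct enumeration with the closed-form probability of
# each heterozygote count (product-of-factorials formula, no recurrence).
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_b <- 2 * n_bb + n_ab
  n_rare <- min(n_b, 2 * n - n_b)
  if (n_rare == 0) return(1)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  prob <- vapply(hets, function(h) {
    hr <- (n_rare - h) / 2
    hc <- n - h - hr
    exp(
      lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
        h * log(2) + lfactorial(n_rare) + lfactorial(2 * n - n_rare) -
        lfactorial(2 * n)
    )
  }, numeric(1))
  p_obs <- prob[hets == n_ab]
  # same "no more probable than observed" convention as the implementation,
  # including the relative tie tolerance
  sum(prob[prob <= p_obs * (1 + 1e-12)]) / sum(prob)
}

# Greedy LD pruning over the full pair matrix (window = everything), the
# stated removal rule written as a plain double loop.
prune_oracle <- function(geno, map, r2_max) {
  mafs <- aquaimpute::maf(geno)
  kept <- lapply(split(map$snp, factor(map$chrom, levels = unique(map$chrom))), function(snps) {
    active <- snps
    repeat {
      worst <- NULL
      for (i in seq_along(active)) {
        for (j in seq_along(active)) {
          if (j <= i) next
          r2 <- aquaimpute::compute_r2(geno[, active[i]], geno[, active[j]])
          if (r2 > r2_max) {
            worst <- c(active[i], active[j])
            break
          }
        }
        if (!is.null(worst)) break
      }
      if (is.null(worst)) break
      m <- mafs[worst]
      drop <- if (m[1] < m[2]) worst[1] else if (m[2] < m[1]) worst[2] else worst[2]
      active <- setdiff(active, drop)
    }
    active
  })
  unname(unlist(kept))
}

# Exhaustive minimal-cost two-state path over <= ~12 informative markers,
# with the tie rules (fewer switches, then state 1) applied on full paths.
gamete_path_oracle <- function(mism, switch_penalty) {
  k <- ncol(mism)
  grid <- as.matrix(expand.grid(rep(list(1:2), k)))
  costs <- apply(grid, 1, function(st) {
    sum(mism[cbind(st, seq_len(k))]) + switch_penalty * sum(diff(st) != 0)
  })
  sw <- apply(grid, 1, function(st) sum(diff(st) != 0))
  best_cost <- min(costs)
  at_cost <- abs(costs - best_cost) < 1e-9
  best_sw <- min(sw[at_cost])
  tied <- which(at_cost & sw == best_sw)
  # paths tied on both cost and switch count differ only in switch position;
  # that residual tie is left unspecified, so report all tied optima
  list(
    states = grid[tied[1], ], cost = best_cost, n_switches = best_sw,
    tied_states = grid[tied, , drop = FALSE]
  )
}

# GBLUP solutions by direct inversion of the mixed-model equations
# (requires an invertible G; jitter added by the caller when needed).
mme_oracle <- function(y, X, G, sigma_a2, sigma_e2) {
  n <- length(y)
  lambda <- sigma_e2 / sigma_a2
  Ginv <- solve(G)
  lhs <- rbind(
    cbind(crossprod(X), t(X)),
    cbind(X, diag(n) + Ginv * lambda)
  )
  rhs <- c(crossprod(X, y), y)
  sol <- solve(lhs, rhs)
  list(beta = sol[seq_len(ncol(X))], ebv = sol[-seq_len(ncol(X))])
}

# random genotype matrix in HWE with given allele frequencies
random_geno <- function(n, p, ids = sprintf("i%03d", seq_len(n)),
                        snps = sprintf("s%04d", seq_along(p))) {
  g <- vapply(p, function(pi) stats::rbinom(n, 2, pi), numeric(n))
  geno_matrix(matrix(as.integer(g), n, length(p), dimnames = list(ids, snps)))
}
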