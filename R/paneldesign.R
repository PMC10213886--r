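new_panel <- function(snps, map, method, target, details = list()) {
  snps <- map$snp[map$snp %in% snps]   # map order, unique
  per_chrom <- dplyr::count(map[map$snp %in% snps, ], .data$chrom, name = "n_snps")
  structure(
    list(
      snps = snps, method = method, target = as.integer(target),
      achieved = length(snps), per_chrom = per_chrom, details = details
    ),
    class = "snp_panel"
  )
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf(
    "<snp_panel> method=%s target=%d achieved=%d on %d chromosome(s)\n",
    x$method, x$target, x$achieved, nrow(x$per_chrom)
  ))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.snp_panel <- function(x, ...) {
  tibble::tibble(snp = x$snps, method = x$method, target = x$target)
}

#' Allocate panel SNPs to chromosomes proportionally to length
#'
#' Chromosome length is taken as the position of its last mapped SNP. Counts
#' are proportional to length with largest-remainder rounding so they sum to
#' `target`, subject to a floor of 2 per chromosome (the first and last SNP
#' of each chromosome are always selected). Remainder ties are broken by
#' chromosome order.
#'
#' @param map Marker map.
#' @param target Total panel size; must be at least `2 * n_chromosomes`.
#' @return A tibble `chrom`, `length_bp`, `n_alloc`.
#' @export
allocate_per_chromosome <- function(map, target) {
  lens <- map |>
    dplyr::summarise(length_bp = max(.data$pos), .by = "chrom")
  k <- nrow(lens)
  if (target < 2 * k) stop("target must be at least 2 SNPs per chromosome")
  quota <- target * as.numeric(lens$length_bp) / sum(as.numeric(lens$length_bp))
  n <- pmax(2L, floor(quota))
  rem <- quota - floor(quota)
  # largest-remainder top-up, ties by chromosome order; floors above quota
  # (from the minimum of 2) are charged against the remainder pool first
  while (sum(n) < target) {
    cand <- order(-rem, seq_len(k))
    i <- cand[which(rem[cand] > -Inf)[1]]
    n[i] <- n[i] + 1L
    rem[i] <- rem[i] - 1
  }
  while (sum(n) > target) {
    adj <- which(n > 2L)
    i <- adj[order(rem[adj], -seq_along(rem)[adj])][1]
    n[i] <- n[i] - 1L
    rem[i] <- rem[i] + 1
  }
  tibble::tibble(chrom = lens$chrom, length_bp = lens$length_bp, n_alloc = as.integer(n))
}

#' Select a low-density panel by physical spacing
#'
#' Per chromosome with allocation k: the first and last SNPs are always
#' selected; the remaining k - 2 target positions are equally spaced between
#' them and each is resolved to the nearest not-yet-selected SNP
#' (equidistant ties go to the higher position). A chromosome with fewer
#' SNPs than its allocation contributes all of them and the shortfall is not
#' redistributed, so the achieved density may fall below the target.
#'
#' @param map Marker map.
#' @param target Total panel size.
#' @return An object of class `snp_panel`.
#' @export
select_physical <- function(map, target) {
  alloc <- allocate_per_chromosome(map, target)
  chosen <- character(0)
  for (i in seq_len(nrow(alloc))) {
    sub <- map[map$chrom == alloc$chrom[i], ]
    if (nrow(sub) < 2L) stop("chromosome ", alloc$chrom[i], " has fewer than 2 SNPs")
    k <- alloc$n_alloc[i]
    if (nrow(sub) <= k) {
      chosen <- c(chosen, sub$snp)
      next
    }
    pos <- sub$pos
    sel <- c(1L, nrow(sub))
    if (k > 2L) {
      targets <- seq(pos[1], pos[nrow(sub)], length.out = k)[2:(k - 1)]
      for (tp in targets) {
        avail <- setdiff(seq_len(nrow(sub)), sel)
        d <- abs(pos[avail] - tp)
        best <- avail[d == min(d)]
        sel <- c(sel, best[which.max(pos[best])])   # tie -> higher bp
      }
    }
    chosen <- c(chosen, sub$snp[sort(sel)])
  }
  new_panel(chosen, map, method = "physical", target = target)
}

#' Squared correlation between two SNP dosage vectors
#'
#' Pearson correlation squared over pairwise-complete individuals. Pairs
#' with fewer than two complete observations, or zero variance in either
#' vector, return 0 (so invariant SNPs never trigger LD pruning).
#'
#' @param geno_a,geno_b Dosage vectors of equal length.
#' @return The squared correlation in \[0, 1\].
#' @export
compute_r2 <- function(geno_a, geno_b) {
  ok <- !is.na(geno_a) & !is.na(geno_b)
  if (sum(ok) < 2L) return(0)
  a <- geno_a[ok]; b <- geno_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(0)
  stats::cor(a, b)^2
}

# pairwise r^2 matrix for a block of SNP columns; zero-variance columns give 0
r2_matrix <- function(g) {
  suppressWarnings(r <- stats::cor(g, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  r^2
}

#' Windowed greedy LD pruning
#'
#' Mirrors count-windowed pairwise pruning: within each window of
#' `window_ct` SNPs (windows never span chromosomes), while any kept pair
#' has squared correlation above `r2_max`, the offending pair's lower-MAF
#' member is removed (ties by later map order); the window then shifts
#' forward by `step_ct` SNPs. Pairs are scanned in map order and the matrix
#' is re-examined after each removal, giving a deterministic greedy result.
#'
#' @param geno Genotype matrix (used for both r-squared and MAF).
#' @param map Marker map ordered by chromosome and position.
#' @param window_ct Window size in SNPs (>= 2).
#' @param step_ct Window shift in SNPs (>= 1).
#' @param r2_max Pruning threshold in (0, 1\].
#' @return Character vector of kept SNP ids, in map order.
#' @export
prune_ld <- function(geno, map, window_ct = 50, step_ct = 5, r2_max = 0.5) {
  if (window_ct < 2) stop("window_ct must be at least 2")
  if (step_ct < 1) stop("step_ct must be positive")
  geno <- as_geno(geno)
  geno <- geno[, map$snp, drop = FALSE]
  mafs <- maf(geno)
  kept <- character(0)
  for (cn in unique(map$chrom)) {
    snps <- map$snp[map$chrom == cn]
    keep <- rep(TRUE, length(snps))
    start <- 1L
    repeat {
      end <- min(start + window_ct - 1L, length(snps))
      idx <- which(keep[start:end]) + start - 1L
      if (length(idx) >= 2L) {
        r2 <- r2_matrix(unclass(geno)[, snps[idx], drop = FALSE])
        active <- rep(TRUE, length(idx))
        repeat {
          off <- which(r2 > r2_max & upper.tri(r2) &
            outer(active, active, `&`), arr.ind = TRUE)
          if (nrow(off) == 0L) break
          off <- off[order(off[, 1], off[, 2]), , drop = FALSE]
          i <- off[1, 1]; j <- off[1, 2]
          mi <- mafs[snps[idx[i]]]; mj <- mafs[snps[idx[j]]]
          drop_local <- if (mi < mj) i else if (mj < mi) j else max(i, j)
          active[drop_local] <- FALSE
          r2[drop_local, ] <- 0
          r2[, drop_local] <- 0
        }
        keep[idx[!active]] <- FALSE
      }
      if (end >= length(snps)) break
      start <- start + step_ct
    }
    kept <- c(kept, snps[keep])
  }
  kept
}

#' Select a low-density panel by LD pruning to a target size
#'
#' Searches the pruning threshold by bisection (window 50 SNPs, step 5) so
#' the pruned set is as close as possible to `target`, then enforces the
#' exact size: surplus SNPs are trimmed at evenly spaced indices, a deficit
#' is topped up with the highest-MAF excluded SNPs. The final threshold and
#' any adjustment are recorded in the panel's `details`.
#'
#' @param geno Genotype matrix (complete, high density).
#' @param map Marker map.
#' @param target Desired panel size (<= number of mapped SNPs).
#' @param window_ct,step_ct Pruning window parameters.
#' @param max_iter Bisection iterations.
#' @return An object of class `snp_panel`.
#' @export
select_genetic <- function(geno, map, target, window_ct = 50, step_ct = 5,
                           max_iter = 20) {
  if (target > nrow(map)) stop("target exceeds the number of mapped SNPs")
  geno <- as_geno(geno)
  lo <- 0; hi <- 1
  kept_hi <- map$snp   # r2_max = 1 keeps everything (threshold is strict >)
  best <- list(kept = kept_hi, r2 = 1)
  size_at <- function(r) prune_ld(geno, map, window_ct, step_ct, r)
  if (target < nrow(map)) {
    for (it in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      kept <- size_at(mid)
      if (abs(length(kept) - target) < abs(length(best$kept) - target)) {
        best <- list(kept = kept, r2 = mid)
      }
      if (length(kept) == target) break
      if (length(kept) > target) hi <- mid else lo <- mid
    }
  }
  kept <- best$kept
  adjustment <- "none"
  if (length(kept) > target) {
    surplus <- length(kept) - target
    drop_idx <- unique(round(seq(1, length(kept), length.out = surplus)))
    while (length(drop_idx) < surplus) {
      drop_idx <- union(drop_idx, setdiff(seq_along(kept), drop_idx)[1])
    }
    kept <- kept[-drop_idx]
    adjustment <- sprintf("trimmed %d surplus SNPs at even indices", surplus)
  } else if (length(kept) < target) {
    deficit <- target - length(kept)
    excluded <- setdiff(map$snp, kept)
    mafs <- maf(geno)[excluded]
    add <- excluded[order(-mafs, match(excluded, map$snp))][seq_len(deficit)]
    kept <- c(kept, add)
    adjustment <- sprintf("topped up %d SNPs by highest MAF", deficit)
  }
  new_panel(kept, map,
    method = "genetic", target = target,
    details = list(r2_threshold = best$r2, adjustment = adjustment)
  )
}

#' Select a low-density panel uniformly at random
#'
#' @param map Marker map.
#' @param target Panel size (<= number of mapped SNPs).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return An object of class `snp_panel`.
#' @export
select_random <- function(map, target, seed = 1) {
  if (target > nrow(map)) stop("target exceeds the number of mapped SNPs")
  snps <- with_substream(seed, "random_panel", sample(map$snp, target))
  new_panel(snps, map, method = "random", target = target)
}

#' Mask target individuals down to a low-density panel
#'
#' Sets off-panel genotypes to missing for the target individuals (the
#' offspring to be imputed); all other individuals -- typically the
#' high-density genotyped parents -- are left untouched.
#'
#' @param geno Genotype matrix.
#' @param panel An `snp_panel` (or character vector of SNP ids).
#' @param targets Ids of the individuals to mask.
#' @return The masked genotype matrix.
#' @export
mask_to_panel <- function(geno, panel, targets) {
  geno <- as_geno(geno)
  snps <- if (inherits(panel, "snp_panel")) panel$snps else as.character(panel)
  if (!all(snps %in% colnames(geno))) stop("panel contains SNPs absent from the genotypes")
  if (!all(targets %in% rownames(geno))) stop("unknown target individual ids")
  off_panel <- setdiff(colnames(geno), snps)
  out <- unclass(geno)
  out[targets, off_panel] <- NA_integer_
  geno_matrix(out)
}
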