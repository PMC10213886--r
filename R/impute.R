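#' Phase parent genotypes with a windowed haplotype-library heuristic
#'
#' Parents genotyped at high density are phased chromosome by chromosome in
#' two stages. Within non-overlapping windows of `window_sites` SNPs, an EM
#' iteration estimates the frequencies of the window haplotypes implied by
#' all consistent decompositions of each genotype and assigns every parent
#' its most probable haplotype pair (homozygous-only windows are trivially
#' phased). Adjacent windows are then chained: each parent's two growing
#' chromosome haplotypes are extended by the window pair in the orientation
#' best supported by haplotype sharing with the other parents (counts of
#' observed left-tail/window-haplotype continuations), which exploits the
#' long shared haplotypes of closely related broodstock. `method = "oracle"`
#' bypasses the heuristic and returns supplied true haplotypes, isolating
#' downstream error sources in simulation studies.
#'
#' @param parent_geno Complete genotype matrix of the parents.
#' @param map Marker map covering the columns.
#' @param window_sites Window width in SNPs (default 12; decompositions are
#'   enumerated per window, so widths much beyond ~14 get expensive).
#' @param max_iter EM iterations per window (default 20).
#' @param seed Integer seed (tie-breaking in ambiguous orientations).
#' @param method `"library"` (default) or `"oracle"`.
#' @param truth `phased_haps` with true phases, required for oracle mode.
#' @param tail_sites Number of trailing SNPs of the growing haplotypes used
#'   as the sharing key when chaining windows (default 15).
#' @return A `phased_haps` object.
#' @export
phase_parents <- function(parent_geno, map, window_sites = 12, max_iter = 20,
                          seed = 1, method = c("library", "oracle"),
                          truth = NULL, tail_sites = 15) {
  method <- match.arg(method)
  parent_geno <- as_geno(parent_geno)
  if (method == "oracle") {
    if (is.null(truth)) stop("oracle phasing needs the true haplotypes")
    out <- subset_haps(truth, ids = rownames(parent_geno), snps = colnames(parent_geno))
    if (!identical(unclass(haps_to_geno(out)), unclass(parent_geno[, , drop = FALSE]))) {
      stop("true haplotypes are inconsistent with the parent genotypes")
    }
    return(out)
  }
  if (anyNA(parent_geno)) stop("parents must be complete at high density before phasing")
  if (window_sites < 2) stop("window_sites must be at least 2")
  n <- nrow(parent_geno)
  g <- unclass(parent_geno)

  with_substream(seed, "phasing", {
    h1 <- matrix(0L, n, ncol(g), dimnames = dimnames(g))
    h2 <- h1
    for (cn in unique(map$chrom)) {
      cols <- which(map$chrom == cn)
      starts <- seq(1L, length(cols), by = window_sites)
      win_pairs <- lapply(starts, function(s) {
        w <- cols[s:min(s + window_sites - 1L, length(cols))]
        phase_window_em(g[, w, drop = FALSE], max_iter = max_iter)
      })
      # chain windows left to right by shared-continuation voting
      cur1 <- win_pairs[[1]]$hap_a
      cur2 <- win_pairs[[1]]$hap_b
      for (wi in seq_along(win_pairs)[-1]) {
        a <- win_pairs[[wi]]$hap_a
        b <- win_pairs[[wi]]$hap_b
        tail_idx <- max(1L, ncol(cur1) - tail_sites + 1L):ncol(cur1)
        flip <- chain_orientations(
          cur1[, tail_idx, drop = FALSE], cur2[, tail_idx, drop = FALSE], a, b
        )
        new1 <- a; new2 <- b
        new1[flip, ] <- b[flip, , drop = FALSE]
        new2[flip, ] <- a[flip, , drop = FALSE]
        cur1 <- cbind(cur1, new1)
        cur2 <- cbind(cur2, new2)
      }
      # polish: re-phase every window over all its consistent decompositions,
      # scored by haplotype sharing with the other parents' current phase in
      # the window and both flanking contexts; repairs both mis-oriented
      # windows and within-window EM errors
      for (pass in 1:2) {
        changed <- FALSE
        for (wi in seq_along(starts)) {
          w <- starts[wi]:min(starts[wi] + window_sites - 1L, length(cols))
          lt <- if (starts[wi] > 1L) max(1L, starts[wi] - tail_sites):(starts[wi] - 1L) else integer(0)
          rt <- if (w[length(w)] < length(cols)) {
            (w[length(w)] + 1L):min(w[length(w)] + tail_sites, length(cols))
          } else integer(0)
          upd <- polish_window(
            g[, cols[w], drop = FALSE],
            cur1, cur2, w, lt, rt
          )
          if (upd$changed) changed <- TRUE
          cur1 <- upd$cur1
          cur2 <- upd$cur2
        }
        if (!changed) break
      }
      h1[, cols] <- cur1
      h2[, cols] <- cur2
    }
    phased_haps(h1, h2, map[match(colnames(g), map$snp), ])
  })
}

# re-assign one window's haplotype pair for every individual, choosing among
# all consistent decompositions the pair best supported by sharing with the
# other individuals over (left context, window, right context)
polish_window <- function(gw, cur1, cur2, w, lt, rt) {
  n <- nrow(gw)
  ham_cross <- function(a, b) {
    s <- tcrossprod(2 * a - 1, 2 * b - 1)
    (ncol(a) - s) / 2
  }
  ctx <- function(idx) rbind(cur1[, idx, drop = FALSE], cur2[, idx, drop = FALSE])
  wmat <- ctx(w)
  kl <- if (length(lt)) exp(-ham_cross(ctx(lt), ctx(lt))) else matrix(1, 2 * n, 2 * n)
  kr <- if (length(rt)) exp(-ham_cross(ctx(rt), ctx(rt))) else matrix(1, 2 * n, 2 * n)
  changed <- FALSE
  for (i in seq_len(n)) {
    het <- which(gw[i, ] == 1L)
    if (length(het) < 2L) next
    cand <- enumerate_pairs(gw[i, ], max_het = 12L)
    if (nrow(cand$a) < 2L) next
    h1 <- i; h2 <- n + i
    base1 <- kl[h1, ] * kr[h1, ]
    base2 <- kl[h2, ] * kr[h2, ]
    base1[c(h1, h2)] <- 0
    base2[c(h1, h2)] <- 0
    ka <- exp(-ham_cross(cand$a, wmat))
    kb <- exp(-ham_cross(cand$b, wmat))
    # both orientations of each unordered pair
    s_keep <- as.numeric(ka %*% base1 + kb %*% base2)
    s_swap <- as.numeric(kb %*% base1 + ka %*% base2)
    best_keep <- which.max(s_keep)
    best_swap <- which.max(s_swap)
    cur_key1 <- cur1[i, w]
    if (max(s_swap) > max(s_keep)) {
      new1 <- cand$b[best_swap, ]
      new2 <- cand$a[best_swap, ]
    } else {
      new1 <- cand$a[best_keep, ]
      new2 <- cand$b[best_keep, ]
    }
    if (!all(new1 == cur_key1)) {
      cur1[i, w] <- new1
      cur2[i, w] <- new2
      changed <- TRUE
    }
  }
  list(cur1 = cur1, cur2 = cur2, changed = changed)
}

# all consistent (a, b) haplotype decompositions of one genotype vector,
# canonical orientation: first heterozygous allele on a
enumerate_pairs <- function(gi, max_het = 16L) {
  het <- which(gi == 1L)
  base <- as.integer(gi == 2L)
  if (length(het) == 0L) {
    return(list(a = matrix(base, 1), b = matrix(base, 1)))
  }
  h <- length(het)
  if (h > max_het) {
    extra <- het[-seq_len(max_het)]
    het <- het[seq_len(max_het)]
    base[extra] <- 1L
    h <- max_het
  }
  combos <- if (h == 1L) {
    matrix(0L, 1, 0)
  } else {
    as.matrix(expand.grid(rep(list(0:1), h - 1)))
  }
  amat <- matrix(rep(base, each = nrow(combos)), nrow(combos))
  amat[, het[1]] <- 1L
  if (h > 1) amat[, het[-1]] <- combos
  bmat <- matrix(rep(gi, each = nrow(amat)), nrow(amat)) - amat
  list(a = amat, b = bmat)
}

# EM over window haplotype frequencies; returns an (arbitrary-orientation)
# haplotype pair per individual as two matrices of 0/1 alleles
phase_window_em <- function(gw, max_iter = 20, max_het = 16L) {
  n <- nrow(gw)
  w <- ncol(gw)
  # cap the enumeration at max_het heterozygous sites per window; beyond it
  # the extra sites are phased arbitrarily onto haplotype a
  cand <- lapply(seq_len(n), function(i) enumerate_pairs(gw[i, ], max_het = max_het))
  all_a <- do.call(rbind, lapply(cand, `[[`, "a"))
  all_b <- do.call(rbind, lapply(cand, `[[`, "b"))
  key_of <- function(m) apply(m, 1, paste, collapse = "")
  ka <- key_of(all_a)
  kb <- key_of(all_b)
  keys <- unique(c(ka, kb))
  ia <- match(ka, keys)
  ib <- match(kb, keys)
  grp <- rep(seq_len(n), vapply(cand, function(cc) nrow(cc$a), integer(1)))
  mult <- ifelse(ia == ib, 1, 2)
  f <- rep(1 / length(keys), length(keys))
  wgt <- rep(1, length(grp))
  for (it in seq_len(max_iter)) {
    wgt <- f[ia] * f[ib] * mult
    tot <- rowsum(wgt, grp)[, 1]
    bad <- tot == 0
    if (any(bad)) {
      wgt[grp %in% which(bad)] <- 1
      tot <- rowsum(wgt, grp)[, 1]
    }
    wgt <- wgt / tot[grp]
    cnt <- rowsum(c(wgt, wgt), c(ia, ib))
    f_new <- numeric(length(keys))
    f_new[as.integer(rownames(cnt))] <- cnt[, 1]
    f_new <- f_new / (2 * n)
    if (max(abs(f_new - f)) < 1e-8) {
      f <- f_new
      break
    }
    f <- f_new
  }
  wgt <- f[ia] * f[ib] * mult
  best <- vapply(split(seq_along(wgt), grp), function(ii) ii[which.max(wgt[ii])], integer(1))
  list(hap_a = all_a[best, , drop = FALSE], hap_b = all_b[best, , drop = FALSE])
}

# choose per-individual orientation (flip or not) for appending a window.
# Haplotype sharing across individuals decides: a left-tail haplotype votes
# for the window continuation carried by other near-identical tails. Hamming
# similarity kernels make the votes tolerant of isolated phasing errors in
# either the tail or the window assignment.
chain_orientations <- function(tails1, tails2, wina, winb, passes = 3L) {
  n <- nrow(tails1)
  tails <- rbind(tails1, tails2)       # rows 1..n = hap1, n+1..2n = hap2
  wins <- rbind(wina, winb)            # rows 1..n = option a, n+1..2n = option b
  ham <- function(m) {
    s <- tcrossprod(2 * m - 1)         # agreements - disagreements
    (ncol(m) - s) / 2
  }
  kt <- exp(-ham(tails))
  kw <- exp(-ham(wins))
  flip <- rep(FALSE, n)
  # cont[h'] = row in `wins` currently continuing left-haplotype h'
  cont <- c(seq_len(n), seq_len(n) + n)
  set_cont <- function(i) {
    cont[c(i, n + i)] <<- if (flip[i]) c(n + i, i) else c(i, n + i)
  }
  vote <- function(i, voters) {
    h1 <- i; h2 <- n + i
    ra <- i; rb <- n + i
    if (length(voters) == 0L) return(c(0, 0))
    cw <- cont[voters]
    keep <- sum(kt[h1, voters] * kw[ra, cw]) + sum(kt[h2, voters] * kw[rb, cw])
    swap <- sum(kt[h1, voters] * kw[rb, cw]) + sum(kt[h2, voters] * kw[ra, cw])
    c(keep, swap)
  }
  # online first pass: each individual is oriented by the individuals already
  # chained, so arbitrary initial orientations never vote
  for (i in seq_len(n)) {
    voters <- if (i > 1L) c(seq_len(i - 1L), n + seq_len(i - 1L)) else integer(0)
    s <- vote(i, voters)
    flip[i] <- s[2] > s[1]
    set_cont(i)
  }
  # full leave-one-out refinement passes
  for (pass in seq_len(passes)) {
    changed <- FALSE
    for (i in seq_len(n)) {
      voters <- setdiff(c(seq_len(n), n + seq_len(n)), c(i, n + i))
      s <- vote(i, voters)
      new_flip <- if (s[2] > s[1]) TRUE else if (s[1] > s[2]) FALSE else flip[i]
      if (new_flip != flip[i]) {
        flip[i] <- new_flip
        changed <- TRUE
        set_cont(i)
      }
    }
    if (!changed) break
  }
  flip
}

#' Fill offspring genotypes forced by Mendelian inheritance
#'
#' A missing offspring genotype is filled only when the parent pair forces a
#' unique value: hom x hom parents (0x0 -> 0, 2x2 -> 2, 0x2 -> 1). All other
#' configurations are left missing for the haplotype-based stages.
#'
#' @param offspring_ld Offspring genotype matrix (low density, with missing).
#' @param sire_geno,dam_geno Complete parental dosage vectors or matrices
#'   aligned to the same SNPs (one row per offspring when matrices).
#' @return The offspring matrix with forced genotypes filled; attribute
#'   `"filled"` is a logical matrix marking the filled entries.
#' @export
mendelian_fill <- function(offspring_ld, sire_geno, dam_geno) {
  g <- unclass(as_geno(offspring_ld))
  s <- if (is.matrix(sire_geno)) sire_geno else matrix(sire_geno, nrow(g), ncol(g), byrow = TRUE)
  d <- if (is.matrix(dam_geno)) dam_geno else matrix(dam_geno, nrow(g), ncol(g), byrow = TRUE)
  forced <- is.na(g) & !is.na(s) & !is.na(d) & s != 1L & d != 1L
  fill <- s / 2L + d / 2L
  g[forced] <- as.integer(fill[forced])
  out <- geno_matrix(g)
  attr(out, "filled") <- forced
  out
}

#' Decode which parental haplotype a gamete copies along a chromosome
#'
#' At markers where the offspring's genotype and the other parent's genotype
#' jointly determine the allele transmitted by the focal parent, and where
#' the focal parent is heterozygous, the transmitted allele identifies one
#' of the parent's two haplotypes. The minimal-cost two-state path over
#' these informative markers (mismatch cost per disagreement, switch cost
#' per state change) is computed by dynamic programming; ties prefer fewer
#' switches, then haplotype 1.
#'
#' @param offspring_geno Offspring dosages along one chromosome (may contain
#'   missing values).
#' @param parent_hap1,parent_hap2 The focal parent's phased alleles.
#' @param other_parent_geno The other parent's dosages.
#' @param switch_penalty,mismatch_penalty Positive costs.
#' @return A list of class `gamete_path`: `informative` (marker indices),
#'   `states` (1 or 2 per informative marker), `cost`, `n_switches`. Empty
#'   `informative` means no origin information (downstream falls back to
#'   allele-frequency filling).
#' @export
infer_gamete_origin <- function(offspring_geno, parent_hap1, parent_hap2,
                                other_parent_geno, switch_penalty = 3,
                                mismatch_penalty = 1) {
  if (switch_penalty <= 0 || mismatch_penalty <= 0) stop("penalties must be positive")
  transmitted <- transmitted_allele(offspring_geno, other_parent_geno)
  info <- which(!is.na(transmitted) & parent_hap1 != parent_hap2)
  if (length(info) == 0L) {
    return(structure(
      list(informative = integer(0), states = integer(0), cost = 0, n_switches = 0L),
      class = "gamete_path"
    ))
  }
  t_all <- transmitted[info]
  mism <- rbind(
    (parent_hap1[info] != t_all) * mismatch_penalty,
    (parent_hap2[info] != t_all) * mismatch_penalty
  )
  k <- length(info)
  # DP over (cost, n_switches) lexicographic; tie at the end -> state 1
  cost <- matrix(0, 2, k)
  nsw <- matrix(0L, 2, k)
  back <- matrix(1L, 2, k)
  cost[, 1] <- mism[, 1]
  for (j in 2:max(2, k)) {
    if (k == 1L) break
    for (s in 1:2) {
      stay <- c(cost[s, j - 1], nsw[s, j - 1])
      move <- c(cost[3 - s, j - 1] + switch_penalty, nsw[3 - s, j - 1] + 1L)
      take_stay <- stay[1] < move[1] ||
        (stay[1] == move[1] && (stay[2] < move[2] ||
          (stay[2] == move[2] && s == 1L)))
      if (take_stay) {
        cost[s, j] <- stay[1] + mism[s, j]
        nsw[s, j] <- as.integer(stay[2])
        back[s, j] <- s
      } else {
        cost[s, j] <- move[1] + mism[s, j]
        nsw[s, j] <- as.integer(move[2])
        back[s, j] <- 3L - s
      }
    }
  }
  end <- if (cost[1, k] < cost[2, k] ||
    (cost[1, k] == cost[2, k] && nsw[1, k] <= nsw[2, k])) 1L else 2L
  states <- integer(k)
  states[k] <- end
  if (k > 1L) {
    for (j in k:2) states[j - 1] <- back[states[j], j]
  }
  structure(
    list(
      informative = info, states = states, cost = cost[end, k],
      n_switches = sum(diff(states) != 0L)
    ),
    class = "gamete_path"
  )
}

# allele transmitted by the focal parent, NA when not jointly determined
transmitted_allele <- function(offspring_geno, other_parent_geno) {
  t_all <- rep(NA_integer_, length(offspring_geno))
  o <- offspring_geno
  q <- other_parent_geno
  known <- !is.na(o) & !is.na(q)
  # other parent homozygous: its contribution is fixed
  hom <- known & q != 1L
  t_hom <- o - q / 2L
  ok <- hom & t_hom %in% c(0L, 1L)
  t_all[ok] <- as.integer(t_hom[ok])
  # other parent het but offspring homozygous: transmitted allele is forced
  forced <- known & q == 1L & o != 1L
  t_all[forced] <- as.integer(o[forced] / 2L)
  t_all
}

#' Impute offspring to high density from parental haplotypes
#'
#' For each offspring and each gamete, the gamete-origin path assigns a
#' parental haplotype between consecutive informative markers; every masked
#' marker inside a constant-state stretch copies the allele of that
#' haplotype. Markers falling in a switch interval (between two informative
#' markers decoded to different haplotypes), or on chromosomes with no path,
#' are filled by sampling the allele from the reference-population allele
#' frequency -- the honest-uncertainty treatment of unresolved
#' recombination. Observed genotypes are never altered and the output is
#' complete.
#'
#' @param offspring_ld Masked offspring genotype matrix.
#' @param ped Pedigree linking offspring to parents.
#' @param parent_haps Phased parental haplotypes (from [phase_parents()]).
#' @param allele_freqs Reference-allele frequencies used for random filling;
#'   default computed from the parents.
#' @param switch_penalty,mismatch_penalty Passed to [infer_gamete_origin()].
#' @param seed Integer seed for the random fills.
#' @return A list of class `imputed_genotypes`: `geno` (complete matrix) and
#'   `provenance` (character matrix with entries `observed`, `mendelian`,
#'   `haplotype-copy`, `random-fill`).
#' @export
impute_offspring <- function(offspring_ld, ped, parent_haps,
                             allele_freqs = NULL, switch_penalty = 3,
                             mismatch_penalty = 1, seed = 1) {
  g <- unclass(as_geno(offspring_ld))
  map <- parent_haps$map
  stopifnot(identical(colnames(g), map$snp))
  parent_geno <- haps_to_geno(parent_haps)
  if (is.null(allele_freqs)) allele_freqs <- colMeans(parent_geno) / 2
  kids <- rownames(g)
  pk <- ped[match(kids, ped$id), ]
  if (anyNA(pk$sire)) stop("every imputation target needs both parents in the pedigree")
  if (!all(c(pk$sire, pk$dam) %in% rownames(parent_haps$hap1))) {
    stop("all parents of the targets must be phased")
  }
  chrom_cols <- split(seq_len(ncol(g)), factor(map$chrom, levels = unique(map$chrom)))

  out <- g
  prov <- matrix("observed", nrow(g), ncol(g), dimnames = dimnames(g))
  with_substream(seed, "imputation", {
    for (i in seq_along(kids)) {
      sire <- pk$sire[i]; dam <- pk$dam[i]
      obs <- g[i, ]
      filled <- mendelian_fill(
        matrix(obs, 1, dimnames = list(kids[i], colnames(g))),
        parent_geno[sire, ], parent_geno[dam, ]
      )
      mend <- attr(filled, "filled")[1, ]
      row <- unclass(filled)[1, ]
      prov[i, mend] <- "mendelian"

      gam <- matrix(NA_integer_, 2, ncol(g))   # per-gamete alleles (sire, dam)
      for (side in 1:2) {
        p_id <- if (side == 1L) sire else dam
        o_id <- if (side == 1L) dam else sire
        for (cols in chrom_cols) {
          hp1 <- parent_haps$hap1[p_id, cols]
          hp2 <- parent_haps$hap2[p_id, cols]
          # parent homozygous: the transmitted allele is certain, no path needed
          hom <- hp1 == hp2
          gam[side, cols[hom]] <- hp1[hom]
          path <- infer_gamete_origin(
            obs[cols], hp1, hp2, parent_geno[o_id, cols],
            switch_penalty = switch_penalty, mismatch_penalty = mismatch_penalty
          )
          if (length(path$informative) == 0L) next
          info <- path$informative
          states <- path$states
          # assign each marker the state of its flanking informative markers;
          # markers strictly inside a switch interval stay unresolved
          left <- findInterval(seq_along(cols), info)
          state_at <- rep(NA_integer_, length(cols))
          at_left <- left >= 1L
          state_at[!at_left] <- states[1L]           # before first informative marker
          lft <- left[at_left]
          rgt <- pmin(lft + 1L, length(info))
          same <- states[lft] == states[rgt]
          state_at[at_left][same] <- states[lft][same]
          hsel <- state_at
          take <- !is.na(hsel)
          hp <- ifelse(hsel[take] == 1L,
            parent_haps$hap1[p_id, cols[take]],
            parent_haps$hap2[p_id, cols[take]]
          )
          gam[side, cols[take]] <- as.integer(hp)
        }
      }
      need <- which(is.na(row))
      if (length(need) > 0L) {
        a1 <- gam[1, need]
        a2 <- gam[2, need]
        r1 <- is.na(a1)
        r2 <- is.na(a2)
        a1[r1] <- stats::rbinom(sum(r1), 1L, allele_freqs[need][r1])
        a2[r2] <- stats::rbinom(sum(r2), 1L, allele_freqs[need][r2])
        row[need] <- a1 + a2
        prov[i, need] <- ifelse(r1 | r2, "random-fill", "haplotype-copy")
      }
      out[i, ] <- row
    }
  })
  structure(
    list(geno = geno_matrix(out), provenance = prov),
    class = "imputed_genotypes"
  )
}

#' @export
print.imputed_genotypes <- function(x, ...) {
  tab <- table(x$provenance)
  cat(sprintf(
    "<imputed_genotypes> %d x %d complete; %s\n",
    nrow(x$geno), ncol(x$geno),
    paste(sprintf("%s %.1f%%", names(tab), 100 * tab / sum(tab)), collapse = ", ")
  ))
  invisible(x)
}

#' Round-trip genotypes through an external imputation tool
#'
#' Writes the masked target genotypes and the high-density reference to
#' tab-separated files in a simple dosage dialect, invokes a user-supplied
#' tool function or command, reads the tool's output back, and validates
#' completeness and shape. External imputation software is not bundled; this
#' adapter exists so that results from standalone imputers can flow through
#' the same evaluation pipeline as the built-in method.
#'
#' @param geno_ld Masked target genotype matrix.
#' @param geno_ref Complete reference (parent) genotype matrix.
#' @param ped Pedigree, written for the tool's use.
#' @param tool A function `(ld_file, ref_file, ped_file, out_file) -> NULL`
#'   expected to write the completed target matrix to `out_file`, or a shell
#'   command template containing `{ld}`, `{ref}`, `{ped}`, `{out}`.
#' @param workdir Directory for the exchange files.
#' @return A list of class `imputed_genotypes` (provenance all `"external"`
#'   except observed entries).
#' @export
external_imputer_adapter <- function(geno_ld, geno_ref, ped, tool,
                                     workdir = tempfile("imputer")) {
  geno_ld <- as_geno(geno_ld)
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  ld_file <- file.path(workdir, "target_ld.tsv")
  ref_file <- file.path(workdir, "reference_hd.tsv")
  ped_file <- file.path(workdir, "pedigree.tsv")
  out_file <- file.path(workdir, "imputed.tsv")
  write_dosage_tsv(geno_ld, ld_file)
  write_dosage_tsv(geno_ref, ref_file)
  utils::write.table(ped, ped_file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (is.function(tool)) {
    tool(ld_file, ref_file, ped_file, out_file)
  } else if (is.character(tool)) {
    cmd <- gsub("{ld}", ld_file, tool, fixed = TRUE)
    cmd <- gsub("{ref}", ref_file, cmd, fixed = TRUE)
    cmd <- gsub("{ped}", ped_file, cmd, fixed = TRUE)
    cmd <- gsub("{out}", out_file, cmd, fixed = TRUE)
    exe <- strsplit(trimws(cmd), "\\s+")[[1]][1]
    if (Sys.which(exe) == "" && !file.exists(exe)) {
      stop("external imputation tool not found: ", exe, " (skipping)")
    }
    status <- system(cmd)
    if (status != 0) stop("external imputer exited with status ", status)
  } else {
    stop("tool must be a function or a command template")
  }
  if (!file.exists(out_file)) stop("external imputer produced no output file")
  imp <- read_dosage_tsv(out_file)
  if (!identical(dim(imp), dim(unclass(geno_ld))) ||
    !identical(colnames(imp), colnames(geno_ld)) ||
    !identical(rownames(imp), rownames(geno_ld))) {
    stop("external imputer output does not match the target dimensions/ids")
  }
  if (anyNA(imp)) stop("external imputer output is incomplete (missing genotypes remain)")
  obs <- !is.na(unclass(geno_ld))
  if (!all(imp[obs] == unclass(geno_ld)[obs])) {
    stop("external imputer altered observed genotypes")
  }
  prov <- matrix("external", nrow(imp), ncol(imp), dimnames = dimnames(imp))
  prov[obs] <- "observed"
  structure(list(geno = geno_matrix(imp), provenance = prov),
    class = "imputed_genotypes"
  )
}

write_dosage_tsv <- function(geno, path) {
  df <- data.frame(id = rownames(geno), unclass(geno), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
}

read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
    colClasses = "character"
  )
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Switch-error rate of inferred haplotypes against the truth
#'
#' For each individual and chromosome, the inferred haplotype pair is
#' compared with the true pair at heterozygous sites; after choosing the
#' orientation that matches the first heterozygous site, every change of
#' matching haplotype along the chromosome counts as one switch error. The
#' rate divides switches by the number of heterozygous-site transitions.
#'
#' @param inferred,truth `phased_haps` over the same individuals and SNPs.
#' @return A tibble `id`, `chrom`, `n_het`, `n_switches`, `rate`.
#' @export
switch_error_rate <- function(inferred, truth) {
  stopifnot(
    identical(rownames(inferred$hap1), rownames(truth$hap1)),
    identical(colnames(inferred$hap1), colnames(truth$hap1))
  )
  map <- inferred$map
  res <- list()
  for (cn in unique(map$chrom)) {
    cols <- which(map$chrom == cn)
    for (i in seq_len(nrow(inferred$hap1))) {
      gi <- inferred$hap1[i, cols] + inferred$hap2[i, cols]
      het <- which(gi == 1L)
      n_sw <- 0L
      if (length(het) >= 2L) {
        # at a het site, inferred hap1 carries the allele of true hap1 or hap2
        match1 <- inferred$hap1[i, cols][het] == truth$hap1[i, cols][het]
        n_sw <- sum(diff(match1) != 0L)
      }
      res[[length(res) + 1L]] <- tibble::tibble(
        id = rownames(inferred$hap1)[i], chrom = cn,
        n_het = length(het), n_switches = n_sw,
        rate = if (length(het) >= 2L) n_sw / (length(het) - 1L) else NA_real_
      )
    }
  }
  dplyr::bind_rows(res)
}

#' Refine parent phasing using offspring gamete paths
#'
#' A switch error in a parent's inferred haplotypes makes the gamete-origin
#' path of every one of its offspring change state at that same position,
#' whereas genuine crossovers fall at offspring-specific positions. For each
#' parent and chromosome, the offspring's decoded paths are overlaid: any
#' position where at least `min_fraction` of the path-informative offspring
#' place a state switch (and at least `min_offspring` offspring are
#' informative there) is called a phase-switch error, and the parent's
#' haplotypes are flipped from that position onward. The scan repeats until
#' no position qualifies. Offspring genotyped at low density carry enough
#' informative markers to anchor this even for sparse panels.
#'
#' @param parent_haps `phased_haps` for the parents (from [phase_parents()]).
#' @param offspring_ld Masked offspring genotype matrix (the imputation
#'   targets).
#' @param ped Pedigree linking offspring to parents.
#' @param switch_penalty,mismatch_penalty Passed to [infer_gamete_origin()].
#' @param min_fraction Minimum fraction of informative offspring whose paths
#'   must switch at a position to call a parent phase error (default 0.5).
#' @param min_offspring Minimum number of informative offspring (default 5).
#' @param max_iter Maximum flips per parent and chromosome (default 20).
#' @return The corrected `phased_haps`.
#' @export
refine_parent_phase <- function(parent_haps, offspring_ld, ped,
                                switch_penalty = 3, mismatch_penalty = 1,
                                min_fraction = 0.5, min_offspring = 5,
                                max_iter = 20) {
  g_off <- unclass(as_geno(offspring_ld))
  map <- parent_haps$map
  stopifnot(identical(colnames(g_off), map$snp))
  parent_geno <- haps_to_geno(parent_haps)
  h1 <- parent_haps$hap1
  h2 <- parent_haps$hap2
  parents <- rownames(h1)
  pk <- ped[match(rownames(g_off), ped$id), ]
  chrom_cols <- split(seq_len(ncol(g_off)), factor(map$chrom, levels = unique(map$chrom)))

  for (p in parents) {
    as_sire <- which(pk$sire == p)
    as_dam <- which(pk$dam == p)
    kids <- c(as_sire, as_dam)
    other <- c(pk$dam[as_sire], pk$sire[as_dam])
    keep <- other %in% parents
    kids <- kids[keep]
    other <- other[keep]
    if (length(kids) < min_offspring) next
    for (cols in chrom_cols) {
      m_c <- length(cols)
      for (it in seq_len(max_iter)) {
        # per-marker tallies: how many offspring paths span / switch here
        spanned <- integer(m_c)
        switched <- integer(m_c)
        sw_lo <- rep(m_c + 1L, 1)  # intersection bounds of the modal switch
        for (ki in seq_along(kids)) {
          path <- infer_gamete_origin(
            g_off[kids[ki], cols], h1[p, cols], h2[p, cols],
            parent_geno[other[ki], cols],
            switch_penalty = switch_penalty, mismatch_penalty = mismatch_penalty
          )
          info <- path$informative
          if (length(info) < 2L) next
          spanned[info[1]:info[length(info)]] <- spanned[info[1]:info[length(info)]] + 1L
          sw <- which(diff(path$states) != 0L)
          for (s in sw) {
            lo <- info[s] + 1L
            hi <- info[s + 1L]
            switched[lo:hi] <- switched[lo:hi] + 1L
          }
        }
        ok <- spanned >= min_offspring & switched / pmax(spanned, 1L) >= min_fraction
        if (!any(ok)) break
        # flip from the centre of the best-supported run of positions
        frac <- ifelse(spanned > 0, switched / spanned, 0)
        best <- which(ok)[which.max(frac[ok])]
        run <- ok & cumsum(!ok) == cumsum(!ok)[best]   # contiguous run containing best
        flip_at <- floor((min(which(run)) + max(which(run))) / 2)
        idx <- cols[flip_at:m_c]
        tmp <- h1[p, idx]
        h1[p, idx] <- h2[p, idx]
        h2[p, idx] <- tmp
      }
    }
  }
  phased_haps(h1, h2, map)
}
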