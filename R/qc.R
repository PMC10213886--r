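#' Quality-control thresholds
#'
#' Defaults match routine SNP-array QC in aquaculture genomic selection:
#' individuals are dropped above 20% missing genotypes or when exactly one of
#' their two parents is genotyped; SNPs are dropped above 10% missingness,
#' below the exact Hardy-Weinberg p-value 1e-6, below 5% minor allele
#' frequency, or above a 10% Mendelian error rate. All comparisons are
#' strict, so boundary values are kept.
#'
#' @param ind_missing_max Maximum tolerated per-individual missing fraction.
#' @param snp_missing_max Maximum tolerated per-SNP missing fraction.
#' @param hwe_p_min Minimum exact Hardy-Weinberg p-value.
#' @param maf_min Minimum minor allele frequency.
#' @param mendel_rate_max Maximum per-SNP Mendelian error rate.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(ind_missing_max = 0.20, snp_missing_max = 0.10,
                          hwe_p_min = 1e-6, maf_min = 0.05,
                          mendel_rate_max = 0.10) {
  th <- list(
    ind_missing_max = ind_missing_max, snp_missing_max = snp_missing_max,
    hwe_p_min = hwe_p_min, maf_min = maf_min, mendel_rate_max = mendel_rate_max
  )
  fr <- unlist(th[c("ind_missing_max", "snp_missing_max", "maf_min", "mendel_rate_max")])
  if (any(fr < 0 | fr > 1)) stop("fraction thresholds must lie in [0, 1]")
  if (hwe_p_min <= 0 || hwe_p_min >= 1) stop("hwe_p_min must lie in (0, 1)")
  structure(th, class = "qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test: given the allele counts, the p-value is the summed
#' probability of all heterozygote counts whose probability under the exact
#' sampling distribution does not exceed that of the observed count
#' (Wigginton-style). Monomorphic sites return 1 by convention.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (non-negative, total > 0).
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts))) stop("counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("total genotype count must be positive")
  n_a <- 2 * n_hom_alt + n_het     # alt allele count
  n_rare <- min(n_a, 2 * n - n_a)
  if (n_rare == 0) return(1)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  # log P(het | n, rare allele count), multinomial over genotypes / hypergeometric over alleles
  hom_rare <- (n_rare - hets) / 2
  hom_common <- n - hets - hom_rare
  logp <- lgamma(n + 1) - lgamma(hom_rare + 1) - lgamma(hets + 1) -
    lgamma(hom_common + 1) + hets * log(2) -
    (lgamma(2 * n + 1) - lgamma(n_rare + 1) - lgamma(2 * n - n_rare + 1))
  prob <- exp(logp)
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_het, hets)]
  if (is.na(p_obs)) stop("heterozygote count incompatible with allele counts")
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

# 3x3 lookup of offspring dosages possible for each (sire, dam) dosage pair
mendel_possible <- local({
  allowed <- array(FALSE, dim = c(3, 3, 3))
  gametes <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  for (s in 0:2) for (d in 0:2) {
    kids <- unique(outer(gametes[[s + 1]], gametes[[d + 1]], `+`))
    allowed[s + 1, d + 1, kids + 1] <- TRUE
  }
  allowed
})

#' Mendelian error rates per SNP and per trio
#'
#' An error is an offspring genotype impossible given the two parental
#' genotypes (e.g. 0 x 0 parents with an offspring carrying the alternate
#' allele). Comparisons with any missing genotype in the trio are skipped.
#' Genotypes are reported, never altered.
#'
#' @param geno Genotype matrix covering offspring and their parents.
#' @param ped Pedigree; trios are offspring with both parents genotyped.
#' @return A list with tibbles `per_snp` (`snp`, `n_errors`,
#'   `n_informative`, `rate`) and `per_trio` (`id`, `n_errors`,
#'   `n_informative`, `rate`). If no complete trio exists, both tibbles are
#'   empty and a warning is raised.
#' @export
mendelian_error_rate <- function(geno, ped) {
  geno <- as_geno(geno)
  kids <- ped_offspring(ped)
  kids <- kids[kids %in% rownames(geno)]
  pk <- ped[match(kids, ped$id), ]
  ok <- pk$sire %in% rownames(geno) & pk$dam %in% rownames(geno)
  pk <- pk[ok, ]
  if (nrow(pk) == 0L) {
    warning("no complete trios; Mendelian error rates unavailable")
    empty <- tibble::tibble(n_errors = integer(), n_informative = integer(), rate = double())
    return(list(
      per_snp = dplyr::bind_cols(tibble::tibble(snp = character()), empty),
      per_trio = dplyr::bind_cols(tibble::tibble(id = character()), empty)
    ))
  }
  o <- geno[pk$id, , drop = FALSE]
  s <- geno[pk$sire, , drop = FALSE]
  d <- geno[pk$dam, , drop = FALSE]
  informative <- !is.na(o) & !is.na(s) & !is.na(d)
  err <- matrix(FALSE, nrow(o), ncol(o))
  idx <- which(informative)
  err[idx] <- !mendel_possible[cbind(s[idx] + 1L, d[idx] + 1L, o[idx] + 1L)]
  rate_tbl <- function(errs, infs) {
    tibble::tibble(
      n_errors = as.integer(errs), n_informative = as.integer(infs),
      rate = unname(ifelse(infs > 0, errs / infs, NA_real_))
    )
  }
  list(
    per_snp = dplyr::bind_cols(
      tibble::tibble(snp = colnames(geno)),
      rate_tbl(colSums(err), colSums(informative))
    ),
    per_trio = dplyr::bind_cols(
      tibble::tibble(id = pk$id),
      rate_tbl(rowSums(err), rowSums(informative))
    )
  )
}

#' Filter individuals on missingness and parent genotyping
#'
#' Removes individuals whose missing-genotype fraction exceeds
#' `th$ind_missing_max`, and offspring for which exactly one of the two
#' pedigree parents is genotyped (such half-anchored individuals cannot be
#' imputed reliably from the family). Parents (pedigree founders) are never
#' removed by the one-parent rule. Missingness is assessed on the raw input,
#' before any SNP filtering.
#'
#' @param geno Genotype matrix.
#' @param ped Pedigree covering the genotyped individuals.
#' @param th A [qc_thresholds()].
#' @return A list of class `qc_report` with `individuals` (tibble `id`,
#'   `missing_frac`, `n_parents_genotyped`, `kept`, `reason`) and `geno`
#'   (the kept subset).
#' @export
filter_individuals <- function(geno, ped, th = qc_thresholds()) {
  if (NROW(geno) == 0L || NCOL(geno) == 0L) stop("empty genotype matrix")
  geno <- as_geno(geno)
  ids <- rownames(geno)
  if (!all(ids %in% ped$id)) stop("pedigree must cover all genotyped individuals")
  pd <- ped[match(ids, ped$id), ]
  miss <- rowMeans(is.na(geno))
  is_offspring <- !is.na(pd$sire)
  npar <- ifelse(is_offspring,
    (pd$sire %in% ids) + (pd$dam %in% ids), NA_integer_
  )
  reason <- rep(NA_character_, length(ids))
  reason[miss > th$ind_missing_max] <- "missingness"
  one_parent <- is_offspring & !is.na(npar) & npar == 1L
  reason[is.na(reason) & one_parent] <- "one-parent"
  kept <- is.na(reason)
  report <- tibble::tibble(
    id = ids, missing_frac = miss, n_parents_genotyped = as.integer(npar),
    kept = kept, reason = reason
  )
  structure(
    list(individuals = report, geno = geno[kept, , drop = FALSE]),
    class = "qc_report"
  )
}

snp_qc_table <- function(geno, ped) {
  miss <- colMeans(is.na(geno))
  p <- allele_freqs(geno)
  mafs <- pmin(p, 1 - p)
  hwe <- vapply(seq_len(ncol(geno)), function(j) {
    g <- geno[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0L) return(1)
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, numeric(1))
  mend <- suppressWarnings(mendelian_error_rate(geno, ped)$per_snp)
  tibble::tibble(
    snp = colnames(geno), missing_frac = miss, hwe_p = hwe, maf = mafs,
    mendel_rate = mend$rate[match(colnames(geno), mend$snp)]
  )
}

#' Filter SNPs on missingness, Hardy-Weinberg, MAF and Mendelian errors
#'
#' Every criterion is computed on the input data (not sequentially
#' re-estimated), and the reported removal reason is the first failing
#' criterion in the order missingness, HWE, MAF, Mendelian error.
#'
#' @param geno Genotype matrix.
#' @param map Marker map covering the genotype columns.
#' @param ped Pedigree (for Mendelian error rates).
#' @param th A [qc_thresholds()].
#' @return A list of class `qc_report` with `snps` (tibble `snp`,
#'   `missing_frac`, `hwe_p`, `maf`, `mendel_rate`, `kept`, `reason`),
#'   `geno` (kept subset) and `map` (kept subset).
#' @export
filter_snps <- function(geno, map, ped, th = qc_thresholds()) {
  geno <- as_geno(geno)
  if (!all(colnames(geno) %in% map$snp)) stop("map must cover all genotyped SNPs")
  tab <- snp_qc_table(geno, ped)
  reason <- rep(NA_character_, nrow(tab))
  reason[tab$missing_frac > th$snp_missing_max] <- "missingness"
  reason[is.na(reason) & tab$hwe_p < th$hwe_p_min] <- "hwe"
  reason[is.na(reason) & tab$maf < th$maf_min] <- "maf"
  reason[is.na(reason) & !is.na(tab$mendel_rate) &
    tab$mendel_rate > th$mendel_rate_max] <- "mendel"
  kept <- is.na(reason)
  tab$kept <- kept
  tab$reason <- reason
  keep_snps <- tab$snp[kept]
  structure(
    list(
      snps = tab,
      geno = geno[, keep_snps, drop = FALSE],
      map = map[map$snp %in% keep_snps, ]
    ),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  if (!is.null(x$individuals)) {
    cat(sprintf(
      "<qc_report> individuals: %d kept / %d removed\n",
      sum(x$individuals$kept), sum(!x$individuals$kept)
    ))
    if (any(!x$individuals$kept)) {
      print(dplyr::count(x$individuals[!x$individuals$kept, ], .data$reason))
    }
  }
  if (!is.null(x$snps)) {
    cat(sprintf(
      "<qc_report> SNPs: %d kept / %d removed\n",
      sum(x$snps$kept), sum(!x$snps$kept)
    ))
    if (any(!x$snps$kept)) print(dplyr::count(x$snps[!x$snps$kept, ], .data$reason))
  }
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.qc_report <- function(x, ...) {
  parts <- list()
  if (!is.null(x$individuals)) {
    parts$individuals <- dplyr::mutate(
      tidyr::pivot_longer(x$individuals, -c("id", "kept", "reason"),
        names_to = "metric", values_to = "value"
      ),
      unit = "individual"
    ) |> dplyr::rename(item = "id")
  }
  if (!is.null(x$snps)) {
    parts$snps <- dplyr::mutate(
      tidyr::pivot_longer(x$snps, -c("snp", "kept", "reason"),
        names_to = "metric", values_to = "value"
      ),
      unit = "snp"
    ) |> dplyr::rename(item = "snp")
  }
  dplyr::bind_rows(parts)
}

#' Re-filter on MAF after imputation
#'
#' Random filling of poorly anchored genotypes can push rare SNPs below the
#' usable frequency range, so the MAF filter is applied once more on the
#' complete imputed matrix before building the GRM.
#'
#' @param geno Complete (imputed) genotype matrix.
#' @param maf_min Minimum minor allele frequency; strictly smaller is removed.
#' @return The genotype matrix restricted to SNPs with MAF >= `maf_min`;
#'   errors if nothing survives.
#' @export
post_imputation_maf_filter <- function(geno, maf_min = 0.05) {
  geno <- as_geno(geno)
  if (anyNA(geno)) stop("post-imputation filter expects complete genotypes")
  keep <- maf(geno) >= maf_min
  if (!any(keep)) stop("no SNPs left after post-imputation MAF filter")
  geno[, keep, drop = FALSE]
}
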