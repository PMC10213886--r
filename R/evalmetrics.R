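masked_site_matrix <- function(truth, masked) {
  if (is.matrix(masked)) {
    stopifnot(identical(dim(masked), dim(unclass(truth))))
    return(masked)
  }
  # masked given as a list of per-individual SNP-id sets
  out <- matrix(FALSE, nrow(truth), ncol(truth), dimnames = dimnames(truth))
  for (id in names(masked)) out[id, masked[[id]]] <- TRUE
  out
}

#' Per-individual imputation accuracy
#'
#' The headline imputation statistic: for every target individual, the
#' Pearson correlation between true and imputed dosages over that
#' individual's masked sites only (observed panel SNPs are excluded by
#' default, so the statistic is not inflated by genotypes that were never
#' imputed; set `include_observed = TRUE` for the alternative convention).
#' Individuals whose truth or imputed vector has zero variance have an
#' undefined correlation; they are recorded as `NA`, excluded from the mean
#' and counted.
#'
#' @param truth Complete true genotype matrix of the targets.
#' @param imputed An `imputed_genotypes` object or a complete matrix.
#' @param masked Logical matrix marking the masked (imputed) entries, or a
#'   named list of per-individual masked SNP-id vectors. Defaults to the
#'   entries not tagged `observed` in `imputed`'s provenance.
#' @param include_observed If `TRUE`, compute correlations over all sites.
#' @return A list of class `imputation_accuracy` with `per_individual`
#'   (tibble `id`, `n_masked`, `r`), `mean`, `sd` and `n_undefined`.
#' @export
per_individual_accuracy <- function(truth, imputed, masked = NULL,
                                    include_observed = FALSE) {
  truth <- as_geno(truth)
  imp <- if (inherits(imputed, "imputed_genotypes")) imputed$geno else as_geno(imputed)
  imp <- imp[rownames(truth), colnames(truth), drop = FALSE]
  if (is.null(masked)) {
    if (!inherits(imputed, "imputed_genotypes")) {
      stop("masked sites must be supplied unless `imputed` carries provenance")
    }
    masked <- imputed$provenance[rownames(truth), colnames(truth), drop = FALSE] != "observed"
  } else {
    masked <- masked_site_matrix(truth, masked)
  }
  if (include_observed) masked[] <- TRUE
  r <- vapply(seq_len(nrow(truth)), function(i) {
    sel <- masked[i, ]
    x <- unclass(truth)[i, sel]
    y <- unclass(imp)[i, sel]
    if (sum(sel) < 2L || stats::var(x) == 0 || stats::var(y) == 0) {
      return(NA_real_)
    }
    stats::cor(x, y)
  }, numeric(1))
  per_ind <- tibble::tibble(
    id = rownames(truth), n_masked = unname(rowSums(masked)), r = r
  )
  structure(
    list(
      per_individual = per_ind,
      mean = mean(r, na.rm = TRUE),
      sd = stats::sd(r, na.rm = TRUE),
      n_undefined = sum(is.na(r))
    ),
    class = "imputation_accuracy"
  )
}

#' @export
print.imputation_accuracy <- function(x, ...) {
  cat(sprintf(
    "<imputation_accuracy> mean r = %.4f (sd %.4f) over %d individuals (%d undefined)\n",
    x$mean, x$sd, nrow(x$per_individual), x$n_undefined
  ))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.imputation_accuracy <- function(x, ...) x$per_individual

#' @rdname tidiers
#' @export
glance.imputation_accuracy <- function(x, ...) {
  tibble::tibble(
    mean_r = x$mean, sd_r = x$sd,
    n_individuals = nrow(x$per_individual), n_undefined = x$n_undefined
  )
}

#' Per-SNP imputation concordance
#'
#' Percentage of masked genotypes imputed exactly equal to the truth, per
#' SNP. Panel SNPs (zero masked observations among the targets) are
#' reported with `on_panel = TRUE` and concordance 100 by construction.
#'
#' @inheritParams per_individual_accuracy
#' @return A tibble `snp`, `n_masked`, `pct_correct`, `on_panel`.
#' @export
per_snp_concordance <- function(truth, imputed, masked = NULL) {
  truth <- as_geno(truth)
  imp <- if (inherits(imputed, "imputed_genotypes")) imputed$geno else as_geno(imputed)
  imp <- imp[rownames(truth), colnames(truth), drop = FALSE]
  if (is.null(masked)) {
    masked <- imputed$provenance[rownames(truth), colnames(truth), drop = FALSE] != "observed"
  } else {
    masked <- masked_site_matrix(truth, masked)
  }
  agree <- (unclass(truth) == unclass(imp)) & masked
  n_masked <- colSums(masked)
  tibble::tibble(
    snp = colnames(truth),
    n_masked = unname(n_masked),
    pct_correct = unname(ifelse(n_masked > 0, 100 * colSums(agree) / n_masked, 100)),
    on_panel = unname(n_masked == 0)
  )
}

#' Imputation accuracy by minor-allele-frequency bin
#'
#' Per-SNP truth-vs-imputed correlations over masked genotypes, grouped
#' into the five MAF bins (0,0.1], (0.1,0.2], (0.2,0.3], (0.3,0.4],
#' (0.4,0.5] (half-open on the left, closed on the right, so MAF = 0.1
#' falls in the first bin). SNPs with MAF 0 are excluded with a warning.
#'
#' @inheritParams per_individual_accuracy
#' @param freqs Per-SNP minor allele frequencies (named); default computed
#'   from the truth matrix.
#' @return A list with `per_snp` (tibble `snp`, `maf`, `bin`, `r`) and
#'   `per_bin` (tibble `bin`, `n_snps`, `mean_r`, `sd_r`, `iqr_r`).
#' @export
maf_binned_accuracy <- function(truth, imputed, masked = NULL, freqs = NULL) {
  truth <- as_geno(truth)
  imp <- if (inherits(imputed, "imputed_genotypes")) imputed$geno else as_geno(imputed)
  imp <- imp[rownames(truth), colnames(truth), drop = FALSE]
  if (is.null(masked)) {
    masked <- imputed$provenance[rownames(truth), colnames(truth), drop = FALSE] != "observed"
  } else {
    masked <- masked_site_matrix(truth, masked)
  }
  if (is.null(freqs)) freqs <- maf(truth)
  freqs <- freqs[colnames(truth)]
  if (any(freqs == 0)) {
    warning(sum(freqs == 0), " monomorphic SNPs excluded from MAF-binned accuracy")
  }
  edges <- seq(0, 0.5, by = 0.1)
  labels <- sprintf("(%.1f,%.1f]", edges[-6], edges[-1])
  r <- vapply(seq_len(ncol(truth)), function(j) {
    sel <- masked[, j]
    if (sum(sel) < 2L) return(NA_real_)
    x <- unclass(truth)[sel, j]
    y <- unclass(imp)[sel, j]
    if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  per_snp <- tibble::tibble(
    snp = colnames(truth), maf = unname(freqs),
    bin = cut(freqs, breaks = edges, labels = labels, right = TRUE),
    r = r
  ) |> dplyr::filter(.data$maf > 0)
  per_bin <- per_snp |>
    dplyr::filter(!is.na(.data$r)) |>
    dplyr::summarise(
      n_snps = dplyr::n(),
      mean_r = mean(.data$r),
      sd_r = stats::sd(.data$r),
      iqr_r = stats::IQR(.data$r),
      .by = "bin"
    ) |>
    dplyr::arrange(.data$bin)
  list(per_snp = per_snp, per_bin = per_bin)
}

#' Plot per-individual imputation accuracy
#'
#' @param object An `imputation_accuracy` object.
#' @param ... Unused.
#' @return A ggplot: histogram of per-individual correlations with the mean
#'   marked.
#' @export
autoplot.imputation_accuracy <- function(object, ...) {
  df <- dplyr::filter(object$per_individual, !is.na(.data$r))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$mean, linetype = 2) +
    ggplot2::labs(
      x = "per-individual imputation accuracy (Pearson r)",
      y = "individuals"
    )
}
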