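#' Genomic relationship matrix
#'
#' VanRaden-style GRM averaged over standardized SNPs:
#' `g_jk = (1/N) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`,
#' with the reference-allele frequency `p_i` estimated from the supplied
#' genotypes. Monomorphic SNPs carry no information and are excluded with a
#' warning; residual missing genotypes are mean-imputed with a message.
#'
#' @param geno Complete (post-QC, post-imputation-filter) genotype matrix.
#' @return A symmetric matrix of class `grm` with attributes `freqs` (the
#'   allele frequencies used) and `n_snps`.
#' @export
compute_grm <- function(geno) {
  geno <- as_geno(geno)
  x <- unclass(geno)
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    message("mean-imputing ", sum(is.na(x)), " residual missing genotypes for the GRM")
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  p <- colMeans(x) / 2
  poly <- p > 0 & p < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic SNPs excluded from the GRM")
    x <- x[, poly, drop = FALSE]
    p <- p[poly]
  }
  if (ncol(x) == 0L) stop("no polymorphic SNPs available for the GRM")
  z <- sweep(x, 2, 2 * p)
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), `/`)
  G <- tcrossprod(z) / ncol(x)
  attr(G, "freqs") <- p
  attr(G, "n_snps") <- ncol(x)
  class(G) <- c("grm", class(G))
  G
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf(
    "<grm> %d individuals from %d SNPs; mean diagonal %.3f\n",
    nrow(x), attr(x, "n_snps"), mean(diag(x))
  ))
  invisible(x)
}

grm_eigen <- function(G, jitter_tol = 1e-8, jitter = 1e-6) {
  eig <- eigen(unclass(G), symmetric = TRUE)
  if (min(eig$values) < jitter_tol) {
    # semidefinite up to round-off is routine (GRM rank <= SNPs); only a
    # materially indefinite matrix is worth reporting
    if (min(eig$values) < -1e-6) {
      message(sprintf(
        "GRM smallest eigenvalue %.2e; adding %.0e to the diagonal",
        min(eig$values), jitter
      ))
    }
    eig$values <- eig$values + jitter
  }
  eig
}

build_design <- function(data, formula) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("fixed-effects design is singular; collinear columns: ",
      paste(bad, collapse = ", "))
  }
  list(y = as.numeric(y), X = X)
}

#' REML variance components for the GBLUP model
#'
#' Fits `y = X b + a + e` with `a ~ N(0, G sigma_a^2)` and
#' `e ~ N(0, I sigma_e^2)` by restricted maximum likelihood. The GRM is
#' eigendecomposed once; on the rotated data the covariance is diagonal in
#' the variance ratio, so the REML log-likelihood is profiled and maximized
#' over `h2 = sigma_a^2 / (sigma_a^2 + sigma_e^2)` on \[1e-6, 1 - 1e-6\] by
#' one-dimensional optimization.
#'
#' @param data Tibble with an `id` column, the response and any fixed-effect
#'   columns; rows must be individuals present in `G`.
#' @param G GRM covering (at least) `data$id`.
#' @param formula Fixed-effects formula, default `phenotype ~ 1`.
#' @param eig Optional precomputed `eigen()` of the `G` submatrix for
#'   `data$id` (in `data$id` order), reused across repeated fits.
#' @return An object of class `reml_fit`: `sigma_a2`, `sigma_e2`, `h2`,
#'   `loglik` (REML), `beta`, `converged`, `n`, plus the rotated data
#'   needed by [gblup_predict()].
#' @export
reml_fit <- function(data, G, formula = phenotype ~ 1, eig = NULL) {
  ids <- data$id
  if (is.null(ids)) stop("`data` must carry an `id` column")
  if (!all(ids %in% rownames(G))) stop("all ids must appear in the GRM")
  des <- build_design(data, formula)
  y <- des$y
  X <- des$X
  n <- length(y)
  p <- ncol(X)
  if (is.null(eig)) eig <- grm_eigen(unclass(G)[ids, ids])
  U <- eig$vectors
  d <- eig$values
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)

  profile <- function(h2) {
    w <- h2 * d + (1 - h2)
    wi <- 1 / w
    XtWX <- crossprod(Xs, Xs * wi)
    XtWy <- crossprod(Xs, ys * wi)
    b <- solve(XtWX, XtWy)
    r <- ys - Xs %*% b
    s2 <- sum(r^2 * wi) / (n - p)
    ll <- -0.5 * ((n - p) * log(s2) + sum(log(w)) +
      determinant(XtWX, logarithm = TRUE)$modulus + (n - p))
    list(ll = as.numeric(ll), b = b, s2 = s2)
  }
  opt <- stats::optimize(function(h2) profile(h2)$ll,
    interval = c(1e-6, 1 - 1e-6), maximum = TRUE, tol = 1e-8
  )
  h2 <- opt$maximum
  prof <- profile(h2)
  structure(
    list(
      sigma_a2 = h2 * prof$s2, sigma_e2 = (1 - h2) * prof$s2, h2 = h2,
      loglik = prof$ll, beta = stats::setNames(as.numeric(prof$b), colnames(X)),
      converged = TRUE, n = n, formula = formula, ids = ids
    ),
    class = "reml_fit"
  )
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf(
    "<reml_fit> n=%d  sigma_a2=%.4f  sigma_e2=%.4f  h2=%.3f  REML logLik=%.2f\n",
    x$n, x$sigma_a2, x$sigma_e2, x$h2, x$loglik
  ))
  invisible(x)
}

#' Broom-style tidiers
#'
#' `tidy()` returns the per-term or per-item table of an aquaimpute result
#' object; `glance()` returns its one-row summary.
#'
#' @param x A fitted/result object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.reml_fit <- function(x, ...) {
  tibble::tibble(
    term = c("sigma_a2", "sigma_e2", "h2"),
    estimate = c(x$sigma_a2, x$sigma_e2, x$h2)
  )
}

#' @rdname tidiers
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(
    h2 = x$h2, sigma_a2 = x$sigma_a2, sigma_e2 = x$sigma_e2,
    logLik = x$loglik, n = x$n, converged = x$converged
  )
}

#' Predict breeding values for validation individuals by GBLUP
#'
#' Fits (or reuses) REML variance components on the training individuals
#' and returns the BLUP breeding values of the validation individuals,
#' `a_v = sigma_a^2 G_vt V^{-1} (y_t - X_t b)` with
#' `V = sigma_a^2 G_tt + sigma_e^2 I` -- the mixed-model solutions at the
#' REML estimates. Training EBVs are returned as well.
#'
#' @param data Phenotype tibble for the *training* individuals (`id`,
#'   response, fixed effects). Validation phenotypes are not used.
#' @param G GRM covering training and validation individuals.
#' @param validation_ids Ids (in `G`) to predict.
#' @param formula Fixed-effects formula.
#' @param fit Optional `reml_fit` on the training data to reuse.
#' @return A tibble `id`, `ebv`, `set` (`"training"`/`"validation"`).
#' @export
gblup_predict <- function(data, G, validation_ids, formula = phenotype ~ 1,
                          fit = NULL) {
  if (!all(validation_ids %in% rownames(G))) {
    stop("validation individuals missing from the GRM")
  }
  train_ids <- setdiff(data$id, validation_ids)
  data_t <- data[data$id %in% train_ids, ]
  if (is.null(fit)) fit <- reml_fit(data_t, G, formula = formula)
  des <- build_design(data_t, formula)
  Gm <- unclass(G)
  Gtt <- Gm[data_t$id, data_t$id]
  V <- fit$sigma_a2 * Gtt + diag(fit$sigma_e2, nrow(Gtt))
  resid <- des$y - as.numeric(des$X %*% fit$beta)
  alpha <- solve(V, resid)
  ebv_t <- fit$sigma_a2 * as.numeric(Gtt %*% alpha)
  ebv_v <- fit$sigma_a2 * as.numeric(Gm[validation_ids, data_t$id, drop = FALSE] %*% alpha)
  dplyr::bind_rows(
    tibble::tibble(id = data_t$id, ebv = ebv_t, set = "training"),
    tibble::tibble(id = validation_ids, ebv = ebv_v, set = "validation")
  )
}

#' Genomic prediction accuracy
#'
#' The cross-validation statistic: Pearson correlation between predicted
#' breeding values and observed phenotypes of the validation set, divided
#' by the square root of the heritability estimated once from the full
#' dataset.
#'
#' @param ebv_val Predicted breeding values.
#' @param y_val Observed validation phenotypes.
#' @param h2_full Full-data heritability estimate (> 0).
#' @return The accuracy `cor(ebv, y) / sqrt(h2_full)`.
#' @export
prediction_accuracy <- function(ebv_val, y_val, h2_full) {
  if (!is.finite(h2_full) || h2_full <= 0) {
    stop("h2_full must be a positive heritability estimate")
  }
  stats::cor(ebv_val, y_val) / sqrt(h2_full)
}

#' Replicated k-fold cross-validation of GBLUP prediction accuracy
#'
#' For each replicate, phenotyped individuals are partitioned uniformly at
#' random into `k` folds; each fold in turn is masked, variance components
#' are re-estimated on the training portion, validation breeding values are
#' predicted by GBLUP and the fold's [prediction_accuracy()] is recorded.
#' Accuracies are averaged over all replicate-by-fold values (when folds
#' are singletons the predictions of a replicate are pooled instead, since
#' a per-fold correlation is undefined).
#'
#' @param data Phenotype tibble (`id`, response, fixed-effect columns).
#' @param G GRM covering `data$id` (built once from the chosen marker
#'   panel; allele frequencies are not re-estimated per fold).
#' @param formula Fixed-effects formula.
#' @param k Number of folds (default 5).
#' @param reps Number of replicates (default 20).
#' @param h2_full Full-data heritability for the accuracy denominator;
#'   default re-estimated from `data` and `G`. In a multi-panel study pass
#'   the HD-panel estimate so all panels share one denominator.
#' @param seed Integer seed; fold draws are deterministic given the seed.
#' @return An object of class `gblup_cv`: `results` (tibble `rep`, `fold`,
#'   `n_val`, `accuracy`), `mean`, `sd`, `h2_full`, `folds` (assignments),
#'   `seed`.
#' @export
cross_validate <- function(data, G, formula = phenotype ~ 1, k = 5, reps = 20,
                           h2_full = NULL, seed = 1) {
  n <- nrow(data)
  if (n < k) stop("need at least k phenotyped individuals")
  if (is.null(h2_full)) h2_full <- reml_fit(data, G, formula = formula)$h2
  response <- all.vars(formula)[1]
  fold_tbl <- list()
  res <- list()
  for (r in seq_len(reps)) {
    folds <- with_substream(seed, paste0("cv_rep_", r), {
      sample(rep_len(seq_len(k), n))
    })
    fold_tbl[[r]] <- tibble::tibble(rep = r, id = data$id, fold = folds)
    singleton <- any(tabulate(folds, k) == 1L)
    pooled_ebv <- numeric(0)
    pooled_y <- numeric(0)
    for (f in seq_len(k)) {
      val_ids <- data$id[folds == f]
      y_val <- data[[response]][folds == f]
      if (length(y_val) > 1L && stats::var(y_val) == 0) {
        warning(sprintf("replicate %d fold %d has zero phenotype variance; skipped", r, f))
        next
      }
      pred <- gblup_predict(data[folds != f, ], G, val_ids, formula = formula)
      ebv_v <- pred$ebv[pred$set == "validation"][match(val_ids, pred$id[pred$set == "validation"])]
      if (singleton) {
        pooled_ebv <- c(pooled_ebv, ebv_v)
        pooled_y <- c(pooled_y, y_val)
      } else {
        res[[length(res) + 1L]] <- tibble::tibble(
          rep = r, fold = f, n_val = length(val_ids),
          accuracy = prediction_accuracy(ebv_v, y_val, h2_full)
        )
      }
    }
    if (singleton && length(pooled_y) > 1L) {
      res[[length(res) + 1L]] <- tibble::tibble(
        rep = r, fold = NA_integer_, n_val = length(pooled_y),
        accuracy = prediction_accuracy(pooled_ebv, pooled_y, h2_full)
      )
    }
  }
  results <- dplyr::bind_rows(res)
  structure(
    list(
      results = results, mean = mean(results$accuracy),
      sd = stats::sd(results$accuracy), h2_full = h2_full,
      folds = dplyr::bind_rows(fold_tbl), seed = seed
    ),
    class = "gblup_cv"
  )
}

#' @export
print.gblup_cv <- function(x, ...) {
  cat(sprintf(
    "<gblup_cv> accuracy %.3f +/- %.3f over %d replicate-fold values (h2_full = %.3f)\n",
    x$mean, x$sd, nrow(x$results), x$h2_full
  ))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.gblup_cv <- function(x, ...) x$results

#' @rdname tidiers
#' @export
glance.gblup_cv <- function(x, ...) {
  tibble::tibble(
    mean_accuracy = x$mean, sd_accuracy = x$sd,
    n_values = nrow(x$results), h2_full = x$h2_full
  )
}

#' Plot cross-validation accuracies
#'
#' @param object A `gblup_cv` object.
#' @param ... Unused.
#' @return A ggplot: per-replicate accuracy distribution.
#' @export
autoplot.gblup_cv <- function(object, ...) {
  ggplot2::ggplot(object$results, ggplot2::aes(x = factor(.data$rep), y = .data$accuracy)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean, linetype = 2) +
    ggplot2::labs(x = "replicate", y = "prediction accuracy")
}
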