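#' Configuration for a full panel-evaluation experiment
#'
#' @param population A list as returned by [sim_preset()] (fields
#'   `chromosomes`, `design`, `trait`, `switch_rate`, `n_ancestral`).
#' @param panels Tibble or data frame with columns `method`
#'   (`physical`/`genetic`/`random`) and `density`.
#' @param qc A [qc_thresholds()].
#' @param phasing `"library"` or `"oracle"` parent phasing for imputation.
#' @param cv_k,cv_reps Cross-validation folds and replicates.
#' @param cv_panels Which panel genotype sets get a cross-validation run:
#'   any of `"ld"` (masked panel without imputation) and `"imputed"`.
#' @param seed Root seed; all stage seeds derive from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(population = sim_preset("salmon_like"),
                              panels = tidyr::expand_grid(
                                method = "physical",
                                density = c(300L, 1000L, 3000L)
                              ),
                              qc = qc_thresholds(),
                              phasing = c("library", "oracle"),
                              cv_k = 5, cv_reps = 20,
                              cv_panels = c("ld", "imputed"),
                              seed = 1) {
  phasing <- match.arg(phasing)
  panels <- tibble::as_tibble(panels)
  stopifnot(all(c("method", "density") %in% names(panels)))
  bad <- setdiff(panels$method, c("physical", "genetic", "random"))
  if (length(bad)) stop("unknown panel methods: ", paste(bad, collapse = ", "))
  structure(
    list(
      population = population, panels = panels, qc = qc, phasing = phasing,
      cv_k = cv_k, cv_reps = cv_reps, cv_panels = cv_panels, seed = seed
    ),
    class = "experiment_config"
  )
}

#' Run the full panel-evaluation experiment
#'
#' Executes the complete workflow on one synthetic population: simulate,
#' quality-control, estimate the full-data heritability and the HD-panel
#' cross-validated prediction accuracy, then for every requested panel:
#' design it, mask the offspring to it, impute back to high density from
#' the phased parents, and measure imputation accuracy plus the
#' cross-validated prediction accuracy of the low-density and the imputed
#' genotypes. The whole run is deterministic given the config's root seed.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; when given, the report and per-stage
#'   tables are written as TSV.
#' @return A list of class `experiment_result`: `report` (tibble with
#'   columns `method`, `density`, `imputation`, `metric`, `mean`, `sd`,
#'   `n`), `h2_full`, `sim`, `panels`, and per-panel accuracy objects.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  pop <- config$population
  seed <- config$seed
  sim <- simulate_population(
    chromosomes = pop$chromosomes, design = pop$design, trait = pop$trait,
    n_ancestral = pop$n_ancestral, switch_rate = pop$switch_rate,
    n_proto = pop$n_proto,
    proto_switch_rate = pop$proto_switch_rate %||% 4e-7,
    sire_map_scale = pop$sire_map_scale %||% 1,
    dam_map_scale = pop$dam_map_scale %||% 1,
    seed = seed
  )

  ind_qc <- filter_individuals(sim$geno, sim$ped, config$qc)
  snp_qc <- filter_snps(ind_qc$geno, sim$map, sim$ped, config$qc)
  geno <- snp_qc$geno
  map <- snp_qc$map
  offspring <- intersect(sim$offspring, rownames(geno))
  pheno <- sim$phenotypes[sim$phenotypes$id %in% offspring, ]

  G_hd <- compute_grm(geno)
  fit_full <- reml_fit(pheno, G_hd)
  h2_full <- fit_full$h2
  report <- list()
  acc_objects <- list()
  panels <- list()

  cv_hd <- cross_validate(pheno, G_hd,
    k = config$cv_k, reps = config$cv_reps,
    h2_full = h2_full, seed = substream_seed(seed, "cv_hd")
  )
  report[[1]] <- tibble::tibble(
    method = "hd", density = ncol(geno), imputation = "none",
    metric = "cv_accuracy", mean = cv_hd$mean, sd = cv_hd$sd,
    n = nrow(cv_hd$results)
  )

  parent_haps <- if (nrow(config$panels) > 0) {
    phase_parents(
      geno[sim$parents, , drop = FALSE], map,
      method = config$phasing, truth = if (config$phasing == "oracle") sim$haps,
      seed = substream_seed(seed, "phase")
    )
  }

  for (i in seq_len(nrow(config$panels))) {
    method <- config$panels$method[i]
    density <- config$panels$density[i]
    tag <- sprintf("%s_%d", method, density)
    panel <- switch(method,
      physical = select_physical(map, density),
      genetic = select_genetic(geno, map, density),
      random = select_random(map, density, seed = substream_seed(seed, tag))
    )
    panels[[tag]] <- panel
    masked_geno <- mask_to_panel(geno, panel, offspring)
    imp <- impute_offspring(
      masked_geno[offspring, , drop = FALSE], sim$ped, parent_haps,
      seed = substream_seed(seed, paste0("imp_", tag))
    )
    acc <- per_individual_accuracy(geno[offspring, , drop = FALSE], imp)
    acc_objects[[tag]] <- acc
    report[[length(report) + 1L]] <- tibble::tibble(
      method = method, density = density, imputation = "imputed",
      metric = "imputation_accuracy", mean = acc$mean, sd = acc$sd,
      n = nrow(acc$per_individual) - acc$n_undefined
    )
    if ("ld" %in% config$cv_panels) {
      G_ld <- compute_grm(geno[, panel$snps, drop = FALSE])
      cv_ld <- cross_validate(pheno, G_ld,
        k = config$cv_k, reps = config$cv_reps,
        h2_full = h2_full, seed = substream_seed(seed, paste0("cv_ld_", tag))
      )
      report[[length(report) + 1L]] <- tibble::tibble(
        method = method, density = density, imputation = "none",
        metric = "cv_accuracy", mean = cv_ld$mean, sd = cv_ld$sd,
        n = nrow(cv_ld$results)
      )
    }
    if ("imputed" %in% config$cv_panels) {
      full_imp <- rbind(unclass(geno[sim$parents, , drop = FALSE]), unclass(imp$geno))
      imp_flt <- post_imputation_maf_filter(geno_matrix(full_imp), config$qc$maf_min)
      G_imp <- compute_grm(imp_flt)
      cv_imp <- cross_validate(pheno, G_imp,
        k = config$cv_k, reps = config$cv_reps,
        h2_full = h2_full, seed = substream_seed(seed, paste0("cv_imp_", tag))
      )
      report[[length(report) + 1L]] <- tibble::tibble(
        method = method, density = density, imputation = "imputed",
        metric = "cv_accuracy", mean = cv_imp$mean, sd = cv_imp$sd,
        n = nrow(cv_imp$results)
      )
    }
  }
  report <- dplyr::bind_rows(report)
  out <- structure(
    list(
      report = report, h2_full = h2_full, sim = sim, panels = panels,
      imputation_accuracy = acc_objects, config = config
    ),
    class = "experiment_result"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(report, file.path(out_dir, "report.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> h2_full = %.3f\n", x$h2_full))
  print(x$report, n = Inf)
  invisible(x)
}

#' Plot the prediction-accuracy curves of an experiment
#'
#' @param object An `experiment_result`.
#' @param ... Unused.
#' @return A ggplot of cross-validated accuracy against panel density, one
#'   line per panel treatment, with the HD accuracy as a dashed reference.
#' @export
autoplot.experiment_result <- function(object, ...) {
  cv <- dplyr::filter(object$report, .data$metric == "cv_accuracy", .data$method != "hd")
  hd <- dplyr::filter(object$report, .data$method == "hd")
  ggplot2::ggplot(cv, ggplot2::aes(
    x = .data$density, y = .data$mean,
    colour = paste(.data$method, .data$imputation), group = paste(.data$method, .data$imputation)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd,
        fill = paste(.data$method, .data$imputation)),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::geom_hline(yintercept = hd$mean, linetype = 2) +
    ggplot2::labs(
      x = "panel density (SNPs)", y = "prediction accuracy",
      colour = "panel", fill = "panel"
    )
}

#' Genotyping cost comparison
#'
#' Totals and percentage cost reduction when genotyping a population with a
#' low-density instead of a high-density panel.
#'
#' @param n_animals Number of animals genotyped (> 0).
#' @param cost_hd,cost_ld Per-animal genotyping costs; `cost_hd` must be
#'   positive.
#' @return A tibble `n_animals`, `cost_hd`, `cost_ld`, `total_hd`,
#'   `total_ld`, `percent_reduction`.
#' @export
cost_comparison <- function(n_animals, cost_hd, cost_ld) {
  if (n_animals <= 0) stop("n_animals must be positive")
  if (cost_hd <= 0) stop("cost_hd must be positive (reduction undefined otherwise)")
  if (cost_ld < 0) stop("costs must be non-negative")
  total_hd <- n_animals * cost_hd
  total_ld <- n_animals * cost_ld
  tibble::tibble(
    n_animals = n_animals, cost_hd = cost_hd, cost_ld = cost_ld,
    total_hd = total_hd, total_ld = total_ld,
    percent_reduction = 100 * (total_hd - total_ld) / total_hd
  )
}
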