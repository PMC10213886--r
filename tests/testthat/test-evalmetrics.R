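fake_imputed <- function(geno, provenance) {
  structure(list(geno = geno_matrix(geno), provenance = provenance),
    class = "imputed_genotypes")
}

test_that("per-individual accuracy matches hand arithmetic", {
  truth <- rbind(a = c(0L, 1L, 2L, 1L, 0L), b = c(0L, 1L, 2L, 1L, 0L))
  colnames(truth) <- sprintf("s%d", 1:5)
  imp <- rbind(a = c(0L, 1L, 2L, 0L, 1L), b = c(0L, 1L, 2L, 1L, 0L))
  colnames(imp) <- colnames(truth)
  masked <- matrix(TRUE, 2, 5, dimnames = dimnames(truth))
  rep <- per_individual_accuracy(geno_matrix(truth), geno_matrix(imp), masked)
  # direct Pearson arithmetic: cov 0.36, both variances 0.56 -> r = 9/14
  expect_equal(rep$per_individual$r[1], 9 / 14, tolerance = 1e-12)
  expect_equal(rep$per_individual$r[2], 1, tolerance = 1e-12)
  expect_equal(rep$mean, mean(c(9 / 14, 1)), tolerance = 1e-12)
  # perfect imputation: r = 1 for everyone, zero dispersion
  perfect <- per_individual_accuracy(geno_matrix(truth), geno_matrix(truth), masked)
  expect_equal(perfect$per_individual$r, c(1, 1), tolerance = 1e-12)
  expect_equal(perfect$sd, 0, tolerance = 1e-12)
})

test_that("degenerate per-individual vectors are excluded and counted", {
  truth <- rbind(a = c(1L, 1L, 1L, 1L), b = c(0L, 1L, 2L, 0L))
  colnames(truth) <- sprintf("s%d", 1:4)
  imp <- rbind(a = c(1L, 1L, 0L, 1L), b = c(0L, 1L, 2L, 1L))
  colnames(imp) <- colnames(truth)
  masked <- matrix(TRUE, 2, 4, dimnames = dimnames(truth))
  rep <- per_individual_accuracy(geno_matrix(truth), geno_matrix(imp), masked)
  expect_true(is.na(rep$per_individual$r[1]))   # zero-variance truth
  expect_identical(rep$n_undefined, 1L)
  expect_equal(rep$mean, rep$per_individual$r[2])
})

test_that("null imputation by random fill has near-zero accuracy", {
  # constant allele frequency: any correlation would have to come from
  # individual-level information, of which a blind fill has none (a varying
  # frequency profile alone induces a positive per-individual correlation,
  # which is why the analysis reports accuracy on masked sites of real
  # panels rather than against frequency-free nulls)
  set.seed(41)
  n_sites <- 2000
  truth <- matrix(rbinom(5 * n_sites, 2, 0.5), 5,
    dimnames = list(sprintf("i%d", 1:5), sprintf("s%04d", 1:n_sites)))
  fill <- matrix(rbinom(5 * n_sites, 2, 0.5), 5, dimnames = dimnames(truth))
  masked <- matrix(TRUE, 5, n_sites, dimnames = dimnames(truth))
  rep <- per_individual_accuracy(geno_matrix(truth), geno_matrix(fill), masked)
  expect_lt(abs(rep$mean), 0.05)
  expect_true(all(abs(rep$per_individual$r) < 0.1))
})

test_that("per-SNP concordance counts exact matches and flags panel SNPs", {
  set.seed(43)
  truth <- random_geno(10, c(0.5, 0.3, 0.6))
  imp <- unclass(truth)
  imp[1:3, 2] <- (imp[1:3, 2] + 1L) %% 3L    # 3 of 10 wrong at SNP 2
  masked <- matrix(TRUE, 10, 3, dimnames = dimnames(truth))
  masked[, 3] <- FALSE                        # SNP 3 on the panel
  conc <- per_snp_concordance(truth, geno_matrix(imp), masked)
  expect_equal(conc$pct_correct, c(100, 70, 100))
  expect_identical(conc$on_panel, c(FALSE, FALSE, TRUE))
})

test_that("random-fill concordance approaches the HWE matching probability", {
  # at p = 0.5 the genotype distribution is (1/4, 1/2, 1/4); matching an
  # independent draw succeeds with probability sum of squares = 0.375
  set.seed(47)
  n <- 4000
  truth <- matrix(rbinom(n, 2, 0.5), n, 1, dimnames = list(sprintf("i%d", 1:n), "s1"))
  fill <- matrix(rbinom(n, 2, 0.5), n, 1, dimnames = dimnames(truth))
  masked <- matrix(TRUE, n, 1, dimnames = dimnames(truth))
  conc <- per_snp_concordance(geno_matrix(truth), geno_matrix(fill), masked)
  expect_equal(conc$pct_correct, 37.5, tolerance = 0.08)
})

test_that("MAF bins use half-open left, closed right edges", {
  set.seed(53)
  n <- 200
  truth <- random_geno(n, c(0.1, 0.11, 0.5, 0.3),
    snps = c("s1", "s2", "s3", "s4"))
  freqs <- c(s1 = 0.1, s2 = 0.10001, s3 = 0.5, s4 = 0.3)
  imp <- unclass(truth)
  imp[1, ] <- (imp[1, ] + 1L) %% 3L
  masked <- matrix(TRUE, n, 4, dimnames = dimnames(truth))
  out <- maf_binned_accuracy(truth, geno_matrix(imp), masked, freqs = freqs)
  expect_identical(as.character(out$per_snp$bin[out$per_snp$snp == "s1"]), "(0.0,0.1]")
  expect_identical(as.character(out$per_snp$bin[out$per_snp$snp == "s2"]), "(0.1,0.2]")
  expect_identical(as.character(out$per_snp$bin[out$per_snp$snp == "s3"]), "(0.4,0.5]")
  # all SNPs in one bin leaves the others absent without error
  one_bin <- maf_binned_accuracy(truth[, 3, drop = FALSE],
    geno_matrix(imp[, 3, drop = FALSE]),
    masked[, 3, drop = FALSE], freqs = freqs[3])
  expect_identical(nrow(one_bin$per_bin), 1L)
  # monomorphic SNPs are excluded with a warning
  truth0 <- cbind(unclass(truth), s5 = rep(0L, n))
  imp0 <- cbind(imp, s5 = rep(0L, n))
  expect_warning(
    out0 <- maf_binned_accuracy(geno_matrix(truth0), geno_matrix(imp0),
      cbind(masked, s5 = rep(TRUE, n)), freqs = c(freqs, s5 = 0)),
    "monomorphic"
  )
  expect_false("s5" %in% out0$per_snp$snp)
})

test_that("rare SNPs show the widest accuracy spread under fast LD decay", {
  pre <- sim_preset("oyster_like", n_chrom = 4, n_snps_total = 1200,
    n_parents = 24, n_families = 30, n_offspring = 300)
  sim <- simulate_population(pre$chromosomes, pre$design, trait = NULL,
    n_ancestral = pre$n_ancestral, switch_rate = pre$switch_rate,
    maf_law = function(n) stats::rbeta(n, 0.6, 0.6) * 0.96 + 0.02,
    seed = 71)
  pan <- select_physical(sim$map, 120)
  masked <- mask_to_panel(sim$geno, pan, sim$offspring)
  ph <- phase_parents(sim$geno[sim$parents, ], sim$map, seed = 3)
  imp <- impute_offspring(masked[sim$offspring, ], sim$ped, ph, seed = 5)
  out <- maf_binned_accuracy(sim$geno[sim$offspring, ], imp)
  iqr <- out$per_bin$iqr_r[match(
    c("(0.0,0.1]", "(0.2,0.3]", "(0.4,0.5]"), as.character(out$per_bin$bin))]
  expect_gt(iqr[1], iqr[2])
  expect_gt(iqr[1], iqr[3])
})

test_that("accuracy reports are invariant to individual and SNP order", {
  sim <- tiny_population()
  pan <- select_physical(sim$map, 30)
  masked <- mask_to_panel(sim$geno, pan, sim$offspring)
  ph <- phase_parents(sim$geno[sim$parents, ], sim$map, seed = 2)
  imp <- impute_offspring(masked[sim$offspring, ], sim$ped, ph, seed = 3)
  rep1 <- per_individual_accuracy(sim$geno[sim$offspring, ], imp)
  perm <- sample(sim$offspring)
  rep2 <- per_individual_accuracy(sim$geno[perm, ], fake_imputed(
    unclass(imp$geno)[perm, ], imp$provenance[perm, ]))
  expect_equal(
    rep1$per_individual$r[match(perm, rep1$per_individual$id)],
    rep2$per_individual$r
  )
  expect_equal(rep1$mean, rep2$mean)
  # perfection equivalence: r = 1 iff concordance 100 when variance exists
  conc <- per_snp_concordance(sim$geno[sim$offspring, ], imp)
  bins <- maf_binned_accuracy(sim$geno[sim$offspring, ], imp)
  joined <- merge(conc, bins$per_snp, by = "snp")
  with_var <- joined[!is.na(joined$r), ]
  expect_identical(with_var$pct_correct == 100, abs(with_var$r - 1) < 1e-12)
})
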