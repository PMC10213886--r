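test_that("the GRM matches the standardized-dosage formula", {
  g <- rbind(i1 = c(0L), i2 = c(2L))
  colnames(g) <- "s1"
  G <- compute_grm(geno_matrix(g))
  # p = 0.5: entries (x - 1)^2 / (2 * 0.25) = +/- 2
  expect_equal(unclass(G), matrix(c(2, -2, -2, 2), 2,
    dimnames = list(c("i1", "i2"), c("i1", "i2"))), tolerance = 1e-12,
    ignore_attr = TRUE)
  # an all-heterozygous SNP sits exactly at its mean: zero contribution
  g2 <- cbind(g, s2 = c(1L, 1L))
  G2 <- compute_grm(geno_matrix(g2))
  expect_equal(unclass(G2), unclass(G) / 2, tolerance = 1e-12, ignore_attr = TRUE)
  # monomorphic SNPs are excluded with a warning
  g3 <- cbind(g, s3 = c(0L, 0L))
  expect_warning(G3 <- compute_grm(geno_matrix(g3)), "monomorphic")
  expect_identical(attr(G3, "n_snps"), 1L)
})

test_that("GRM diagonal averages one under random mating", {
  set.seed(61)
  geno <- random_geno(500, runif(800, 0.1, 0.9))
  G <- compute_grm(geno)
  expect_equal(mean(diag(unclass(G))), 1, tolerance = 0.05)
  expect_true(isSymmetric(unclass(G)))
})

test_that("REML with an identity GRM matches the closed-form variance split", {
  set.seed(63)
  n <- 120
  X <- cbind(1, rnorm(n))
  y <- as.numeric(X %*% c(2, 0.5) + rnorm(n))
  G <- diag(n)
  dimnames(G) <- list(sprintf("i%d", 1:n), sprintf("i%d", 1:n))
  dat <- tibble::tibble(id = rownames(G), phenotype = y, x = X[, 2])
  fit <- reml_fit(dat, G, phenotype ~ x)
  # with G = I only the total variance is identified; it must equal the
  # ordinary REML residual variance RSS / (n - p)
  rss <- sum(stats::lm(y ~ X[, 2])$residuals^2)
  expect_equal(fit$sigma_a2 + fit$sigma_e2, rss / (n - 2), tolerance = 1e-6)
  expect_equal(unname(fit$beta), unname(coef(stats::lm(y ~ X[, 2]))),
    tolerance = 1e-6)
})

test_that("REML keeps null heritability near zero", {
  set.seed(67)
  geno <- random_geno(400, runif(600, 0.1, 0.9))
  G <- suppressWarnings(compute_grm(geno))
  eig <- eigen(unclass(G), symmetric = TRUE)
  eig$values <- eig$values + 1e-6
  hits <- 0L
  for (rep in 1:15) {
    dat <- tibble::tibble(id = rownames(G), phenotype = rnorm(400))
    fit <- reml_fit(dat, G, eig = eig)
    if (fit$h2 < 0.1) hits <- hits + 1L
  }
  expect_gte(hits, 13L)
})

test_that("REML recovers a simulated heritability", {
  sim <- simulate_population(
    chromosomes = tiny_chromosomes(3, n_snps = 250),
    design = population_design(10, 10, 20, 25, "factorial"),
    seed = 97
  )
  G <- suppressWarnings(compute_grm(sim$geno[sim$offspring, ]))
  eig <- eigen(unclass(G), symmetric = TRUE)
  eig$values <- eig$values + 1e-6
  h2_hat <- vapply(1:10, function(rep) {
    ph <- simulate_phenotypes(sim$geno[sim$offspring, ],
      trait_model(0.5, 100), seed = 600 + rep)
    reml_fit(ph, G, eig = eig)$h2
  }, numeric(1))
  expect_lt(abs(mean(h2_hat) - 0.5), 0.07)
})

test_that("tidy and glance summarize fitted objects", {
  set.seed(69)
  geno <- random_geno(80, runif(200, 0.2, 0.8))
  G <- compute_grm(geno)
  dat <- tibble::tibble(id = rownames(G), phenotype = rnorm(80))
  fit <- reml_fit(dat, G)
  td <- tidy(fit)
  expect_identical(td$term, c("sigma_a2", "sigma_e2", "h2"))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$converged)
  expect_equal(gl$h2, fit$h2)
})

test_that("GBLUP solutions match direct mixed-model-equation inversion", {
  set.seed(71)
  for (rep in 1:5) {
    n <- sample(25:50, 1)
    geno <- random_geno(n, runif(150, 0.2, 0.8),
      ids = sprintf("id%03d", 1:n))
    G <- unclass(compute_grm(geno)) + diag(1e-4, n)
    dimnames(G) <- list(rownames(geno), rownames(geno))
    dat <- tibble::tibble(
      id = rownames(G), phenotype = rnorm(n), grp = rep_len(c("a", "b"), n)
    )
    val <- dat$id[1:4]
    train <- dat[!dat$id %in% val, ]
    fit <- reml_fit(train, G, phenotype ~ grp)
    pred <- gblup_predict(dat, G, val, phenotype ~ grp, fit = fit)
    des <- stats::model.matrix(~grp, train)
    mme <- mme_oracle(train$phenotype, des, G[train$id, train$id],
      fit$sigma_a2, fit$sigma_e2)
    ebv_train <- pred$ebv[pred$set == "training"]
    expect_equal(ebv_train, unname(mme$ebv), tolerance = 1e-8)
  }
})

test_that("breeding values vanish as the additive variance goes to zero", {
  set.seed(73)
  n <- 60
  geno <- random_geno(n, runif(100, 0.2, 0.8))
  G <- compute_grm(geno)
  dat <- tibble::tibble(id = rownames(G), phenotype = rnorm(n))
  fit0 <- structure(list(
    sigma_a2 = 1e-10, sigma_e2 = 1, h2 = 1e-10, beta = c(`(Intercept)` = mean(dat$phenotype)),
    converged = TRUE, n = n
  ), class = "reml_fit")
  pred <- gblup_predict(dat, G, dat$id[1:10], fit = fit0)
  expect_true(all(abs(pred$ebv) < 1e-8))
})

test_that("prediction accuracy is the correlation scaled by root heritability", {
  set.seed(79)
  ebv <- rnorm(200)
  y <- 0.3 * ebv + rnorm(200)
  expect_equal(
    prediction_accuracy(ebv, y, 0.25),
    cor(ebv, y) / 0.5
  )
  expect_error(prediction_accuracy(ebv, y, 0), "positive")
  noise <- rnorm(200)
  expect_lt(abs(prediction_accuracy(noise, y, 0.25)), 0.3)
})

test_that("prediction accuracy is invariant to linear phenotype rescaling", {
  sim <- tiny_population()
  G <- suppressWarnings(compute_grm(sim$geno[sim$offspring, ]))
  dat <- sim$phenotypes
  cv1 <- cross_validate(dat, G, k = 4, reps = 2, seed = 5)
  dat2 <- dplyr::mutate(dat, phenotype = 3 * .data$phenotype + 100)
  cv2 <- cross_validate(dat2, G, k = 4, reps = 2, h2_full = cv1$h2_full, seed = 5)
  expect_equal(cv1$results$accuracy, cv2$results$accuracy, tolerance = 1e-6)
})

test_that("cross-validation is deterministic and respects fold structure", {
  sim <- tiny_population()
  G <- suppressWarnings(compute_grm(sim$geno[sim$offspring, ]))
  dat <- sim$phenotypes
  cv1 <- cross_validate(dat, G, k = 5, reps = 3, seed = 9)
  cv2 <- cross_validate(dat, G, k = 5, reps = 3, seed = 9)
  expect_identical(cv1$results, cv2$results)
  expect_identical(cv1$folds, cv2$folds)
  # folds partition individuals, each about 20%
  f1 <- cv1$folds[cv1$folds$rep == 1, ]
  expect_setequal(f1$id, dat$id)
  expect_true(all(abs(table(f1$fold) - nrow(dat) / 5) <= 1))
  cv3 <- cross_validate(dat, G, k = 5, reps = 3, seed = 10)
  expect_false(identical(cv1$results$accuracy, cv3$results$accuracy))
})

test_that("leave-one-out folds pool predictions within replicates", {
  set.seed(83)
  sim <- tiny_population()
  ids <- sim$offspring[1:20]
  G <- suppressWarnings(compute_grm(sim$geno[ids, ]))
  dat <- sim$phenotypes[sim$phenotypes$id %in% ids, ]
  cv <- cross_validate(dat, G, k = 20, reps = 1, seed = 4)
  expect_identical(nrow(cv$results), 1L)
  expect_identical(cv$results$n_val, 20L)
  expect_true(is.finite(cv$mean))
})

test_that("genomic prediction exploits relatives and beats a destroyed GRM", {
  sim <- simulate_population(
    chromosomes = tiny_chromosomes(2, n_snps = 300),
    design = population_design(12, 12, 12, 20, "monogamous"),
    trait = trait_model(0.4, 80),
    seed = 55
  )
  off <- sim$offspring
  G <- suppressWarnings(compute_grm(sim$geno[off, ]))
  dat <- sim$phenotypes
  fam <- sim$families$family[match(off, sim$families$id)]
  # validation: families 11 and 12 have no relatives in training (monogamous
  # mating -> families are unrelated); 20 sib-connected individuals do
  singletons <- off[fam %in% c("fam011", "fam012")]
  sibs <- off[fam %in% c("fam001", "fam002")][1:20]
  val <- c(singletons, sibs)
  pred <- gblup_predict(dat[!dat$id %in% val, ], G, val)
  ebv <- pred$ebv[pred$set == "validation"]
  names(ebv) <- pred$id[pred$set == "validation"]
  expect_gt(mean(abs(ebv[sibs])), mean(abs(ebv[singletons])))

  # positive control vs permuted GRM
  h2_full <- reml_fit(dat, G)$h2
  cv <- cross_validate(dat, G, k = 5, reps = 3, h2_full = h2_full, seed = 21)
  perm <- sample(nrow(G))
  Gp <- unclass(G)[perm, perm]
  dimnames(Gp) <- dimnames(G)
  cv_perm <- cross_validate(dat, Gp, k = 5, reps = 3, h2_full = h2_full, seed = 21)
  expect_gt(cv$mean, 0)
  expect_lte(cv$mean, 1.2)   # accuracy statistic can exceed 1 only by noise
  expect_gt(cv$mean, cv_perm$mean)
})

test_that("singular fixed-effect designs are reported with the offending column", {
  set.seed(89)
  geno <- random_geno(40, runif(60, 0.2, 0.8))
  G <- compute_grm(geno)
  dat <- tibble::tibble(
    id = rownames(G), phenotype = rnorm(40),
    x1 = rnorm(40)
  )
  dat$x2 <- dat$x1   # perfectly collinear
  expect_error(reml_fit(dat, G, phenotype ~ x1 + x2), "x2")
})
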