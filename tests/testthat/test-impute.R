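zero_recomb_population <- function(seed = 19, n_snps = 120) {
  simulate_population(
    chromosomes = chromosome_spec(2, length_bp = 4e6, genetic_length_cm = 0,
      n_snps = n_snps),
    design = population_design(4, 4, 6, 8, "factorial"),
    seed = seed
  )
}

test_that("Mendelian fill completes only parent-forced genotypes", {
  off <- geno_matrix(matrix(NA_integer_, 1, 4,
    dimnames = list("O1", sprintf("s%d", 1:4))))
  filled <- mendelian_fill(off, sire_geno = c(0L, 2L, 1L, 2L), dam_geno = c(0L, 2L, 0L, 0L))
  expect_identical(as.vector(unclass(filled)), c(0L, 2L, NA, 1L))
  expect_identical(as.vector(attr(filled, "filled")), c(TRUE, TRUE, FALSE, TRUE))
  # observed genotypes are untouched even when parents disagree
  off2 <- geno_matrix(matrix(c(2L, NA, NA, NA), 1, 4,
    dimnames = list("O1", sprintf("s%d", 1:4))))
  filled2 <- mendelian_fill(off2, c(0L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L))
  expect_identical(unclass(filled2)[1, 1], 2L)
})

test_that("Mendelian fill fraction equals the hom-x-hom parent-pair fraction", {
  sim <- zero_recomb_population()
  pan <- select_physical(sim$map, 10)
  masked <- mask_to_panel(sim$geno, pan, sim$offspring)
  kid <- sim$offspring[1]
  prow <- sim$ped[sim$ped$id == kid, ]
  s <- unclass(sim$geno)[prow$sire, ]
  d <- unclass(sim$geno)[prow$dam, ]
  obs <- unclass(masked)[kid, , drop = FALSE]
  filled <- mendelian_fill(geno_matrix(obs), s, d)
  expect_identical(
    sum(attr(filled, "filled")),
    sum(is.na(obs[1, ]) & s != 1L & d != 1L)
  )
})

test_that("gamete-origin decoding recovers simple paths", {
  # parent het at 6 markers, offspring follows hap1 then hap2
  hap1 <- c(1L, 1L, 1L, 1L, 1L, 1L)
  hap2 <- c(0L, 0L, 0L, 0L, 0L, 0L)
  other <- rep(0L, 6)
  off <- c(1L, 1L, 1L, 0L, 0L, 0L)   # transmitted: 1,1,1,0,0,0
  path <- infer_gamete_origin(off, hap1, hap2, other,
    switch_penalty = 1, mismatch_penalty = 10)
  expect_identical(path$states, c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_identical(path$n_switches, 1L)
  # constant path when the offspring matches hap1 everywhere
  path1 <- infer_gamete_origin(rep(1L, 6), hap1, hap2, other, 3, 1)
  expect_identical(path1$states, rep(1L, 6))
  expect_identical(path1$n_switches, 0L)
  # no informative markers
  none <- infer_gamete_origin(rep(1L, 6), hap1, hap2, rep(1L, 6), 3, 1)
  expect_identical(length(none$informative), 0L)
  expect_error(infer_gamete_origin(off, hap1, hap2, other, -1, 1), "positive")
})

test_that("dynamic program equals exhaustive path enumeration", {
  set.seed(23)
  for (rep in 1:100) {
    k <- sample(2:10, 1)
    hap1 <- rbinom(k, 1, 0.5)
    hap2 <- 1L - hap1              # het everywhere: all markers informative
    transmitted <- rbinom(k, 1, 0.5)
    off <- transmitted             # other parent transmits 0
    other <- rep(0L, k)
    sp <- runif(1, 0.5, 5)
    mp <- runif(1, 0.5, 2)
    path <- infer_gamete_origin(off, hap1, hap2, other, sp, mp)
    mism <- rbind((hap1 != transmitted) * mp, (hap2 != transmitted) * mp)
    oracle <- gamete_path_oracle(mism, sp)
    expect_equal(path$cost, oracle$cost, tolerance = 1e-10)
    expect_identical(path$n_switches, as.integer(oracle$n_switches))
    # the decoded path must be one of the optima; it is pinned uniquely
    # whenever the optimum is unique at the (cost, switches) level
    hit <- apply(oracle$tied_states, 1, function(st) all(st == path$states))
    expect_true(any(hit))
  }
})

test_that("oracle phasing returns the simulated truth", {
  sim <- tiny_population()
  truth <- sim$haps
  ph <- phase_parents(sim$geno[sim$parents, ], sim$map,
    method = "oracle", truth = truth)
  expect_identical(ph$hap1, truth$hap1[sim$parents, ])
  expect_identical(ph$hap2, truth$hap2[sim$parents, ])
  expect_error(
    phase_parents(sim$geno[sim$parents, ], sim$map, method = "oracle"),
    "true haplotypes"
  )
})

test_that("library phasing is exact for homozygous parents and recovers shared haplotypes", {
  # fully homozygous parent: phase is determined
  gm <- rbind(
    P1 = c(0L, 2L, 0L, 2L, 2L, 0L),
    P2 = c(0L, 2L, 2L, 0L, 2L, 0L)
  )
  colnames(gm) <- sprintf("s%d", 1:6)
  g <- geno_matrix(gm)
  map <- marker_map(colnames(g), "c1", 1:6 * 10)
  ph <- phase_parents(g, map, window_sites = 3)
  expect_identical(ph$hap1, ph$hap2)
  expect_identical(ph$hap1["P1", ] + ph$hap2["P1", ], unclass(g)["P1", ])

  # founders copied from a small ancestral pool without mosaicism share
  # whole-chromosome haplotypes; the heuristic should phase them without
  # switch errors in nearly every replicate
  n_zero <- 0L
  n_rep <- 10L
  for (rep in seq_len(n_rep)) {
    chr <- chromosome_spec(1, 3e6, 30, 150)
    f <- simulate_founders(chr, n_founders = 30, n_ancestral = 4,
      switch_rate = 0, seed = 300 + rep)
    geno <- haps_to_geno(f)
    ph <- phase_parents(geno, f$map, seed = rep)
    se <- switch_error_rate(ph, f)
    if (sum(se$n_switches) == 0L) n_zero <- n_zero + 1L
  }
  expect_gte(n_zero, n_rep - 1L)
})

test_that("imputation is perfect under zero recombination with oracle phasing", {
  sim <- zero_recomb_population()
  # build a fully informative panel: start from a physical panel, then add,
  # for every (offspring, chromosome, parent) gamete, a marker where the
  # focal parent is heterozygous and the transmitted allele is determined
  pan_snps <- select_physical(sim$map, 80)$snps
  for (kid in sim$offspring) {
    prow <- sim$ped[sim$ped$id == kid, ]
    for (cn in unique(sim$map$chrom)) {
      cols <- which(sim$map$chrom == cn)
      for (par in c(prow$sire, prow$dam)) {
        other <- setdiff(c(prow$sire, prow$dam), par)
        ta_all <- aquaimpute:::transmitted_allele(
          unclass(sim$geno)[kid, cols], unclass(sim$geno)[other, cols]
        )
        het <- sim$haps$hap1[par, cols] != sim$haps$hap2[par, cols]
        good <- sim$map$snp[cols][!is.na(ta_all) & het]
        if (length(good) > 0 && !any(good %in% pan_snps)) {
          pan_snps <- c(pan_snps, good[1])
        }
      }
    }
  }
  masked <- mask_to_panel(sim$geno, pan_snps, sim$offspring)
  # precondition of the guarantee now holds wherever it can
  for (kid in sim$offspring) {
    prow <- sim$ped[sim$ped$id == kid, ]
    for (cn in unique(sim$map$chrom)) {
      cols <- which(sim$map$chrom == cn)
      obs <- unclass(masked)[kid, cols]
      for (par in c(prow$sire, prow$dam)) {
        other <- setdiff(c(prow$sire, prow$dam), par)
        ta <- aquaimpute:::transmitted_allele(obs, unclass(sim$geno)[other, cols])
        het <- sim$haps$hap1[par, cols] != sim$haps$hap2[par, cols]
        if (sum(het) > 0) expect_gt(sum(!is.na(ta) & het), 0)
      }
    }
  }
  ph <- phase_parents(sim$geno[sim$parents, ], sim$map,
    method = "oracle", truth = sim$haps)
  imp <- impute_offspring(masked[sim$offspring, ], sim$ped, ph, seed = 6)
  expect_identical(unclass(imp$geno), unclass(sim$geno)[sim$offspring, ])
  acc <- per_individual_accuracy(sim$geno[sim$offspring, ], imp)
  expect_equal(acc$per_individual$r, rep(1, length(sim$offspring)), tolerance = 1e-12)
  expect_equal(acc$mean, 1, tolerance = 1e-12)
  expect_identical(
    unclass(imp$geno)[, pan_snps],
    unclass(sim$geno)[sim$offspring, pan_snps]
  )
})

test_that("random filling preserves the reference allele frequency", {
  set.seed(29)
  m <- 1000
  snps <- sprintf("s%04d", 1:m)
  map <- marker_map(snps, "c1", seq_len(m) * 100)
  p_ref <- runif(m, 0.2, 0.8)
  # both parents heterozygous everywhere: no informative markers anywhere
  h1 <- matrix(1L, 2, m, dimnames = list(c("S1", "D1"), snps))
  h2 <- matrix(0L, 2, m, dimnames = list(c("S1", "D1"), snps))
  haps <- phased_haps(h1, h2, map)
  kids <- sprintf("O%02d", 1:10)
  off <- geno_matrix(matrix(NA_integer_, 10, m, dimnames = list(kids, snps)))
  ped <- pedigree(
    id = c("S1", "D1", kids),
    sire = c(NA, NA, rep("S1", 10)), dam = c(NA, NA, rep("D1", 10))
  )
  imp <- impute_offspring(off, ped, haps, allele_freqs = p_ref, seed = 9)
  expect_false(anyNA(imp$geno))
  expect_true(all(imp$provenance %in% "random-fill"))
  expect_equal(mean(unclass(imp$geno)) / 2, mean(p_ref), tolerance = 0.02)
})

test_that("provenance partitions entries and observed genotypes are unchanged", {
  sim <- tiny_population()
  pan <- select_physical(sim$map, 30)
  masked <- mask_to_panel(sim$geno, pan, sim$offspring)
  ph <- phase_parents(sim$geno[sim$parents, ], sim$map, seed = 2)
  imp <- impute_offspring(masked[sim$offspring, ], sim$ped, ph, seed = 3)
  expect_false(anyNA(imp$geno))
  expect_true(all(imp$provenance %in%
    c("observed", "mendelian", "haplotype-copy", "random-fill")))
  obs <- imp$provenance == "observed"
  expect_identical(
    unclass(imp$geno)[obs],
    unclass(masked)[sim$offspring, ][obs]
  )
  expect_identical(
    which(imp$provenance == "observed"),
    which(!is.na(unclass(masked)[sim$offspring, ]))
  )
})

test_that("imputation accuracy rises with panel density", {
  sim <- tiny_population()
  ph <- phase_parents(sim$geno[sim$parents, ], sim$map, seed = 2)
  accs <- vapply(c(20, 60, 150), function(d) {
    pan <- select_physical(sim$map, d)
    masked <- mask_to_panel(sim$geno, pan, sim$offspring)
    imp <- impute_offspring(masked[sim$offspring, ], sim$ped, ph, seed = 3)
    per_individual_accuracy(sim$geno[sim$offspring, ], imp)$mean
  }, numeric(1))
  expect_true(all(diff(accs) > 0))
})

test_that("the external-imputer adapter validates round-trips", {
  sim <- zero_recomb_population(seed = 31, n_snps = 40)
  pan <- select_physical(sim$map, 12)
  masked <- mask_to_panel(sim$geno, pan, sim$offspring)
  target <- masked[sim$offspring, ]
  ref <- sim$geno[sim$parents, ]

  # identity tool: leaves missing genotypes -> completeness validation fails
  identity_tool <- function(ld, ref, ped, out) file.copy(ld, out)
  expect_error(
    external_imputer_adapter(target, ref, sim$ped, identity_tool),
    "incomplete"
  )

  # wrong shape -> dialect error
  truncating_tool <- function(ld, reff, ped, out) {
    x <- utils::read.table(ld, sep = "\t", header = TRUE, check.names = FALSE)
    utils::write.table(x[, 1:3], out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  expect_error(
    external_imputer_adapter(target, ref, sim$ped, truncating_tool),
    "does not match"
  )

  # the built-in imputer driven through the adapter equals the direct call
  ph <- phase_parents(ref, sim$map, method = "oracle", truth = sim$haps)
  reference_tool <- function(ld, reff, pedf, out) {
    geno <- aquaimpute:::read_dosage_tsv(ld)
    imp <- impute_offspring(geno_matrix(geno), sim$ped, ph, seed = 11)
    aquaimpute:::write_dosage_tsv(imp$geno, out)
  }
  via_adapter <- external_imputer_adapter(target, ref, sim$ped, reference_tool)
  direct <- impute_offspring(target, sim$ped, ph, seed = 11)
  expect_identical(unclass(via_adapter$geno), unclass(direct$geno))
  # a missing external binary is reported, not silently ignored
  expect_error(
    external_imputer_adapter(target, ref, sim$ped,
      "no_such_imputer --in {ld} --ref {ref} --out {out}"),
    "not found"
  )
})

test_that("offspring paths expose and repair a planted parent phase error", {
  set.seed(97)
  m <- 200
  snps <- sprintf("s%04d", 1:m)
  map <- marker_map(snps, "c1", seq_len(m) * 1000)
  # one sire/dam pair with many offspring, no recombination
  h1 <- rbind(S1 = rbinom(m, 1, 0.5), D1 = rbinom(m, 1, 0.5))
  h2 <- rbind(S1 = rbinom(m, 1, 0.5), D1 = rbinom(m, 1, 0.5))
  colnames(h1) <- colnames(h2) <- snps
  truth <- phased_haps(h1, h2, map)
  kids <- sprintf("O%02d", 1:20)
  ped <- pedigree(
    id = c("S1", "D1", kids),
    sire = c(NA, NA, rep("S1", 20)), dam = c(NA, NA, rep("D1", 20))
  )
  haps <- gene_drop(ped, truth, genetic_length_cm = c(c1 = 0), seed = 3)
  geno <- haps_to_geno(haps)
  # plant a phase switch error in the sire at marker 100
  bad1 <- truth$hap1
  bad2 <- truth$hap2
  bad1["S1", 100:m] <- truth$hap2["S1", 100:m]
  bad2["S1", 100:m] <- truth$hap1["S1", 100:m]
  bad <- phased_haps(bad1, bad2, map)
  # offspring keep a 60-SNP panel; the error sits between informative markers
  panel <- snps[seq(5, m, by = 4)]
  masked <- mask_to_panel(geno, panel, kids)
  fixed <- refine_parent_phase(bad, masked[kids, ], ped)
  se_bad <- switch_error_rate(
    aquaimpute:::subset_haps(bad, ids = "S1"),
    aquaimpute:::subset_haps(truth, ids = "S1")
  )
  se_fixed <- switch_error_rate(
    aquaimpute:::subset_haps(fixed, ids = "S1"),
    aquaimpute:::subset_haps(truth, ids = "S1")
  )
  expect_gt(se_bad$n_switches, 0)
  # the flip is undone up to the resolution of the informative markers: the
  # long swapped arm disappears, leaving at most a residual micro-segment
  mis_sites <- function(h) {
    a <- sum(h$hap1["S1", ] != truth$hap1["S1", ])
    min(a, sum(h$hap1["S1", ] != truth$hap2["S1", ]))
  }
  expect_gt(mis_sites(bad), 30)
  expect_lt(mis_sites(fixed), 8)
  expect_lte(se_fixed$n_switches, 2L)
  # the dam's correct phase is left alone
  expect_identical(fixed$hap1["D1", ], bad$hap1["D1", ])
})
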