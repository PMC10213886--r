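# Small simulated populations shared across test files. Built once per test
# run; sizes chosen so the whole suite stays fast.

tiny_chromosomes <- function(n_chrom = 2, n_snps = 150, length_bp = 5e6,
                             cm = 50) {
  chromosome_spec(n_chrom, length_bp = length_bp, genetic_length_cm = cm,
    n_snps = n_snps)
}

tiny_population <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_population(
        chromosomes = tiny_chromosomes(),
        design = population_design(6, 6, 10, 10, "factorial"),
        trait = trait_model(0.4, 50),
        seed = 42
      )
    }
    cache
  }
})

# a hand-built trio table: 5 trios, 4 SNPs, two Mendelian errors at SNP 3
trio_fixture <- function() {
  ids <- c(
    sprintf("S%d", 1:5), sprintf("D%d", 1:5), sprintf("O%d", 1:5)
  )
  ped <- pedigree(
    id = ids,
    sire = c(rep(NA, 10), sprintf("S%d", 1:5)),
    dam = c(rep(NA, 10), sprintf("D%d", 1:5))
  )
  g <- rbind(
    # sires             s1 s2 s3 s4
    S1 = c(0, 1, 0, 2), S2 = c(0, 1, 0, 2), S3 = c(1, 1, 0, 2),
    S4 = c(2, 1, 0, 2), S5 = c(0, 1, 0, 2),
    # dams
    D1 = c(0, 1, 0, 0), D2 = c(2, 1, 0, 0), D3 = c(1, 1, 0, 0),
    D4 = c(2, 1, 0, 0), D5 = c(0, 1, 0, 0),
    # offspring: O1 and O2 carry an impossible genotype at SNP 3
    O1 = c(0, 1, 1, 1), O2 = c(1, 1, 2, 1), O3 = c(1, 1, 0, 1),
    O4 = c(2, 1, 0, 1), O5 = c(0, 1, 0, 1)
  )
  colnames(g) <- sprintf("snp%d", 1:4)
  list(geno = geno_matrix(g), ped = ped)
}
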