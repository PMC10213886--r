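#' Write a simulated truth set to standard text formats
#'
#' Emits the phased truth as VCF (phased GT field, via the vcfR package),
#' the genotypes as PLINK PED/MAP text, the pedigree as a 3-column TSV
#' (`id`, `sire`, `dam`, 0 = unknown) and the phenotypes as TSV.
#'
#' @param sim A `sim_population`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_sim_truth <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    vcf = file.path(dir, "truth.vcf.gz"),
    ped = file.path(dir, "truth.ped"),
    map = file.path(dir, "truth.map"),
    pedigree = file.path(dir, "pedigree.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv")
  )
  write_phased_vcf(sim$haps, files["vcf"])
  write_plink(sim$geno, sim$map, sim$ped, files["ped"], files["map"])
  ped_out <- sim$ped
  ped_out$sire[is.na(ped_out$sire)] <- "0"
  ped_out$dam[is.na(ped_out$dam)] <- "0"
  utils::write.table(ped_out, files["pedigree"],
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!is.null(sim$phenotypes)) {
    utils::write.table(sim$phenotypes, files["phenotypes"],
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(files)
}

#' Write phased haplotypes as a VCF with phased genotypes
#'
#' @param haps A `phased_haps` object.
#' @param path Output path (`.vcf.gz`).
#' @return Invisibly, `path`.
#' @export
write_phased_vcf <- function(haps, path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the vcfR package is required to write VCF")
  }
  map <- haps$map
  n_snp <- nrow(map)
  gt <- matrix(
    paste0(t(haps$hap1), "|", t(haps$hap2)),
    nrow = n_snp, ncol = nrow(haps$hap1),
    dimnames = list(NULL, rownames(haps$hap1))
  )
  gt <- cbind(FORMAT = rep("GT", n_snp), gt)
  fix <- cbind(
    CHROM = map$chrom, POS = as.character(map$pos), ID = map$snp,
    REF = "A", ALT = "B", QUAL = ".", FILTER = "PASS", INFO = "."
  )
  vcf <- new("vcfR",
    meta = c(
      "##fileformat=VCFv4.2",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
    ),
    fix = fix, gt = gt
  )
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' @param path VCF path (optionally gzipped).
#' @return A list with `geno` (a `geno_matrix` of ALT-allele dosages) and
#'   `map` (marker map).
#' @export
read_vcf_geno <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the vcfR package is required to read VCF")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dosage[clean == "0/0"] <- 0L
  dosage[clean %in% c("0/1", "1/0")] <- 1L
  dosage[clean == "1/1"] <- 2L
  fix <- vcfR::getFIX(vcf)
  map <- marker_map(snp = fix[, "ID"], chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]))
  geno <- geno_matrix(t(dosage)[, map$snp, drop = FALSE])
  list(geno = geno, map = map)
}

#' Write genotypes as PLINK PED/MAP text files
#'
#' Alleles are coded A (reference) and B (alternate); missing genotypes as
#' `0 0`. Pedigree parents are written in the PED family columns when
#' supplied (0 = unknown).
#'
#' @param geno Genotype matrix.
#' @param map Marker map.
#' @param ped Optional pedigree for the parent columns.
#' @param ped_path,map_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_plink <- function(geno, map, ped = NULL, ped_path, map_path) {
  geno <- as_geno(geno)
  g <- unclass(geno)[, map$snp, drop = FALSE]
  a1 <- matrix("0", nrow(g), ncol(g))
  a2 <- a1
  a1[g == 0L] <- "A"; a2[g == 0L] <- "A"
  a1[g == 1L] <- "A"; a2[g == 1L] <- "B"
  a1[g == 2L] <- "B"; a2[g == 2L] <- "B"
  inter <- matrix("", nrow(g), 2 * ncol(g))
  inter[, seq(1, 2 * ncol(g), by = 2)] <- a1
  inter[, seq(2, 2 * ncol(g), by = 2)] <- a2
  ids <- rownames(g)
  sire <- dam <- rep("0", length(ids))
  if (!is.null(ped)) {
    i <- match(ids, ped$id)
    sire <- ifelse(is.na(ped$sire[i]), "0", ped$sire[i])
    dam <- ifelse(is.na(ped$dam[i]), "0", ped$dam[i])
  }
  lines <- cbind("FAM", ids, sire, dam, "0", "-9", inter)
  utils::write.table(lines, ped_path,
    sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  utils::write.table(
    data.frame(map$chrom, map$snp, 0, map$pos),
    map_path, sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(c(ped_path, map_path))
}

#' Read PLINK PED/MAP text files
#'
#' @param ped_path,map_path Input paths.
#' @return A list with `geno` (B-allele dosages), `map`, and `ped` (the
#'   pedigree columns of the PED file).
#' @export
read_plink <- function(ped_path, map_path) {
  map_df <- utils::read.table(map_path, col.names = c("chrom", "snp", "cm", "pos"),
    colClasses = c("character", "character", "NULL", "integer")
  )
  map <- marker_map(snp = map_df$snp, chrom = map_df$chrom, pos = map_df$pos)
  ped_df <- utils::read.table(ped_path, colClasses = "character")
  n_snp <- (ncol(ped_df) - 6L) / 2L
  if (n_snp != nrow(map)) stop("PED/MAP SNP counts disagree")
  ids <- ped_df[[2]]
  al <- as.matrix(ped_df[, -(1:6), drop = FALSE])
  a1 <- al[, seq(1, 2 * n_snp, by = 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * n_snp, by = 2), drop = FALSE]
  g <- (a1 == "B") + (a2 == "B")
  g[a1 == "0" | a2 == "0"] <- NA
  ord <- match(map$snp, map_df$snp)
  g <- g[, ord, drop = FALSE]
  dimnames(g) <- list(ids, map$snp)
  list(
    geno = geno_matrix(g),
    map = map,
    ped = pedigree(id = ids, sire = ped_df[[3]], dam = ped_df[[4]])
  )
}

#' Write a panel as a PLINK extract file (one SNP id per line)
#'
#' @param panel An `snp_panel`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, path) {
  writeLines(panel$snps, path)
  invisible(path)
}
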