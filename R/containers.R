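#' Build a genotype matrix
#'
#' A genotype matrix holds reference-allele dosages (0, 1, 2, or `NA` for
#' missing) with individuals in rows and SNPs in columns. Row names are
#' individual ids and column names SNP ids; both are mandatory because every
#' downstream stage (QC, masking, imputation, GBLUP) joins on them.
#'
#' @param x Numeric matrix of dosages in \{0, 1, 2, NA\}.
#' @param ids Optional character vector of individual ids (overrides rownames).
#' @param snps Optional character vector of SNP ids (overrides colnames).
#' @return An integer matrix with class `geno_matrix`.
#' @export
geno_matrix <- function(x, ids = rownames(x), snps = colnames(x)) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(ids) || is.null(snps)) {
    stop("genotype matrix needs individual ids (rownames) and SNP ids (colnames)")
  }
  bad <- !(x %in% c(0L, 1L, 2L) | is.na(x))
  if (any(bad)) stop("genotypes must be dosages 0/1/2 or NA")
  storage.mode(x) <- "integer"
  dimnames(x) <- list(as.character(ids), as.character(snps))
  class(x) <- c("geno_matrix", class(x))
  x
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d individuals x %d SNPs (%.1f%% missing)\n",
    nrow(x), ncol(x), 100 * mean(is.na(x))
  ))
  invisible(x)
}

#' @export
`[.geno_matrix` <- function(x, i, j, ..., drop = FALSE) {
  if (nargs() - (!missing(drop)) <= 2L) {
    return(unclass(x)[i])    # linear indexing
  }
  out <- unclass(x)[i, j, drop = drop]
  if (is.matrix(out)) class(out) <- c("geno_matrix", class(out))
  out
}

as_geno <- function(x) {
  # internal: accept plain matrices in user input, validate lazily
  if (inherits(x, "geno_matrix")) x else geno_matrix(x)
}

#' Build a marker map
#'
#' @param snp Character vector of SNP ids (unique).
#' @param chrom Chromosome labels.
#' @param pos 1-based physical positions in bp, strictly increasing within
#'   each chromosome.
#' @return A tibble with columns `snp`, `chrom`, `pos`, ordered by chromosome
#'   (first appearance) then position.
#' @export
marker_map <- function(snp, chrom, pos) {
  map <- tibble::tibble(
    snp = as.character(snp),
    chrom = as.character(chrom),
    pos = as.integer(pos)
  )
  if (anyDuplicated(map$snp)) stop("duplicate SNP ids in map")
  if (any(map$pos < 1L)) stop("positions must be >= 1 (1-based bp)")
  chrom_order <- unique(map$chrom)
  map <- dplyr::arrange(map, match(.data$chrom, chrom_order), .data$pos)
  dup_pos <- map |>
    dplyr::summarise(dup = anyDuplicated(.data$pos) > 0L, .by = "chrom")
  if (any(dup_pos$dup)) stop("positions must be strictly increasing within chromosomes")
  map
}

#' Build a pedigree table
#'
#' Two-generation pedigrees are the working structure: founders have both
#' parents unknown (`NA`), offspring have both known. `"0"` is accepted as an
#' alias for unknown on input (PLINK convention).
#'
#' @param id,sire,dam Character vectors; `sire`/`dam` may contain `NA` or "0".
#' @return A tibble `id`, `sire`, `dam` with `NA` for unknown parents.
#' @export
pedigree <- function(id, sire, dam) {
  clean <- function(p) {
    p <- as.character(p)
    p[p %in% c("0", "")] <- NA_character_
    p
  }
  ped <- tibble::tibble(id = as.character(id), sire = clean(sire), dam = clean(dam))
  if (anyDuplicated(ped$id)) stop("duplicate ids in pedigree")
  one_parent <- xor(is.na(ped$sire), is.na(ped$dam))
  if (any(one_parent)) {
    stop(
      "individuals with exactly one known parent are not supported: ",
      paste(utils::head(ped$id[one_parent], 5), collapse = ", ")
    )
  }
  ped
}

ped_founders <- function(ped) ped$id[is.na(ped$sire) & is.na(ped$dam)]
ped_offspring <- function(ped) ped$id[!is.na(ped$sire) & !is.na(ped$dam)]

#' Phased haplotypes
#'
#' Stores the two chromosome copies of each individual as a pair of 0/1
#' allele matrices aligned to a marker map. `hap1 + hap2` reproduces the
#' dosage genotype at every site.
#'
#' @param hap1,hap2 Integer matrices (individuals x SNPs) of 0/1 alleles with
#'   matching dimnames.
#' @param map Marker map covering the columns.
#' @return An object of class `phased_haps`.
#' @export
phased_haps <- function(hap1, hap2, map) {
  stopifnot(
    identical(dim(hap1), dim(hap2)),
    identical(dimnames(hap1), dimnames(hap2)),
    identical(colnames(hap1), map$snp)
  )
  if (!all(hap1 %in% 0:1) || !all(hap2 %in% 0:1)) stop("haplotype alleles must be 0/1")
  storage.mode(hap1) <- "integer"
  storage.mode(hap2) <- "integer"
  structure(list(hap1 = hap1, hap2 = hap2, map = map), class = "phased_haps")
}

#' @export
print.phased_haps <- function(x, ...) {
  cat(sprintf(
    "<phased_haps> %d individuals, %d SNPs on %d chromosome(s)\n",
    nrow(x$hap1), ncol(x$hap1), length(unique(x$map$chrom))
  ))
  invisible(x)
}

#' Collapse phased haplotypes to a genotype matrix
#'
#' @param haps A `phased_haps` object.
#' @return A `geno_matrix` of dosages.
#' @export
haps_to_geno <- function(haps) {
  geno_matrix(haps$hap1 + haps$hap2)
}

subset_haps <- function(haps, ids = NULL, snps = NULL) {
  h1 <- haps$hap1
  h2 <- haps$hap2
  map <- haps$map
  if (!is.null(ids)) {
    h1 <- h1[ids, , drop = FALSE]
    h2 <- h2[ids, , drop = FALSE]
  }
  if (!is.null(snps)) {
    h1 <- h1[, snps, drop = FALSE]
    h2 <- h2[, snps, drop = FALSE]
    map <- map[match(snps, map$snp), ]
  }
  phased_haps(h1, h2, map)
}

# Deterministic per-stage random substreams: every stage draws from a seed
# derived from the root seed and a stage label, so stages can be re-run in
# isolation without disturbing each other.
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 2654435761) %% 1e9
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

with_substream <- function(seed, label, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, label))
  force(code)
}

#' Allele frequencies of the reference allele
#'
#' @param geno Genotype matrix (dosages of the reference allele).
#' @return Named numeric vector of per-SNP reference-allele frequencies,
#'   computed over non-missing genotypes.
#' @export
allele_freqs <- function(geno) {
  colMeans(geno, na.rm = TRUE) / 2
}

#' Minor allele frequencies
#'
#' @param geno Genotype matrix.
#' @return Named numeric vector, `pmin(p, 1 - p)` of the reference-allele
#'   frequency `p`.
#' @export
maf <- function(geno) {
  p <- allele_freqs(geno)
  pmin(p, 1 - p)
}
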