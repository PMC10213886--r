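#' Chromosome specification for simulation
#'
#' @param n_chrom Number of chromosome pairs.
#' @param length_bp Physical length of each chromosome (recycled).
#' @param genetic_length_cm Genetic length in centiMorgan (recycled). The
#'   default applies 1 cM/Mb to the physical length.
#' @param n_snps SNPs per chromosome (recycled), at least 2.
#' @param snp_clustering Non-negative clustering strength for SNP positions.
#'   0 (default) spreads SNPs uniformly along the chromosome; larger values
#'   concentrate them in blocks of variable density (marker maps from SNP
#'   arrays and RAD-seq are strongly clustered). Implemented as gamma random
#'   density weights over 2.5-Mb blocks with shape `1 / snp_clustering`.
#' @return A tibble with one row per chromosome: `name`, `length_bp`,
#'   `genetic_length_cm`, `n_snps`, `snp_clustering`.
#' @export
chromosome_spec <- function(n_chrom, length_bp, genetic_length_cm = length_bp / 1e6,
                            n_snps, snp_clustering = 0) {
  spec <- tibble::tibble(
    name = sprintf("chr%02d", seq_len(n_chrom)),
    length_bp = as.integer(rep_len(length_bp, n_chrom)),
    genetic_length_cm = as.numeric(rep_len(genetic_length_cm, n_chrom)),
    n_snps = as.integer(rep_len(n_snps, n_chrom)),
    snp_clustering = as.numeric(rep_len(snp_clustering, n_chrom))
  )
  if (any(spec$n_snps < 2L)) stop("each chromosome needs at least 2 SNPs")
  if (any(spec$genetic_length_cm < 0)) stop("genetic length must be non-negative")
  if (any(spec$snp_clustering < 0)) stop("snp_clustering must be non-negative")
  spec
}

#' Population design: parents, families, mating
#'
#' @param n_sires,n_dams Number of male and female parents.
#' @param n_families Number of full-sib families (distinct sire x dam pairs).
#' @param offspring_per_family Offspring per family.
#' @param mating `"factorial"` draws `n_families` distinct pairs from the
#'   sire x dam grid; `"monogamous"` pairs the i-th sire with the i-th dam.
#' @return A list of class `population_design`.
#' @export
population_design <- function(n_sires, n_dams, n_families, offspring_per_family,
                              mating = c("factorial", "monogamous")) {
  mating <- match.arg(mating)
  if (n_families > n_sires * n_dams) {
    stop("n_families cannot exceed n_sires * n_dams")
  }
  if (mating == "monogamous" && n_families > min(n_sires, n_dams)) {
    stop("monogamous mating needs n_families <= min(n_sires, n_dams)")
  }
  structure(
    list(
      n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
      n_families = as.integer(n_families),
      offspring_per_family = as.integer(offspring_per_family),
      mating = mating
    ),
    class = "population_design"
  )
}

#' Trait architecture for phenotype simulation
#'
#' @param h2_target Target narrow-sense (genomic) heritability in (0, 1).
#' @param n_qtl Number of causal SNPs drawn from the segregating markers.
#' @param trait_type `"continuous"` or `"binary"` (liability threshold).
#' @param prevalence Case fraction for binary traits, in (0, 1).
#' @param fixed_effects Optional list of fixed effects, each a list with
#'   `name`, `n_levels` and `sd` (standard deviation of level effects).
#' @param qtl_placement `"uniform_snp"` samples causal SNPs uniformly from
#'   the segregating markers; `"uniform_bp"` weights each marker by the
#'   physical interval it represents, so causal positions are uniform along
#'   the genome even when the marker map is clustered (requires a map).
#' @return A list of class `trait_model`.
#' @export
trait_model <- function(h2_target, n_qtl, trait_type = c("continuous", "binary"),
                        prevalence = 0.5, fixed_effects = list(),
                        qtl_placement = c("uniform_snp", "uniform_bp")) {
  trait_type <- match.arg(trait_type)
  qtl_placement <- match.arg(qtl_placement)
  if (h2_target <= 0 || h2_target >= 1) stop("h2_target must lie in (0, 1)")
  if (trait_type == "binary" && (prevalence <= 0 || prevalence >= 1)) {
    stop("prevalence must lie strictly in (0, 1)")
  }
  structure(
    list(
      h2_target = h2_target, n_qtl = as.integer(n_qtl),
      trait_type = trait_type, prevalence = prevalence,
      fixed_effects = fixed_effects, qtl_placement = qtl_placement
    ),
    class = "trait_model"
  )
}

# bp interval represented by each SNP: half-distance to its neighbours
snp_bp_weights <- function(map) {
  w <- numeric(nrow(map))
  for (cn in unique(map$chrom)) {
    i <- which(map$chrom == cn)
    pos <- map$pos[i]
    if (length(i) == 1L) {
      w[i] <- 1
    } else {
      gaps <- diff(pos)
      w[i] <- c(gaps[1], gaps) / 2 + c(gaps, gaps[length(gaps)]) / 2
    }
  }
  w
}

# Draw SNP positions: strictly increasing, in [1, length_bp]; clustering > 0
# concentrates SNPs in blocks of gamma-weighted density
draw_positions <- function(n_snps, length_bp, clustering = 0) {
  if (clustering <= 0) {
    return(as.integer(sort(sample.int(length_bp, n_snps))))
  }
  block <- 2.5e6
  n_blocks <- max(1L, ceiling(length_bp / block))
  w <- stats::rgamma(n_blocks, shape = 1 / clustering)
  w <- w / sum(w)
  counts <- as.vector(stats::rmultinom(1, n_snps, w))
  pos <- unlist(lapply(seq_len(n_blocks), function(b) {
    if (counts[b] == 0L) return(integer(0))
    lo <- (b - 1) * block + 1
    hi <- min(b * block, length_bp)
    lo + sample.int(hi - lo + 1L, counts[b]) - 1L
  }))
  pos <- sort(unique(as.integer(pos)))
  while (length(pos) < n_snps) {   # resolve rare duplicate collisions
    extra <- sample.int(length_bp, n_snps - length(pos))
    pos <- sort(unique(c(pos, as.integer(extra))))
  }
  pos
}

# n_out mosaic haplotypes over a source pool: geometric segments with the
# given per-bp switch rate, each switch moving to a different source row
mosaic_haplotypes <- function(pool, n_out, map, chrom_idx, rate) {
  n_src <- nrow(pool)
  out <- matrix(0L, nrow = n_out, ncol = ncol(pool))
  for (snps in chrom_idx) {
    gaps <- diff(map$pos[snps])
    p_switch <- 1 - exp(-rate * gaps)
    for (h in seq_len(n_out)) {
      state <- sample.int(n_src, 1L)
      states <- integer(length(snps))
      states[1L] <- state
      if (length(snps) > 1L) {
        switches <- stats::runif(length(gaps)) < p_switch
        for (k in seq_along(gaps)) {
          if (switches[k]) {
            state <- sample.int(n_src - 1L, 1L)
            if (state >= states[k]) state <- state + 1L
          }
          states[k + 1L] <- state
        }
      }
      out[h, snps] <- pool[cbind(states, snps)]
    }
  }
  out
}

#' Simulate founder haplotypes with tunable linkage disequilibrium
#'
#' Founders are mosaics of a small pool of ancestral haplotypes. Each founder
#' haplotype copies one ancestor and switches to a different ancestor between
#' adjacent SNPs with probability `1 - exp(-switch_rate * gap_bp)`, giving
#' geometrically distributed segment lengths. Fewer ancestors and a lower
#' switch rate produce longer shared haplotypes and stronger LD.
#'
#' The ancestral pool itself can carry two-scale structure: with
#' `n_proto < n_ancestral`, the ancestors are mosaics (at
#' `proto_switch_rate`) of a smaller set of proto-haplotypes. Locally the
#' population then collapses onto few variants (strong short-range LD, as
#' left by a handful of wild source stocks), while over longer ranges the
#' ancestors recombine independently (weak long-range tagging) -- the LD
#' profile typical of aquaculture base populations.
#'
#' @param chromosomes A [chromosome_spec()] tibble.
#' @param n_founders Number of founder individuals.
#' @param n_ancestral Size of the ancestral haplotype pool (>= 2).
#' @param switch_rate Per-bp mosaic switch rate (>= 0); 0 gives founders that
#'   are exact copies of ancestral haplotypes.
#' @param maf_law Function `n -> p` drawing per-SNP reference-allele
#'   frequencies; default uniform on (0.1, 0.9).
#' @param n_proto Optional proto-haplotype pool size behind the ancestors
#'   (`NULL`, the default, draws ancestors independently per SNP).
#' @param proto_switch_rate Per-bp switch rate of the ancestor-of-proto
#'   mosaics; typically well above `switch_rate`.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param ids Optional founder ids, default `fnd001, ...`.
#' @return A `phased_haps` object for the founders, whose `map` carries the
#'   simulated marker map.
#' @export
simulate_founders <- function(chromosomes, n_founders, n_ancestral = 8,
                              switch_rate = 1e-7,
                              maf_law = function(n) stats::runif(n, 0.1, 0.9),
                              n_proto = NULL, proto_switch_rate = 4e-7,
                              seed = 1, ids = NULL) {
  if (!is.finite(switch_rate) || switch_rate < 0) {
    stop("switch_rate must be finite and non-negative")
  }
  if (n_ancestral < 2) stop("n_ancestral must be at least 2")
  if (!is.null(n_proto) && n_proto < 2) stop("n_proto must be at least 2")
  if (is.null(ids)) ids <- sprintf("fnd%03d", seq_len(n_founders))

  with_substream(seed, "founders", {
    maps <- purrr::pmap(chromosomes, function(name, length_bp, genetic_length_cm,
                                               n_snps, snp_clustering = 0, ...) {
      tibble::tibble(
        chrom = name,
        pos = draw_positions(n_snps, length_bp, clustering = snp_clustering)
      )
    })
    map <- dplyr::bind_rows(maps)
    map <- marker_map(
      snp = sprintf("%s_s%05d", map$chrom, stats::ave(map$pos, map$chrom, FUN = seq_along)),
      chrom = map$chrom, pos = map$pos
    )
    m <- nrow(map)

    p_ref <- maf_law(m)
    if (any(p_ref <= 0 | p_ref >= 1)) stop("maf_law must return frequencies in (0, 1)")
    chrom_idx <- split(seq_len(m), map$chrom)[unique(map$chrom)]
    if (is.null(n_proto)) {
      anc <- matrix(
        stats::rbinom(n_ancestral * m, 1L, rep(p_ref, each = n_ancestral)),
        nrow = n_ancestral, ncol = m
      )
    } else {
      proto <- matrix(
        stats::rbinom(n_proto * m, 1L, rep(p_ref, each = n_proto)),
        nrow = n_proto, ncol = m
      )
      anc <- mosaic_haplotypes(proto, n_ancestral, map, chrom_idx, proto_switch_rate)
    }

    n_hap <- 2L * n_founders
    hap <- mosaic_haplotypes(anc, n_hap, map, chrom_idx, switch_rate)

    hap1 <- hap[seq(1L, n_hap, by = 2L), , drop = FALSE]
    hap2 <- hap[seq(2L, n_hap, by = 2L), , drop = FALSE]
    dimnames(hap1) <- dimnames(hap2) <- list(ids, map$snp)
    phased_haps(hap1, hap2, map)
  })
}

#' Drop founder haplotypes through a pedigree with recombination
#'
#' Each transmitted gamete is a recombinant of the parent's two haplotypes:
#' the crossover count per chromosome is Poisson with mean
#' `genetic_length_cm / 100` and crossover positions are uniform on the
#' genetic map (Haldane model, no interference; constant cM/bp within a
#' chromosome). Genotypes are Mendelian-consistent by construction.
#'
#' @param ped A [pedigree()] tibble; every non-founder's parents must appear
#'   before it and founders must all have haplotypes.
#' @param founder_haps `phased_haps` for the founders (rownames = ids).
#' @param genetic_length_cm Named vector of per-chromosome sex-averaged
#'   genetic lengths in cM; default 1 cM/Mb over the span of mapped SNPs.
#' @param sire_map_scale,dam_map_scale Multipliers on the genetic length for
#'   gametes produced by sires and dams. Both default to 1; salmonids show
#'   strong male recombination suppression (e.g. 0.2 and 1.8).
#' @param seed Integer seed.
#' @return `phased_haps` covering every individual in the pedigree (founders
#'   keep their input haplotypes; hap1 = paternal, hap2 = maternal for
#'   offspring).
#' @export
gene_drop <- function(ped, founder_haps, genetic_length_cm = NULL,
                      sire_map_scale = 1, dam_map_scale = 1, seed = 1) {
  map <- founder_haps$map
  chroms <- unique(map$chrom)
  if (is.null(genetic_length_cm)) {
    spans <- tapply(map$pos, factor(map$chrom, levels = chroms), function(p) diff(range(p)))
    genetic_length_cm <- spans / 1e6   # 1 cM/Mb default
  }
  if (is.null(names(genetic_length_cm))) names(genetic_length_cm) <- chroms
  founders <- ped_founders(ped)
  if (!all(founders %in% rownames(founder_haps$hap1))) {
    stop("all pedigree founders must have founder haplotypes")
  }
  kids <- ped_offspring(ped)
  ped_kids <- ped[match(kids, ped$id), ]
  known <- c(founders)
  for (i in seq_len(nrow(ped_kids))) {
    if (!all(c(ped_kids$sire[i], ped_kids$dam[i]) %in% known)) {
      stop("parents must precede offspring in the pedigree")
    }
    known <- c(known, ped_kids$id[i])
  }

  m <- nrow(map)
  n_all <- nrow(ped)
  hap1 <- matrix(0L, n_all, m, dimnames = list(ped$id, map$snp))
  hap2 <- hap1
  hap1[founders, ] <- founder_haps$hap1[founders, , drop = FALSE]
  hap2[founders, ] <- founder_haps$hap2[founders, , drop = FALSE]

  chrom_idx <- split(seq_len(m), factor(map$chrom, levels = chroms))

  with_substream(seed, "gametes", {
    make_gamete <- function(h1, h2, map_scale = 1) {
      out <- integer(m)
      for (cn in chroms) {
        snps <- chrom_idx[[cn]]
        pos <- map$pos[snps]
        lo <- min(pos); hi <- max(pos)
        n_xo <- stats::rpois(1L, map_scale * genetic_length_cm[[cn]] / 100)
        start <- sample.int(2L, 1L)
        if (n_xo == 0L || lo == hi) {
          out[snps] <- if (start == 1L) h1[snps] else h2[snps]
        } else {
          xo <- sort(stats::runif(n_xo, lo, hi))
          seg <- findInterval(pos, xo)          # 0..n_xo
          state <- (start - 1L + seg) %% 2L     # 0 => hap1
          out[snps] <- ifelse(state == 0L, h1[snps], h2[snps])
        }
      }
      out
    }
    for (i in seq_len(nrow(ped_kids))) {
      id <- ped_kids$id[i]
      hap1[id, ] <- make_gamete(hap1[ped_kids$sire[i], ], hap2[ped_kids$sire[i], ],
        sire_map_scale)
      hap2[id, ] <- make_gamete(hap1[ped_kids$dam[i], ], hap2[ped_kids$dam[i], ],
        dam_map_scale)
    }
    phased_haps(hap1, hap2, map)
  })
}

#' Simulate phenotypes and true breeding values from genotypes
#'
#' Causal SNPs (QTL) are drawn from the segregating markers with normal
#' effects, and the breeding value of an individual is the sum of its QTL
#' dosages weighted by the effects. Effects are rescaled so the realized
#' additive variance equals `h2_target` of the phenotypic variance (residual
#' variance `1 - h2_target`). Binary traits threshold the continuous
#' liability at its realized `1 - prevalence` quantile, so the case
#' fraction matches the requested prevalence up to rounding.
#'
#' @param geno Genotype matrix (no missing values at the QTL).
#' @param model A [trait_model()].
#' @param map Marker map; required for `qtl_placement = "uniform_bp"`.
#' @param seed Integer seed.
#' @return A tibble `id`, `phenotype`, `tbv` (true breeding value), plus one
#'   column per fixed effect; QTL ids and effects are attached as the
#'   `"qtl"` attribute (a tibble `snp`, `effect`).
#' @export
simulate_phenotypes <- function(geno, model, map = NULL, seed = 1) {
  geno <- as_geno(geno)
  p <- allele_freqs(geno)
  segregating <- which(p > 0 & p < 1)
  if (length(segregating) == 0L) stop("all SNPs are monomorphic; cannot place QTL")
  if (model$n_qtl > length(segregating)) {
    stop("n_qtl exceeds the number of segregating SNPs")
  }
  weights <- NULL
  if (identical(model$qtl_placement, "uniform_bp")) {
    if (is.null(map)) stop("uniform_bp QTL placement needs the marker map")
    w_all <- snp_bp_weights(map)
    weights <- w_all[match(colnames(geno)[segregating], map$snp)]
  }
  n <- nrow(geno)
  with_substream(seed, "effects", {
    qtl <- sort(sample(segregating, model$n_qtl, prob = weights))
    u <- stats::rnorm(model$n_qtl)
    a_raw <- as.numeric(geno[, qtl, drop = FALSE] %*% u)
    v <- stats::var(a_raw)
    scale <- if (v > 0) sqrt(model$h2_target / v) else 0
    a <- (a_raw - mean(a_raw)) * scale
    u <- u * scale

    fixed <- tibble::tibble(.rows = n)
    fixed_part <- numeric(n)
    for (fe in model$fixed_effects) {
      lev <- sample.int(fe$n_levels, n, replace = TRUE)
      eff <- stats::rnorm(fe$n_levels, sd = fe$sd)
      fixed[[fe$name]] <- factor(paste0(fe$name, lev))
      fixed_part <- fixed_part + eff[lev]
    }

    e <- stats::rnorm(n, sd = sqrt(1 - model$h2_target))
    liability <- a + e
    y <- if (model$trait_type == "binary") {
      # threshold on the realized liability: the case fraction matches the
      # requested prevalence up to rounding
      as.integer(liability > stats::quantile(liability, 1 - model$prevalence))
    } else {
      fixed_part + liability
    }
    out <- tibble::tibble(id = rownames(geno), phenotype = y, tbv = a)
    out <- dplyr::bind_cols(out, fixed)
    attr(out, "qtl") <- tibble::tibble(snp = colnames(geno)[qtl], effect = u)
    out
  })
}

build_pedigree <- function(design, seed = 1) {
  sires <- sprintf("S%03d", seq_len(design$n_sires))
  dams <- sprintf("D%03d", seq_len(design$n_dams))
  pairs <- if (design$mating == "monogamous") {
    tibble::tibble(sire = sires[seq_len(design$n_families)],
                   dam = dams[seq_len(design$n_families)])
  } else {
    grid <- tidyr::expand_grid(sire = sires, dam = dams)
    with_substream(seed, "mating", grid[sample.int(nrow(grid), design$n_families), ])
  }
  kid <- 0L
  off <- purrr::pmap(cbind(pairs, fam = seq_len(nrow(pairs))), function(sire, dam, fam) {
    ids <- sprintf("O%05d", kid + seq_len(design$offspring_per_family))
    kid <<- kid + design$offspring_per_family
    tibble::tibble(id = ids, sire = sire, dam = dam, family = sprintf("fam%03d", fam))
  })
  off <- dplyr::bind_rows(off)
  ped <- pedigree(
    id = c(sires, dams, off$id),
    sire = c(rep(NA, length(sires) + length(dams)), off$sire),
    dam = c(rep(NA, length(sires) + length(dams)), off$dam)
  )
  list(ped = ped, families = off)
}

#' Simulate a complete two-generation study population
#'
#' Convenience wrapper running [simulate_founders()] for the parents,
#' [gene_drop()] for the offspring and [simulate_phenotypes()] for the
#' offspring phenotypes, under one root seed with named substreams.
#'
#' @param chromosomes A [chromosome_spec()] tibble.
#' @param design A [population_design()].
#' @param trait A [trait_model()], or `NULL` to skip phenotypes.
#' @param n_ancestral,switch_rate,maf_law,n_proto,proto_switch_rate Passed to
#'   [simulate_founders()].
#' @param sire_map_scale,dam_map_scale Passed to [gene_drop()] (sex-specific
#'   recombination).
#' @param genotyping_error Per-genotype symmetric error rate applied to the
#'   reported (not true) genotypes; default 0.
#' @param seed Root seed.
#' @return A list of class `sim_population` with elements `haps` (truth,
#'   all individuals), `geno` (reported genotypes), `map`, `ped`,
#'   `families`, `phenotypes` (offspring only), `parents`, `offspring`,
#'   `seed`.
#' @export
simulate_population <- function(chromosomes, design, trait = NULL,
                                n_ancestral = 8, switch_rate = 1e-7,
                                maf_law = function(n) stats::runif(n, 0.1, 0.9),
                                n_proto = NULL, proto_switch_rate = 4e-7,
                                sire_map_scale = 1, dam_map_scale = 1,
                                genotyping_error = 0, seed = 1) {
  n_parents <- design$n_sires + design$n_dams
  pedinfo <- build_pedigree(design, seed = seed)
  parents <- ped_founders(pedinfo$ped)
  founders <- simulate_founders(
    chromosomes, n_founders = n_parents, n_ancestral = n_ancestral,
    switch_rate = switch_rate, maf_law = maf_law,
    n_proto = n_proto, proto_switch_rate = proto_switch_rate,
    seed = seed, ids = parents
  )
  haps <- gene_drop(
    pedinfo$ped, founders,
    genetic_length_cm = stats::setNames(chromosomes$genetic_length_cm, chromosomes$name),
    sire_map_scale = sire_map_scale, dam_map_scale = dam_map_scale,
    seed = seed
  )
  geno <- haps_to_geno(haps)
  if (genotyping_error > 0) {
    geno <- with_substream(seed, "geno_error", {
      flip <- stats::runif(length(geno)) < genotyping_error
      shift <- sample(c(-1L, 1L), length(geno), replace = TRUE)
      g <- ifelse(flip, pmin(pmax(geno + shift, 0L), 2L), geno)
      geno_matrix(matrix(g, nrow(geno), dimnames = dimnames(geno)))
    })
  }
  offspring <- ped_offspring(pedinfo$ped)
  phen <- if (!is.null(trait)) {
    ph <- simulate_phenotypes(geno[offspring, , drop = FALSE], trait,
      map = haps$map, seed = seed)
    dplyr::left_join(ph, pedinfo$families[, c("id", "family")], by = "id")
  }
  structure(
    list(
      haps = haps, geno = geno, map = haps$map, ped = pedinfo$ped,
      families = pedinfo$families, phenotypes = phen,
      parents = parents, offspring = offspring, seed = seed
    ),
    class = "sim_population"
  )
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf(
    "<sim_population> %d parents, %d offspring in %d families; %d SNPs on %d chromosomes\n",
    length(x$parents), length(x$offspring), nrow(dplyr::distinct(x$families[, c("sire", "dam")])),
    nrow(x$map), length(unique(x$map$chrom))
  ))
  invisible(x)
}

#' Preset study designs
#'
#' Ready-made simulation settings shaped like typical aquaculture breeding
#' populations. The salmon-like preset uses 29 chromosome pairs and a
#' two-scale founder pool -- few proto-haplotypes recombined into a larger
#' ancestor pool -- giving strong short-range LD with weak long-range
#' tagging and long haplotypes shared between the closely related parents.
#' The oyster-like preset uses 10 chromosome pairs and a fast-decaying,
#' more diverse founder pool. Scale is controlled by `n_snps_total` and
#' `n_offspring`.
#'
#' @param name `"salmon_like"` or `"oyster_like"`.
#' @param n_chrom Number of chromosome pairs (default 29 salmon-like, 10
#'   oyster-like).
#' @param n_snps_total Total SNPs across the genome (default 10000).
#' @param n_parents Total parents, split evenly into sires and dams (default 60).
#' @param n_families Full-sib families (default 100).
#' @param n_offspring Total offspring (default 1000).
#' @param h2 Trait heritability (default 0.3).
#' @return A list with `chromosomes`, `design`, `trait`, `switch_rate`,
#'   `n_ancestral`, `n_proto`, `proto_switch_rate`, suitable for splicing
#'   into [simulate_population()].
#' @export
sim_preset <- function(name = c("salmon_like", "oyster_like"),
                       n_chrom = if (name == "salmon_like") 29 else 10,
                       n_snps_total = 10000, n_parents = 60, n_families = 100,
                       n_offspring = 1000,
                       h2 = if (name == "salmon_like") 0.2 else 0.3) {
  name <- match.arg(name)
  chromosomes <- chromosome_spec(
    n_chrom = n_chrom, length_bp = 7.5e7, genetic_length_cm = 75,
    n_snps = max(2L, round(n_snps_total / n_chrom)),
    snp_clustering = if (name == "salmon_like") 3 else 0
  )
  design <- population_design(
    n_sires = floor(n_parents / 2), n_dams = ceiling(n_parents / 2),
    n_families = n_families,
    offspring_per_family = max(1L, round(n_offspring / n_families)),
    mating = "factorial"
  )
  trait <- trait_model(
    h2_target = h2, n_qtl = max(10L, round(n_snps_total / 50)),
    qtl_placement = if (name == "salmon_like") "uniform_bp" else "uniform_snp"
  )
  if (name == "salmon_like") {
    list(
      chromosomes = chromosomes, design = design, trait = trait,
      switch_rate = 3e-8, n_ancestral = 10,
      n_proto = NULL, proto_switch_rate = 4e-7,
      sire_map_scale = 0.1, dam_map_scale = 1.3
    )
  } else {
    list(
      chromosomes = chromosomes, design = design, trait = trait,
      switch_rate = 1e-6, n_ancestral = 24,
      n_proto = NULL, proto_switch_rate = 4e-7,
      sire_map_scale = 1, dam_map_scale = 1
    )
  }
}
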