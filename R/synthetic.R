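# Synthetic data with the statistical structure the pipeline assumes:
# Balding-Nichols drift around a shared ancestral frequency, two-way
# admixture with known mixture proportion and age, and sequencing reads with
# error and 5' terminal deamination.

#' Default desk-scale SNP panel
#'
#' Uniform genetic map over `n_chrom` chromosomes of `chrom_cM` centimorgans
#' with `sites_per_chrom` evenly spaced sites; alleles drawn at random
#' (all unordered base pairs, so both transitions and transversions occur).
#'
#' @param n_chrom Number of chromosomes (labelled 1..n, all autosomal).
#' @param chrom_cM Map length per chromosome, centimorgans.
#' @param sites_per_chrom Sites per chromosome.
#' @param seed Integer seed for allele assignment.
#' @return A [as_snp_panel()] tibble.
#' @export
sim_panel <- function(n_chrom = 3, chrom_cM = 100, sites_per_chrom = 5000,
                      seed = 1) {
  bases <- c("A", "C", "G", "T")
  with_seed(derive_seed(seed, "panel"), {
    per <- lapply(seq_len(n_chrom), function(ch) {
      g <- seq(0, chrom_cM / 100, length.out = sites_per_chrom)
      a1 <- sample(bases, sites_per_chrom, replace = TRUE)
      a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1), "")
      tibble(
        id = sprintf("snp_%d_%d", ch, seq_len(sites_per_chrom)),
        chrom = ch, gpos = g,
        ppos = as.integer(seq(1e4, by = 2e4, length.out = sites_per_chrom)),
        a1 = a1, a2 = unname(a2)
      )
    })
    as_snp_panel(dplyr::bind_rows(per))
  })
}

#' Specify a multi-population drift/admixture model
#'
#' Populations drift independently from a shared ancestral allele frequency
#' under the Balding-Nichols model: `p_pop ~ Beta(p(1-F)/F, (1-p)(1-F)/F)`.
#' Admixed populations mix two earlier populations with proportion `alpha`
#' (weight of `sourceA`) and then drift by their own `F`.
#'
#' @param populations Data frame with columns `label`, `F` (drift, `[0,1)`).
#' @param admixtures Optional data frame with columns `target`, `sourceA`,
#'   `sourceB`, `alpha`, `F` (post-admixture drift).
#' @param ancestral Range of the uniform ancestral frequency spectrum.
#' @return A `pop_model` object.
#' @export
pop_model <- function(populations, admixtures = NULL,
                      ancestral = c(0.05, 0.95)) {
  populations <- as_tibble(populations)
  stopifnot(all(c("label", "F") %in% names(populations)),
            all(populations$F >= 0 & populations$F < 1))
  known <- populations$label
  if (!is.null(admixtures)) {
    admixtures <- as_tibble(admixtures)
    stopifnot(all(c("target", "sourceA", "sourceB", "alpha", "F") %in% names(admixtures)),
              all(admixtures$alpha >= 0 & admixtures$alpha <= 1))
    for (i in seq_len(nrow(admixtures))) {
      if (!all(c(admixtures$sourceA[i], admixtures$sourceB[i]) %in% known)) {
        abort("admixture sources must precede their target")
      }
      known <- c(known, admixtures$target[i])
    }
  }
  structure(list(populations = populations, admixtures = admixtures,
                 ancestral = ancestral), class = "pop_model")
}

.bn_drift <- function(p, F) {
  if (F == 0) return(p)
  rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

#' Simulate per-population allele frequencies
#'
#' @param model A [pop_model()].
#' @param n_sites Number of unlinked sites.
#' @param seed Integer seed.
#' @return A tibble with one column per population (allele1 frequencies);
#'   the ancestral draw is attached as attribute `ancestral`.
#' @export
simulate_freqs <- function(model, n_sites, seed = 1) {
  stopifnot(inherits(model, "pop_model"), n_sites >= 1)
  with_seed(derive_seed(seed, "freqs"), {
    anc <- runif(n_sites, model$ancestral[1], model$ancestral[2])
    out <- list()
    for (i in seq_len(nrow(model$populations))) {
      out[[model$populations$label[i]]] <- .bn_drift(anc, model$populations$F[i])
    }
    if (!is.null(model$admixtures)) {
      for (i in seq_len(nrow(model$admixtures))) {
        a <- model$admixtures[i, ]
        mix <- a$alpha * out[[a$sourceA]] + (1 - a$alpha) * out[[a$sourceB]]
        out[[a$target]] <- .bn_drift(mix, a$F)
      }
    }
    res <- as_tibble(out)
    attr(res, "ancestral") <- anc
    res
  })
}

#' Simulate genotype calls from allele frequencies
#'
#' Diploid calls are `Binomial(2, p)`; pseudohaploid calls are
#' `2 * Bernoulli(p)` (a single sampled allele reported homozygous).
#'
#' @param freqs Tibble of per-population allele1 frequencies
#'   ([simulate_freqs()]), or a subset of its columns.
#' @param panel Panel whose first `nrow(freqs)` sites the frequencies map to.
#' @param n_per_pop Individuals per population (scalar or named vector).
#' @param ploidy "diploid" or "pseudohaploid" (scalar or named per population).
#' @param seed Integer seed.
#' @return A [geno_matrix()].
#' @export
simulate_genotypes <- function(freqs, panel, n_per_pop, ploidy = "diploid",
                               seed = 1) {
  pops <- names(freqs)
  n_sites <- nrow(freqs)
  panel <- as_snp_panel(panel)
  stopifnot(n_sites == nrow(panel))
  if (is.null(names(n_per_pop))) n_per_pop <- setNames(rep(n_per_pop, length(pops))[seq_along(pops)], pops)
  if (is.null(names(ploidy))) ploidy <- setNames(rep(ploidy, length(pops))[seq_along(pops)], pops)
  rows <- list(); ind <- list()
  for (pop in pops) {
    n <- n_per_pop[[pop]]
    p <- freqs[[pop]]
    m <- with_seed(derive_seed(seed, "genotypes", pop), {
      if (ploidy[[pop]] == "diploid") {
        matrix(rbinom(n * n_sites, 2L, rep(p, each = n)), nrow = n)
      } else {
        matrix(2L * rbinom(n * n_sites, 1L, rep(p, each = n)), nrow = n)
      }
    })
    rows[[pop]] <- m
    ind[[pop]] <- tibble(id = sprintf("%s_%d", pop, seq_len(n)), sex = "U",
                         population = pop, ploidy = unname(ploidy[[pop]]))
  }
  geno_matrix(do.call(rbind, rows), panel, dplyr::bind_rows(ind))
}

#' Draw a haplotype pool from population frequencies
#'
#' @param p Allele1 frequency per site.
#' @param panel Matching panel.
#' @param n_hap Number of haplotypes.
#' @param label Population label.
#' @param seed Integer seed.
#' @return A `hap_pool`: binary haplotype matrix (allele1 indicator) plus panel.
#' @export
hap_pool <- function(p, panel, n_hap, label = "pop", seed = 1) {
  panel <- as_snp_panel(panel)
  stopifnot(length(p) == nrow(panel))
  haps <- with_seed(derive_seed(seed, "hap_pool", label), {
    matrix(rbinom(n_hap * length(p), 1L, rep(p, each = n_hap)), nrow = n_hap)
  })
  structure(list(haps = haps, ancestry = NULL, panel = panel, label = label),
            class = "hap_pool")
}

#' Simulate admixed haplotypes by random mating with recombination
#'
#' Founders are drawn from pool A with probability `alpha`, else pool B;
#' `g` generations of random mating follow, with crossovers arriving as a
#' Poisson process of rate 1 per Morgan. Founder ancestry is tracked along
#' the same crossovers, so admixture LD in the output decays as
#' `exp(-g * d)` in the genetic distance `d` (Morgans).
#'
#' @param pool_a,pool_b Source [hap_pool()]s sharing a panel.
#' @param alpha Founder proportion from `pool_a`.
#' @param g Generations since admixture (`>= 0`).
#' @param n_out Haplotypes to output (sampled from the final generation).
#' @param seed Integer seed.
#' @param n_pop Breeding population size in haplotypes (default 2000, and
#'   never below `n_out`). A population much larger than the output sample
#'   keeps post-admixture drift LD negligible, so the output decay follows
#'   the admixture signal `exp(-g d)` rather than drift.
#' @return A `hap_pool` with an additional binary `ancestry` matrix
#'   (1 = founder from pool A).
#' @export
simulate_admixture_haplotypes <- function(pool_a, pool_b, alpha, g, n_out,
                                          seed = 1, n_pop = 2000) {
  stopifnot(inherits(pool_a, "hap_pool"), inherits(pool_b, "hap_pool"))
  panel <- pool_a$panel
  gpos <- panel$gpos
  chroms <- unique(panel$chrom) # panel is sorted, so chromosomes are runs
  chrom_starts <- c(match(chroms, panel$chrom), nrow(panel) + 1L)
  chrom_lens <- vapply(chroms, function(ch) max(gpos[panel$chrom == ch]), 0)
  n_pop <- max(n_pop, n_out)
  with_seed(derive_seed(seed, "admix_haps"), {
    from_a <- runif(n_pop) < alpha
    # sites x haplotypes, so each haplotype is contiguous in memory
    haps <- matrix(0L, nrow(panel), n_pop)
    haps[, from_a] <- t(pool_a$haps[sample.int(nrow(pool_a$haps), sum(from_a),
                                               replace = TRUE), , drop = FALSE])
    haps[, !from_a] <- t(pool_b$haps[sample.int(nrow(pool_b$haps), sum(!from_a),
                                                replace = TRUE), , drop = FALSE])
    anc <- matrix(rep(as.integer(from_a), each = nrow(panel)), nrow(panel))
    res <- wf_admix(haps, anc, gpos, c(chrom_starts) - 1L, chrom_lens,
                    as.integer(g), as.integer(n_out))
    structure(list(haps = t(res$haps), ancestry = t(res$ancestry),
                   panel = panel,
                   label = paste0(pool_a$label, "x", pool_b$label)),
              class = "hap_pool")
  })
}

#' Pair haplotypes into diploid genotypes
#'
#' @param pool A `hap_pool` with an even number of haplotypes.
#' @param population Population label for the resulting individuals.
#' @return A [geno_matrix()] of `n_hap/2` diploid individuals.
#' @export
haps_to_genotypes <- function(pool, population = pool$label) {
  n <- nrow(pool$haps)
  stopifnot(n %% 2L == 0L)
  odd <- seq(1, n, by = 2)
  calls <- pool$haps[odd, , drop = FALSE] + pool$haps[odd + 1L, , drop = FALSE]
  geno_matrix(calls, pool$panel,
              tibble(id = sprintf("%s_%d", population, seq_along(odd)), sex = "U",
                     population = population, ploidy = "diploid"))
}

#' Read-simulation parameters
#'
#' @param mean_depth Poisson mean coverage per (diploid) site.
#' @param error_rate Per-base sequencing error (uniform among other bases).
#' @param deam_amplitude 5' terminal C-to-T deamination probability.
#' @param deam_decay Per-position geometric decay factor of deamination
#'   (`0 < k < 1`).
#' @param read_length Read length in bases.
#' @return A `read_sim_params` list.
#' @export
read_sim_params <- function(mean_depth = 1, error_rate = 0.001,
                            deam_amplitude = 0, deam_decay = 0.5,
                            read_length = 75) {
  stopifnot(error_rate >= 0, error_rate <= 1, deam_amplitude >= 0,
            deam_amplitude <= 1, deam_decay > 0, deam_decay < 1,
            read_length >= 1)
  structure(list(mean_depth = mean_depth, error_rate = error_rate,
                 deam_amplitude = deam_amplitude, deam_decay = deam_decay,
                 read_length = as.integer(read_length)),
            class = "read_sim_params")
}

.OTHER_BASES <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                     G = c("A", "C", "T"), T = c("A", "C", "G"))

#' Simulate sequencing reads over panel sites for one individual
#'
#' Per site, depth is Poisson with mean `mean_depth * copies / 2`; each read
#' templates one of the individual's two alleles uniformly. 5' C-to-T
#' deamination is applied with probability `deam_amplitude * deam_decay^pos`
#' (mirrored as G-to-A on the minus strand, matching pileup orientation),
#' then sequencing error substitutes uniformly among the other bases. The
#' panel's allele1 plays the role of the reference base.
#'
#' @param genotype Integer vector of allele1 copies (0/1/2, `NA` skipped)
#'   along the panel.
#' @param panel Matching [as_snp_panel()].
#' @param params A [read_sim_params()].
#' @param seed Integer seed.
#' @param copies Per-site template copy number (2 = autosomal diploid;
#'   1 halves coverage as on male sex chromosomes; 0 yields no reads).
#' @return Observation tibble with `chrom`, `ppos`, `ref`, `base`, `strand`,
#'   `bq`, `mq`, `read_pos`, `read_len`.
#' @export
simulate_reads <- function(genotype, panel, params, seed = 1, copies = 2) {
  panel <- as_snp_panel(panel)
  stopifnot(inherits(params, "read_sim_params"),
            length(genotype) == nrow(panel))
  copies <- rep_len(copies, nrow(panel))
  with_seed(derive_seed(seed, "reads"), {
    lam <- params$mean_depth * copies / 2
    lam[is.na(genotype)] <- 0
    depth <- rpois(nrow(panel), lam)
    site <- rep.int(seq_len(nrow(panel)), depth)
    n <- length(site)
    if (n == 0L) {
      return(tibble(chrom = integer(), ppos = integer(), ref = character(),
                    base = character(), strand = character(), bq = integer(),
                    mq = integer(), read_pos = integer(), read_len = integer()))
    }
    # template allele: allele1 with probability genotype/2
    take1 <- runif(n) < genotype[site] / 2
    base <- ifelse(take1, panel$a1[site], panel$a2[site])
    strand <- ifelse(runif(n) < 0.5, "+", "-")
    read_pos <- as.integer(floor(runif(n, 0, params$read_length)))
    # 5' terminal deamination in read orientation
    pdeam <- params$deam_amplitude * params$deam_decay^read_pos
    hit <- runif(n) < pdeam
    ct <- hit & strand == "+" & base == "C"
    ga <- hit & strand == "-" & base == "G"
    base[ct] <- "T"
    base[ga] <- "A"
    err <- runif(n) < params$error_rate
    if (any(err)) {
      pickv <- ceiling(runif(sum(err)) * 3)
      base[err] <- mapply(function(b, k) .OTHER_BASES[[b]][k], base[err], pickv)
    }
    tibble(chrom = panel$chrom[site], ppos = panel$ppos[site],
           ref = panel$a1[site], base = base, strand = strand,
           bq = 40L, mq = 60L, read_pos = read_pos,
           read_len = params$read_length)
  })
}
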