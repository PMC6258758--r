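# Pseudohaploid genotype calling from pileup observations, terminal
# deamination profiling, phenotype-SNP read counting and coverage QC.

#' Pseudohaploid caller configuration
#'
#' @param min_bq Minimum base quality (phred). Default 30.
#' @param min_mq Minimum mapping quality (phred). Default 30.
#' @param transversions_only Restrict calls to transversion sites.
#' @param trim_bases Observations within this many bases of either read end
#'   are discarded (default 2), removing the positions most affected by
#'   residual deamination; equivalent in effect to trimming the reads.
#' @param seed Integer seed for the random read draw.
#' @return A `caller_config` list.
#' @export
caller_config <- function(min_bq = 30, min_mq = 30, transversions_only = FALSE,
                          trim_bases = 2, seed = 1) {
  stopifnot(min_bq >= 0, min_mq >= 0, trim_bases >= 0)
  structure(list(min_bq = min_bq, min_mq = min_mq,
                 transversions_only = transversions_only,
                 trim_bases = as.integer(trim_bases), seed = as.integer(seed)),
            class = "caller_config")
}

.filter_obs <- function(obs, config) {
  keep <- (is.na(obs$bq) | obs$bq >= config$min_bq) &
    (is.na(obs$mq) | obs$mq >= config$min_mq)
  if (config$trim_bases > 0L) {
    near5 <- !is.na(obs$read_pos) & obs$read_pos < config$trim_bases
    near3 <- !is.na(obs$read_pos) & !is.na(obs$read_len) &
      obs$read_pos >= obs$read_len - config$trim_bases
    keep <- keep & !near5 & !near3
  }
  obs[keep, , drop = FALSE]
}

#' Call pseudohaploid genotypes from pileup observations
#'
#' Observations are filtered by base/mapping quality and end-trim, then one
#' surviving read per site is drawn uniformly at random; the individual is
#' reported homozygous for its base: 2 copies of allele1 if the base matches
#' allele1, 0 if it matches allele2, missing otherwise (including `N`) or
#' when no read survives. The draw is keyed by `(individual, site)` so site
#' insertion order is irrelevant.
#'
#' @param obs Observation tibble ([read_pileup()] / [simulate_reads()]).
#' @param panel Site panel.
#' @param config A [caller_config()].
#' @param individual Identifier entering the random-draw key.
#' @return Integer vector of calls (`NA` = missing) along the panel.
#' @export
call_pseudohaploid <- function(obs, panel, config = caller_config(),
                               individual = "sample") {
  panel <- as_snp_panel(panel)
  obs <- .filter_obs(obs, config)
  site <- match(paste(obs$chrom, obs$ppos), paste(panel$chrom, panel$ppos))
  obs <- obs[!is.na(site), , drop = FALSE]
  site <- site[!is.na(site)]
  calls <- rep(NA_integer_, nrow(panel))
  if (nrow(obs) > 0L) {
    # deterministic per-(individual, site) draw among surviving reads;
    # reads are put in a canonical order first so the draw does not depend
    # on input row order
    ord <- order(site, obs$base, obs$bq, obs$mq, obs$strand, obs$read_pos,
                 method = "radix")
    obs <- obs[ord, , drop = FALSE]; site <- site[ord]
    counts <- tabulate(site, nbins = nrow(panel))
    covered <- which(counts > 0L)
    first <- cumsum(c(0L, counts))[covered] # offset of each site's run
    u <- hash_unit(derive_seed(config$seed, "pseudohaploid", individual),
                   rep(1, length(covered)), covered)
    pick <- first + pmin(floor(u * counts[covered]), counts[covered] - 1L) + 1L
    b <- obs$base[pick]
    calls[covered] <- ifelse(b == panel$a1[covered], 2L,
                             ifelse(b == panel$a2[covered], 0L, NA_integer_))
  }
  if (config$transversions_only) {
    calls[!transversion_mask(panel)] <- NA_integer_
  }
  calls
}

#' Genotype many individuals' pileups into a matrix
#'
#' @param obs_list Named list of observation tibbles, one per individual.
#' @param panel Site panel.
#' @param config A [caller_config()].
#' @param populations Optional named vector of population labels.
#' @return A [geno_matrix()] of pseudohaploid individuals.
#' @export
genotype_pileups <- function(obs_list, panel, config = caller_config(),
                             populations = NULL) {
  panel <- as_snp_panel(panel)
  ids <- names(obs_list) %||% sprintf("ind_%d", seq_along(obs_list))
  calls <- do.call(rbind, lapply(seq_along(obs_list), function(i) {
    call_pseudohaploid(obs_list[[i]], panel, config, individual = ids[i])
  }))
  pops <- if (is.null(populations)) ids else unname(populations[ids])
  geno_matrix(calls, panel,
              tibble(id = ids, sex = "U", population = pops,
                     ploidy = "pseudohaploid"))
}

#' Transversion site mask
#'
#' `TRUE` for sites whose allele pair is a transversion; the transition
#' pairs `{C,T}` and `{G,A}` are masked out, removing sites confusable with
#' post-mortem deamination artefacts.
#'
#' @param panel Site panel.
#' @return Logical vector along the panel.
#' @export
transversion_mask <- function(panel) {
  pair <- paste(pmin(panel$a1, panel$a2), pmax(panel$a1, panel$a2))
  !(pair %in% c("C T", "A G"))
}

#' Terminal substitution (deamination) profile
#'
#' At each distance `i` from the read's own 5' end, the C-to-T frequency is
#' the fraction of reference-C positions read as T in read orientation
#' (on minus-strand reads this appears as reference G read as A in pileup
#' orientation); the 3' G-to-A profile is the mirrored count from the 3'
#' end. Positions never observed report `NA`, not 0.
#'
#' @param obs Observation tibble carrying `read_pos`, `read_len`, `strand`
#'   and the per-site reference base `ref`.
#' @param window Number of terminal positions to profile (default 25).
#' @return A tibble: `position`, `ct_5prime`, `n_ct`, `ga_3prime`, `n_ga`.
#' @export
damage_profile <- function(obs, window = 25) {
  obs <- obs[!is.na(obs$read_pos), , drop = FALSE]
  pos5 <- obs$read_pos
  pos3 <- obs$read_len - 1L - obs$read_pos # NA without read lengths
  # read-orientation C opportunities: ref C on +, ref G on -
  opp5 <- ifelse(obs$strand == "+", obs$ref == "C", obs$ref == "G")
  hit5 <- opp5 & ifelse(obs$strand == "+", obs$base == "T", obs$base == "A")
  # read-orientation G opportunities (3' mirror): ref G on +, ref C on -
  opp3 <- ifelse(obs$strand == "+", obs$ref == "G", obs$ref == "C")
  hit3 <- opp3 & ifelse(obs$strand == "+", obs$base == "A", obs$base == "T")
  idx <- seq_len(window) - 1L
  n5 <- vapply(idx, function(i) sum(opp5 & pos5 == i), 0)
  h5 <- vapply(idx, function(i) sum(hit5 & pos5 == i), 0)
  n3 <- vapply(idx, function(i) sum(opp3 & pos3 == i, na.rm = TRUE), 0)
  h3 <- vapply(idx, function(i) sum(hit3 & pos3 == i, na.rm = TRUE), 0)
  tibble(position = idx,
         ct_5prime = ifelse(n5 > 0, h5 / n5, NA_real_), n_ct = n5,
         ga_3prime = ifelse(n3 > 0, h3 / n3, NA_real_), n_ga = n3)
}

#' Per-SNP allele read counts (phenotype SNPs)
#'
#' Counts reads supporting each panel allele after quality filtering; no
#' random draw is involved.
#'
#' @param obs Observation tibble.
#' @param panel Site panel.
#' @param snp_ids SNP identifiers to tabulate (subset of the panel).
#' @param config A [caller_config()] (only the quality filters apply).
#' @return Tibble: `id`, `allele1`, `allele2`, `n_allele1`, `n_allele2`,
#'   `n_other`.
#' @export
phenotype_table <- function(obs, panel, snp_ids, config = caller_config()) {
  panel <- as_snp_panel(panel)
  stopifnot(all(snp_ids %in% panel$id))
  obs <- .filter_obs(obs, config)
  sub <- panel[match(snp_ids, panel$id), ]
  site <- match(paste(obs$chrom, obs$ppos), paste(sub$chrom, sub$ppos))
  ok <- !is.na(site)
  obs <- obs[ok, , drop = FALSE]; site <- site[ok]
  n1 <- tabulate(site[obs$base == sub$a1[site]], nbins = nrow(sub))
  n2 <- tabulate(site[obs$base == sub$a2[site]], nbins = nrow(sub))
  nt <- tabulate(site, nbins = nrow(sub))
  tibble(id = sub$id, allele1 = sub$a1, allele2 = sub$a2,
         n_allele1 = n1, n_allele2 = n2, n_other = nt - n1 - n2)
}

#' Minimum-SNP coverage QC
#'
#' An individual passes when its number of non-missing autosomal calls is
#' at least `threshold` (default 15,000); individuals below the threshold
#' are conventionally excluded from downstream analyses.
#'
#' @param x A [geno_matrix()].
#' @param threshold Minimum autosomal call count.
#' @return Tibble: `id`, `n_snps`, `pass`.
#' @export
qc_min_snps <- function(x, threshold = 15000) {
  aut <- x$panel$chrom <= 22L
  n <- unname(rowSums(!is.na(x$calls[, aut, drop = FALSE])))
  tibble(id = x$ind$id, n_snps = as.integer(n), pass = n >= threshold)
}
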