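# Shared fixture builders; everything is generated in code at test time.

tiny_panel <- function(n = 4, chrom = 1) {
  as_snp_panel(tibble::tibble(
    id = sprintf("s%d", seq_len(n)), chrom = chrom,
    gpos = seq(0, by = 0.001, length.out = n),
    ppos = seq(1000L, by = 1000L, length.out = n),
    a1 = rep(c("A", "C"), length.out = n),
    a2 = rep(c("C", "G"), length.out = n)
  ))
}

# two diverged sources, an alpha-admixed target, and structured rights for
# qpWave/qpAdm experiments
qpadm_sim_model <- function(alpha = 0.3, spurious = FALSE) {
  pops <- tibble::tibble(
    label = c("Out", "S1", "S2", if (spurious) "S3", "OutB", "OutC"),
    F = c(0.3, 0.1, 0.1, if (spurious) 0.12, 0.2, 0.25)
  )
  adm <- tibble::tibble(
    target = c("R1", "R2", "R3", "R4", "T"),
    sourceA = c("S1", "S2", "S1", "S2", "S1"),
    sourceB = c("OutB", "OutB", "OutC", "OutC", "S2"),
    alpha = c(0.5, 0.5, 0.3, 0.3, alpha),
    F = c(0.05, 0.05, 0.05, 0.05, 0.05)
  )
  pop_model(pops, adm)
}

qpadm_rights <- c("Out", "R1", "R2", "OutB", "R3")

# population frequency estimates sampled as Binomial(2n, p) / 2n, the
# sampling distribution of allele-frequency estimates from n diploids
sim_freq_table <- function(model, panel, seed, n_alleles = 50) {
  fr <- simulate_freqs(model, nrow(panel), seed = seed)
  p <- t(as.matrix(fr))
  ph <- with_seed(derive_seed(seed, "freq_sampling"), {
    matrix(stats::rbinom(length(p), n_alleles, p) / n_alleles, nrow(p),
           dimnames = dimnames(p))
  })
  freq_table(ph, panel, matrix(n_alleles, nrow(p), ncol(p),
                               dimnames = dimnames(p)))
}

with_seed <- sibtrace:::with_seed
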