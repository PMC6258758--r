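test_that("zero drift reproduces the ancestral frequencies exactly", {
  model <- pop_model(tibble::tibble(label = c("A", "B"), F = c(0, 0)))
  fr <- simulate_freqs(model, 100, seed = 1)
  anc <- attr(fr, "ancestral")
  expect_equal(fr$A, anc)
  expect_equal(fr$B, anc)
})

test_that("boundary admixture proportions collapse to a single source", {
  model <- pop_model(
    tibble::tibble(label = c("A", "B"), F = c(0.1, 0.1)),
    admixtures = tibble::tibble(target = "C", sourceA = "A", sourceB = "B",
                                alpha = 1, F = 0)
  )
  fr <- simulate_freqs(model, 200, seed = 2)
  expect_equal(fr$C, fr$A)
  model0 <- pop_model(
    tibble::tibble(label = c("A", "B"), F = c(0.1, 0.1)),
    admixtures = tibble::tibble(target = "C", sourceA = "A", sourceB = "B",
                                alpha = 0, F = 0)
  )
  fr0 <- simulate_freqs(model0, 200, seed = 2)
  expect_equal(fr0$C, fr0$B)
  expect_error(pop_model(tibble::tibble(label = "A", F = 0.1),
                         tibble::tibble(target = "C", sourceA = "A",
                                        sourceB = "Z", alpha = 0.5, F = 0)),
               "precede")
})

test_that("pairwise FST under drift matches the Beta-model expectation", {
  # oracle: numerical integration of E[(pA-pB)^2] / E[pA(1-pB) + pB(1-pA)]
  # under Balding-Nichols with F = 0.1 and Uniform(0.05, 0.95) ancestral p
  # under Balding-Nichols, Var(p_pop | p) = F p(1-p) and drifts are
  # independent, so E[(pA-pB)^2 | p] = 2F p(1-p) and
  # E[pA(1-pB) + pB(1-pA) | p] = 2 p(1-p); integrate over the ancestral law
  F <- 0.1
  num_int <- stats::integrate(function(p) 2 * F * p * (1 - p) / 0.9,
                              0.05, 0.95)$value
  den_int <- stats::integrate(function(p) 2 * p * (1 - p) / 0.9,
                              0.05, 0.95)$value
  fst_expected <- num_int / den_int
  model <- pop_model(tibble::tibble(label = c("A", "B"), F = c(F, F)))
  fr <- simulate_freqs(model, 50000, seed = 7)
  num <- mean((fr$A - fr$B)^2)
  den <- mean(fr$A * (1 - fr$B) + fr$B * (1 - fr$A))
  expect_lt(abs(num / den - fst_expected) / fst_expected, 0.1)
})

test_that("genotype sampling respects boundary and binomial frequencies", {
  panel <- sim_panel(1, 10, 2000, seed = 1)
  p0 <- tibble::tibble(P = rep(0, 2000))
  g0 <- simulate_genotypes(p0, panel, 5, seed = 1)
  expect_true(all(g0$calls == 0L))
  p1 <- tibble::tibble(P = rep(1, 2000))
  g1 <- simulate_genotypes(p1, panel, 5, ploidy = "pseudohaploid", seed = 1)
  expect_true(all(g1$calls == 2L))
  expect_true(all(g1$calls %in% c(0L, 2L)))
  # sample frequency at n = 500 diploids within 3 binomial SDs for 99% of sites
  model <- pop_model(tibble::tibble(label = "P", F = 0))
  fr <- simulate_freqs(model, 2000, seed = 3)
  g <- simulate_genotypes(fr, panel, 500, seed = 4)
  phat <- colMeans(g$calls) / 2
  tol <- 3 * sqrt(fr$P * (1 - fr$P) / 1000)
  expect_gte(mean(abs(phat - fr$P) <= tol), 0.99)
})

test_that("identical seeds reproduce outputs; different seeds are exchangeable", {
  model <- pop_model(tibble::tibble(label = c("A", "B"), F = c(0.1, 0.2)))
  f1 <- simulate_freqs(model, 3000, seed = 42)
  f2 <- simulate_freqs(model, 3000, seed = 42)
  expect_identical(f1, f2)
  # KS comparisons across seed pairs: site-frequency distributions agree
  pvals <- vapply(1:10, function(k) {
    a <- simulate_freqs(model, 3000, seed = 100 + k)$A
    b <- simulate_freqs(model, 3000, seed = 200 + k)$A
    suppressWarnings(stats::ks.test(a, b)$p.value)
  }, 0)
  expect_gte(mean(pvals > 0.01), 0.9)
})

test_that("read simulation honours error, damage and depth settings", {
  panel <- sim_panel(1, 20, 1500, seed = 9)
  clean <- read_sim_params(mean_depth = 2, error_rate = 0, deam_amplitude = 0)
  geno <- with_seed(5, sample(c(0L, 2L), nrow(panel), replace = TRUE))
  obs <- simulate_reads(geno, panel, clean, seed = 2)
  site <- match(paste(obs$chrom, obs$ppos), paste(panel$chrom, panel$ppos))
  allele <- ifelse(geno[site] == 2L, panel$a1[site], panel$a2[site])
  expect_true(all(obs$base == allele))
  # lambda = 0 -> empty pileup
  none <- simulate_reads(geno, panel, read_sim_params(mean_depth = 0), seed = 2)
  expect_equal(nrow(none), 0)
  # terminal damage frequencies follow delta0 * k^pos
  dam <- read_sim_params(mean_depth = 12, error_rate = 0,
                         deam_amplitude = 0.3, deam_decay = 0.5,
                         read_length = 25)
  geno_hom <- rep(2L, nrow(panel))
  obs_d <- simulate_reads(geno_hom, panel, dam, seed = 3)
  dp <- damage_profile(obs_d)
  expect_lt(abs(dp$ct_5prime[1] - 0.3), 3 * sqrt(0.3 * 0.7 / dp$n_ct[1]))
  expect_lt(abs(dp$ct_5prime[2] - 0.15), 3 * sqrt(0.15 * 0.85 / dp$n_ct[2]))
})

test_that("admixed haplotypes carry whole-chromosome tracts at g = 0", {
  panel <- sim_panel(2, 50, 200, seed = 3)
  model <- pop_model(tibble::tibble(label = c("A", "B"), F = c(0.2, 0.2)))
  fr <- simulate_freqs(model, nrow(panel), seed = 4)
  pa <- hap_pool(fr$A, panel, 100, "A", seed = 5)
  pb <- hap_pool(fr$B, panel, 100, "B", seed = 6)
  adm0 <- simulate_admixture_haplotypes(pa, pb, 0.4, 0, 60, seed = 7)
  for (ch in unique(panel$chrom)) {
    anc_ch <- adm0$ancestry[, panel$chrom == ch, drop = FALSE]
    expect_true(all(apply(anc_ch, 1, function(r) length(unique(r)) == 1)))
  }
  adm_b <- simulate_admixture_haplotypes(pa, pb, 0, 5, 60, seed = 8)
  expect_true(all(adm_b$ancestry == 0L))
})

test_that("local-ancestry covariance decays at the admixture age", {
  panel <- sim_panel(3, 100, 1200, seed = 11)
  model <- pop_model(tibble::tibble(label = c("A", "B"), F = c(0.2, 0.2)))
  fr <- simulate_freqs(model, nrow(panel), seed = 12)
  pa <- hap_pool(fr$A, panel, 400, "A", seed = 13)
  pb <- hap_pool(fr$B, panel, 400, "B", seed = 14)
  g_true <- 17
  adm <- simulate_admixture_haplotypes(pa, pb, 0.4, g_true, 400, seed = 15)
  # regression of log ancestry covariance on distance over 1-20 cM
  covs <- list(); ds <- list()
  for (ch in unique(panel$chrom)) {
    idx <- which(panel$chrom == ch)
    sub <- idx[seq(1, length(idx), by = 8)]
    C <- stats::cov(adm$ancestry[, sub])
    D <- abs(outer(panel$gpos[sub], panel$gpos[sub], `-`))
    sel <- upper.tri(C) & D >= 0.01 & D <= 0.20
    covs[[ch]] <- C[sel]; ds[[ch]] <- D[sel]
  }
  d <- unlist(ds); cv <- unlist(covs)
  bins <- floor(d / 0.01)
  bc <- tapply(cv, bins, mean)
  bd <- tapply(d, bins, mean)
  ok <- bc > 0
  slope <- -stats::coef(stats::lm(log(bc[ok]) ~ bd[ok]))[2]
  expect_lt(abs(slope - g_true) / g_true, 0.15)
})
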