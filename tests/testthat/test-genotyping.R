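obs_row <- function(panel, i, base, bq = 40L, mq = 60L, strand = "+",
                    read_pos = 30L, read_len = 75L) {
  tibble::tibble(chrom = panel$chrom[i], ppos = panel$ppos[i],
                 ref = panel$a1[i], base = base, strand = strand, bq = bq,
                 mq = mq, read_pos = read_pos, read_len = read_len)
}

test_that("pseudohaploid calls follow the single-read rule", {
  panel <- tiny_panel(3) # alleles A/C, C/G, A/C
  # unanimous reads -> deterministic call
  o <- dplyr::bind_rows(obs_row(panel, 1, "A"), obs_row(panel, 1, "A"))
  expect_equal(call_pseudohaploid(o, panel)[1], 2L)
  o2 <- dplyr::bind_rows(obs_row(panel, 1, "C"), obs_row(panel, 1, "C"))
  expect_equal(call_pseudohaploid(o2, panel)[1], 0L)
  # below quality threshold -> missing
  o3 <- obs_row(panel, 1, "A", bq = 20L)
  expect_true(is.na(call_pseudohaploid(o3, panel)[1]))
  o4 <- obs_row(panel, 1, "A", mq = 10L)
  expect_true(is.na(call_pseudohaploid(o4, panel)[1]))
  # base matching neither allele, or N -> missing
  o5 <- obs_row(panel, 1, "G")
  expect_true(is.na(call_pseudohaploid(o5, panel)[1]))
  o6 <- obs_row(panel, 1, "N")
  expect_true(is.na(call_pseudohaploid(o6, panel)[1]))
  # no coverage -> missing
  expect_true(all(is.na(call_pseudohaploid(o, panel)[2:3])))
})

test_that("end-trimmed observations are discarded before the draw", {
  panel <- tiny_panel(1)
  cfg <- caller_config(trim_bases = 2)
  near5 <- obs_row(panel, 1, "A", read_pos = 1L)
  near3 <- obs_row(panel, 1, "A", read_pos = 73L)
  inside <- obs_row(panel, 1, "C", read_pos = 2L)
  o <- dplyr::bind_rows(near5, near3, inside)
  expect_equal(call_pseudohaploid(o, panel, cfg)[1], 0L) # only 'inside' left
  expect_true(is.na(call_pseudohaploid(dplyr::bind_rows(near5, near3),
                                       panel, cfg)[1]))
})

test_that("the random draw is fair and insertion-order independent", {
  n <- 10000
  panel <- sim_panel(1, 100, n, seed = 2)
  o <- dplyr::bind_rows(
    tibble::tibble(chrom = panel$chrom, ppos = panel$ppos, ref = panel$a1,
                   base = panel$a1, strand = "+", bq = 40L, mq = 60L,
                   read_pos = 30L, read_len = 75L),
    tibble::tibble(chrom = panel$chrom, ppos = panel$ppos, ref = panel$a1,
                   base = panel$a2, strand = "+", bq = 40L, mq = 60L,
                   read_pos = 31L, read_len = 75L)
  )
  calls <- call_pseudohaploid(o, panel, caller_config(seed = 11), "ind1")
  expect_true(all(!is.na(calls)))
  expect_lt(abs(mean(calls == 2L) - 0.5), 0.015) # 3 binomial SDs at n = 1e4
  # permuting observation rows changes nothing
  perm <- with_seed(3, o[sample.int(nrow(o)), ])
  expect_identical(call_pseudohaploid(perm, panel, caller_config(seed = 11),
                                      "ind1"), calls)
  # and the same seed is bit-reproducible
  expect_identical(call_pseudohaploid(o, panel, caller_config(seed = 11),
                                      "ind1"), calls)
})

test_that("transversion mask excludes exactly the transition pairs", {
  panel <- tiny_panel(2) # A/C (transversion), C/G (transversion)
  expect_equal(transversion_mask(panel), c(TRUE, TRUE))
  tpan <- as_snp_panel(tibble::tibble(
    id = c("x", "y"), chrom = 1, gpos = c(0, 0.1), ppos = c(1, 2),
    a1 = c("A", "T"), a2 = c("G", "C")
  ))
  expect_equal(transversion_mask(tpan), c(FALSE, FALSE))
  # brute-force set membership on a random panel
  panel_r <- sim_panel(1, 10, 1000, seed = 6)
  brute <- !(paste0(panel_r$a1, panel_r$a2) %in%
               c("CT", "TC", "GA", "AG"))
  expect_equal(transversion_mask(panel_r), brute)
  cfg <- caller_config(transversions_only = TRUE)
  o <- dplyr::bind_rows(obs_row(tpan, 1, "A"), obs_row(tpan, 2, "T"))
  expect_true(all(is.na(call_pseudohaploid(o, tpan, cfg))))
})

test_that("damage profile handles no-damage, short reads and empty cells", {
  panel <- sim_panel(1, 20, 2000, seed = 3)
  clean <- read_sim_params(mean_depth = 4, error_rate = 0.001,
                           deam_amplitude = 0, read_length = 10)
  obs <- simulate_reads(rep(2L, nrow(panel)), panel, clean, seed = 5)
  dp <- damage_profile(obs, window = 25)
  ok <- !is.na(dp$ct_5prime)
  expect_true(all(dp$ct_5prime[ok] <=
                    0.001 + 3 * sqrt(0.001 / pmax(dp$n_ct[ok], 1))))
  # window beyond the read length: trailing positions missing, not zero
  expect_true(all(is.na(dp$ct_5prime[dp$position >= 10])))
  expect_true(all(dp$n_ct[dp$position >= 10] == 0))
})

test_that("phenotype tables count allele-supporting reads without drawing", {
  panel <- tiny_panel(3)
  o <- dplyr::bind_rows(obs_row(panel, 1, "A"), obs_row(panel, 1, "A"),
                        obs_row(panel, 1, "C"), obs_row(panel, 1, "T"))
  tab <- phenotype_table(o, panel, panel$id)
  expect_equal(tab$n_allele1, c(2L, 0L, 0L))
  expect_equal(tab$n_allele2, c(1L, 0L, 0L))
  expect_equal(tab$n_other, c(1L, 0L, 0L))
  # simulated heterozygote: allele1 read fraction 0.5 within 3 binomial SDs
  panel2 <- sim_panel(1, 10, 200, seed = 4)
  obs2 <- simulate_reads(rep(1L, 200), panel2,
                         read_sim_params(mean_depth = 20, error_rate = 0),
                         seed = 6)
  tab2 <- phenotype_table(obs2, panel2, panel2$id)
  tot <- sum(tab2$n_allele1) + sum(tab2$n_allele2)
  expect_lt(abs(sum(tab2$n_allele1) / tot - 0.5), 3 * sqrt(0.25 / tot))
})

test_that("minimum-SNP QC applies the threshold to autosomal calls", {
  panel <- sim_panel(1, 100, 16000, seed = 5)
  calls <- matrix(NA_integer_, 3, 16000)
  calls[1, seq_len(14999)] <- 2L
  calls[2, seq_len(15000)] <- 2L
  ind <- tibble::tibble(id = c("below", "at", "empty"), sex = "U",
                        population = "P", ploidy = "pseudohaploid")
  qc <- qc_min_snps(geno_matrix(calls, panel, ind))
  expect_equal(qc$pass, c(FALSE, TRUE, FALSE))
  expect_equal(qc$n_snps, c(14999L, 15000L, 0L))
})

test_that("pseudohaploid frequency estimates from reads are unbiased", {
  panel <- sim_panel(1, 50, 1500, seed = 7)
  model <- pop_model(tibble::tibble(label = "P", F = 0))
  fr <- simulate_freqs(model, nrow(panel), seed = 8)
  g <- simulate_genotypes(fr, panel, 40, seed = 9)
  obs_list <- lapply(seq_len(40), function(i) {
    simulate_reads(g$calls[i, ], panel,
                   read_sim_params(mean_depth = 2, error_rate = 0),
                   seed = derive_seed(10, i))
  })
  names(obs_list) <- g$ind$id
  called <- genotype_pileups(obs_list, panel, caller_config(seed = 12),
                             populations = setNames(rep("P", 40), g$ind$id))
  fq <- allele_freqs(called)
  n <- fq$n["P", ]
  dev <- abs(fq$p["P", ] - fr$P)
  tol <- 3 * sqrt(fr$P * (1 - fr$P) / pmax(n, 1))
  expect_gte(mean(dev <= tol, na.rm = TRUE), 0.99)
})
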