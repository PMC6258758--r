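test_that("eigenstrat genotype and snp lines decode as specified", {
  td <- withr::local_tempdir()
  writeLines(c("rs1 1 0.012 1000 A G", "rs2 2 0.000 500 C A"),
             file.path(td, "x.snp"))
  writeLines(c("029", "111"), file.path(td, "x.geno"))
  writeLines(c("i1 M P1", "i2 F P1", "i3 U P2"), file.path(td, "x.ind"))
  g <- read_eigenstrat(file.path(td, "x"))
  # panel sorts by (chrom, ppos); rs1 stays first
  expect_equal(g$panel$id, c("rs1", "rs2"))
  expect_equal(g$panel$gpos[1], 0.012)
  expect_equal(g$panel$ppos[1], 1000L)
  expect_equal(g$panel$a1[1], "A")
  expect_equal(unname(g$calls[, 1]), c(0L, 2L, NA))
  expect_equal(unname(g$calls[, 2]), c(1L, 1L, 1L))
  expect_equal(g$ind$ploidy, c("diploid", "diploid", "diploid"))
})

test_that("individuals without heterozygous calls are flagged pseudohaploid", {
  td <- withr::local_tempdir()
  writeLines(c("rs1 1 0.0 1000 A G", "rs2 1 0.0 2000 C A"),
             file.path(td, "x.snp"))
  writeLines(c("02", "21"), file.path(td, "x.geno"))
  writeLines(c("i1 U P1", "i2 U P1"), file.path(td, "x.ind"))
  g <- read_eigenstrat(file.path(td, "x"))
  expect_equal(g$ind$ploidy, c("pseudohaploid", "diploid"))
  g2 <- read_eigenstrat(file.path(td, "x"), ploidy = c(i1 = "diploid"))
  expect_equal(g2$ind$ploidy, c("diploid", "diploid"))
})

test_that("eigenstrat round-trip is byte-identical on canonical files", {
  panel <- sim_panel(2, 50, 60, seed = 3)
  model <- pop_model(tibble::tibble(label = c("A", "B"), F = c(0.05, 0.1)))
  fr <- simulate_freqs(model, nrow(panel), seed = 5)
  g <- simulate_genotypes(fr, panel, n_per_pop = c(A = 4, B = 3),
                          ploidy = c(A = "diploid", B = "pseudohaploid"),
                          seed = 2)
  p1 <- file.path(withr::local_tempdir(), "a")
  p2 <- file.path(withr::local_tempdir(), "b")
  write_eigenstrat(g, p1)
  write_eigenstrat(read_eigenstrat(p1), p2)
  for (ext in c(".snp", ".geno", ".ind")) {
    expect_identical(readLines(paste0(p1, ext)), readLines(paste0(p2, ext)))
  }
})

test_that("degenerate genotype matrices write valid files", {
  panel <- tiny_panel(1)
  g0 <- geno_matrix(matrix(integer(0), 0, 1), panel,
                    tibble::tibble(id = character(), sex = character(),
                                   population = character(),
                                   ploidy = character()))
  p <- file.path(withr::local_tempdir(), "e")
  write_eigenstrat(g0, p)
  expect_identical(readLines(paste0(p, ".geno")), "")
  expect_identical(readLines(paste0(p, ".ind")), character(0))
  g1 <- geno_matrix(matrix(2L, 1, 1), panel,
                    tibble::tibble(id = "i", sex = "U", population = "P",
                                   ploidy = "pseudohaploid"))
  write_eigenstrat(g1, p)
  expect_identical(readLines(paste0(p, ".geno")), "2")
})

test_that("malformed eigenstrat input reports file and position", {
  td <- withr::local_tempdir()
  writeLines(c("rs1 1 0.0 1000 A G"), file.path(td, "x.snp"))
  writeLines(c("012"), file.path(td, "x.geno"))
  writeLines(c("i1 U P1", "i2 U P1"), file.path(td, "x.ind"))
  expect_error(read_eigenstrat(file.path(td, "x")), "line 1.*2 individuals")
  writeLines(c("0x"), file.path(td, "x.geno"))
  expect_error(read_eigenstrat(file.path(td, "x")),
               "line 1 position 2.*invalid")
  writeLines(c("01", "22"), file.path(td, "x.geno"))
  expect_error(read_eigenstrat(file.path(td, "x")), "2 genotype rows")
})

test_that("pileup dialect decodes bases, strands, qualities and markup", {
  panel <- as_snp_panel(tibble::tibble(
    id = c("a", "b", "c"), chrom = 1, gpos = c(0, 0.001, 0.002),
    ppos = c(100L, 200L, 300L), a1 = c("C", "A", "G"), a2 = c("A", "G", "T")
  ))
  lines <- c(
    "1\t100\tC\t4\t.,..\tIIII\t]]]]",
    "1\t200\tA\t2\t.+2AG.\tII\t]]",
    "1\t300\tG\t3\t^].t$*\tIJ5\t]]]",
    "1\t999\tT\t1\t.\tI\t]" # not in panel: dropped
  )
  obs <- read_pileup(lines, panel)
  s1 <- obs[obs$ppos == 100, ]
  expect_equal(s1$base, rep("C", 4))
  expect_equal(s1$strand, c("+", "-", "+", "+"))
  expect_equal(s1$bq, rep(40L, 4))
  expect_equal(nrow(obs[obs$ppos == 200, ]), 2) # insertion consumed
  s3 <- obs[obs$ppos == 300, ]
  expect_equal(s3$base, c("G", "T")) # deletion placeholder dropped
  expect_equal(s3$strand, c("+", "-"))
  expect_false(any(obs$ppos == 999))
  expect_error(read_pileup("1\t100\tC\t2\t..\tIII\t]]]", panel),
               "line 1.*qualities")
})

test_that("simulated reads round-trip through pileup text with counts conserved", {
  panel <- sim_panel(1, 10, 50, seed = 8)
  params <- read_sim_params(mean_depth = 3, error_rate = 0.01,
                            deam_amplitude = 0.2)
  geno <- with_seed(1, sample(c(0L, 1L, 2L), nrow(panel), replace = TRUE))
  obs <- simulate_reads(geno, panel, params, seed = 4)
  f <- withr::local_tempfile()
  write_pileup(obs, f)
  back <- read_pileup(f, panel)
  expect_equal(nrow(back), nrow(obs))
  tab1 <- dplyr::count(obs, ppos, base)
  tab2 <- dplyr::count(back, ppos, base)
  expect_equal(dplyr::arrange(tab1, ppos, base),
               dplyr::arrange(tab2, ppos, base))
})

test_that("calibration curves load, sort and interpolate linearly", {
  cc <- read_calcurve(c("# IntCal-style header", "2000, 1900, 10",
                        "1000, 950, 10"))
  expect_equal(cc$cal_bp, c(1000, 2000)) # ascending after sort
  at <- sibtrace:::.curve_at(cc, 1500)
  expect_equal(at$mu, 1425)
  ident <- read_calcurve(sprintf("%d %d 1", 50:1, 50:1))
  expect_equal(sibtrace:::.curve_at(ident, 17.5)$mu, 17.5)
  expect_error(read_calcurve("1000 950 10"), "at least 2 rows")
  expect_error(read_calcurve(c("1000 950 10", "1000 900 10", "900 800 10")),
               "non-monotone")
  expect_error(read_calcurve(c("1000 950 0", "900 800 10")), "positive")
})

test_that("snp panel invariants are enforced", {
  expect_error(as_snp_panel(tibble::tibble(id = "s", chrom = "MT", gpos = 0,
                                           ppos = 1, a1 = "A", a2 = "C")),
               "unsupported chromosome")
  expect_error(as_snp_panel(tibble::tibble(id = "s", chrom = 1, gpos = 0,
                                           ppos = 1, a1 = "A", a2 = "A")),
               "differ")
  expect_error(as_snp_panel(tibble::tibble(id = c("s", "t"), chrom = 1,
                                           gpos = 0, ppos = 1,
                                           a1 = "A", a2 = "C")),
               "duplicate")
  x <- as_snp_panel(tibble::tibble(id = c("s", "t"), chrom = c(1, "X"),
                                   gpos = 0, ppos = 1, a1 = "A", a2 = "C"))
  expect_equal(x$chrom, c(1L, 23L))
})
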