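panel_q <- sim_panel(3, 100, 2000, seed = 2)

test_that("f4 matrix cells equal standalone f4 statistics exactly", {
  ft <- sim_freq_table(qpadm_sim_model(), panel_q, seed = 21)
  fm <- build_f4_matrix(ft, "T", c("S1", "S2"), qpadm_rights,
                        min_sites_warn = 0, min_sites_error = 10)
  for (i in 1:2) {
    for (j in 1:4) {
      ref <- f4(ft, c("S1", "S2")[i], "T", qpadm_rights[j + 1],
                qpadm_rights[1])
      expect_equal(fm$X[i, j], ref$estimate, tolerance = 1e-12)
    }
  }
})

test_that("allsnps and intersection modes agree on complete data", {
  ft <- sim_freq_table(qpadm_sim_model(), panel_q, seed = 22)
  fm1 <- build_f4_matrix(ft, "T", c("S1", "S2"), qpadm_rights,
                         allsnps = TRUE, min_sites_warn = 0,
                         min_sites_error = 10)
  fm2 <- build_f4_matrix(ft, "T", c("S1", "S2"), qpadm_rights,
                         allsnps = FALSE, min_sites_warn = 0,
                         min_sites_error = 10)
  expect_equal(fm1$X, fm2$X)
  expect_equal(fm1$Q, fm2$Q)
})

test_that("rank-test degrees of freedom and degenerate cases are exact", {
  # synthetic f4 matrix with identity covariance
  fm <- structure(list(
    X = matrix(0, 5, 6), Q = diag(30),
    reps = matrix(0, 4, 30), counts = matrix(1e4, 5, 6),
    target = "T", sources = paste0("S", 1:5), rights = paste0("R", 0:6),
    n_blocks = 4
  ), class = "f4_matrix")
  for (r in 0:4) {
    res <- qpwave_rank(fm, r)
    expect_equal(res$chi2, 0, tolerance = 1e-10)
    expect_equal(res$p_value, 1)
  }
  expect_equal(qpwave_rank(fm, 4)$dof, (5 - 4) * (6 - 4))
})

test_that("rank tests recognise the number of ancestry streams", {
  # two-stream data: left = {T, S1, S2} with T admixed from S1, S2 gives a
  # rank-1 f4 matrix; rank 0 must be rejected, rank 1 must not
  rej0 <- 0; acc1 <- 0
  for (r in 1:5) {
    ft <- sim_freq_table(qpadm_sim_model(), panel_q, seed = 400 + r)
    fm <- build_f4_matrix(ft, "T", c("S1", "S2"), qpadm_rights,
                          min_sites_warn = 0, min_sites_error = 10)
    if (qpwave_rank(fm, 0)$p_value < 0.01) rej0 <- rej0 + 1
    if (qpwave_rank(fm, 1)$p_value > 0.05) acc1 <- acc1 + 1
  }
  expect_equal(rej0, 5)
  expect_gte(acc1, 4)
})

test_that("qpAdm recovers mixture weights and normalizes them exactly", {
  ft <- sim_freq_table(qpadm_sim_model(alpha = 0.3), panel_q, seed = 23)
  m <- qpadm_fit(ft, "T", c("S1", "S2"), qpadm_rights,
                 min_sites_warn = 0, min_sites_error = 10)
  expect_equal(sum(m$weights), 1, tolerance = 1e-12)
  expect_lt(abs(m$weights["S1"] - 0.3), 4 * m$se["S1"])
  expect_true(m$feasible)
  expect_equal(nrow(tidy(m)), 2)
  expect_equal(glance(m)$n_sources, 2)
})

test_that("a duplicated population fits as a one-source clade model", {
  pops <- tibble::tibble(label = c("Out", "S1", "OutB", "OutC", "R1"),
                         F = c(0.3, 0.1, 0.2, 0.25, 0.15))
  adm <- tibble::tibble(target = "T", sourceA = "S1", sourceB = "S1",
                        alpha = 1, F = 0)
  ft <- sim_freq_table(pop_model(pops, adm), panel_q, seed = 24)
  rights1 <- c("Out", "OutB", "OutC", "R1")
  m <- qpadm_fit(ft, "T", "S1", rights1, min_sites_warn = 0,
                 min_sites_error = 10)
  expect_equal(unname(m$weights), 1)
  expect_gt(m$p_value, 0.05)
  # with one source, the fit statistic is exactly the rank-0 qpWave test
  fm <- build_f4_matrix(ft, "T", "S1", rights1, min_sites_warn = 0,
                        min_sites_error = 10)
  expect_equal(m$chi2, qpwave_rank(fm, 0)$chi2, tolerance = 1e-8)
  expect_equal(m$dof, qpwave_rank(fm, 0)$dof)
})

test_that("relabelling sources permutes the weights", {
  ft <- sim_freq_table(qpadm_sim_model(alpha = 0.3), panel_q, seed = 25)
  m12 <- qpadm_fit(ft, "T", c("S1", "S2"), qpadm_rights,
                   min_sites_warn = 0, min_sites_error = 10)
  m21 <- qpadm_fit(ft, "T", c("S2", "S1"), qpadm_rights,
                   min_sites_warn = 0, min_sites_error = 10)
  expect_equal(unname(m12$weights["S1"]), unname(m21$weights["S1"]),
               tolerance = 1e-8)
  expect_equal(m12$chi2, m21$chi2, tolerance = 1e-8)
})

test_that("model search prefers minimal feasible models", {
  # search with identical outgroup sets is order-invariant
  ft <- sim_freq_table(qpadm_sim_model(alpha = 0.3, spurious = TRUE),
                       panel_q, seed = 26)
  ogs <- list(OG1 = qpadm_rights, OG2 = qpadm_rights)
  s1 <- model_search(ft, "T", c("S1", "S2", "S3"), ogs,
                     min_sites_warn = 0, min_sites_error = 10)
  expect_false(is.null(s1$selected))
  expect_true(setequal(s1$selected$sources, c("S1", "S2")))
  expect_equal(s1$selected$outgroup_set, "OG1")
  expect_true(all(c("p_value", "feasible") %in% names(s1$trials)))
  # a single source identical to the target beats any extension
  pops <- tibble::tibble(label = c("Out", "S1", "S2", "OutB", "OutC", "R1"),
                         F = c(0.3, 0.1, 0.15, 0.2, 0.25, 0.15))
  adm <- tibble::tibble(target = "T", sourceA = "S1", sourceB = "S1",
                        alpha = 1, F = 0)
  ft2 <- sim_freq_table(pop_model(pops, adm), panel_q, seed = 27)
  s2 <- model_search(ft2, "T", c("S1", "S2"),
                     list(OG1 = c("Out", "OutB", "OutC", "R1")),
                     min_sites_warn = 0, min_sites_error = 10)
  expect_false(is.null(s2$selected))
  expect_equal(s2$selected$sources, "S1")
})

test_that("self-sourced f4 matrices vanish within noise", {
  pops <- tibble::tibble(label = c("Out", "S1", "OutB", "OutC"),
                         F = c(0.3, 0.1, 0.2, 0.25))
  adm <- tibble::tibble(target = "T", sourceA = "S1", sourceB = "S1",
                        alpha = 1, F = 0)
  ft <- sim_freq_table(pop_model(pops, adm), panel_q, seed = 28)
  fm <- build_f4_matrix(ft, "T", "S1", c("Out", "OutB", "OutC"),
                        min_sites_warn = 0, min_sites_error = 10)
  z <- fm$X / sqrt(matrix(diag(fm$Q), nrow(fm$X)))
  expect_true(all(abs(z) < 4))
})
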