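# End-to-end orchestration: a one-command synthetic demo scenario and a
# configurable pipeline over its stages.

#' Pipeline configuration
#'
#' @param dir Scenario directory (as written by [make_demo()]).
#' @param out_dir Output directory for the report (default `dir`).
#' @param stages Named logical toggles: call, qc, sexdet, damage, fstats,
#'   qpadm, alder, pca, contam (the contamination power stage defaults to
#'   off; it is the slowest stage).
#' @param min_bq,min_mq,trim_bases Caller thresholds.
#' @param min_snps QC threshold on autosomal calls.
#' @param p_cutoff qpAdm working-model p-value cutoff.
#' @param min_d ALDER minimum fit distance, cM.
#' @param generation_time Years per generation.
#' @param seed Integer seed, recorded in the report.
#' @return A `run_config` list.
#' @export
run_config <- function(dir, out_dir = dir,
                       stages = c(call = TRUE, qc = TRUE, sexdet = TRUE,
                                  damage = TRUE, fstats = TRUE, qpadm = TRUE,
                                  alder = TRUE, pca = TRUE, contam = FALSE),
                       min_bq = 30, min_mq = 30, trim_bases = 2,
                       min_snps = 15000, p_cutoff = 0.05, min_d = 1.0,
                       generation_time = 29, seed = 1) {
  stopifnot(min_bq > 0, min_mq > 0, min_snps > 0, p_cutoff > 0, min_d > 0,
            generation_time > 0)
  structure(list(dir = dir, out_dir = out_dir, stages = stages,
                 min_bq = min_bq, min_mq = min_mq, trim_bases = trim_bases,
                 min_snps = min_snps, p_cutoff = p_cutoff, min_d = min_d,
                 generation_time = generation_time, seed = as.integer(seed)),
            class = "run_config")
}

#' Write a synthetic demo scenario
#'
#' Builds a three-source history (a European hunter-gatherer-like source, a
#' Siberian-like source and an early-farmer-like source, plus outgroups),
#' an admixed ancient target population created `g` generations before
#' sampling, EIGENSTRAT genotypes of all populations, damaged read pileups
#' for the ancient individuals (with X/Y sites for sex determination), and
#' a YAML file recording the simulation truth for recovery tests.
#'
#' @param dir Output directory (created).
#' @param seed Integer seed.
#' @param sites_per_chrom Autosomal panel sites per chromosome (3
#'   chromosomes of 100 cM).
#' @param alpha True Siberian-source admixture proportion of the target.
#' @param g True admixture age, generations.
#' @param n_target Diploid target individuals.
#' @return Invisibly, the scenario paths.
#' @export
make_demo <- function(dir, seed = 1, sites_per_chrom = 2000, alpha = 0.4,
                      g = 17, n_target = 40) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aut <- sim_panel(3, 100, sites_per_chrom, seed = seed)
  nx <- 200L; ny <- 100L
  sex_panel <- tibble(
    id = c(sprintf("x_%d", seq_len(nx)), sprintf("y_%d", seq_len(ny))),
    chrom = c(rep(23L, nx), rep(24L, ny)),
    gpos = c(seq(0, 1, length.out = nx), seq(0, 0.5, length.out = ny)),
    ppos = c(seq.int(1e4, by = 2e4, length.out = nx),
             seq.int(1e4, by = 2e4, length.out = ny)),
    a1 = "A", a2 = "C"
  )
  panel <- as_snp_panel(dplyr::bind_rows(aut, sex_panel))
  model <- pop_model(
    populations = tibble(
      label = c("HG_west", "Siberian", "Farmer", "OutA", "OutB", "OutC", "OutD"),
      F = c(0.08, 0.12, 0.08, 0.2, 0.15, 0.1, 0.25)
    )
  )
  freqs <- simulate_freqs(model, nrow(panel), seed = derive_seed(seed, "demo_freqs"))
  moderns <- simulate_genotypes(freqs, panel, n_per_pop = 20,
                                seed = derive_seed(seed, "demo_geno"))
  aut_idx <- which(panel$chrom <= 22)
  poolA <- hap_pool(freqs$Siberian[aut_idx], aut, 2 * n_target, "Siberian",
                    seed = derive_seed(seed, "demo_poolA"))
  poolB <- hap_pool(freqs$HG_west[aut_idx], aut, 2 * n_target, "HG_west",
                    seed = derive_seed(seed, "demo_poolB"))
  adm <- simulate_admixture_haplotypes(poolA, poolB, alpha, g, 2 * n_target,
                                       seed = derive_seed(seed, "demo_adm"))
  target_aut <- haps_to_genotypes(adm, "AncientNorth")
  # pad target calls with missing on the sex sites so panels align
  tcalls <- matrix(NA_integer_, nrow(target_aut$calls), nrow(panel))
  tcalls[, aut_idx] <- target_aut$calls
  target <- geno_matrix(tcalls, panel, target_aut$ind)
  write_eigenstrat(moderns, file.path(dir, "moderns"))
  write_eigenstrat(target, file.path(dir, "target"))
  # damaged pileups for two ancient individuals (one female, one male)
  params <- read_sim_params(mean_depth = 5, error_rate = 0.001,
                            deam_amplitude = 0.3, deam_decay = 0.5)
  sexes <- c(anc1 = "F", anc2 = "M")
  for (i in seq_along(sexes)) {
    id <- names(sexes)[i]
    p_pop <- alpha * freqs$Siberian + (1 - alpha) * freqs$HG_west
    geno <- with_seed(derive_seed(seed, "demo_ind", id), {
      2L * rbinom(nrow(panel), 1L, p_pop)
    })
    copies <- rep(2, nrow(panel))
    if (sexes[i] == "F") {
      copies[panel$chrom == 24L] <- 0
    } else {
      copies[panel$chrom >= 23L] <- 1
    }
    obs <- simulate_reads(geno, panel, params,
                          seed = derive_seed(seed, "demo_reads", id),
                          copies = copies)
    write_pileup(obs, file.path(dir, paste0(id, ".pileup")),
                 has_read_pos = TRUE)
  }
  truth <- list(
    alpha = alpha, g = g, seed = seed,
    populations = list(label = model$populations$label,
                       F = model$populations$F),
    target = "AncientNorth", sources = c("Siberian", "HG_west", "Farmer"),
    outgroup_sets = list(OG1 = c("OutA", "OutB", "OutC", "OutD"),
                         OG2 = c("OutA", "OutB", "OutD")),
    ancients = names(sexes), sexes = unname(sexes),
    sites_per_chrom = sites_per_chrom
  )
  yaml::write_yaml(truth, file.path(dir, "scenario.yaml"))
  invisible(dir)
}

.stage_on <- function(config, name) {
  isTRUE(unname(config$stages[name])) # absent toggles count as off
}

#' Run the pipeline on a scenario directory
#'
#' Executes the toggled stages (calling, QC, sex determination, damage
#' profiling, f-statistics, qpAdm model search, admixture-LD dating, PCA
#' projection) on a [make_demo()]-style scenario and writes a
#' machine-readable JSON report. The run is a pure function of (inputs,
#' config, seed).
#'
#' @param config A [run_config()].
#' @return The report list, invisibly; written to
#'   `file.path(out_dir, "report.json")`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  truth <- yaml::read_yaml(file.path(config$dir, "scenario.yaml"))
  moderns <- read_eigenstrat(file.path(config$dir, "moderns"))
  target <- read_eigenstrat(file.path(config$dir, "target"))
  panel <- moderns$panel
  report <- list(seed = config$seed, scenario = truth$target)
  cc <- caller_config(config$min_bq, config$min_mq,
                      trim_bases = config$trim_bases,
                      seed = derive_seed(config$seed, "caller"))
  obs_list <- NULL
  if (.stage_on(config, "call") || .stage_on(config, "sexdet") ||
      .stage_on(config, "damage")) {
    obs_list <- lapply(truth$ancients, function(id) {
      read_pileup(file.path(config$dir, paste0(id, ".pileup")), panel,
                  has_read_pos = TRUE)
    })
    names(obs_list) <- truth$ancients
  }
  ancients <- NULL
  if (.stage_on(config, "call")) {
    ancients <- genotype_pileups(obs_list, panel, cc)
    report$call <- list(n_individuals = nrow(ancients$calls),
                        n_calls = unname(rowSums(!is.na(ancients$calls))))
  }
  if (.stage_on(config, "qc") && !is.null(ancients)) {
    qc <- qc_min_snps(ancients, config$min_snps)
    report$qc <- list(threshold = config$min_snps, pass = qc$pass,
                      n_snps = qc$n_snps)
  }
  if (.stage_on(config, "sexdet")) {
    counts <- dplyr::bind_rows(lapply(obs_list, count_reads_by_class,
                                      panel = panel, config = cc))
    sx <- determine_sex(counts, id = truth$ancients)
    report$sexdet <- list(id = sx$id, x_rate = sx$x_rate, y_rate = sx$y_rate,
                          assignment = sx$assignment)
  }
  if (.stage_on(config, "damage")) {
    dmg <- lapply(obs_list, damage_profile)
    report$damage <- list(ct_first = vapply(dmg, function(d) d$ct_5prime[1], 0),
                          ct_second = vapply(dmg, function(d) d$ct_5prime[2], 0))
  }
  combined <- geno_matrix(rbind(moderns$calls, target$calls), panel,
                          dplyr::bind_rows(moderns$ind, target$ind))
  freqs <- allele_freqs(combined)
  if (.stage_on(config, "fstats")) {
    f3r <- f3(freqs, truth$target, truth$sources[1], truth$sources[2])
    f4r <- f4(freqs, "OutA", truth$sources[1], truth$sources[2], truth$target)
    report$fstats <- list(
      f3 = list(pops = f3r$pops, estimate = f3r$estimate, z = f3r$z,
                n_snps = f3r$n_snps),
      f4 = list(pops = f4r$pops, estimate = f4r$estimate, z = f4r$z)
    )
  }
  if (.stage_on(config, "qpadm")) {
    sr <- model_search(freqs, truth$target, truth$sources,
                       truth$outgroup_sets, p_cutoff = config$p_cutoff,
                       min_sites_warn = 0, min_sites_error = 10)
    report$qpadm <- if (is.null(sr$selected)) {
      list(feasible_model = FALSE)
    } else {
      list(feasible_model = TRUE, sources = sr$selected$sources,
           weights = unname(sr$selected$weights),
           se = unname(sr$selected$se), p_value = sr$selected$p_value,
           outgroup_set = sr$selected$outgroup_set)
    }
  }
  if (.stage_on(config, "alder")) {
    curve <- weighted_ld_curve(target, freqs$p[truth$sources[1], ],
                               freqs$p[truth$sources[2], ])
    fit <- fit_decay(curve, min_distance = config$min_d)
    report$alder <- if (isTRUE(fit$decay)) {
      dt <- admixture_date(fit$g, fit$se_g,
                           generation_time = config$generation_time)
      list(g = fit$g, se_g = fit$se_g, amplitude = fit$A,
           date_ybp = dt$date_ybp, date_se = dt$se)
    } else {
      list(g = NA, decay = FALSE)
    }
  }
  if (.stage_on(config, "pca")) {
    pcs <- fit_pca(moderns, n_pc = 5)
    proj <- project_pca(pcs, target)
    report$pca <- list(target_pc1_mean = mean(proj$PC1),
                       target_pc2_mean = mean(proj$PC2))
  }
  if (.stage_on(config, "contam")) {
    # power to detect contamination of the target by the farmer-like source
    clusters <- t(freqs$p[c("Siberian", "HG_west", "Farmer"), , drop = FALSE])
    scen <- contam_scenario(
      clusters,
      setNames(c(truth$alpha, 1 - truth$alpha), c("Siberian", "HG_west")),
      freqs$p["Farmer", ]
    )
    pw <- detection_power(scen, rates = c(0.05, 0.1), n_reps = 10,
                          seed = derive_seed(config$seed, "contam"))
    report$contam <- list(rates = pw$power$rate, power = pw$power$power,
                          min_detected = pw$min_detected)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
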