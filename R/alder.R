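# Weighted admixture-LD decay, exponential fitting, and conversion of
# generations since admixture into calendar dates.

# delta-scaled covariance matrix of genotype columns for one chromosome;
# pairwise-complete when calls are missing (pseudohaploid targets)
.scaled_cov <- function(calls, delta) {
  n <- nrow(calls)
  obs <- !is.na(calls)
  mu <- colSums(calls * obs, na.rm = TRUE) / pmax(colSums(obs), 1)
  Z <- sweep(calls, 2, mu)
  Z[!obs] <- 0
  Z <- sweep(Z, 2, delta, `*`)
  if (all(obs)) {
    crossprod(Z) / (n - 1)
  } else {
    nxy <- crossprod(obs)
    out <- crossprod(Z) / pmax(nxy - 1, 1)
    out[nxy < 2] <- NA_real_
    out
  }
}

#' Weighted admixture-LD decay curve
#'
#' For every intra-chromosome site pair within `max_d`, accumulates
#' `z(x, y) * delta(x) * delta(y)` into genetic-distance bins, where
#' `z` is the sample covariance of the target genotypes at the two sites
#' and `delta(s)` is the allele-frequency difference between the two
#' reference populations. Under a single admixture pulse `g` generations
#' ago the expectation decays as `exp(-g * d)` with `d` in Morgans.
#'
#' @param target A [geno_matrix()] of the admixed target population (or a
#'   calls matrix with `panel` supplied).
#' @param ref1,ref2 Allele1 frequency vectors of the two reference
#'   populations along the panel (`NA` sites are skipped).
#' @param panel Panel (defaults to `target$panel`).
#' @param bin_width Bin width, centimorgans (default 0.05).
#' @param max_d Maximum pair distance, centimorgans (default 30).
#' @return An `ld_curve` tibble (`d_cM` bin centers, weighted-LD `a`,
#'   `n_pairs`) with per-chromosome partial sums attached for jackknifing.
#' @export
weighted_ld_curve <- function(target, ref1, ref2, panel = NULL,
                              bin_width = 0.05, max_d = 30) {
  if (inherits(target, "geno_matrix")) {
    calls <- target$calls
    if (is.null(panel)) panel <- target$panel
    n_pseudo <- sum(target$ind$ploidy == "pseudohaploid")
    n_need <- if (n_pseudo > 0) 20 else 10
    if (nrow(calls) < n_need) {
      warn(sprintf("weighted LD: only %d target individuals (recommended >= %d)",
                   nrow(calls), n_need))
    }
  } else {
    calls <- target
    if (is.null(panel)) abort("panel required when target is a plain matrix")
  }
  panel <- as_snp_panel(panel)
  if (all(panel$gpos == 0)) abort("weighted LD requires a genetic map")
  delta <- ref1 - ref2
  keep <- !is.na(delta)
  bw_m <- bin_width / 100; max_m <- max_d / 100
  nbins <- as.integer(ceiling(max_m / bw_m + 1e-9))
  chroms <- unique(panel$chrom)
  sums <- matrix(0, nbins, length(chroms))
  counts <- matrix(0, nbins, length(chroms))
  for (ci in seq_along(chroms)) {
    idx <- which(panel$chrom == chroms[ci] & keep)
    if (length(idx) < 2) next
    C <- .scaled_cov(calls[, idx, drop = FALSE], delta[idx])
    res <- ld_pair_bins(C, panel$gpos[idx], bw_m, max_m)
    sums[, ci] <- res$sums
    counts[, ci] <- res$counts
  }
  a <- rowSums(sums) / pmax(rowSums(counts), 1)
  a[rowSums(counts) == 0] <- NA_real_
  out <- tibble(d_cM = (seq_len(nbins) - 0.5) * bin_width, a = a,
                n_pairs = rowSums(counts))
  attr(out, "chrom_sums") <- sums
  attr(out, "chrom_counts") <- counts
  attr(out, "chroms") <- chroms
  attr(out, "bin_width") <- bin_width
  class(out) <- unique(c("ld_curve", class(out)))
  out
}

.fit_exp <- function(d_m, a, wts) {
  ok <- !is.na(a) & wts > 0
  d_m <- d_m[ok]; a <- a[ok]; wts <- wts[ok]
  if (length(a) < 4) return(NULL)
  c0 <- weighted.mean(a[d_m > max(d_m) / 2], wts[d_m > max(d_m) / 2])
  resid <- a - c0
  pos <- resid > 0
  if (sum(pos) >= 3) {
    lf <- stats::lm(log(resid[pos]) ~ d_m[pos], weights = wts[pos])
    g0 <- max(-coef(lf)[2], 0.5)
    A0 <- exp(coef(lf)[1])
  } else {
    g0 <- 10; A0 <- max(a[1] - c0, 1e-6)
  }
  dat <- data.frame(d_m = d_m, a = a, wts = wts)
  start <- list(A = unname(A0), g = unname(g0), c0f = unname(c0))
  fit <- tryCatch(
    if (requireNamespace("minpack.lm", quietly = TRUE)) {
      minpack.lm::nlsLM(a ~ A * exp(-g * d_m) + c0f, start = start,
                        data = dat, weights = wts,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      nls(a ~ A * exp(-g * d_m) + c0f, start = start, data = dat,
          weights = wts, algorithm = "port",
          control = list(maxiter = 200))
    },
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  c(A = unname(cf["A"]), g = unname(cf["g"]), c = unname(cf["c0f"]))
}

#' Fit an exponential decay to a weighted-LD curve
#'
#' Weighted least squares of `a(d) = A exp(-g d) + c` over bins with center
#' at or above `min_distance` (weights = pair counts; `d` in Morgans, so
#' the decay rate is in generations). Standard errors come from a
#' delete-one-chromosome jackknife of the whole pipeline (curve
#' re-aggregation plus refit).
#'
#' @param curve An [weighted_ld_curve()] result.
#' @param min_distance Minimum fitted distance, centimorgans (default 1).
#' @param max_distance Maximum fitted distance, centimorgans (default 20).
#'   The exponential is the short-range approximation of the per-meiosis
#'   transmission function; restricting the fit keeps its bias on the decay
#'   rate below the percent level.
#' @return An `ld_fit` tibble: `A`, `g`, `c`, their jackknife SEs,
#'   `decay` flag (`FALSE` when no positive-rate fit was found) and
#'   `n_bins`.
#' @export
fit_decay <- function(curve, min_distance = 1.0, max_distance = 20.0) {
  sums <- attr(curve, "chrom_sums"); counts <- attr(curve, "chrom_counts")
  use <- curve$d_cM >= min_distance & curve$d_cM <= max_distance
  if (sum(use & !is.na(curve$a)) < 10) {
    warn("fewer than 10 usable bins above min_distance")
  }
  d_m <- curve$d_cM[use] / 100
  agg <- function(drop_ci = NULL) {
    keep <- setdiff(seq_len(ncol(sums)), drop_ci)
    s <- rowSums(sums[use, keep, drop = FALSE])
    n <- rowSums(counts[use, keep, drop = FALSE])
    list(a = ifelse(n > 0, s / n, NA_real_), n = n)
  }
  full <- agg()
  est <- .fit_exp(d_m, full$a, full$n)
  if (is.null(est) || est["g"] <= 0) {
    out <- tibble(A = NA_real_, g = NA_real_, c = NA_real_, se_A = NA_real_,
                  se_g = NA_real_, se_c = NA_real_, decay = FALSE,
                  n_bins = sum(use))
    class(out) <- unique(c("ld_fit", class(out)))
    return(out)
  }
  nch <- ncol(sums)
  loo <- matrix(NA_real_, nch, 3)
  for (ci in seq_len(nch)) {
    part <- agg(ci)
    e <- .fit_exp(d_m, part$a, part$n)
    if (!is.null(e)) loo[ci, ] <- e
  }
  ok <- complete.cases(loo)
  se <- if (sum(ok) >= 2) {
    mloo <- colMeans(loo[ok, , drop = FALSE])
    sqrt(colSums(sweep(loo[ok, , drop = FALSE], 2, mloo)^2) * (sum(ok) - 1) / sum(ok))
  } else {
    rep(NA_real_, 3)
  }
  out <- tibble(A = est["A"], g = est["g"], c = est["c"], se_A = se[1],
                se_g = se[2], se_c = se[3], decay = TRUE, n_bins = sum(use))
  attr(out, "loo") <- loo
  class(out) <- unique(c("ld_fit", class(out)))
  out
}

#' Convert an admixture age in generations to a calendar date
#'
#' `t = sample_age + generation_time * g` years before present, with
#' first-order error propagation
#' `se_t = sqrt(sample_age_se^2 + (generation_time * se_g)^2)`.
#' For modern targets the sample age is 0 +/- 0.
#'
#' @param g Generations since admixture (with standard error `se_g`).
#' @param se_g Standard error of `g`.
#' @param sample_age Sample age, calBP years (default 0 = modern).
#' @param sample_age_se Standard error of the sample age.
#' @param generation_time Years per generation (default 29).
#' @return Tibble: `date_ybp`, `se`, plus the inputs.
#' @export
admixture_date <- function(g, se_g = 0, sample_age = 0, sample_age_se = 0,
                           generation_time = 29) {
  stopifnot(g >= 0)
  tibble(
    g = g, se_g = se_g, sample_age = sample_age,
    generation_time = generation_time,
    date_ybp = sample_age + generation_time * g,
    se = sqrt(sample_age_se^2 + (generation_time * se_g)^2)
  )
}

#' Plot a weighted-LD decay curve with its fitted trendline
#'
#' @param curve An [weighted_ld_curve()] result.
#' @param fit Optional [fit_decay()] result to overlay.
#' @param min_distance Greyed-out region below this distance (cM).
#' @return A ggplot object.
#' @export
plot_ld_curve <- function(curve, fit = NULL, min_distance = 1.0) {
  p <- ggplot2::ggplot(dplyr::filter(curve, !is.na(.data$a)),
                       ggplot2::aes(x = .data$d_cM, y = .data$a)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_vline(xintercept = min_distance, linetype = "dashed") +
    ggplot2::labs(x = "genetic distance (cM)", y = "weighted LD") +
    ggplot2::theme_minimal()
  if (!is.null(fit) && isTRUE(fit$decay)) {
    grid <- tibble(d_cM = seq(min_distance, max(curve$d_cM), length.out = 200))
    grid$a <- fit$A * exp(-fit$g * grid$d_cM / 100) + fit$c
    p <- p + ggplot2::geom_line(data = grid, colour = "red")
  }
  p
}
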