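# Radiocarbon calibration against a supplied curve: posterior density over
# calendar age with a flat prior, summarized as mean/SD and highest-density
# intervals.

#' Calibrate a radiocarbon determination
#'
#' Posterior over calendar age theta on a 1-year grid:
#' `post(theta) ~ N(r; mu(theta), sigma_r^2 + sigma_curve(theta)^2)` with a
#' flat prior, where `mu` and `sigma_curve` interpolate the calibration
#' curve linearly. Reports the posterior mean and SD (calBP), and
#' highest-density regions by density thresholding (ties broken toward
#' older years). calBCE = calBP - 1950.
#'
#' @param age Radiocarbon age, 14C years BP.
#' @param sigma One-sigma measurement error (> 0).
#' @param curve A [read_calcurve()] table.
#' @param hdi_mass Mass of the highest-density region (default 0.954).
#' @param grid_step Grid step in years (default 1).
#' @return A `cal_result`: density grid, `mean_calbp`, `sd_calbp`,
#'   `median_calbp`, and an `hdi` tibble (`older`, `younger` in calBP with
#'   calBCE renderings).
#' @export
calibrate_c14 <- function(age, sigma, curve, hdi_mass = 0.954,
                          grid_step = 1) {
  stopifnot(sigma > 0, inherits(curve, "cal_curve") || is.data.frame(curve))
  grid <- seq(min(curve$cal_bp), max(curve$cal_bp), by = grid_step)
  cv <- .curve_at(curve, grid)
  v <- sigma^2 + cv$sigma^2
  logd <- -((age - cv$mu)^2) / (2 * v) - 0.5 * log(v)
  dens <- exp(logd - max(logd))
  dens <- dens / sum(dens)
  # posterior piling up at the grid ends means the curve was truncated; an
  # uninformative (flat) posterior carries its uniform share there and is fine
  edge <- grid <= min(grid) + 5 | grid >= max(grid) - 5
  edge_mass <- sum(dens[edge])
  if (edge_mass > max(1e-3, 3 * mean(edge))) {
    abort("curve range insufficient: posterior mass at the grid edges")
  }
  mean_cal <- sum(grid * dens)
  sd_cal <- sqrt(sum((grid - mean_cal)^2 * dens))
  cdf <- cumsum(dens)
  median_cal <- grid[which.max(cdf >= 0.5)]
  # HDI by density thresholding, ties toward older (larger calBP) years
  ord <- order(dens, grid, decreasing = TRUE)
  need <- ord[seq_len(which.max(cumsum(dens[ord]) >= hdi_mass))]
  inset <- sort(need)
  runs <- cumsum(c(1, diff(inset) != 1))
  hdi <- dplyr::bind_rows(lapply(split(inset, runs), function(ix) {
    tibble(older = grid[max(ix)], younger = grid[min(ix)],
           mass = sum(dens[ix]))
  }))
  hdi <- dplyr::arrange(hdi, dplyr::desc(.data$older))
  hdi$older_calbce <- hdi$older - 1950
  hdi$younger_calbce <- hdi$younger - 1950
  structure(list(
    grid_calbp = grid, density = dens, age = age, sigma = sigma,
    mean_calbp = mean_cal, sd_calbp = sd_cal, median_calbp = median_cal,
    hdi = hdi, hdi_mass = hdi_mass
  ), class = "cal_result")
}

#' @export
print.cal_result <- function(x, ...) {
  cat(sprintf("<cal_result> %.0f +/- %.0f 14C BP -> %.0f +/- %.0f calBP\n",
              x$age, x$sigma, x$mean_calbp, x$sd_calbp))
  cat(sprintf("  %.1f%% HDI:\n", 100 * x$hdi_mass))
  print(x$hdi)
  invisible(x)
}

#' Tidy the highest-density intervals of a calibration
#' @param x A `cal_result`.
#' @param ... Unused.
#' @export
tidy.cal_result <- function(x, ...) x$hdi

#' One-row summary of a calibration
#' @param x A `cal_result`.
#' @param ... Unused.
#' @export
glance.cal_result <- function(x, ...) {
  tibble(age = x$age, sigma = x$sigma, mean_calbp = x$mean_calbp,
         sd_calbp = x$sd_calbp, median_calbp = x$median_calbp,
         hdi_older = max(x$hdi$older), hdi_younger = min(x$hdi$younger))
}

#' Plot a calibrated posterior density
#'
#' @param x A [calibrate_c14()] result.
#' @return A ggplot object.
#' @export
plot_calibration <- function(x) {
  df <- tibble(calbp = x$grid_calbp, density = x$density)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$calbp, y = .data$density)) +
    ggplot2::geom_area(fill = "grey70") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "calendar age (calBP)", y = "posterior density") +
    ggplot2::theme_minimal()
}
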