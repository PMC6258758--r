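# Genetic sex determination from relative X/Y/autosome coverage.
# Females are expected at x-rate 1 and y-rate 0; males at 0.5 and 0.5.

#' Count quality-filtered reads per chromosome class
#'
#' @param obs Observation tibble.
#' @param panel Site panel (autosomes 1-22, X = 23, Y = 24).
#' @param config A [caller_config()] (quality filters only).
#' @return One-row tibble of read and site counts per class.
#' @export
count_reads_by_class <- function(obs, panel, config = caller_config()) {
  panel <- as_snp_panel(panel)
  obs <- .filter_obs(obs, config)
  site <- match(paste(obs$chrom, obs$ppos), paste(panel$chrom, panel$ppos))
  cls <- function(ch) panel$chrom %in% ch
  reads_in <- function(ch) sum(panel$chrom[site[!is.na(site)]] %in% ch)
  tibble(
    n_reads_aut = reads_in(1:22), n_reads_x = reads_in(.CHROM_X),
    n_reads_y = reads_in(.CHROM_Y),
    n_sites_aut = sum(cls(1:22)), n_sites_x = sum(cls(.CHROM_X)),
    n_sites_y = sum(cls(.CHROM_Y))
  )
}

.sex_rate <- function(n_reads, n_sites, cov_aut, n_reads_aut) {
  rate <- (n_reads / n_sites) / cov_aut
  se <- if (n_reads > 0) {
    rate * sqrt(1 / n_reads + 1 / n_reads_aut)
  } else {
    # Poisson zero count: propagate a one-count scale so the SE is finite
    (1 / n_sites) / cov_aut * sqrt(1 + 1 / n_reads_aut)
  }
  c(rate, se)
}

#' Determine genetic sex from relative sex-chromosome coverage
#'
#' Computes `x_rate = coverage_X / coverage_autosomes` and the analogous
#' `y_rate`, with standard errors by first-order propagation treating each
#' chromosome-class read total as Poisson:
#' `se = rate * sqrt(1/n_reads_class + 1/n_reads_aut)`.
#' Assignment: `XX` when `x_rate - 2 se_x > 0.75` and `y_rate + 2 se_y <
#' 0.1`; `XY` when `|x_rate - 0.5| < 2 se_x + 0.1` and `y_rate - 2 se_y >
#' 0.3`; a `consistent-with-` variant when only one criterion of a pair
#' binds; otherwise `undetermined`.
#'
#' @param counts One-row tibble as from [count_reads_by_class()] (or any
#'   data frame with those six columns; extra rows are processed rowwise).
#' @param id Optional identifier column to carry through.
#' @return Tibble with rates, standard errors and `assignment`.
#' @export
determine_sex <- function(counts, id = NULL) {
  counts <- as_tibble(counts)
  out <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    if (r$n_reads_aut == 0) {
      return(tibble(x_rate = NA_real_, y_rate = NA_real_, se_x = NA_real_,
                    se_y = NA_real_, assignment = "undetermined"))
    }
    cov_aut <- r$n_reads_aut / r$n_sites_aut
    x <- .sex_rate(r$n_reads_x, r$n_sites_x, cov_aut, r$n_reads_aut)
    y <- .sex_rate(r$n_reads_y, r$n_sites_y, cov_aut, r$n_reads_aut)
    xx1 <- x[1] - 2 * x[2] > 0.75
    xx2 <- y[1] + 2 * y[2] < 0.1
    xy1 <- abs(x[1] - 0.5) < 2 * x[2] + 0.1
    xy2 <- y[1] - 2 * y[2] > 0.3
    assignment <- if (xx1 && xx2 && !(xy1 && xy2)) {
      "XX"
    } else if (xy1 && xy2 && !(xx1 && xx2)) {
      "XY"
    } else if (xor(xx1, xx2) && !xy1 && !xy2) {
      "consistent-with-XX"
    } else if (xor(xy1, xy2) && !xx1 && !xx2) {
      "consistent-with-XY"
    } else {
      "undetermined"
    }
    tibble(x_rate = x[1], y_rate = y[1], se_x = x[2], se_y = y[2],
           assignment = assignment)
  })
  res <- dplyr::bind_cols(counts, dplyr::bind_rows(out))
  if (!is.null(id)) res <- dplyr::bind_cols(tibble(id = id), res)
  res
}

#' Scatter plot of sex-determination rates
#'
#' x-rate against y-rate with one-standard-error bars; the female (1, 0)
#' and male (0.5, 0.5) expectations are marked.
#'
#' @param results Tibble from [determine_sex()].
#' @return A ggplot object.
#' @export
plot_sex <- function(results) {
  expect <- tibble(x_rate = c(1, 0.5), y_rate = c(0, 0.5),
                   label = c("XX", "XY"))
  ggplot2::ggplot(results, ggplot2::aes(x = .data$x_rate, y = .data$y_rate)) +
    ggplot2::geom_point(data = expect, shape = 4, size = 3, colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$y_rate - .data$se_y,
                                        ymax = .data$y_rate + .data$se_y),
                           width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$x_rate - .data$se_x,
                                         xmax = .data$x_rate + .data$se_x),
                            height = 0) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$assignment)) +
    ggplot2::labs(x = "x-rate (X / autosomal coverage)",
                  y = "y-rate (Y / autosomal coverage)") +
    ggplot2::theme_minimal()
}
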