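# Supervised ancestry decomposition against fixed reference clusters, a
# contamination-injection operator, and the power analysis quantifying the
# smallest detectable contamination rate.

# batched EM on the binomial mixture likelihood; X: sites x reps matrix of
# allele1 counts (NA = missing site, handled per replicate), shared m and F
# Batched EM with a safeguarded squared-extrapolation (SQUAREM-style)
# acceleration: each cycle runs two EM steps, extrapolates along the
# observed contraction, and keeps the extrapolated point only when its
# log-likelihood does not fall below the plain double-step. The
# log-likelihood is therefore non-decreasing across cycles by construction.
.sup_anc_em <- function(X, m, F, tol = 1e-8, max_iter = 2000, trace = FALSE) {
  K <- ncol(F); R <- ncol(X)
  obs <- !is.na(X)
  Xz <- X; Xz[!obs] <- 0
  Mz <- m * obs
  msum <- colSums(Mz)
  Fc <- 1 - F
  em_step <- function(Qa, Xa, Ma, ms) {
    P <- F %*% Qa
    N1 <- crossprod(F, Xa / P) * Qa
    N2 <- crossprod(Fc, (Ma - Xa) / (1 - P)) * Qa
    sweep(N1 + N2, 2, ms, `/`)
  }
  llfun <- function(Qa, Xa, Ma) {
    P <- F %*% Qa
    colSums(Xa * log(P) + (Ma - Xa) * log1p(-P))
  }
  Q <- matrix(1 / K, K, R)
  ll <- rep(NA_real_, R)
  iter_used <- rep(max_iter, R)
  converged <- rep(FALSE, R)
  act <- seq_len(R) # converged replicates drop out of the working set
  Xa <- Xz; Ma <- Mz; Qa <- Q
  ll_old <- llfun(Qa, Xa, Ma)
  ll_trace <- if (trace) list(ll_old) else NULL
  it <- 0L
  while (it < max_iter && length(act)) {
    q1 <- em_step(Qa, Xa, Ma, msum[act])
    q2 <- em_step(q1, Xa, Ma, msum[act])
    it <- it + 2L
    if (it + 2L <= max_iter) {
      # extrapolate: q' = q0 - 2 a r + a^2 v with a = -|r|/|v|, capped at -1
      r <- q1 - Qa
      v <- q2 - q1 - r
      a <- -sqrt(colSums(r^2) / pmax(colSums(v^2), 1e-300))
      a <- pmin(a, -1)
      qe <- Qa - sweep(r, 2, 2 * a, `*`) + sweep(v, 2, a^2, `*`)
      qe <- pmax(qe, 1e-12)
      qe <- sweep(qe, 2, colSums(qe), `/`)
      qe <- em_step(qe, Xa, Ma, msum[act]) # stabilizing EM step
      it <- it + 2L
      ll_e <- llfun(qe, Xa, Ma)
      ll_2 <- llfun(q2, Xa, Ma)
      use_e <- is.finite(ll_e) & ll_e >= ll_2
      ll_new <- ifelse(use_e, ll_e, ll_2)
      Qa <- q2
      if (any(use_e)) Qa[, use_e] <- qe[, use_e]
    } else {
      ll_new <- llfun(q2, Xa, Ma)
      Qa <- q2
    }
    if (trace) ll_trace[[length(ll_trace) + 1L]] <- ll_new
    done <- (ll_new - ll_old) < tol
    if (any(done)) {
      idx <- act[done]
      Q[, idx] <- Qa[, done]
      ll[idx] <- ll_new[done]
      iter_used[idx] <- it
      converged[idx] <- TRUE
      keep <- !done
      act <- act[keep]; Xa <- Xa[, keep, drop = FALSE]
      Ma <- Ma[, keep, drop = FALSE]; Qa <- Qa[, keep, drop = FALSE]
      ll_new <- ll_new[keep]
    }
    ll_old <- ll_new
  }
  if (length(act)) {
    Q[, act] <- Qa
    ll[act] <- ll_old
  }
  out <- list(Q = Q, loglik = ll, converged = converged, n_iter = iter_used)
  if (trace) out$ll_trace <- ll_trace
  out
}

#' Supervised ancestry decomposition
#'
#' Maximizes the binomial mixture likelihood
#' `sum_s [ x log(sum_k q_k f_ks) + (m - x) log(1 - sum_k q_k f_ks) ]`
#' over the simplex of cluster proportions `q`, with the reference cluster
#' frequencies `f` held fixed (EM iteration; the log-likelihood is
#' non-decreasing by construction). Reference frequencies are clamped away
#' from 0 and 1 to keep the likelihood finite.
#'
#' @param x Allele1 copy counts per site (0..m; `NA` = missing).
#' @param m Copies observed per site: 2 for diploid calls, 1 for
#'   pseudohaploid.
#' @param ref_freqs Sites x K matrix of cluster allele1 frequencies
#'   (column names label the clusters).
#' @param clamp Clamping bound; frequencies are forced into
#'   `[clamp, 1 - clamp]`. Use `1 / (2 n_ref + 1)` for reference panels of
#'   `n_ref` diploids.
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter Maximum EM iterations.
#' @return A `supervised_ancestry` list: `q`, `loglik`, `n_sites`,
#'   `converged`, `n_iter`.
#' @export
supervised_ancestry <- function(x, m, ref_freqs, clamp = 1e-3, tol = 1e-8,
                                max_iter = 2000) {
  ref_freqs <- as.matrix(ref_freqs)
  stopifnot(length(x) == nrow(ref_freqs))
  m <- rep_len(m, length(x))
  keep <- !is.na(x)
  if (sum(keep) < 1) abort("no non-missing sites")
  F <- pmin(pmax(ref_freqs[keep, , drop = FALSE], clamp), 1 - clamp)
  if (ncol(F) == 1L) {
    return(structure(list(q = setNames(1, colnames(ref_freqs)),
                          loglik = sum(x[keep] * log(F) + (m[keep] - x[keep]) * log(1 - F)),
                          n_sites = sum(keep), converged = TRUE, n_iter = 0L),
                     class = "supervised_ancestry"))
  }
  fit <- .sup_anc_em(matrix(x[keep], ncol = 1), m[keep], F, tol, max_iter,
                     trace = TRUE)
  structure(list(
    q = setNames(drop(fit$Q), colnames(ref_freqs)),
    loglik = fit$loglik[1], n_sites = sum(keep),
    converged = fit$converged[1], n_iter = fit$n_iter[1],
    ll_trace = unlist(fit$ll_trace)
  ), class = "supervised_ancestry")
}

#' @export
print.supervised_ancestry <- function(x, ...) {
  cat(sprintf("<supervised_ancestry> %d sites, loglik %.2f%s\n", x$n_sites,
              x$loglik, if (x$converged) "" else " (not converged)"))
  print(round(x$q, 4))
  invisible(x)
}

#' Inject contamination into clean data
#'
#' Call mode (numeric input): each pseudohaploid call is independently
#' replaced, with probability `rate`, by `2 * Bernoulli(f_contaminant)`.
#' Pileup mode (observation tibble): each read is replaced, with
#' probability `rate`, by a read templated from the contaminant population
#' (no deamination, as expected of a modern contaminant).
#'
#' @param x Pseudohaploid call vector along the panel, or an observation
#'   tibble.
#' @param contam_freq Contaminant allele1 frequency per panel site.
#' @param rate Replacement probability in `[0, 1]`.
#' @param panel Panel (required in pileup mode, for allele lookup).
#' @param seed Integer seed.
#' @return Object of the same shape as `x`.
#' @export
inject_contamination <- function(x, contam_freq, rate, panel = NULL, seed = 1) {
  stopifnot(rate >= 0, rate <= 1)
  if (is.data.frame(x)) {
    if (is.null(panel)) abort("panel required in pileup mode")
    panel <- as_snp_panel(panel)
    site <- match(paste(x$chrom, x$ppos), paste(panel$chrom, panel$ppos))
    with_seed(derive_seed(seed, "contaminate", "pileup"), {
      hit <- runif(nrow(x)) < rate & !is.na(site)
      take1 <- runif(nrow(x)) < contam_freq[site]
      x$base[hit] <- ifelse(take1[hit], panel$a1[site[hit]], panel$a2[site[hit]])
      x$read_pos[hit] <- NA_integer_ # fresh template, position unknown
    })
    x
  } else {
    with_seed(derive_seed(seed, "contaminate", "calls"), {
      hit <- runif(length(x)) < rate & !is.na(x)
      x[hit] <- 2L * rbinom(sum(hit), 1L, contam_freq[hit])
    })
    x
  }
}

#' Contamination scenario for the power analysis
#'
#' @param ref_freqs Sites x K cluster frequency matrix (named columns).
#' @param true_q True cluster proportions of the test individual (named,
#'   summing to 1; zero entries define the "outside" clusters).
#' @param contam_freq Contaminant allele1 frequencies per site.
#' @return A `contam_scenario` list.
#' @export
contam_scenario <- function(ref_freqs, true_q, contam_freq) {
  ref_freqs <- as.matrix(ref_freqs)
  stopifnot(abs(sum(true_q) - 1) < 1e-8,
            length(contam_freq) == nrow(ref_freqs),
            all(names(true_q) %in% colnames(ref_freqs)))
  q <- setNames(numeric(ncol(ref_freqs)), colnames(ref_freqs))
  q[names(true_q)] <- true_q
  structure(list(ref_freqs = ref_freqs, true_q = q,
                 contam_freq = contam_freq), class = "contam_scenario")
}

#' Power to detect injected contamination
#'
#' For each rate, `n_reps` pseudohaploid replicates of the scenario's test
#' individual are simulated, contaminated, and decomposed against the
#' reference clusters. A replicate is flagged when the summed proportion
#' assigned to clusters outside the individual's true ancestry exceeds
#' `mean + rule_sd * SD` of the clean (`rate = 0`) replicates. Reports
#' per-rate power and the smallest rate with power >= 0.5.
#'
#' @param scenario A [contam_scenario()].
#' @param rates Contamination rates to test (0 is added if absent: it
#'   calibrates the detection threshold).
#' @param n_reps Replicates per rate (>= 10).
#' @param seed Integer seed.
#' @param rule_sd Detection threshold in null SDs (default 3).
#' @param clamp,tol,max_iter Passed to the decomposition.
#' @return A `power_result`: per-rate power table, per-replicate outside
#'   proportions, threshold and `min_detected`.
#' @export
detection_power <- function(scenario, rates, n_reps, seed = 1, rule_sd = 3,
                            clamp = 1e-3, tol = 1e-8, max_iter = 2000) {
  stopifnot(inherits(scenario, "contam_scenario"))
  if (n_reps < 10) abort("n_reps must be >= 10")
  rates <- sort(unique(c(0, rates)))
  F <- pmin(pmax(scenario$ref_freqs, clamp), 1 - clamp)
  S <- nrow(F); K <- ncol(F)
  q_true <- scenario$true_q
  p_ind <- drop(scenario$ref_freqs %*% q_true) # per-site allele1 prob
  outside <- q_true == 0
  X <- matrix(NA_real_, S, length(rates) * n_reps)
  col <- 0L
  for (r in rates) {
    for (rep in seq_len(n_reps)) {
      col <- col + 1L
      clean <- with_seed(derive_seed(seed, "power_clean", rep, round(1e6 * r)), {
        2L * rbinom(S, 1L, p_ind)
      })
      X[, col] <- inject_contamination(clean, scenario$contam_freq, r,
                                       seed = derive_seed(seed, "power_inject", rep, round(1e6 * r))) / 2
    }
  }
  fit <- .sup_anc_em(X, m = 1, F = F, tol = tol, max_iter = max_iter)
  stat <- colSums(fit$Q[outside, , drop = FALSE])
  stat_m <- matrix(stat, n_reps, length(rates))
  null_stats <- stat_m[, 1]
  threshold <- mean(null_stats) + rule_sd * sd(null_stats)
  detected <- stat_m > threshold
  power <- colMeans(detected)
  tab <- tibble(rate = rates, power = power, mean_outside = colMeans(stat_m))
  pos <- which(rates > 0 & power >= 0.5)
  structure(list(
    power = tab, stats = stat_m, threshold = threshold,
    min_detected = if (length(pos)) rates[min(pos)] else NA_real_,
    rule_sd = rule_sd, n_reps = n_reps
  ), class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("<power_result> threshold %.4f (%.0f SD rule); min detected rate: %s\n",
              x$threshold, x$rule_sd,
              ifelse(is.na(x$min_detected), "none", format(x$min_detected))))
  print(x$power)
  invisible(x)
}

#' Plot detection power against contamination rate
#'
#' @param x A [detection_power()] result.
#' @return A ggplot object.
#' @export
plot_power <- function(x) {
  ggplot2::ggplot(x$power, ggplot2::aes(x = .data$rate, y = .data$power)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "contamination rate", y = "detection power") +
    ggplot2::theme_minimal()
}
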