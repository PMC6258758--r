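# qpWave rank tests and qpAdm admixture-weight estimation on f4 matrices,
# plus the rotating-outgroup model-search protocol.

# eigenvalue-floored inverse of a symmetric matrix (jackknife covariances
# are often rank-deficient)
.psolve <- function(Q, floor_frac = 1e-12) {
  e <- eigen((Q + t(Q)) / 2, symmetric = TRUE)
  fl <- floor_frac * sum(abs(e$values))
  vals <- pmax(e$values, fl)
  if (fl <= 0) vals[vals <= 0] <- Inf
  e$vectors %*% (t(e$vectors) / vals)
}

#' Build an f4 matrix for qpWave/qpAdm
#'
#' Left set is `{target, sources}` with the target as basis; right set has
#' its first population as basis. Cell (i, j) holds
#' `f4(source_i, target; right_j, right_1)`. With `allsnps = TRUE`
#' (default) each cell uses its own maximal non-missing site set; otherwise
#' all cells use the global intersection. The covariance of `vec(X)` comes
#' from a delete-one-block jackknife with blocks shared across cells.
#'
#' @param freqs A [allele_freqs()] table.
#' @param target Target population (left basis).
#' @param sources Source populations.
#' @param rights Right (outgroup) populations; first is the basis.
#' @param blocks Optional block ids ([assign_blocks()] default).
#' @param allsnps Per-cell maximal site sets (default `TRUE`).
#' @param min_sites_warn,min_sites_error Cell site-count thresholds.
#' @return An `f4_matrix`: `X`, covariance `Q`, delete-one-block replicates
#'   and labels.
#' @export
build_f4_matrix <- function(freqs, target, sources, rights, blocks = NULL,
                            allsnps = TRUE, min_sites_warn = 10000,
                            min_sites_error = 1000) {
  stopifnot(length(rights) >= 2, length(sources) >= 1)
  if (is.null(blocks)) blocks <- assign_blocks(freqs$panel)
  k <- length(sources); m <- length(rights) - 1L
  pT <- .freq_rows(freqs, target)[1, ]
  pS <- .freq_rows(freqs, sources)
  pR <- .freq_rows(freqs, rights)
  obs_all <- complete.cases(t(rbind(pT, pS, pR)))
  g <- length(unique(blocks))
  bid <- match(blocks, sort(unique(blocks)))
  bs <- array(0, c(k, m, g)); bw <- array(0, c(k, m, g))
  for (i in seq_len(k)) {
    left_d <- pS[i, ] - pT
    for (j in seq_len(m)) {
      contrib <- left_d * (pR[j + 1L, ] - pR[1L, ])
      use <- if (allsnps) !is.na(contrib) else obs_all
      if (sum(use) < min_sites_error) {
        abort(sprintf("f4 cell (%s, %s): only %d sites", sources[i],
                      rights[j + 1L], sum(use)))
      }
      if (sum(use) < min_sites_warn) {
        warn(sprintf("f4 cell (%s, %s): only %d sites", sources[i],
                     rights[j + 1L], sum(use)))
      }
      bs[i, j, ] <- tapply(contrib[use], factor(bid[use], levels = seq_len(g)), sum, default = 0)
      bw[i, j, ] <- tapply(rep(1, sum(use)), factor(bid[use], levels = seq_len(g)), sum, default = 0)
    }
  }
  tot <- apply(bs, 1:2, sum); totw <- apply(bw, 1:2, sum)
  X <- tot / totw
  reps <- matrix(0, g, k * m) # leave-one-block-out vec(X) replicates
  for (b in seq_len(g)) {
    reps[b, ] <- as.vector((tot - bs[, , b]) / (totw - bw[, , b]))
  }
  vbar <- colMeans(reps)
  centred <- sweep(reps, 2, vbar)
  Q <- crossprod(centred) * (g - 1) / g
  structure(list(X = X, Q = Q, reps = reps, counts = totw, target = target,
                 sources = sources, rights = rights, n_blocks = g),
            class = "f4_matrix")
}

# chi-square distance of X from the best rank-r approximation, ALS over
# factor pairs with multi-start
.rank_chi2 <- function(v, Qinv, k, m, r, seed, n_starts = 5, tol = 1e-10,
                       max_iter = 500) {
  if (r == 0) return(drop(t(v) %*% Qinv %*% v))
  best <- Inf
  with_seed(derive_seed(seed, "rank_chi2", r), {
    for (s in seq_len(n_starts)) {
      B <- matrix(rnorm(r * m), r, m)
      obj_old <- Inf
      for (it in seq_len(max_iter)) {
        MA <- t(B) %x% diag(k)
        a <- solve(t(MA) %*% Qinv %*% MA + diag(1e-12, k * r),
                   t(MA) %*% Qinv %*% v)
        A <- matrix(a, k, r)
        MB <- diag(m) %x% A
        bvec <- solve(t(MB) %*% Qinv %*% MB + diag(1e-12, r * m),
                      t(MB) %*% Qinv %*% v)
        B <- matrix(bvec, r, m)
        resid <- v - as.vector(A %*% B)
        obj <- drop(t(resid) %*% Qinv %*% resid)
        if (abs(obj_old - obj) < tol) break
        obj_old <- obj
      }
      if (obj < best) best <- obj
    }
  })
  best
}

#' qpWave rank test
#'
#' Tests whether the f4 matrix is consistent with rank `r`, i.e. whether
#' `r + 1` independent ancestry streams relate the left populations to the
#' rights. The statistic is the chi-square distance between `X` and its
#' best rank-`r` approximation under the jackknife covariance, with
#' `dof = (|L| - 1 - r)(|R| - 1 - r)`.
#'
#' @param fm An [build_f4_matrix()] object.
#' @param r Rank under the null (`0 <= r < min(dim(X))`).
#' @param seed Seed for the multi-start minimization.
#' @return Tibble: `rank`, `chi2`, `dof`, `p_value`.
#' @export
qpwave_rank <- function(fm, r, seed = 1) {
  k <- nrow(fm$X); m <- ncol(fm$X)
  stopifnot(r >= 0, r < min(k, m))
  Qinv <- .psolve(fm$Q)
  chi2 <- .rank_chi2(as.vector(fm$X), Qinv, k, m, r, seed)
  dof <- (k - r) * (m - r)
  tibble(rank = r, chi2 = chi2, dof = dof,
         p_value = pchisq(chi2, dof, lower.tail = FALSE))
}

# covariance of y = t(X) %*% w given the covariance of vec(X)
.project_cov <- function(Q, w, k, m) {
  Qa <- array(Q, c(k, m, k, m))
  S <- matrix(0, m, m)
  for (j in seq_len(m)) {
    for (jp in j:m) {
      S[j, jp] <- S[jp, j] <- drop(t(w) %*% Qa[, j, , jp] %*% w)
    }
  }
  S
}

.fit_weights <- function(X, Q, tol = 1e-8, max_iter = 100) {
  k <- nrow(X); m <- ncol(X)
  w <- rep(1 / k, k)
  trace <- list()
  for (it in seq_len(max_iter)) {
    Si <- .psolve(.project_cov(Q, w, k, m))
    A <- X %*% Si %*% t(X)
    w_new <- drop(.psolve(A) %*% rep(1, k))
    w_new <- w_new / sum(w_new)
    trace[[it]] <- w_new
    if (sqrt(sum((w_new - w)^2)) < tol) {
      return(list(w = w_new, converged = TRUE, n_iter = it, Si = Si))
    }
    w <- w_new
  }
  list(w = w, converged = FALSE, n_iter = max_iter, trace = trace,
       Si = .psolve(.project_cov(Q, w, k, m)))
}

#' Estimate admixture proportions (qpAdm)
#'
#' Finds mixture weights `w` (summing to 1) minimizing the chi-square norm
#' of the projected f4 vector `t(X) w` under its jackknife covariance,
#' re-linearizing the covariance by fixed-point iteration. The model
#' p-value is the rank test of the left set at rank `k - 1` (`dof = |R| -
#' k`); weight standard errors come from refitting each delete-one-block
#' replicate. A model is feasible when every weight lies in `[0, 1]`.
#'
#' @inheritParams build_f4_matrix
#' @param fm Optionally a prebuilt [build_f4_matrix()] object (then `freqs`
#'   etc. are ignored).
#' @param outgroup_set Label recorded for provenance (e.g. "OG1").
#' @param ... Passed to [build_f4_matrix()].
#' @return A `qpadm_model` object; see [tidy.qpadm_model()] and
#'   [glance.qpadm_model()].
#' @export
qpadm_fit <- function(freqs = NULL, target = NULL, sources = NULL,
                      rights = NULL, fm = NULL, outgroup_set = "custom", ...) {
  if (is.null(fm)) {
    stopifnot(length(sources) >= 1, length(rights) >= length(sources) + 1)
    fm <- build_f4_matrix(freqs, target, sources, rights, ...)
  }
  k <- nrow(fm$X); m <- ncol(fm$X)
  fit <- .fit_weights(fm$X, fm$Q)
  if (!fit$converged) {
    tr <- vapply(tail(fit$trace, 3), paste, "", collapse = ",")
    abort(paste0("qpAdm weight iteration did not converge; last iterates: ",
                 paste(tr, collapse = " | ")))
  }
  w <- fit$w
  y <- drop(t(fm$X) %*% w)
  chi2 <- drop(t(y) %*% fit$Si %*% y)
  dof <- m - (k - 1L)
  p <- pchisq(chi2, dof, lower.tail = FALSE)
  g <- nrow(fm$reps)
  w_reps <- matrix(NA_real_, g, k)
  for (b in seq_len(g)) {
    Xb <- matrix(fm$reps[b, ], k, m)
    fb <- .fit_weights(Xb, fm$Q)
    w_reps[b, ] <- fb$w
  }
  wbar <- colMeans(w_reps)
  se <- sqrt(colSums(sweep(w_reps, 2, wbar)^2) * (g - 1) / g)
  tol <- 1e-6
  structure(list(
    target = fm$target, sources = fm$sources, rights = fm$rights,
    weights = setNames(w, fm$sources), se = setNames(se, fm$sources),
    chi2 = chi2, dof = dof, p_value = p,
    feasible = all(w >= -tol & w <= 1 + tol),
    snps_used = min(fm$counts), outgroup_set = outgroup_set,
    converged = fit$converged, n_iter = fit$n_iter
  ), class = "qpadm_model")
}

#' @export
print.qpadm_model <- function(x, ...) {
  cat(sprintf("<qpadm_model> %s = %s | rights: %s [%s]\n", x$target,
              paste(x$sources, collapse = " + "),
              paste(x$rights, collapse = ", "), x$outgroup_set))
  cat(sprintf("  chi2 = %.3f (dof %d), p = %.4g, %s\n", x$chi2, x$dof,
              x$p_value, if (x$feasible) "feasible" else "infeasible"))
  print(tibble(source = x$sources, weight = x$weights, se = x$se))
  invisible(x)
}

#' Tidy a qpAdm model: one row per source
#' @param x A `qpadm_model`.
#' @param ... Unused.
#' @export
tidy.qpadm_model <- function(x, ...) {
  tibble(target = x$target, source = x$sources,
         weight = unname(x$weights), se = unname(x$se))
}

#' One-row model summary of a qpAdm fit
#' @param x A `qpadm_model`.
#' @param ... Unused.
#' @export
glance.qpadm_model <- function(x, ...) {
  tibble(target = x$target, n_sources = length(x$sources),
         chi2 = x$chi2, dof = x$dof, p_value = x$p_value,
         feasible = x$feasible, snps_used = x$snps_used,
         outgroup_set = x$outgroup_set)
}

#' Model search over sources and rotating outgroup sets
#'
#' Implements the search protocol: fit the full source model on the first
#' outgroup set; while the fit has `p >= p_cutoff` but an infeasible
#' (negative) weight, drop the most negative source and refit; if no
#' working model emerges, advance to the next outgroup set. Among working
#' models the one needing the fewest sources is preferred (the fitted model
#' is greedily reduced by dropping its smallest weight while the reduction
#' still works). Every model tried is recorded.
#'
#' @param freqs A [allele_freqs()] table.
#' @param target Target population.
#' @param source_pool Candidate source populations.
#' @param outgroup_sets Named list of right-population vectors, tried in
#'   order (e.g. `list(OG1 = ..., OG2 = ...)`).
#' @param p_cutoff Working-model p-value threshold (default 0.05).
#' @param ... Passed to [build_f4_matrix()].
#' @return List with `selected` (a `qpadm_model` or `NULL`) and `trials`, a
#'   tibble logging every model tried.
#' @export
model_search <- function(freqs, target, source_pool, outgroup_sets,
                         p_cutoff = 0.05, ...) {
  if (is.null(names(outgroup_sets))) {
    names(outgroup_sets) <- sprintf("OG%d", seq_along(outgroup_sets))
  }
  trials <- list()
  log_trial <- function(model) {
    trials[[length(trials) + 1L]] <<- tibble(
      outgroup_set = model$outgroup_set,
      sources = paste(model$sources, collapse = "+"),
      n_sources = length(model$sources), p_value = model$p_value,
      feasible = model$feasible,
      weights = paste(sprintf("%.4f", model$weights), collapse = ",")
    )
  }
  working <- function(model) model$p_value >= p_cutoff && model$feasible
  fit1 <- function(sources, og) {
    qpadm_fit(freqs, target, sources, outgroup_sets[[og]],
              outgroup_set = og, ...)
  }
  selected <- NULL
  for (og in names(outgroup_sets)) {
    sources <- source_pool
    model <- NULL
    while (length(sources) >= 1) {
      model <- fit1(sources, og)
      log_trial(model)
      if (working(model)) break
      neg <- which(model$weights < 0)
      if (model$p_value >= p_cutoff && length(neg) > 0 && length(sources) > 1) {
        sources <- sources[-which.min(model$weights)]
      } else {
        model <- NULL
        break
      }
    }
    if (!is.null(model) && working(model)) {
      # prefer the minimal model: drop the smallest weight while it works
      while (length(model$sources) > 1) {
        reduced <- fit1(model$sources[-which.min(model$weights)], og)
        log_trial(reduced)
        if (working(reduced)) model <- reduced else break
      }
      selected <- model
      break
    }
  }
  list(selected = selected, trials = dplyr::bind_rows(trials))
}
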