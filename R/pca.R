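# PCA on a modern reference panel with least-squares projection of
# high-missingness samples, and an optional shrinkage correction.

#' Fit a PCA model on a reference panel
#'
#' Sites are centered by twice the panel allele frequency and scaled by
#' `sqrt(p(1-p))`; sites monomorphic in the panel are dropped and missing
#' entries (rare in a reference panel) are set to the site mean. Site
#' loadings are orthonormal, so ordinary least squares on observed sites
#' projects new samples ("lsqproject").
#'
#' @param x A [geno_matrix()] reference panel (expects < 5% missingness
#'   per individual and at least two populations).
#' @param n_pc Number of components to retain (default 10).
#' @return A `pc_model`: site means/normalizations, orthonormal loadings,
#'   eigenvalues and panel scores.
#' @export
fit_pca <- function(x, n_pc = 10) {
  stopifnot(inherits(x, "geno_matrix"))
  if (length(unique(x$ind$population)) < 2) abort("panel needs >= 2 populations")
  n <- nrow(x$calls)
  if (n <= n_pc) abort(sprintf("%d individuals cannot support %d PCs", n, n_pc))
  missfrac <- rowMeans(is.na(x$calls))
  if (any(missfrac > 0.05)) {
    warn(sprintf("%d panel individuals exceed 5%% missingness",
                 sum(missfrac > 0.05)))
  }
  p <- colMeans(x$calls, na.rm = TRUE) / 2
  keep <- which(!is.na(p) & p > 0 & p < 1)
  calls <- x$calls[, keep, drop = FALSE]
  p <- p[keep]
  M <- sweep(calls, 2, 2 * p)
  M <- sweep(M, 2, sqrt(p * (1 - p)), `/`)
  M[is.na(M)] <- 0
  K <- tcrossprod(M)
  e <- eigen(K, symmetric = TRUE)
  lambda <- e$values[seq_len(n_pc)]
  U <- e$vectors[, seq_len(n_pc), drop = FALSE]
  V <- crossprod(M, U) %*% diag(1 / sqrt(lambda), n_pc)
  scores <- U %*% diag(sqrt(lambda), n_pc)
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  structure(list(
    panel = x$panel, sites = keep, means = 2 * p, norms = sqrt(p * (1 - p)),
    loadings = V, evals = lambda, n_pc = n_pc, M = M,
    scores = dplyr::bind_cols(x$ind[c("id", "population")], as_tibble(scores))
  ), class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("<pc_model> %d PCs on %d individuals x %d sites\n", x$n_pc,
              nrow(x$scores), length(x$sites)))
  invisible(x)
}

.project_one <- function(model, calls_row, min_sites_warn = 500) {
  obs <- which(!is.na(calls_row))
  if (length(obs) == 0L) abort("no observed sites to project")
  if (length(obs) < min_sites_warn) {
    warn(sprintf("projection uses only %d observed sites", length(obs)))
  }
  xn <- (calls_row[obs] - model$means[obs]) / model$norms[obs]
  V <- model$loadings[obs, , drop = FALSE]
  drop(solve(crossprod(V) + diag(1e-12, model$n_pc), crossprod(V, xn)))
}

#' Project samples onto fitted principal components
#'
#' Least-squares projection restricted to each sample's non-missing sites;
#' missing sites are excluded from the fit, not imputed. With
#' `shrink = TRUE`, scores are multiplied by per-PC leave-one-out shrink
#' factors ([shrink_factors()]) to counter the outward bias of projecting
#' onto axes estimated from the panel itself.
#'
#' @param model A [fit_pca()] model.
#' @param x A [geno_matrix()] sharing the model's panel.
#' @param shrink Apply the shrink correction (default `FALSE`).
#' @return Tibble: `id`, `population`, `n_sites`, `PC1..PCn`.
#' @export
project_pca <- function(model, x, shrink = FALSE) {
  stopifnot(inherits(model, "pc_model"), inherits(x, "geno_matrix"))
  calls <- x$calls[, model$sites, drop = FALSE]
  sc <- t(apply(calls, 1, function(r) .project_one(model, r)))
  if (shrink) {
    sc <- sweep(sc, 2, shrink_factors(model), `*`)
  }
  colnames(sc) <- paste0("PC", seq_len(model$n_pc))
  dplyr::bind_cols(
    x$ind[c("id", "population")],
    tibble(n_sites = rowSums(!is.na(calls))),
    as_tibble(sc)
  )
}

#' Leave-one-out shrink factors
#'
#' For each panel individual, the PCA is refit without it and the held-out
#' individual projected; the factor per PC is the through-origin regression
#' of projected on fitted scores across individuals, clipped to `(0, 1]`.
#' An approximation to smartpca's "shrinkmode".
#'
#' @param model A [fit_pca()] model.
#' @return Numeric vector of per-PC factors.
#' @export
shrink_factors <- function(model) {
  if (!is.null(model$.shrink)) return(model$.shrink)
  M <- model$M
  n <- nrow(M); n_pc <- model$n_pc
  K <- tcrossprod(M)
  fitted <- as.matrix(model$scores[, paste0("PC", seq_len(n_pc))])
  proj <- matrix(NA_real_, n, n_pc)
  for (i in seq_len(n)) {
    e <- eigen(K[-i, -i, drop = FALSE], symmetric = TRUE)
    lam <- e$values[seq_len(n_pc)]
    U <- e$vectors[, seq_len(n_pc), drop = FALSE]
    # loadings of the reduced fit; project the held-out row by OLS
    s <- drop(crossprod(U, K[-i, i])) / sqrt(lam)
    # eigenvector signs are arbitrary: align the reduced fit with the full one
    sgn <- sign(diag(crossprod(U, fitted[-i, , drop = FALSE])))
    sgn[sgn == 0] <- 1
    proj[i, ] <- s * sgn
  }
  f <- colSums(proj * fitted) / colSums(fitted^2)
  pmin(pmax(f, 1e-6), 1)
}

#' Scatter plot of PCA scores with projected samples
#'
#' @param model A [fit_pca()] model.
#' @param projected Optional tibble from [project_pca()].
#' @param pcs Which two components to draw.
#' @return A ggplot object.
#' @export
plot_pca <- function(model, projected = NULL, pcs = c(1, 2)) {
  ax <- paste0("PC", pcs)
  p <- ggplot2::ggplot(model$scores,
                       ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                                    colour = .data$population)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::theme_minimal()
  if (!is.null(projected)) {
    p <- p + ggplot2::geom_point(data = projected, shape = 17, size = 3)
  }
  p
}
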