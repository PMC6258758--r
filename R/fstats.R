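# f3 and f4 statistics with bias correction and weighted block jackknife.

#' Population allele frequencies and observed allele counts
#'
#' Diploid individuals contribute two allele copies per non-missing call,
#' pseudohaploid individuals one (their single sampled allele). Frequencies
#' are of allele1 and are `NA` where no copies were observed.
#'
#' @param x A [geno_matrix()].
#' @return A `freq_table`: matrices `p` and `n` (populations x sites), the
#'   panel, and a per-population all-pseudohaploid flag.
#' @export
allele_freqs <- function(x) {
  stopifnot(inherits(x, "geno_matrix"))
  pops <- unique(x$ind$population)
  S <- ncol(x$calls)
  p <- matrix(NA_real_, length(pops), S, dimnames = list(pops, NULL))
  n <- matrix(0, length(pops), S, dimnames = list(pops, NULL))
  all_pseudo <- setNames(logical(length(pops)), pops)
  for (pop in pops) {
    rows <- which(x$ind$population == pop)
    if (length(rows) == 0L) abort(sprintf("empty population '%s'", pop))
    calls <- x$calls[rows, , drop = FALSE]
    pseudo <- x$ind$ploidy[rows] == "pseudohaploid"
    all_pseudo[pop] <- all(pseudo)
    copies <- (!is.na(calls)) * ifelse(pseudo, 1L, 2L)
    alle1 <- calls * ifelse(pseudo, 0.5, 1)
    alle1[is.na(alle1)] <- 0
    ncop <- colSums(copies)
    n[pop, ] <- ncop
    p[pop, ] <- ifelse(ncop > 0, colSums(alle1) / ncop, NA_real_)
  }
  structure(list(p = p, n = n, panel = x$panel, all_pseudo = all_pseudo),
            class = "freq_table")
}

#' Construct a frequency table directly from known frequencies
#'
#' Useful for theory checks where population frequencies (not samples) are
#' available; allele counts are treated as effectively infinite unless
#' given.
#'
#' @param p Populations x sites matrix of allele1 frequencies (rownames are
#'   population labels).
#' @param panel Matching panel.
#' @param n Matching matrix of observed allele counts (default `Inf`).
#' @return A `freq_table`.
#' @export
freq_table <- function(p, panel, n = NULL) {
  panel <- as_snp_panel(panel)
  if (ncol(p) != nrow(panel)) {
    abort(sprintf("%d frequency columns but %d panel sites", ncol(p),
                  nrow(panel)))
  }
  if (is.null(n)) n <- matrix(Inf, nrow(p), ncol(p), dimnames = dimnames(p))
  structure(list(p = p, n = n, panel = as_snp_panel(panel),
                 all_pseudo = setNames(logical(nrow(p)), rownames(p))),
            class = "freq_table")
}

#' Assign contiguous genetic-map blocks
#'
#' Default 5 cM contiguous blocks per chromosome; when the map is absent
#' (all genetic positions zero), falls back to `n_fallback` equal-count
#' blocks.
#'
#' @param panel Site panel.
#' @param size_cM Block size in centimorgans.
#' @param n_fallback Number of equal-count blocks without a map.
#' @return Integer block id per site (consecutive from 1).
#' @export
assign_blocks <- function(panel, size_cM = 5, n_fallback = 700) {
  if (all(panel$gpos == 0)) {
    raw <- ceiling(seq_len(nrow(panel)) / (nrow(panel) / n_fallback))
  } else {
    raw <- paste(panel$chrom, floor(panel$gpos / (size_cM / 100)))
  }
  match(raw, unique(raw))
}

# shared site-level aggregation: per-block means/weights + weighted jackknife
.fstat_result <- function(name, pops, contrib, use, blocks) {
  blocks <- blocks[use]
  contrib <- contrib[use]
  bw <- tapply(rep(1, length(contrib)), blocks, sum)
  bs <- tapply(contrib, blocks, sum)
  per_block <- tibble(block = as.integer(names(bw)), value = as.numeric(bs / bw),
                      weight = as.numeric(bw))
  jk <- block_jackknife(per_block$value, per_block$weight)
  out <- tibble(
    statistic = name, pops = paste(pops, collapse = ","),
    estimate = jk$estimate, se = jk$se,
    z = ifelse(is.na(jk$se) || jk$se == 0, NA_real_, jk$estimate / jk$se),
    n_snps = as.integer(sum(bw)), n_blocks = nrow(per_block)
  )
  attr(out, "per_block") <- per_block
  class(out) <- unique(c("fstat_result", class(out)))
  out
}

#' Weighted delete-one block jackknife
#'
#' Given per-block statistic values and weights (SNP counts), returns the
#' weighted overall estimate and the weighted jackknife standard error
#' (Busing-style formula). With equal weights this reduces to the textbook
#' delete-one jackknife of the mean.
#'
#' @param values Per-block statistic values.
#' @param weights Per-block weights (sums of site counts).
#' @return List with `estimate`, `se`, `loo` (leave-one-block-out
#'   estimates).
#' @export
block_jackknife <- function(values, weights) {
  g <- length(values)
  stopifnot(g == length(weights), all(weights > 0))
  n <- sum(weights)
  total <- sum(values * weights)
  est <- total / n
  if (g < 2L) {
    return(list(estimate = est, se = NA_real_, loo = rep(NA_real_, g)))
  }
  loo <- (total - values * weights) / (n - weights)
  h <- n / weights
  theta_j <- g * est - sum((1 - weights / n) * loo)
  pseudo <- h * est - (h - 1) * loo
  v <- sum((pseudo - theta_j)^2 / (h - 1)) / g
  list(estimate = est, se = sqrt(v), loo = loo)
}

.freq_rows <- function(freqs, pops) {
  miss <- setdiff(pops, rownames(freqs$p))
  if (length(miss)) abort(paste("unknown populations:", paste(miss, collapse = ", ")))
  freqs$p[pops, , drop = FALSE]
}

#' f3 statistic with heterozygosity bias correction
#'
#' `f3(C; A, B)` averages `(c - a)(c - b) - c(1 - c)/(n_c - 1)` over sites
#' where all three populations are observed, with the correction term
#' removing the bias from sampling noise in the target frequency.
#' Significantly negative values indicate the target is admixed between
#' populations related to the two sources. When the target population is
#' entirely pseudohaploid the correction is omitted with a warning
#' (within-individual heterozygosity is not estimable).
#'
#' @param freqs A [allele_freqs()] table.
#' @param test,source1,source2 Population labels (target C; sources A, B).
#' @param blocks Optional block ids ([assign_blocks()] default).
#' @return One-row `fstat_result` tibble (estimate, jackknife SE, Z,
#'   SNP/block counts) with per-block values attached.
#' @export
f3 <- function(freqs, test, source1, source2, blocks = NULL) {
  p <- .freq_rows(freqs, c(test, source1, source2))
  n_c <- freqs$n[test, ]
  if (is.null(blocks)) blocks <- assign_blocks(freqs$panel)
  correct <- !isTRUE(freqs$all_pseudo[[test]])
  if (!correct) {
    warn(sprintf("target '%s' is pseudohaploid-only: f3 bias correction omitted", test))
  }
  use <- complete.cases(t(p)) & (if (correct) n_c >= 2 else n_c >= 1)
  cc <- p[1, ]; aa <- p[2, ]; bb <- p[3, ]
  contrib <- (cc - aa) * (cc - bb)
  if (correct) contrib <- contrib - cc * (1 - cc) / (n_c - 1)
  .fstat_result("f3", c(test, source1, source2), contrib, use, blocks)
}

#' f4 statistic
#'
#' `f4(A, B; C, D)` averages `(a - b)(c - d)` over sites where all four
#' populations are observed; no bias correction is needed. Used to test
#' treeness and measure differential allele sharing.
#'
#' @param freqs A [allele_freqs()] table.
#' @param a,b,c,d Population labels.
#' @param blocks Optional block ids.
#' @return One-row `fstat_result` tibble.
#' @export
f4 <- function(freqs, a, b, c, d, blocks = NULL) {
  p <- .freq_rows(freqs, c(a, b, c, d))
  if (is.null(blocks)) blocks <- assign_blocks(freqs$panel)
  use <- complete.cases(t(p))
  contrib <- (p[1, ] - p[2, ]) * (p[3, ] - p[4, ])
  .fstat_result("f4", c(a, b, c, d), contrib, use, blocks)
}

#' Tidy an f-statistic result (plain tibble, per-block attribute dropped)
#' @param x An `fstat_result`.
#' @param ... Unused.
#' @export
tidy.fstat_result <- function(x, ...) {
  attr(x, "per_block") <- NULL
  class(x) <- setdiff(class(x), "fstat_result")
  x
}
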