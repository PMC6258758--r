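# On-disk formats: EIGENSTRAT genotype triplets, SAMtools-style pileup text,
# and IntCal-style radiocarbon calibration tables.

.CHROM_X <- 23L
.CHROM_Y <- 24L

.parse_chrom <- function(x, file = "snp") {
  x <- as.character(x)
  out <- suppressWarnings(as.integer(x))
  out[x %in% c("X", "23")] <- .CHROM_X
  out[x %in% c("Y", "24")] <- .CHROM_Y
  bad <- is.na(out) | out < 1L | out > 24L
  if (any(bad)) {
    abort(sprintf(
      "%s file: unsupported chromosome label '%s' (line %d); autosomes 1-22, X=23, Y=24 only",
      file, x[which(bad)[1]], which(bad)[1]
    ))
  }
  out
}

#' Construct and validate a SNP panel
#'
#' A SNP panel is an ordered table of biallelic sites with columns `id`,
#' `chrom` (1-22 autosomes, 23 = X, 24 = Y), `gpos` (genetic position in
#' Morgans), `ppos` (1-based physical position) and alleles `a1`, `a2`.
#'
#' @param x A data frame with the columns above.
#' @return A validated `snp_panel` tibble.
#' @export
as_snp_panel <- function(x) {
  x <- as_tibble(x)
  need <- c("id", "chrom", "gpos", "ppos", "a1", "a2")
  if (!all(need %in% names(x))) {
    abort(paste("snp panel needs columns:", paste(need, collapse = ", ")))
  }
  x$chrom <- .parse_chrom(x$chrom)
  x$ppos <- as.integer(x$ppos)
  if (any(x$gpos < 0)) abort("genetic positions must be non-negative (Morgans)")
  if (any(x$a1 == x$a2)) abort("allele1 must differ from allele2")
  o <- order(x$chrom, x$ppos)
  if (!identical(o, seq_len(nrow(x)))) x <- x[o, ]
  if (anyDuplicated(x[c("chrom", "ppos")])) {
    abort("duplicate (chromosome, position) in snp panel")
  }
  dg <- unlist(tapply(x$gpos, x$chrom, function(g) c(0, diff(g))))
  if (any(dg < 0)) abort("genetic positions must be non-decreasing within a chromosome")
  class(x) <- unique(c("snp_panel", class(x)))
  x
}

new_geno_matrix <- function(calls, panel, ind) {
  stopifnot(nrow(calls) == nrow(ind), ncol(calls) == nrow(panel))
  storage.mode(calls) <- "integer"
  rownames(calls) <- ind$id
  structure(
    list(calls = calls, panel = panel, ind = as_tibble(ind)),
    class = "geno_matrix"
  )
}

#' Assemble a genotype matrix
#'
#' @param calls Integer matrix, individuals x sites, values 0/1/2 and `NA`
#'   for missing. Pseudohaploid individuals carry only 0/2/`NA`.
#' @param panel A [as_snp_panel()] site table.
#' @param ind Individual table with columns `id`, `sex` (M/F/U),
#'   `population`, `ploidy` ("diploid" or "pseudohaploid").
#' @return A `geno_matrix` object.
#' @export
geno_matrix <- function(calls, panel, ind) {
  panel <- as_snp_panel(panel)
  ind <- as_tibble(ind)
  if (is.null(ind$sex)) ind$sex <- "U"
  if (is.null(ind$ploidy)) {
    ind$ploidy <- ifelse(
      apply(calls, 1, function(r) !any(r == 1L, na.rm = TRUE)),
      "pseudohaploid", "diploid"
    )
  }
  bad <- ind$ploidy == "pseudohaploid" &
    apply(calls, 1, function(r) any(r == 1L, na.rm = TRUE))
  if (any(bad)) {
    abort(sprintf("pseudohaploid individual '%s' has heterozygous calls", ind$id[which(bad)[1]]))
  }
  new_geno_matrix(calls, panel, ind)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d individuals x %d sites (%d populations; %d pseudohaploid)\n",
    nrow(x$calls), ncol(x$calls), length(unique(x$ind$population)),
    sum(x$ind$ploidy == "pseudohaploid")
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

.eig_paths <- function(prefix, snp, geno, ind) {
  if (!is.null(prefix)) {
    list(snp = paste0(prefix, ".snp"), geno = paste0(prefix, ".geno"),
         ind = paste0(prefix, ".ind"))
  } else {
    list(snp = snp, geno = geno, ind = ind)
  }
}

#' Read an EIGENSTRAT genotype triplet
#'
#' Reads `.geno`/`.snp`/`.ind` files. Genotype values count copies of
#' allele1 (the fifth `.snp` column); `9` decodes to missing. Individuals
#' with no heterozygous call are flagged pseudohaploid unless `ploidy`
#' overrides them.
#'
#' @param prefix Path prefix (expects `<prefix>.geno` etc.), or `NULL` to
#'   pass the three paths explicitly.
#' @param snp,geno,ind Explicit file paths when `prefix` is `NULL`.
#' @param ploidy Optional named character vector (`id = "diploid"` /
#'   `"pseudohaploid"`) overriding the heuristic.
#' @return A [geno_matrix()].
#' @export
read_eigenstrat <- function(prefix = NULL, snp = NULL, geno = NULL,
                            ind = NULL, ploidy = NULL) {
  p <- .eig_paths(prefix, snp, geno, ind)
  snp_df <- utils::read.table(p$snp, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("id", "chrom", "gpos", "ppos", "a1", "a2"))
  panel <- as_snp_panel(snp_df)
  ind_df <- utils::read.table(p$ind, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("id", "sex", "population"))
  lines <- readLines(p$geno)
  if (length(lines) != nrow(panel)) {
    abort(sprintf("%s: %d genotype rows but %d snp rows", p$geno,
                  length(lines), nrow(panel)))
  }
  n_ind <- nrow(ind_df)
  widths <- nchar(lines)
  if (any(widths != n_ind)) {
    l <- which(widths != n_ind)[1]
    abort(sprintf("%s line %d: %d genotype columns but %d individuals",
                  p$geno, l, widths[l], n_ind))
  }
  if (n_ind == 0L) {
    calls <- matrix(integer(0), nrow = 0, ncol = nrow(panel))
  } else {
    flat <- utf8ToInt(paste(lines, collapse = ""))
    vals <- flat - utf8ToInt("0")
    bad <- !(vals %in% c(0L, 1L, 2L, 9L))
    if (any(bad)) {
      k <- which(bad)[1] - 1L
      abort(sprintf("%s line %d position %d: invalid genotype character '%s'",
                    p$geno, k %/% n_ind + 1L, k %% n_ind + 1L,
                    intToUtf8(flat[k + 1L])))
    }
    vals[vals == 9L] <- NA_integer_
    calls <- matrix(vals, nrow = n_ind, ncol = nrow(panel)) # sites are rows on disk
  }
  ind_tbl <- tibble(id = as.character(ind_df$id), sex = as.character(ind_df$sex),
                    population = as.character(ind_df$population))
  het <- apply(calls, 1, function(r) any(r == 1L, na.rm = TRUE))
  ind_tbl$ploidy <- ifelse(het, "diploid", "pseudohaploid")
  if (!is.null(ploidy)) {
    hit <- intersect(names(ploidy), ind_tbl$id)
    ind_tbl$ploidy[match(hit, ind_tbl$id)] <- unname(ploidy[hit])
  }
  geno_matrix(calls, panel, ind_tbl)
}

#' Write an EIGENSTRAT genotype triplet
#'
#' Canonical single-space formatting; genetic positions printed with six
#' decimals; missing calls encoded as `9`. `read_eigenstrat()` followed by
#' `write_eigenstrat()` reproduces canonical files byte-identically.
#'
#' @param x A [geno_matrix()].
#' @param prefix Output path prefix.
#' @return Invisibly, the three paths written.
#' @export
write_eigenstrat <- function(x, prefix) {
  stopifnot(inherits(x, "geno_matrix"))
  p <- .eig_paths(prefix, NULL, NULL, NULL)
  panel <- x$panel
  writeLines(sprintf("%s %d %.6f %d %s %s", panel$id, panel$chrom, panel$gpos,
                     panel$ppos, panel$a1, panel$a2), p$snp)
  writeLines(sprintf("%s %s %s", x$ind$id, x$ind$sex, x$ind$population), p$ind)
  calls <- x$calls
  calls[is.na(calls)] <- 9L
  if (nrow(calls) == 0L) {
    writeLines(character(nrow(panel)), p$geno)
  } else {
    writeLines(apply(calls, 2, paste, collapse = ""), p$geno)
  }
  invisible(unlist(p))
}

# ---- pileup ----------------------------------------------------------------

# parse one pileup base string into bases/strands, consuming indel and
# read start/end markup
.parse_bases <- function(s, ref, line_no) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  base <- character(0)
  strand <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L # caret + mapping-quality char
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && chars[j] %in% as.character(0:9)) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len
    } else if (ch == "." ) {
      base <- c(base, ref); strand <- c(strand, "+"); i <- i + 1L
    } else if (ch == ",") {
      base <- c(base, ref); strand <- c(strand, "-"); i <- i + 1L
    } else if (ch %in% c("A", "C", "G", "T", "N")) {
      base <- c(base, ch); strand <- c(strand, "+"); i <- i + 1L
    } else if (ch %in% c("a", "c", "g", "t", "n")) {
      base <- c(base, toupper(ch)); strand <- c(strand, "-"); i <- i + 1L
    } else if (ch == "*") {
      base <- c(base, "*"); strand <- c(strand, "+"); i <- i + 1L # deletion placeholder
    } else {
      abort(sprintf("pileup line %d: unexpected character '%s'", line_no, ch))
    }
  }
  list(base = base, strand = strand)
}

#' Read SAMtools pileup text restricted to a panel
#'
#' Parses the classic pileup dialect (`.`/`,` reference matches, case-coded
#' strand, `+n`/`-n` indels, `^`/`$` read markup). Indels are skipped,
#' deletion placeholders dropped, qualities decoded phred+33, and sites not
#' present in `panel` discarded.
#'
#' @param path Path to a pileup file (or a character vector of lines).
#' @param panel A [as_snp_panel()] table; observations are keyed to it.
#' @param has_mq Does the file carry a mapping-quality column (mpileup
#'   `-s`/`--output-MQ`)? Default `TRUE`.
#' @param has_read_pos Does the file carry a comma-separated within-read
#'   position column (mpileup `-O`/`--output-BP` style, 1-based)? Default
#'   `FALSE`.
#' @return A tibble of observations: `chrom`, `ppos`, `ref`, `base`,
#'   `strand`, `bq`, `mq`, `read_pos` (0-based from the 5' end, `NA`
#'   without the position column), `read_len` (`NA`: pileup does not carry
#'   read lengths).
#' @export
read_pileup <- function(path, panel, has_mq = TRUE, has_read_pos = FALSE) {
  panel <- as_snp_panel(panel)
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(lines)]
  key <- paste(panel$chrom, panel$ppos)
  out <- vector("list", length(lines))
  n_fields <- 5L + has_mq + has_read_pos
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < n_fields) {
      abort(sprintf("pileup line %d: expected %d fields, got %d", k, n_fields, length(f)))
    }
    chrom <- .parse_chrom(f[1], "pileup")
    ppos <- as.integer(f[2])
    if (!(paste(chrom, ppos) %in% key)) next
    ref <- toupper(f[3])
    pb <- .parse_bases(f[5], ref, k)
    bq <- utf8ToInt(f[6]) - 33L
    if (length(pb$base) != length(bq)) {
      abort(sprintf("pileup line %d: %d bases but %d base qualities",
                    k, length(pb$base), length(bq)))
    }
    mq <- if (has_mq) utf8ToInt(f[7]) - 33L else rep(NA_integer_, length(bq))
    rp <- if (has_read_pos) {
      v <- as.integer(strsplit(f[6L + has_mq + 1L], ",", fixed = TRUE)[[1]])
      if (length(v) != length(bq)) {
        abort(sprintf("pileup line %d: %d bases but %d read positions",
                      k, length(bq), length(v)))
      }
      v - 1L # column is 1-based
    } else {
      rep(NA_integer_, length(bq))
    }
    keep <- pb$base != "*"
    if (!any(keep)) next
    out[[k]] <- tibble(
      chrom = chrom, ppos = ppos, ref = ref,
      base = pb$base[keep], strand = pb$strand[keep],
      bq = bq[keep], mq = mq[keep],
      read_pos = rp[keep], read_len = NA_integer_
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(chrom = integer(), ppos = integer(), ref = character(),
                  base = character(), strand = character(), bq = integer(),
                  mq = integer(), read_pos = integer(), read_len = integer())
  }
  res
}

#' Write observations as pileup text
#'
#' Inverse of [read_pileup()] for markup-free data: reference-matching bases
#' become `.`/`,`, mismatches case-coded letters. Within-read positions are
#' not representable in this format and are dropped.
#'
#' @param obs Observation tibble as produced by [simulate_reads()] or
#'   [read_pileup()].
#' @param path Output file.
#' @param has_mq Write the mapping-quality column. Default `TRUE`.
#' @param has_read_pos Also write the 1-based within-read position column.
#' @export
write_pileup <- function(obs, path, has_mq = TRUE, has_read_pos = FALSE) {
  if (nrow(obs) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  obs <- dplyr::arrange(obs, .data$chrom, .data$ppos)
  grp <- dplyr::group_by(obs, .data$chrom, .data$ppos, .data$ref)
  lines <- dplyr::summarise(
    grp,
    depth = dplyr::n(),
    bases = paste(ifelse(.data$base == .data$ref,
                         ifelse(.data$strand == "+", ".", ","),
                         ifelse(.data$strand == "+", .data$base, tolower(.data$base))),
                  collapse = ""),
    quals = intToUtf8(.data$bq + 33L),
    mqs = intToUtf8(dplyr::coalesce(.data$mq, 0L) + 33L),
    rps = paste(.data$read_pos + 1L, collapse = ","),
    .groups = "drop"
  )
  txt <- sprintf("%d\t%d\t%s\t%d\t%s\t%s", lines$chrom, lines$ppos, lines$ref,
                 lines$depth, lines$bases, lines$quals)
  if (has_mq) txt <- paste(txt, lines$mqs, sep = "\t")
  if (has_read_pos) txt <- paste(txt, lines$rps, sep = "\t")
  writeLines(txt, path)
  invisible(path)
}

# ---- calibration curve -----------------------------------------------------

#' Read an IntCal-style calibration curve
#'
#' Accepts comma- or whitespace-separated tables with `#` comment headers;
#' the first three columns are calendar age (calBP), radiocarbon age (14C BP)
#' and the curve's one-sigma error (years). Rows are returned sorted by
#' ascending calendar age; interpolation between rows is linear.
#'
#' @param path File path (or character vector of lines).
#' @return A `cal_curve` tibble with columns `cal_bp`, `c14_bp`, `sigma`.
#' @export
read_calcurve <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L) abort("calibration curve needs at least 2 rows")
  parts <- strsplit(lines, "[,[:space:]]+")
  vals <- suppressWarnings(lapply(parts, as.numeric))
  if (any(vapply(vals, function(v) length(v) < 3 || anyNA(v[1:3]), TRUE))) {
    abort("calibration curve: rows must have 3 numeric columns")
  }
  m <- do.call(rbind, lapply(vals, function(v) v[1:3]))
  curve <- tibble(cal_bp = m[, 1], c14_bp = m[, 2], sigma = m[, 3])
  curve <- dplyr::distinct(dplyr::arrange(curve, .data$cal_bp))
  if (anyDuplicated(curve$cal_bp)) {
    abort("calibration curve: non-monotone calendar ages (duplicate calBP with differing values)")
  }
  if (any(curve$sigma <= 0)) abort("calibration curve: sigma must be positive")
  class(curve) <- unique(c("cal_curve", class(curve)))
  curve
}

# linear interpolation of the curve mean and sigma at calendar ages theta
.curve_at <- function(curve, theta) {
  list(
    mu = stats::approx(curve$cal_bp, curve$c14_bp, theta, rule = 1)$y,
    sigma = stats::approx(curve$cal_bp, curve$sigma, theta, rule = 1)$y
  )
}
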