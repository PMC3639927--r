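# Per-population genotype statistics: count reconstruction from printed
# percentages, allele frequencies, the 1-df Hardy-Weinberg chi-square
# (no continuity correction) and the Spearman rank correlation with a
# t-approximate p-value.

check_counts <- function(counts) {
  if (length(counts) != 3L || any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("genotype counts must be 3 non-negative integers (hom_ref, het, hom_alt)")
  as.integer(round(counts))
}

#' Reconstruct integer genotype counts from printed percentages
#'
#' Published survey tables print genotype frequencies as percentages at
#' 1-2 decimal places.  Given the sample size, the generating integer
#' counts are recovered as the triple summing to `n` that minimises the
#' maximum absolute deviation from `n * pct / 100`.  The minimiser must
#' be unique and deviate by at most 0.75 counts in every class,
#' otherwise reconstruction fails rather than guessing.
#'
#' @param pcts numeric length-3 percentages (near-summing to 100).
#' @param n integer sample size.
#' @param tol_counts maximum admissible per-class deviation (counts).
#' @return integer length-3 counts `(hom_ref, het, hom_alt)`.
#' @examples
#' counts_from_percentages(c(36.4, 59.1, 4.5), 22)  # 8 13 1
#' @export
counts_from_percentages <- function(pcts, n, tol_counts = 0.75) {
  if (length(pcts) != 3L || anyNA(pcts)) stop("pcts must be 3 numbers")
  if (n < 1L) stop("n must be >= 1")
  if (abs(sum(pcts) - 100) > 1.5)
    stop("percentages sum to ", sum(pcts), ", not ~100")
  target <- n * pcts / 100
  a <- rep(0:n, each = n + 1L)
  b <- rep(0:n, times = n + 1L)
  keep <- a + b <= n
  a <- a[keep]; b <- b[keep]; cc <- n - a - b
  dev <- pmax(abs(a - target[1L]), abs(b - target[2L]), abs(cc - target[3L]))
  best <- min(dev)
  if (best > tol_counts)
    stop("no integer triple within ", tol_counts, " counts of targets (",
         paste(sprintf("%.2f", target), collapse = ", "), ") for n = ", n)
  hits <- which(dev <= best + 1e-9)
  if (length(hits) > 1L)
    stop("ambiguous count reconstruction for n = ", n, ": ",
         length(hits), " equally good triples")
  c(a[hits], b[hits], cc[hits])
}

#' Allele frequencies from genotype counts
#'
#' @param counts genotype counts `(hom_ref, het, hom_alt)`.
#' @return named numeric `c(p_ref, p_alt)` on the 0-1 scale;
#'   `p_alt = (het + 2 * hom_alt) / (2n)`.
#' @examples
#' allele_frequencies(c(2, 7, 13))  # deleted-allele frequency 0.75
#' @export
allele_frequencies <- function(counts) {
  counts <- check_counts(counts)
  n <- sum(counts)
  if (n == 0L) stop("no individuals: cannot compute allele frequencies")
  p_alt <- (counts[2L] + 2 * counts[3L]) / (2 * n)
  c(p_ref = 1 - p_alt, p_alt = p_alt)
}

#' Hardy-Weinberg chi-square test (1 df, no continuity correction)
#'
#' Expected counts are `n * (p^2, 2pq, q^2)` from the observed allele
#' frequencies; the statistic is the plain Pearson chi-square over the
#' three genotype classes with one degree of freedom and no Yates
#' correction.  A monomorphic locus returns `chi2 = 0`, `p = 1` and is
#' flagged.
#'
#' @param counts genotype counts `(hom_ref, het, hom_alt)`.
#' @return list with `chi2`, `p_value`, `df` (always 1), `expected`
#'   (length-3), `monomorphic` flag.
#' @examples
#' hwe_chi2(c(8, 13, 1))$chi2  # ~2.18
#' @export
hwe_chi2 <- function(counts) {
  counts <- check_counts(counts)
  n <- sum(counts)
  if (n == 0L) stop("no individuals: cannot test HWE")
  p <- allele_frequencies(counts)[["p_ref"]]
  q <- 1 - p
  expected <- n * c(p^2, 2 * p * q, q^2)
  if (p == 0 || p == 1) {
    return(list(chi2 = 0, p_value = 1, df = 1L, expected = expected,
                monomorphic = TRUE))
  }
  # expected > 0 in all classes once both alleles are observed
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, p_value = pchisq(chi2, df = 1L, lower.tail = FALSE),
       df = 1L, expected = expected, monomorphic = FALSE)
}

#' Spearman rank correlation with t-approximate p-value
#'
#' Midranks for ties; rho is the Pearson correlation of the rank
#' vectors (identical to `1 - 6*sum(d^2)/(n(n^2-1))` when tie-free).
#' The two-sided p-value uses `t = rho * sqrt((n-2)/(1-rho^2))` on
#' `n - 2` degrees of freedom; `|rho| = 1` reports the smallest
#' representable positive double.  An exact permutation p-value is
#' available for small n.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, neither constant.
#' @param exact if `TRUE`, compute the p-value by full enumeration of
#'   rank permutations (supported for `n <= 8`).
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_correlation <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (length(unique(rx)) == 1L || length(unique(ry)) == 1L)
    stop("Spearman correlation undefined for a constant vector")
  rho <- cor(rx, ry)
  if (exact) {
    if (n > 8L) stop("exact permutation p-value supported only for n <= 8")
    perms <- all_permutations(n)
    rhos <- apply(perms, 1L, function(p) cor(rx, ry[p]))
    p_value <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1 - 1e-12) {
    p_value <- .Machine$double.xmin
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p_value <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p_value = p_value, n = n)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    m <- cbind(sub + (sub >= k), k, deparse.level = 0)
    out[[k]] <- m
  }
  do.call(rbind, out)
}

genotype_pcts <- function(counts) {
  n <- sum(counts)
  if (n == 0L) rep(NA_real_, 3L) else 100 * counts / n
}

#' Tabulate per-locus genotype counts for one population
#'
#' @param genotypes a [genotype_table].
#' @param population population label.
#' @param locus `"cnv"` or `"snp"`.
#' @return integer length-3 counts in class order
#'   (`+/+`, `+/-`, `-/-`) or (`AA`, `AG`, `GG`); missing genotypes are
#'   excluded per locus.
#' @export
genotype_counts <- function(genotypes, population, locus = c("cnv", "snp")) {
  locus <- match.arg(locus)
  rows <- genotypes[genotypes$population == population, , drop = FALSE]
  col <- paste0(locus, "_genotype")
  vocab <- if (locus == "cnv") CNV_GENOTYPES else SNP_GENOTYPES
  g <- rows[[col]][!is.na(rows[[col]])]
  as.integer(table(factor(g, levels = vocab)))
}

#' Assemble per-population summary rows
#'
#' For each population: CNV and SNP genotype percentages, CNV allele
#' percentages, the Hardy-Weinberg chi-square on the CNV locus, the
#' EM-based LD r-squared between deletion and tag-SNP alleles (when
#' both loci are typed), and optionally the pooled aCGH log2 intensity.
#' Missing genotypes are excluded per locus, so a sample typed only for
#' the CNV still contributes to the CNV columns.
#'
#' @param genotypes a [genotype_table].
#' @param pooled_log2 optional named numeric: population -> pooled log2
#'   ratio versus the reference pool.
#' @return data.frame, one row per population (rows in order of first
#'   appearance), columns `population`, `n`, `n_cnv`, `n_snp`,
#'   `cnv_pp_pct`, `cnv_pm_pct`, `cnv_mm_pct`, `cnv_plus_pct`,
#'   `cnv_minus_pct`, `snp_AA_pct`, `snp_AG_pct`, `snp_GG_pct`,
#'   `hwe_chi2`, `hwe_p`, `ld_r2`, `pooled_log2`.
#' @export
population_summaries <- function(genotypes, pooled_log2 = NULL) {
  stopifnot(inherits(genotypes, "genotype_table"))
  pops <- unique(genotypes$population)
  if (length(pops) == 0L) stop("genotype table has no populations")
  rows <- lapply(pops, function(pop) {
    cnv <- genotype_counts(genotypes, pop, "cnv")
    snp <- genotype_counts(genotypes, pop, "snp")
    n_cnv <- sum(cnv); n_snp <- sum(snp)
    if (n_cnv == 0L) {
      warning("population ", pop, " has no CNV genotypes; emitting NA row")
      af <- c(NA_real_, NA_real_); hw <- list(chi2 = NA_real_, p_value = NA_real_)
    } else {
      af <- allele_frequencies(cnv)
      hw <- hwe_chi2(cnv)
    }
    r2 <- NA_real_
    n_joint <- sum(!is.na(genotypes$cnv_genotype) & !is.na(genotypes$snp_genotype) &
                   genotypes$population == pop)
    if (n_joint > 0L) {
      ld <- ld_population(genotypes, pop)
      r2 <- ld$r2
    }
    data.frame(
      population = pop,
      n = sum(genotypes$population == pop),
      n_cnv = n_cnv, n_snp = n_snp,
      cnv_pp_pct = genotype_pcts(cnv)[1L], cnv_pm_pct = genotype_pcts(cnv)[2L],
      cnv_mm_pct = genotype_pcts(cnv)[3L],
      cnv_plus_pct = 100 * af[[1L]], cnv_minus_pct = 100 * af[[2L]],
      snp_AA_pct = genotype_pcts(snp)[1L], snp_AG_pct = genotype_pcts(snp)[2L],
      snp_GG_pct = genotype_pcts(snp)[3L],
      hwe_chi2 = hw$chi2, hwe_p = hw$p_value,
      ld_r2 = r2,
      pooled_log2 = if (!is.null(pooled_log2) && pop %in% names(pooled_log2))
        unname(pooled_log2[[pop]]) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
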