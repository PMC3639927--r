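# Two-locus linkage disequilibrium between the deletion (alleles +/-)
# and the tag SNP (alleles A/G) from unphased diploid genotypes.  Only
# the double heterozygote (+/-, AG) is phase-ambiguous; EM splits it
# between the two phases in proportion to current haplotype-frequency
# products.  r2 is computed between the deleted allele "-" and tag
# allele "G" (r2 is symmetric; the choice fixes only the sign of D).

#' Cross-tabulate CNV and SNP genotypes for one population
#'
#' @param genotypes a [genotype_table].
#' @param population population label.
#' @return 3x3 integer matrix, rows `+/+`, `+/-`, `-/-`, columns `AA`,
#'   `AG`, `GG`; samples missing either locus are excluded
#'   (complete-case analysis).
#' @export
tabulate_joint <- function(genotypes, population) {
  rows <- genotypes[genotypes$population == population, , drop = FALSE]
  if (nrow(rows) == 0L) stop("population not present: ", population)
  keep <- !is.na(rows$cnv_genotype) & !is.na(rows$snp_genotype)
  rows <- rows[keep, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("population ", population, " has no samples typed at both loci")
  m <- table(factor(rows$cnv_genotype, levels = CNV_GENOTYPES),
             factor(rows$snp_genotype, levels = SNP_GENOTYPES))
  matrix(as.integer(m), 3L, 3L,
         dimnames = list(CNV_GENOTYPES, SNP_GENOTYPES))
}

# haplotype contributions of the 8 phase-unambiguous cells, as counts of
# (+A, +G, -A, -G) per copy of the cell
unambiguous_hap_counts <- function(counts) {
  ct <- function(i, j) counts[i, j]
  c(`+A` = 2 * ct(1, 1) + ct(1, 2) + ct(2, 1),
    `+G` = 2 * ct(1, 3) + ct(1, 2) + ct(2, 3),
    `-A` = 2 * ct(3, 1) + ct(3, 2) + ct(2, 1),
    `-G` = 2 * ct(3, 3) + ct(3, 2) + ct(2, 3))
}

loglik_haplotypes <- function(counts, f) {
  p <- matrix(0, 3L, 3L)
  p[1, 1] <- f[1]^2;           p[1, 2] <- 2 * f[1] * f[2];  p[1, 3] <- f[2]^2
  p[2, 1] <- 2 * f[1] * f[3];  p[2, 3] <- 2 * f[2] * f[4];  p[3, 1] <- f[3]^2
  p[3, 2] <- 2 * f[3] * f[4];  p[3, 3] <- f[4]^2
  p[2, 2] <- 2 * (f[1] * f[4] + f[2] * f[3])
  obs <- counts > 0
  if (any(obs & p <= 0)) return(-Inf)
  sum(counts[obs] * log(p[obs]))
}

#' EM estimation of two-locus haplotype frequencies
#'
#' Standard EM for a pair of biallelic loci genotyped without phase.
#' The E-step splits the double-heterozygote cell between the coupling
#' (+A/-G) and repulsion (+G/-A) phases in proportion to the current
#' haplotype-frequency products; every other cell determines its
#' haplotypes exactly.  Initialisation is at linkage equilibrium of the
#' observed allele frequencies; the log-likelihood is checked to be
#' non-decreasing at every iteration.
#'
#' @param counts 3x3 joint genotype count matrix from
#'   [tabulate_joint()].
#' @param tol convergence tolerance on `max |delta f|` (default 1e-10).
#' @param max_iter iteration cap (default 1000).
#' @return list with `freqs` (named numeric over `+A`, `+G`, `-A`,
#'   `-G`), `log_likelihood`, `n_iterations`, `converged`.
#' @examples
#' cts <- matrix(c(10, 0, 0, 0, 0, 0, 0, 0, 10), 3, 3, byrow = TRUE,
#'               dimnames = list(c("+/+", "+/-", "-/-"), c("AA", "AG", "GG")))
#' em_haplotypes(cts)$freqs  # perfect coupling: f(+A) = f(-G) = 0.5
#' @export
em_haplotypes <- function(counts, tol = 1e-10, max_iter = 1000L) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 3L, ncol(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0L) stop("empty joint genotype table")
  n_hap <- 2 * n
  fixed <- unambiguous_hap_counts(counts)
  dh <- counts[2L, 2L]
  # initialise at linkage equilibrium of observed allele frequencies
  p_plus <- (2 * sum(counts[1L, ]) + sum(counts[2L, ])) / n_hap
  p_A <- (2 * sum(counts[, 1L]) + sum(counts[, 2L])) / n_hap
  f <- c(p_plus * p_A, p_plus * (1 - p_A),
         (1 - p_plus) * p_A, (1 - p_plus) * (1 - p_A))
  names(f) <- HAPLOTYPES
  ll <- loglik_haplotypes(counts, f)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    denom <- f[1L] * f[4L] + f[2L] * f[3L]
    w <- if (denom > 0) f[1L] * f[4L] / denom else 0.5  # P(coupling | double het)
    f_new <- (fixed + dh * c(w, 1 - w, 1 - w, w)) / n_hap
    ll_new <- loglik_haplotypes(counts, f_new)
    if (ll_new < ll - 1e-8)
      stop("internal error: EM log-likelihood decreased (", ll, " -> ", ll_new, ")")
    delta <- max(abs(f_new - f))
    f <- f_new
    ll <- ll_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (abs(sum(f) - 1) > 1e-10) stop("internal error: haplotype frequencies do not sum to 1")
  list(freqs = f, log_likelihood = ll, n_iterations = iter, converged = converged)
}

#' D, D-prime and r-squared from haplotype frequencies
#'
#' `D = f(-G) - p_minus * p_G` (covariance of the deleted and tag-G
#' alleles); `D' = D / Dmax` with the usual positive/negative bounds;
#' `r2 = D^2 / (p_plus p_minus p_A p_G)`.  If either locus is
#' monomorphic the LD statistics are undefined and returned as `NA`
#' (not an error).
#'
#' @param h result of [em_haplotypes()], or a named numeric of 4
#'   haplotype frequencies over `+A`, `+G`, `-A`, `-G`.
#' @return list with `D`, `D_prime`, `r2`, `p_plus`, `p_minus`, `p_A`,
#'   `p_G`.
#' @export
ld_from_haplotypes <- function(h) {
  f <- if (is.list(h)) h$freqs else h
  if (length(f) != 4L || anyNA(f) || any(f < -1e-12))
    stop("need 4 non-negative haplotype frequencies")
  if (abs(sum(f) - 1) > 1e-8) stop("haplotype frequencies must sum to 1")
  if (is.null(names(f))) names(f) <- HAPLOTYPES
  f <- f[HAPLOTYPES]
  p_plus <- f[["+A"]] + f[["+G"]]; p_minus <- 1 - p_plus
  p_A <- f[["+A"]] + f[["-A"]]; p_G <- 1 - p_A
  D <- f[["-G"]] - p_minus * p_G
  if (p_plus <= 0 || p_minus <= 0 || p_A <= 0 || p_G <= 0) {
    return(list(D = D, D_prime = NA_real_, r2 = NA_real_,
                p_plus = p_plus, p_minus = p_minus, p_A = p_A, p_G = p_G))
  }
  d_max <- if (D >= 0) min(p_minus * p_A, p_plus * p_G)
           else min(p_minus * p_G, p_plus * p_A)
  d_prime <- if (d_max > 0) D / d_max else 0
  r2 <- D^2 / (p_plus * p_minus * p_A * p_G)
  list(D = D, D_prime = d_prime, r2 = min(r2, 1),
       p_plus = p_plus, p_minus = p_minus, p_A = p_A, p_G = p_G)
}

#' LD between deletion and tag SNP for one population
#'
#' Convenience wrapper: [tabulate_joint()] then [em_haplotypes()] then
#' [ld_from_haplotypes()].
#'
#' @inheritParams tabulate_joint
#' @param tol,max_iter passed to [em_haplotypes()].
#' @return the [ld_from_haplotypes()] list, plus `freqs`, `converged`,
#'   `n` (complete-case sample size).
#' @export
ld_population <- function(genotypes, population, tol = 1e-10, max_iter = 1000L) {
  counts <- tabulate_joint(genotypes, population)
  em <- em_haplotypes(counts, tol = tol, max_iter = max_iter)
  out <- ld_from_haplotypes(em)
  out$freqs <- em$freqs
  out$converged <- em$converged
  out$n <- sum(counts)
  out
}

#' LD table across all populations
#'
#' @param genotypes a [genotype_table].
#' @return data.frame with one row per population holding sample size,
#'   the four EM haplotype frequencies, `D`, `D_prime`, `r2` and the
#'   convergence flag; populations with no sample typed at both loci
#'   get an all-`NA` row.
#' @export
ld_table <- function(genotypes) {
  pops <- unique(genotypes$population)
  rows <- lapply(pops, function(pop) {
    res <- tryCatch(ld_population(genotypes, pop), error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(population = pop, n = 0L, f_pA = NA_real_,
                        f_pG = NA_real_, f_mA = NA_real_, f_mG = NA_real_,
                        D = NA_real_, D_prime = NA_real_, r2 = NA_real_,
                        converged = NA, stringsAsFactors = FALSE))
    }
    data.frame(population = pop, n = res$n,
               f_pA = res$freqs[["+A"]], f_pG = res$freqs[["+G"]],
               f_mA = res$freqs[["-A"]], f_mG = res$freqs[["-G"]],
               D = res$D, D_prime = res$D_prime, r2 = res$r2,
               converged = res$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
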