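# Builders and independent brute-force oracles shared across tests.
# Oracles are deliberately naive (explicit loops, no shared code with
# the package internals) so implementation and check stay independent.

toy_probe_table <- function(direct, swap = -direct, start0 = 1000000L,
                            spacing = 10000L, probe_len = 60L,
                            chrom = "chr1", cmp = "TOY_vs_REF") {
  n <- length(direct)
  starts <- start0 + (seq_len(n) - 1L) * spacing
  probe_table(data.frame(
    chrom = chrom, start = starts, end = starts + probe_len,
    probe_id = sprintf("p%03d", seq_len(n)),
    log2_direct = direct, log2_swap = swap,
    stringsAsFactors = FALSE), comparison_id = cmp)
}

toy_genotypes <- function(cnv, snp, population = "POP") {
  genotype_table(data.frame(
    sample_id = sprintf("%s_s%03d", population, seq_along(cnv)),
    population = population, cnv_genotype = cnv, snp_genotype = snp,
    stringsAsFactors = FALSE))
}

# exhaustive run segmentation: every maximal (i, j) stretch of probes
# that all qualify with one direction, checked pairwise
brute_rule_regions <- function(pt, thr = 0.25, min_probes = 3L, min_span = 30000L) {
  d <- pt$log2_direct; s <- pt$log2_swap
  ok <- abs(d) >= thr & abs(s) >= thr & sign(s) == -sign(d) &
    !is.na(d) & !is.na(s)
  dir <- ifelse(d < 0, "loss", "gain")
  n <- nrow(pt)
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      run_ok <- all(ok[i:j]) && length(unique(dir[i:j])) == 1L
      if (!run_ok) next
      maximal <- (i == 1L || !ok[i - 1L] || dir[i - 1L] != dir[i]) &&
        (j == n || !ok[j + 1L] || dir[j + 1L] != dir[j])
      if (!maximal) next
      if (j - i + 1L < min_probes) next
      if (pt$end[j] - pt$start[i] < min_span) next
      out[[length(out) + 1L]] <- c(start = pt$start[i], end = pt$end[j])
    }
  }
  out
}

# naive pairwise half-open interval intersections
brute_overlaps <- function(regions, features) {
  out <- 0L
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(features))) {
      if (regions$chrom[i] != features$chrom[j]) next
      lo <- max(regions$start[i], features$start[j])
      hi <- min(regions$end[i], features$end[j])
      if (hi - lo >= 1L) out <- out + 1L
    }
  }
  out
}

# direct gamete counting for phase-unambiguous joint genotype tables
direct_hap_freqs <- function(counts) {
  stopifnot(counts[2, 2] == 0)
  n2 <- 2 * sum(counts)
  c(`+A` = 2 * counts[1, 1] + counts[1, 2] + counts[2, 1],
    `+G` = 2 * counts[1, 3] + counts[1, 2] + counts[2, 3],
    `-A` = 2 * counts[3, 1] + counts[3, 2] + counts[2, 1],
    `-G` = 2 * counts[3, 3] + counts[3, 2] + counts[2, 3]) / n2
}

# multinomial log-likelihood of a 3x3 genotype table under haplotype
# frequencies f (+A, +G, -A, -G); independent of the package's version
oracle_loglik <- function(counts, f) {
  p <- matrix(c(f[1]^2,       2 * f[1] * f[2],                   f[2]^2,
                2 * f[1] * f[3], 2 * (f[1] * f[4] + f[2] * f[3]), 2 * f[2] * f[4],
                f[3]^2,       2 * f[3] * f[4],                   f[4]^2),
              3L, 3L, byrow = TRUE)
  if (any(counts > 0 & p <= 0)) return(-Inf)
  sum(counts[counts > 0] * log(p[counts > 0]))
}

random_joint_counts <- function(n, seed) {
  set.seed(seed)
  repeat {
    probs <- as.vector(rmultinom(1, 100, rep(1, 9))) / 100
    cts <- matrix(as.vector(rmultinom(1, n, probs)), 3L, 3L,
                  dimnames = list(c("+/+", "+/-", "-/-"), c("AA", "AG", "GG")))
    # need both alleles present at both loci for a non-degenerate check
    row_n <- rowSums(cts); col_n <- colSums(cts)
    p_plus <- (2 * row_n[1] + row_n[2]) / (2 * n)
    p_A <- (2 * col_n[1] + col_n[2]) / (2 * n)
    if (p_plus > 0 && p_plus < 1 && p_A > 0 && p_A < 1) return(cts)
  }
}
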