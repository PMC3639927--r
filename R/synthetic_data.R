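# Seeded generators for individual-level genotypes and pooled aCGH
# probe tables.  Individuals are random unions of gametes drawn i.i.d.
# from a population's four CNVxSNP haplotype frequencies, so each locus
# is in Hardy-Weinberg proportions in expectation.  Pools are exact
# allele-frequency mixtures of the simulated individuals; probe-level
# log2 ratios get independent Gaussian noise on the direct and dye-swap
# labels, the swap being the negation of the true signal.

#' Define a population model
#'
#' @param name population label.
#' @param n_individuals number of sampled individuals (HGDP-style
#'   panels run 11-44 per population).
#' @param haplotype_freqs numeric length-4 frequencies of the
#'   CNVxSNP haplotypes in order `+A`, `+G`, `-A`, `-G`; must be
#'   non-negative and sum to 1 within 1e-12.
#' @return a `population_model` list.
#' @export
population_model <- function(name, n_individuals, haplotype_freqs) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n_individuals <- as.integer(n_individuals)
  if (is.na(n_individuals) || n_individuals < 1L) stop("n_individuals must be >= 1")
  f <- as.numeric(haplotype_freqs)
  if (length(f) != 4L || anyNA(f) || any(f < 0)) stop("need 4 non-negative haplotype frequencies")
  if (abs(sum(f) - 1) > 1e-12) stop("haplotype frequencies must sum to 1 (got ", sum(f), ")")
  names(f) <- HAPLOTYPES
  structure(list(name = name, n_individuals = n_individuals,
                 haplotype_freqs = f),
            class = "population_model")
}

#' Haplotype frequencies with prescribed marginals and r-squared
#'
#' Convenience constructor for parameter-recovery studies: builds the
#' four haplotype frequencies with deleted-allele frequency `p_minus`,
#' tag-G frequency `p_G` and squared allelic correlation `r2` (positive
#' D, i.e. "-" coupled with "G").
#'
#' @param p_minus deleted-allele frequency in (0, 1).
#' @param p_G tag-SNP G-allele frequency in (0, 1).
#' @param r2 target squared correlation in `[0, 1]`.
#' @return named numeric length-4 over `+A`, `+G`, `-A`, `-G`.
#' @export
haplotype_freqs_for_r2 <- function(p_minus, p_G, r2) {
  stopifnot(p_minus > 0, p_minus < 1, p_G > 0, p_G < 1, r2 >= 0, r2 <= 1)
  D <- sqrt(r2 * p_minus * (1 - p_minus) * p_G * (1 - p_G))
  if (D > min(p_minus * (1 - p_G), (1 - p_minus) * p_G) + 1e-12)
    stop("r2 unattainable at these marginals")
  f <- c(`+A` = (1 - p_minus) * (1 - p_G) + D,
         `+G` = (1 - p_minus) * p_G - D,
         `-A` = p_minus * (1 - p_G) - D,
         `-G` = p_minus * p_G + D)
  pmax(f, 0) / sum(pmax(f, 0))
}

#' aCGH simulation parameters
#'
#' @param probe_spacing probe pitch in bp (default 10000: genome-wide
#'   244k arrays tile at roughly 10-kb resolution).
#' @param probe_length probe footprint in bp (default 60, an
#'   oligonucleotide probe).
#' @param noise_sd Gaussian probe noise, log2 units, applied
#'   independently to each label (default 0.1).
#' @param attenuation multiplicative signal compression in (0, 1]
#'   (default 0.5): pooled hybridisations report a damped version of
#'   the ideal log2 copy-number ratio.
#' @param deletion_interval list with `chrom`, `start`, `end`
#'   (0-based half-open); defaults to [lce_deletion_interval()].
#' @param flank_probes probes simulated on each side of the interval
#'   (default 5).
#' @return an `acgh_sim_params` list.
#' @export
acgh_sim_params <- function(probe_spacing = 10000L, probe_length = 60L,
                            noise_sd = 0.1, attenuation = 0.5,
                            deletion_interval = lce_deletion_interval(),
                            flank_probes = 5L) {
  stopifnot(noise_sd >= 0, attenuation > 0, attenuation <= 1,
            probe_spacing >= 1, flank_probes >= 0)
  stopifnot(is.list(deletion_interval),
            all(c("chrom", "start", "end") %in% names(deletion_interval)),
            deletion_interval$start < deletion_interval$end)
  structure(list(probe_spacing = as.integer(probe_spacing),
                 probe_length = as.integer(probe_length),
                 noise_sd = noise_sd, attenuation = attenuation,
                 deletion_interval = deletion_interval,
                 flank_probes = as.integer(flank_probes)),
            class = "acgh_sim_params")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

simulate_genotypes_impl <- function(model) {
  n <- model$n_individuals
  haps <- sample.int(4L, 2L * n, replace = TRUE, prob = model$haplotype_freqs)
  h1 <- haps[seq_len(n) * 2L - 1L]
  h2 <- haps[seq_len(n) * 2L]
  cnv_allele <- function(h) ifelse(h <= 2L, "+", "-")  # haplotypes 1,2 carry "+"
  snp_allele <- function(h) ifelse(h %% 2L == 1L, "A", "G")  # odd indices carry "A"
  n_plus <- (cnv_allele(h1) == "+") + (cnv_allele(h2) == "+")
  n_A <- (snp_allele(h1) == "A") + (snp_allele(h2) == "A")
  data.frame(
    sample_id = sprintf("%s_%03d", model$name, seq_len(n)),
    population = model$name,
    cnv_genotype = CNV_GENOTYPES[3L - n_plus],
    snp_genotype = SNP_GENOTYPES[3L - n_A],
    stringsAsFactors = FALSE)
}

#' Simulate individual genotypes for one population
#'
#' Each individual is the union of two gametes drawn i.i.d. from the
#' model's haplotype frequencies, so both loci satisfy Hardy-Weinberg
#' proportions in expectation.  Deterministic given `seed`.
#'
#' @param model a [population_model].
#' @param seed integer RNG seed.
#' @return a [genotype_table] with `n_individuals` rows.
#' @export
simulate_genotypes <- function(model, seed) {
  stopifnot(inherits(model, "population_model"))
  genotype_table(with_seed(seed, simulate_genotypes_impl(model)))
}

#' Simulate genotypes for a set of populations
#'
#' @param models list of [population_model]s.
#' @param seed integer RNG seed (one stream drawn sequentially across
#'   populations, so the whole table is reproducible).
#' @return a [genotype_table].
#' @export
simulate_genotype_set <- function(models, seed) {
  stopifnot(length(models) >= 1L)
  df <- with_seed(seed, do.call(rbind, lapply(models, simulate_genotypes_impl)))
  genotype_table(df)
}

#' Expected pooled log2 ratio at a deletion
#'
#' In an equimolar pool the mean diploid copy number at a biallelic
#' deletion is `2 * p_nondel` (genotypes `+/+`, `+/-`, `-/-` carry 2,
#' 1, 0 copies), so the ideal test-vs-reference log2 ratio is
#' `log2(p_nondel_test / p_nondel_ref)`; pooled hybridisations compress
#' this by a multiplicative `attenuation` factor.
#'
#' @param p_nondel_test,p_nondel_ref non-deleted allele frequency of
#'   the test and reference pools, in (0, 1].
#' @param attenuation multiplicative compression in (0, 1].
#' @return expected log2 ratio (numeric scalar).
#' @examples
#' expected_pool_log2(0.25, 0.6591, 1)     # ~ -1.399
#' expected_pool_log2(0.25, 0.6591, 0.48)  # ~ -0.67
#' @export
expected_pool_log2 <- function(p_nondel_test, p_nondel_ref, attenuation) {
  if (p_nondel_ref <= 0 || p_nondel_ref > 1)
    stop("p_nondel_ref must be in (0, 1]")
  if (p_nondel_test <= 0 || p_nondel_test > 1)
    stop("p_nondel_test must be in (0, 1]")
  if (attenuation <= 0 || attenuation > 1) stop("attenuation must be in (0, 1]")
  attenuation * log2(p_nondel_test / p_nondel_ref)
}

pool_nondel_freq <- function(gt) {
  counts <- as.integer(table(factor(gt$cnv_genotype, levels = CNV_GENOTYPES)))
  allele_frequencies(counts)[["p_ref"]]
}

#' Simulate pooled aCGH comparisons with ground truth
#'
#' Simulates genotypes for the reference and each test population,
#' forms exact allele-frequency pools, and emits a probe table per
#' test-vs-reference comparison.  Probes tile the deletion interval at
#' `probe_spacing` plus `flank_probes` on each side; probes inside the
#' interval have mean [expected_pool_log2()] evaluated at the realised
#' pool frequencies, outside probes mean 0.  The direct label is signal
#' plus noise, the dye-swap label is the negated signal plus
#' independent noise.  Deterministic given `seed`.
#'
#' @param models list of test-population [population_model]s.
#' @param reference the reference [population_model].
#' @param params an [acgh_sim_params]; the deletion interval must be
#'   longer than `2 * probe_spacing` so at least 3 probes fall inside.
#' @param seed integer RNG seed.
#' @return list with `probes` (named list of [probe_table], one per
#'   comparison `"<pop>_vs_<ref>"`), `truth` (a [cnv_regions] of
#'   expected regions for comparisons whose pools differ), and
#'   `genotypes` (the combined [genotype_table] including the
#'   reference).
#' @export
simulate_pool_acgh <- function(models, reference, params, seed) {
  stopifnot(inherits(params, "acgh_sim_params"),
            inherits(reference, "population_model"), length(models) >= 1L)
  iv <- params$deletion_interval
  if ((iv$end - iv$start) <= 2L * params$probe_spacing)
    stop("deletion interval shorter than 2 * probe_spacing: fewer than 3 probes inside")
  with_seed(seed, {
    gts <- lapply(c(list(reference), models), simulate_genotypes_impl)
    names(gts) <- c(reference$name, vapply(models, `[[`, "", "name"))
    p_ref <- pool_nondel_freq(gts[[1L]])
    if (p_ref == 0) stop("reference pool has no non-deleted alleles")
    inside_starts <- seq.int(iv$start, iv$end - 1L, by = params$probe_spacing)
    starts <- c(iv$start - rev(seq_len(params$flank_probes)) * params$probe_spacing,
                inside_starts,
                max(inside_starts) + seq_len(params$flank_probes) * params$probe_spacing)
    inside <- starts >= iv$start & starts < iv$end
    n_probe <- length(starts)
    probes <- list(); truth <- list()
    for (m in models) {
      p_test <- pool_nondel_freq(gts[[m$name]])
      if (p_test == 0)
        stop("pool for ", m$name, " has no non-deleted alleles; cannot form log2 ratio")
      mu_in <- expected_pool_log2(p_test, p_ref, params$attenuation)
      mu <- ifelse(inside, mu_in, 0)
      direct <- mu + rnorm(n_probe, sd = params$noise_sd)
      swap <- -mu + rnorm(n_probe, sd = params$noise_sd)
      cmp <- paste0(m$name, "_vs_", reference$name)
      probes[[cmp]] <- probe_table(data.frame(
        chrom = iv$chrom, start = starts, end = starts + params$probe_length,
        probe_id = sprintf("%s_P%03d", cmp, seq_len(n_probe)),
        log2_direct = direct, log2_swap = swap,
        stringsAsFactors = FALSE), comparison_id = cmp)
      if (mu_in != 0) {
        truth[[cmp]] <- data.frame(
          chrom = iv$chrom, start = iv$start, end = iv$end,
          direction = if (mu_in < 0) "loss" else "gain",
          n_probes = sum(inside), mean_log2 = mu_in,
          caller = "truth", comparison_id = cmp, stringsAsFactors = FALSE)
      }
    }
    gt_all <- genotype_table(do.call(rbind, gts))
    list(probes = probes,
         truth = cnv_regions(if (length(truth) > 0L) do.call(rbind, truth)
                             else data.frame()),
         genotypes = gt_all)
  })
}
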