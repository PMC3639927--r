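test_that("rule caller applies the probe, span and dye-swap criteria", {
  params <- detection_params()

  # 5 consecutive loss probes over 40 kb: one region
  pass <- toy_probe_table(direct = c(0, rep(-0.6, 5), 0))
  r <- call_rule_based(pass, params)
  expect_equal(nrow(as.data.frame(r)), 1L)
  expect_equal(r$n_probes, 5L)
  expect_equal(r$direction, "loss")
  expect_equal(r$end - r$start, 4L * 10000L + 60L)

  # only 2 qualifying consecutive probes: below the 3-probe criterion
  two <- toy_probe_table(direct = c(0, -0.6, -0.6, 0, 0))
  expect_equal(nrow(as.data.frame(call_rule_based(two, params))), 0L)

  # 4 qualifying probes spanning only ~20 kb: span filter rejects
  narrow <- toy_probe_table(direct = rep(-0.6, 4), spacing = 6500L)
  expect_equal(nrow(as.data.frame(call_rule_based(narrow, params))), 0L)

  # a same-sign dye-swap probe splits the run
  d <- rep(-0.6, 7)
  s <- c(0.6, 0.6, 0.6, -0.6, 0.6, 0.6, 0.6)  # probe 4 fails the swap criterion
  split_pt <- toy_probe_table(direct = d, swap = s)
  got <- call_rule_based(split_pt, params)
  expect_equal(nrow(as.data.frame(got)), 0L)  # 3-probe runs but 20-kb spans
  wide <- toy_probe_table(direct = d, swap = s, spacing = 20000L)
  got_wide <- call_rule_based(wide, params)
  expect_equal(nrow(as.data.frame(got_wide)), 2L)  # run split, both spans pass

  # empty table
  expect_equal(nrow(as.data.frame(call_rule_based(pass[0, ]))), 0L)
})

test_that("rule caller matches exhaustive run enumeration on random toys", {
  set.seed(81)
  params <- detection_params()
  for (rep in 1:60) {
    n <- 10
    d <- round(rnorm(n, 0, 0.5), 2)
    s <- round(-d + rnorm(n, 0, 0.3), 2)
    pt <- toy_probe_table(direct = d, swap = s, spacing = 15000L)
    got <- as.data.frame(call_rule_based(pt, params))
    want <- brute_rule_regions(pt, 0.25, 3L, 30000L)
    expect_equal(nrow(got), length(want))
    if (length(want) > 0) {
      expect_equal(got$start, vapply(want, `[[`, numeric(1), "start"))
      expect_equal(got$end, vapply(want, `[[`, numeric(1), "end"))
    }
  }
})

test_that("window caller flags sustained signal but not isolated outliers", {
  params <- detection_params(window_size = 3L)

  expect_equal(nrow(as.data.frame(call_window(
    toy_probe_table(direct = rep(0, 8)), params))), 0L)

  # single outlier at -5 among zeros: clipped, and the short run the
  # smoother produces dies on the 30-kb span filter
  outlier <- toy_probe_table(direct = c(0, 0, -5, 0, 0))
  expect_equal(nrow(as.data.frame(call_window(outlier, params))), 0L)

  # sustained signal is called
  sus <- toy_probe_table(direct = c(0, rep(-0.6, 5), 0))
  got <- call_window(sus, params)
  expect_equal(nrow(as.data.frame(got)), 1L)
  expect_equal(got$direction, "loss")

  # fewer probes than the window: no calls
  expect_equal(nrow(as.data.frame(call_window(
    toy_probe_table(direct = rep(-0.6, 2)), detection_params(window_size = 5L)))), 0L)
})

test_that("noise-free simulation: window and rule callers agree within one spacing", {
  m <- population_model("T", 40, haplotype_freqs_for_r2(0.75, 0.75, 0.9))
  r <- population_model("R", 40, haplotype_freqs_for_r2(0.3, 0.7, 0.1))
  sim <- simulate_pool_acgh(list(m), r, acgh_sim_params(noise_sd = 0), seed = 2)
  pt <- sim$probes[[1]]
  a <- as.data.frame(call_rule_based(pt))
  b <- as.data.frame(call_window(pt))
  expect_equal(nrow(a), 1L)
  expect_equal(nrow(b), 1L)
  expect_lte(abs(a$start - b$start), 10000L)
  expect_lte(abs(a$end - b$end), 10000L)
})

test_that("consensus is idempotent, rejects disjoint sets and honours reciprocal overlap", {
  a <- cnv_regions(data.frame(chrom = "chr1", start = 0L, end = 100000L,
                              direction = "loss", n_probes = 5L, mean_log2 = -0.5,
                              caller = "rule", comparison_id = "c"))
  same <- cnv_consensus(a, a, 0.5)
  expect_equal(nrow(as.data.frame(same)), 1L)
  expect_equal(same$start, a$start)
  expect_equal(same$caller, "consensus")

  far <- cnv_regions(data.frame(chrom = "chr1", start = 500000L, end = 600000L,
                                direction = "loss", n_probes = 5L, mean_log2 = -0.5,
                                caller = "window", comparison_id = "c"))
  expect_equal(nrow(as.data.frame(cnv_consensus(a, far, 0.5))), 0L)

  # 60% reciprocal overlap: kept at threshold 0.5, dropped at 0.7
  b <- cnv_regions(data.frame(chrom = "chr1", start = 40000L, end = 140000L,
                              direction = "loss", n_probes = 5L, mean_log2 = -0.5,
                              caller = "window", comparison_id = "c"))
  expect_equal(nrow(as.data.frame(cnv_consensus(a, b, 0.5))), 1L)
  expect_equal(nrow(as.data.frame(cnv_consensus(a, b, 0.7))), 0L)

  # direction must match
  gain <- cnv_regions(data.frame(chrom = "chr1", start = 0L, end = 100000L,
                                 direction = "gain", n_probes = 5L, mean_log2 = 0.5,
                                 caller = "window", comparison_id = "c"))
  expect_equal(nrow(as.data.frame(cnv_consensus(a, gain, 0.5))), 0L)
})

test_that("feature annotation uses half-open intersection semantics", {
  reg <- cnv_regions(data.frame(chrom = "chr1", start = 100L, end = 200L,
                                direction = "loss", n_probes = 3L, mean_log2 = -1,
                                caller = "rule", comparison_id = "c"))
  feats <- data.frame(chrom = "chr1", start = 100L, end = 200L, name = "GENE1")
  ann <- annotate_overlaps(reg, feats)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$overlap_frac, 1.0)

  # adjacent half-open intervals share a coordinate but do not overlap
  adj <- data.frame(chrom = "chr1", start = 200L, end = 300L, name = "GENE2")
  expect_equal(nrow(annotate_overlaps(reg, adj)), 0L)

  expect_warning(annotate_overlaps(reg,
    data.frame(chrom = "chr2", start = 100L, end = 200L, name = "X")),
    "chromosome")

  # toy 3 regions x 4 features vs exhaustive pairwise oracle
  regs <- cnv_regions(data.frame(
    chrom = "chr1", start = c(0L, 500L, 900L), end = c(400L, 800L, 1200L),
    direction = "loss", n_probes = 3L, mean_log2 = -1,
    caller = "rule", comparison_id = "c"))
  fs <- data.frame(chrom = "chr1", start = c(100L, 350L, 800L, 1199L),
                   end = c(200L, 600L, 900L, 1500L),
                   name = paste0("G", 1:4))
  expect_equal(nrow(annotate_overlaps(regs, fs)), brute_overlaps(regs, fs))
})

test_that("calls are monotone in the detection thresholds", {
  set.seed(91)
  total_span <- function(r) sum(as.data.frame(r)$end - as.data.frame(r)$start)
  n_regions <- function(r) nrow(as.data.frame(r))
  for (rep in 1:100) {
    d <- rnorm(20, 0, 0.5)
    s <- -d + rnorm(20, 0, 0.2)
    pt <- toy_probe_table(direct = d, swap = s, spacing = 12000L)
    base <- detection_params()
    r0 <- call_rule_based(pt, base)
    # raising any threshold never increases total called span
    for (p in list(detection_params(log2_threshold = 0.4),
                   detection_params(min_consecutive_probes = 4L),
                   detection_params(min_span = 45000L))) {
      expect_lte(total_span(call_rule_based(pt, p)), total_span(r0))
    }
    # the pure filter parameters cannot increase the region count either
    expect_lte(n_regions(call_rule_based(pt, detection_params(min_consecutive_probes = 4L))),
               n_regions(r0))
    expect_lte(n_regions(call_rule_based(pt, detection_params(min_span = 45000L))),
               n_regions(r0))
    # consensus is anti-monotone in the concordance threshold
    w0 <- call_window(pt, base)
    expect_lte(n_regions(cnv_consensus(r0, w0, 0.8)),
               n_regions(cnv_consensus(r0, w0, 0.4)))
  }
})

test_that("called regions never overlap within a comparison", {
  set.seed(101)
  for (rep in 1:20) {
    d <- rnorm(30, 0, 0.6)
    pt <- toy_probe_table(direct = d, swap = -d + rnorm(30, 0, 0.2),
                          spacing = 15000L)
    for (r in list(call_rule_based(pt), call_window(pt))) {
      df <- as.data.frame(r)
      if (nrow(df) < 2) next
      df <- df[order(df$start), ]
      expect_true(all(df$start[-1] >= df$end[-nrow(df)]))
    }
  }
})

test_that("consensus recall stays high at realistic noise over 100 replicates", {
  # strong deletion contrast (PIMA-like vs African reference), noise sd 0.1
  m <- population_model("HIGH", 40, haplotype_freqs_for_r2(0.75, 0.75, 0.9))
  r <- population_model("AFR", 40, haplotype_freqs_for_r2(0.3, 0.7, 0.1))
  params <- acgh_sim_params(noise_sd = 0.1)
  hits <- 0L; tried <- 0L
  for (s in 1:100) {
    sim <- simulate_pool_acgh(list(m), r, params, seed = 200 + s)
    truth <- as.data.frame(sim$truth)
    if (nrow(truth) == 0 || abs(truth$mean_log2) < 0.4) next
    tried <- tried + 1L
    cons <- as.data.frame(cnv_consensus(call_rule_based(sim$probes[[1]]),
                                        call_window(sim$probes[[1]])))
    if (nrow(cons) == 1L && abs(cons$start - truth$start) <= 10000L &&
        abs(cons$end - truth$end) <= 10000L) hits <- hits + 1L
  }
  expect_gte(tried, 90L)
  expect_gte(hits / tried, 0.95)
})
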