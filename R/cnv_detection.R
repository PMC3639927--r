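# CNV-region detection on dye-swap probe data.  Two callers:
#  * rule-based: maximal runs of consecutive probes where BOTH labels
#    clear the log2 threshold with opposite signs and constant
#    direction; runs must reach 3 consecutive probes and a 30-kb span.
#  * windowed-mean: sliding window over the dye-swap-combined signal
#    s = (direct - swap) / 2, with per-probe clipping.
# A consensus filter keeps regions with reciprocal overlap between the
# two callers; regions can then be annotated against BED features.

#' Detection parameters
#'
#' Defaults implement a stringent multi-criterion rule for pooled
#' arrays: log2 ratios beyond 0.25 on both the direct and the dye-swap
#' label for at least 3 consecutive probes, over a span of at least
#' 30 kb.
#'
#' @param log2_threshold per-label absolute log2 cutoff (> 0, default
#'   0.25).
#' @param min_consecutive_probes minimum run length (default 3).
#' @param min_span minimum genomic span in bp, first probe start to
#'   last probe end (default 30000).
#' @param require_dye_swap if `TRUE` (default) a probe qualifies only
#'   when both labels clear the threshold with opposite signs; probes
#'   missing a label terminate runs.
#' @param window_size probe count for the windowed second caller
#'   (default 5, must be >= 3).
#' @param concordance_overlap reciprocal-overlap fraction for the
#'   consensus filter (default 0.5).
#' @param clip absolute bound applied to the combined per-probe signal
#'   in the window caller (default 2.0), limiting single-outlier
#'   influence.
#' @return a `detection_params` list.
#' @export
detection_params <- function(log2_threshold = 0.25, min_consecutive_probes = 3L,
                             min_span = 30000L, require_dye_swap = TRUE,
                             window_size = 5L, concordance_overlap = 0.5,
                             clip = 2.0) {
  stopifnot(log2_threshold > 0, min_consecutive_probes >= 1L, min_span >= 0,
            window_size >= 3L, concordance_overlap > 0, concordance_overlap <= 1,
            clip > 0)
  structure(list(log2_threshold = log2_threshold,
                 min_consecutive_probes = as.integer(min_consecutive_probes),
                 min_span = as.integer(min_span),
                 require_dye_swap = isTRUE(require_dye_swap),
                 window_size = as.integer(window_size),
                 concordance_overlap = concordance_overlap, clip = clip),
            class = "detection_params")
}

combined_signal <- function(pt, clip = Inf) {
  s <- (pt$log2_direct - pt$log2_swap) / 2
  only_direct <- is.na(pt$log2_swap) & !is.na(pt$log2_direct)
  only_swap <- is.na(pt$log2_direct) & !is.na(pt$log2_swap)
  s[only_direct] <- pt$log2_direct[only_direct]
  s[only_swap] <- -pt$log2_swap[only_swap]
  pmin(pmax(s, -clip), clip)
}

regions_from_runs <- function(pt, keep, direction, params, caller, signal,
                              apply_min_probes = TRUE) {
  out <- list()
  r <- rle(paste0(keep, ".", direction))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    i <- starts[k]; j <- ends[k]
    if (!keep[i]) next
    if (apply_min_probes && (j - i + 1L) < params$min_consecutive_probes) next
    span_start <- pt$start[i]; span_end <- pt$end[j]
    if (span_end - span_start < params$min_span) next
    m <- mean(signal[i:j])
    out[[length(out) + 1L]] <- data.frame(
      chrom = pt$chrom[i], start = span_start, end = span_end,
      direction = if (m < 0) "loss" else "gain",
      n_probes = j - i + 1L, mean_log2 = m, caller = caller,
      comparison_id = comparison_id(pt), stringsAsFactors = FALSE)
  }
  cnv_regions(if (length(out) > 0L) do.call(rbind, out) else data.frame())
}

#' Rule-based CNV caller on dye-swap probe data
#'
#' Scans each chromosome for maximal runs of consecutive probes where
#' `|log2_direct| >= log2_threshold` and (with `require_dye_swap`)
#' `|log2_swap| >= log2_threshold` with sign opposite to the direct
#' label, the direction staying constant across the run.  Runs of at
#' least `min_consecutive_probes` probes spanning at least `min_span`
#' bp (first probe start to last probe end) become regions; any probe
#' failing a criterion terminates the run.
#'
#' @param probes a [probe_table] (sorted).
#' @param params a [detection_params].
#' @return a [cnv_regions] set (empty for an empty table).
#' @export
call_rule_based <- function(probes, params = detection_params()) {
  stopifnot(inherits(probes, "probe_table"), inherits(params, "detection_params"))
  if (nrow(probes) == 0L) return(cnv_regions())
  thr <- params$log2_threshold
  d <- probes$log2_direct; s <- probes$log2_swap
  ok_direct <- !is.na(d) & abs(d) >= thr
  if (params$require_dye_swap) {
    ok <- ok_direct & !is.na(s) & abs(s) >= thr & sign(s) == -sign(d)
  } else {
    ok <- ok_direct
  }
  direction <- ifelse(ok, ifelse(d < 0, "loss", "gain"), "none")
  out <- lapply(split(seq_len(nrow(probes)), probes$chrom), function(idx) {
    pt <- probes[idx, , drop = FALSE]
    attr(pt, "comparison_id") <- comparison_id(probes)
    regions_from_runs(pt, ok[idx], direction[idx], params, "rule",
                      combined_signal(pt))
  })
  merged <- do.call(rbind, lapply(out, as.data.frame))
  cnv_regions(if (!is.null(merged)) merged else data.frame())
}

#' Windowed-mean CNV caller (second, independent algorithm)
#'
#' Slides a `window_size`-probe running mean over the
#' dye-swap-combined signal `s = (log2_direct - log2_swap) / 2` (a
#' probe missing one label contributes its available label; per-probe
#' `|s|` is clipped at `clip` to bound outlier influence).  Each
#' window's mean is assigned to its centre probe; maximal runs of
#' centre probes whose smoothed `|s|` reaches `log2_threshold` with a
#' constant direction become regions, subject to the same span filter
#' as the rule caller.  Probes too close to a chromosome edge to carry
#' a full window never qualify.
#'
#' @inheritParams call_rule_based
#' @return a [cnv_regions] set; fewer probes than `window_size` on a
#'   chromosome yields no calls there.
#' @export
call_window <- function(probes, params = detection_params()) {
  stopifnot(inherits(probes, "probe_table"), inherits(params, "detection_params"))
  if (nrow(probes) == 0L) return(cnv_regions())
  w <- params$window_size
  off <- (w - 1L) %/% 2L
  out <- lapply(split(seq_len(nrow(probes)), probes$chrom), function(idx) {
    pt <- probes[idx, , drop = FALSE]
    attr(pt, "comparison_id") <- comparison_id(probes)
    n <- nrow(pt)
    if (n < w) return(cnv_regions())
    sig <- combined_signal(pt, clip = params$clip)
    sig[is.na(sig)] <- 0
    smoothed <- rep(NA_real_, n)
    for (i in seq_len(n - w + 1L)) smoothed[i + off] <- mean(sig[i:(i + w - 1L)])
    qual <- !is.na(smoothed) & abs(smoothed) >= params$log2_threshold
    dir_probe <- ifelse(qual, ifelse(smoothed < 0, "loss", "gain"), "none")
    regions_from_runs(pt, qual, dir_probe, params, "window", sig,
                      apply_min_probes = FALSE)
  })
  merged <- do.call(rbind, lapply(out, as.data.frame))
  cnv_regions(if (!is.null(merged)) merged else data.frame())
}

regions_iranges <- function(regions) {
  IRanges::IRanges(start = regions$start + 1L, end = regions$end)
}

#' Two-caller consensus filter
#'
#' Keeps each region of `regions_a` that has at least
#' `concordance_overlap` reciprocal overlap (intersection over both
#' widths) with a same-chromosome, same-direction region of
#' `regions_b`; kept regions retain list-a intervals with
#' `caller = "consensus"`.
#'
#' @param regions_a,regions_b [cnv_regions] sets from the same
#'   comparison.
#' @param concordance_overlap reciprocal-overlap fraction in (0, 1].
#' @return a [cnv_regions] set.
#' @export
cnv_consensus <- function(regions_a, regions_b, concordance_overlap = 0.5) {
  stopifnot(concordance_overlap > 0, concordance_overlap <= 1)
  a <- as.data.frame(regions_a); b <- as.data.frame(regions_b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(cnv_regions())
  keep <- logical(nrow(a))
  for (key in unique(paste(a$chrom, a$direction))) {
    ia <- which(paste(a$chrom, a$direction) == key)
    ib <- which(paste(b$chrom, b$direction) == key)
    if (length(ib) == 0L) next
    ra <- regions_iranges(a[ia, , drop = FALSE])
    rb <- regions_iranges(b[ib, , drop = FALSE])
    hits <- IRanges::findOverlaps(ra, rb)
    if (length(hits) == 0L) next
    qa <- S4Vectors::queryHits(hits); qb <- S4Vectors::subjectHits(hits)
    inter <- IRanges::width(IRanges::pintersect(ra[qa], rb[qb]))
    recip <- inter >= concordance_overlap * IRanges::width(ra)[qa] &
             inter >= concordance_overlap * IRanges::width(rb)[qb]
    keep[ia[unique(qa[recip])]] <- TRUE
  }
  out <- a[keep, , drop = FALSE]
  if (nrow(out) > 0L) out$caller <- "consensus"
  cnv_regions(out)
}

#' Annotate regions with overlapping features
#'
#' Half-open interval intersection against a BED-style feature table;
#' any intersection of at least 1 bp counts as an overlap ("totally or
#' partially overlapping").  The overlap fraction is the intersection
#' length divided by the region width.
#'
#' @param regions a [cnv_regions] set.
#' @param features data.frame with `chrom`, `start`, `end`, `name`
#'   (see [read_features_bed()]).
#' @return data.frame with one row per (region, overlapping feature):
#'   `region_index`, `chrom`, `start`, `end`, `feature`, `overlap_bp`,
#'   `overlap_frac`.  Regions with no overlapping feature are absent.
#'   If the two inputs share no chromosome names a warning is issued.
#' @export
annotate_overlaps <- function(regions, features) {
  regions <- as.data.frame(regions)
  empty <- data.frame(region_index = integer(), chrom = character(),
                      start = integer(), end = integer(), feature = character(),
                      overlap_bp = integer(), overlap_frac = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(regions) == 0L || nrow(features) == 0L) return(empty)
  if (length(intersect(unique(regions$chrom), unique(features$chrom))) == 0L) {
    warning("regions and features share no chromosome names; zero overlaps")
    return(empty)
  }
  out <- list()
  for (ch in intersect(unique(regions$chrom), unique(features$chrom))) {
    ir <- which(regions$chrom == ch)
    jf <- which(features$chrom == ch)
    rr <- regions_iranges(regions[ir, , drop = FALSE])
    rf <- regions_iranges(features[jf, , drop = FALSE])
    hits <- IRanges::findOverlaps(rr, rf)
    if (length(hits) == 0L) next
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    inter <- IRanges::width(IRanges::pintersect(rr[q], rf[s]))
    out[[ch]] <- data.frame(
      region_index = ir[q], chrom = ch,
      start = regions$start[ir[q]], end = regions$end[ir[q]],
      feature = features$name[jf[s]], overlap_bp = as.integer(inter),
      overlap_frac = inter / (regions$end[ir[q]] - regions$start[ir[q]]),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$region_index), , drop = FALSE]
}
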