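# On-disk formats: probe tables (TSV + "#comparison=" header), genotype
# tables (TSV), called regions (BED6) and population summaries (TSV).
# All intervals are 0-based half-open; read o write is the identity on
# canonical files.

#' Construct a validated probe table
#'
#' A probe table holds one pooled test-vs-reference aCGH comparison:
#' per-probe genomic intervals with direct-label and dye-swap log2
#' ratios.  Rows are sorted by (chromosome, start); `start < end`,
#' probe ids unique, log2 values finite (NA allowed only for a missing
#' label).
#'
#' @param df data.frame with columns `chrom`, `start`, `end`,
#'   `probe_id`, `log2_direct`, `log2_swap`; extra columns are kept as
#'   opaque annotations.
#' @param comparison_id character scalar naming the pool pair, e.g.
#'   `"PIMA_vs_YRI"`.
#' @param on_unsorted `"sort"` (default, with a warning) or `"error"`.
#' @return A `probe_table` (data.frame subclass) with attribute
#'   `comparison_id`.
#' @export
probe_table <- function(df, comparison_id, on_unsorted = c("sort", "error")) {
  on_unsorted <- match.arg(on_unsorted)
  required <- c("chrom", "start", "end", "probe_id", "log2_direct", "log2_swap")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("probe table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!is.character(comparison_id) || length(comparison_id) != 1L || !nzchar(comparison_id))
    stop("comparison_id must be a non-empty string")
  df$chrom <- as.character(df$chrom)
  df$probe_id <- as.character(df$probe_id)
  for (col in c("start", "end")) {
    df[[col]] <- as.integer(df[[col]])
    if (anyNA(df[[col]])) stop("non-integer coordinate in column ", col)
  }
  for (col in c("log2_direct", "log2_swap")) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(is.infinite(df[[col]]))) stop("non-finite log2 value in column ", col)
  }
  bad <- which(df$start >= df$end)
  if (length(bad) > 0L)
    stop("start >= end at row ", bad[1L], " (probe ",
         df$probe_id[bad[1L]], ")")
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe_id: ", df$probe_id[anyDuplicated(df$probe_id)])
  ord <- order(df$chrom, df$start, df$end)
  if (any(ord != seq_len(nrow(df)))) {
    if (on_unsorted == "error") stop("probe table is not sorted by (chrom, start)")
    warning("probe table was unsorted; sorting by (chrom, start)")
    df <- df[ord, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, comparison_id = comparison_id,
            class = c("probe_table", "data.frame"))
}

#' @rdname probe_table
#' @param x object to query.
#' @export
comparison_id <- function(x) attr(x, "comparison_id")

#' Read a probe table from TSV
#'
#' The file carries a `#comparison=<id>` header line followed by a
#' tab-delimited table with columns `chrom`, `start`, `end`,
#' `probe_id`, `log2_direct`, `log2_swap`.  Malformed rows are reported
#' with their file line number.
#'
#' @param path file path.
#' @inheritParams probe_table
#' @return A [probe_table].
#' @export
read_probe_table <- function(path, on_unsorted = c("sort", "error")) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  cmp_line <- grep("^#comparison=", lines)
  cmp <- if (length(cmp_line) > 0L)
    sub("^#comparison=", "", lines[cmp_line[1L]]) else "unknown"
  body_idx <- which(!startsWith(lines, "#"))
  if (length(body_idx) == 0L) stop("probe table has no header row: ", path)
  header_line <- body_idx[1L]
  df <- tryCatch(
    read.delim(text = lines[body_idx], stringsAsFactors = FALSE,
               check.names = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
  # validate with line numbers: data row i sits at file line body_idx[i + 1]
  tryCatch(
    probe_table(df, comparison_id = cmp, on_unsorted = on_unsorted),
    error = function(e) {
      m <- regmatches(conditionMessage(e),
                      regexec("at row ([0-9]+)", conditionMessage(e)))[[1L]]
      if (length(m) == 2L) {
        row <- as.integer(m[2L])
        stop(sub(paste0("at row ", row),
                 paste0("at line ", body_idx[row + 1L], " of ", path),
                 conditionMessage(e)), call. = FALSE)
      }
      stop(conditionMessage(e), call. = FALSE)
    })
}

#' Write a probe table to canonical TSV
#'
#' @param pt a [probe_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(pt, path) {
  stopifnot(inherits(pt, "probe_table"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("#comparison=", comparison_id(pt)), con)
  write.table(as.data.frame(pt), con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Construct a validated genotype table
#'
#' One row per individual: population label, CNV genotype
#' (`+/+`, `+/-`, `-/-`) and SNP genotype (`AA`, `AG`, `GG`); either
#' locus may be missing (`NA`).
#'
#' @param df data.frame with columns `sample_id`, `population`,
#'   `cnv_genotype`, `snp_genotype`.
#' @return A `genotype_table` (data.frame subclass).
#' @export
genotype_table <- function(df) {
  required <- c("sample_id", "population", "cnv_genotype", "snp_genotype")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("genotype table missing column(s): ", paste(missing_cols, collapse = ", "))
  for (col in required) df[[col]] <- as.character(df[[col]])
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ", df$sample_id[anyDuplicated(df$sample_id)])
  if (any(!nzchar(df$population) | is.na(df$population)))
    stop("empty population label")
  check_tokens <- function(col, vocab) {
    bad <- !is.na(df[[col]]) & !(df[[col]] %in% vocab)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("illegal ", col, " token ", dQuote(df[[col]][i]),
           " for sample ", df$sample_id[i])
    }
  }
  check_tokens("cnv_genotype", CNV_GENOTYPES)
  check_tokens("snp_genotype", SNP_GENOTYPES)
  rownames(df) <- NULL
  structure(df, class = c("genotype_table", "data.frame"))
}

#' Read a genotype table from TSV
#'
#' @param path file path.
#' @param missing_code token representing a missing genotype
#'   (default `"NA"`); stored internally as `NA`.
#' @return A [genotype_table].
#' @export
read_genotype_table <- function(path, missing_code = "NA") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                   na.strings = character(0), comment.char = "#")
  for (col in c("cnv_genotype", "snp_genotype")) {
    if (col %in% names(df)) df[[col]][df[[col]] %in% missing_code] <- NA_character_
  }
  genotype_table(df)
}

#' Write a genotype table to TSV
#'
#' @param gt a [genotype_table].
#' @param path output path.
#' @param missing_code token to write for missing genotypes.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gt, path, missing_code = "NA") {
  stopifnot(inherits(gt, "genotype_table"))
  df <- as.data.frame(gt)
  df$cnv_genotype[is.na(df$cnv_genotype)] <- missing_code
  df$snp_genotype[is.na(df$snp_genotype)] <- missing_code
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Construct a validated CNV region set
#'
#' Regions are 0-based half-open intervals with a direction
#' (`loss`/`gain`) consistent with the sign of the mean log2 ratio,
#' a supporting probe count and caller provenance.
#'
#' @param df data.frame with columns `chrom`, `start`, `end`,
#'   `direction`, `n_probes`, `mean_log2`, `caller`, `comparison_id`.
#' @return A `cnv_regions` (data.frame subclass).
#' @export
cnv_regions <- function(df = data.frame()) {
  cols <- c("chrom", "start", "end", "direction", "n_probes",
            "mean_log2", "caller", "comparison_id")
  if (nrow(df) == 0L) {
    df <- data.frame(chrom = character(), start = integer(), end = integer(),
                     direction = character(), n_probes = integer(),
                     mean_log2 = numeric(), caller = character(),
                     comparison_id = character(), stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0L)
    stop("cnv_regions missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, cols, drop = FALSE]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$n_probes <- as.integer(df$n_probes)
  if (any(df$end - df$start < 1L)) stop("region with end - start < 1")
  if (any(df$n_probes < 1L)) stop("region with n_probes < 1")
  if (any(!df$direction %in% c("loss", "gain"))) stop("direction must be loss or gain")
  bad <- (df$direction == "loss" & df$mean_log2 > 0) |
         (df$direction == "gain" & df$mean_log2 < 0)
  if (any(bad)) stop("direction inconsistent with sign of mean_log2")
  rownames(df) <- NULL
  structure(df, class = c("cnv_regions", "data.frame"))
}

#' Write called regions as BED6
#'
#' 0-based half-open BED with `name = comparison|caller|direction` and
#' `score = n_probes`.  An empty region set yields a file with only the
#' header comment.
#'
#' @param regions a [cnv_regions] set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  regions <- cnv_regions(as.data.frame(regions))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore\tstrand", con)
  if (nrow(regions) > 0L) {
    name <- sprintf("%s|%s|%s", regions$comparison_id, regions$caller,
                    regions$direction)
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.", regions$chrom, regions$start,
                       regions$end, name, regions$n_probes), con)
  }
  invisible(path)
}

#' Read a BED file written by [write_regions_bed()]
#'
#' @param path BED path.
#' @return A [cnv_regions] set (`mean_log2` is not stored in BED and is
#'   reconstructed as -1/+1 by direction).
#' @export
read_regions_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  if (length(lines) == 0L) return(cnv_regions())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 6L)) stop("malformed BED6 line in ", path)
  m <- do.call(rbind, parts)
  meta <- strsplit(m[, 4L], "|", fixed = TRUE)
  if (any(lengths(meta) != 3L)) stop("BED name column is not comparison|caller|direction")
  meta <- do.call(rbind, meta)
  cnv_regions(data.frame(
    chrom = m[, 1L], start = as.integer(m[, 2L]), end = as.integer(m[, 3L]),
    direction = meta[, 3L], n_probes = as.integer(m[, 5L]),
    mean_log2 = ifelse(meta[, 3L] == "loss", -1, 1),
    caller = meta[, 2L], comparison_id = meta[, 1L],
    stringsAsFactors = FALSE))
}

#' Read a BED file of annotation features
#'
#' Standard BED semantics: 0-based half-open, columns chrom/start/end
#' and optional name.
#'
#' @param path BED path.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`.
#' @export
read_features_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- grep("^(#|track|browser)", readLines(path), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, function(p) c(p[1:3], if (length(p) >= 4L) p[4L] else ".")))
  out <- data.frame(chrom = m[, 1L], start = as.integer(m[, 2L]),
                    end = as.integer(m[, 3L]), name = m[, 4L],
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("feature with start >= end in ", path)
  out
}

#' Format and write a population summary table
#'
#' Percentages and chi-square statistics print to 2 decimals, p-values
#' to 2 decimals and r-squared to 3 decimals, matching the precision of
#' the published survey tables; r-squared values at or above 0.9995
#' print as `"1"` (or `"1.000"` via `r2_one_style`).
#'
#' @param summaries data.frame from [population_summaries()].
#' @param path output TSV path.
#' @param r2_one_style `"1"` (default) or `"1.000"`.
#' @return `path`, invisibly.
#' @export
write_population_summary <- function(summaries, path, r2_one_style = c("1", "1.000")) {
  r2_one_style <- match.arg(r2_one_style)
  lines <- format_population_summary(summaries, r2_one_style)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Format a population summary as tab-delimited text lines
#'
#' @inheritParams write_population_summary
#' @return character vector: header line then one line per population.
#' @export
format_population_summary <- function(summaries, r2_one_style = c("1", "1.000")) {
  r2_one_style <- match.arg(r2_one_style)
  cols <- c("population", "n", "cnv_pp_pct", "cnv_pm_pct", "cnv_mm_pct",
            "cnv_plus_pct", "cnv_minus_pct", "snp_AA_pct", "snp_AG_pct",
            "snp_GG_pct", "hwe_chi2", "hwe_p", "ld_r2", "pooled_log2")
  header <- paste(cols, collapse = "\t")
  if (is.null(summaries) || nrow(summaries) == 0L) return(header)
  fmt2 <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))
  fmt_r2 <- function(x) {
    out <- ifelse(is.na(x), "NA",
                  ifelse(x >= 0.9995, r2_one_style, sprintf("%.3f", x)))
    out
  }
  body <- vapply(seq_len(nrow(summaries)), function(i) {
    s <- summaries[i, ]
    paste(c(s$population, as.character(s$n),
            fmt2(c(s$cnv_pp_pct, s$cnv_pm_pct, s$cnv_mm_pct,
                   s$cnv_plus_pct, s$cnv_minus_pct,
                   s$snp_AA_pct, s$snp_AG_pct, s$snp_GG_pct,
                   s$hwe_chi2, s$hwe_p)),
            fmt_r2(s$ld_r2), fmt2(s$pooled_log2)),
          collapse = "\t")
  }, character(1))
  c(header, body)
}
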