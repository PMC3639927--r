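# Packaged fixtures: the published worldwide survey of the deletion,
# shipped at printed precision.  "pools13" holds the 13 populations
# hybridised as pools (pooled log2 intensity versus the Yoruba
# reference pool, CNV and SNP genotype percentages, CNV allele
# percentages); "hgdp31" holds the 31-population individual-genotyping
# survey (sample sizes, HWE chi-square and p on the CNV locus, CNV
# allele and SNP genotype percentages, and the deletion-vs-tag-SNP LD
# r2).  Values are carried verbatim, including the source's internal
# inconsistencies (the ITL allele percentages do not sum to 100 and
# the JPN SNP percentages sum to 125.86); consumers that reconstruct
# counts will reject such rows rather than silently repair them.

#' Load a packaged population-survey fixture
#'
#' @param which `"pools13"` (13-population pooled-aCGH survey) or
#'   `"hgdp31"` (31-population individual-genotyping survey).
#' @return data.frame at the survey's printed precision.  `pools13`
#'   columns: `region`, `population`, `pooled_log2`, CNV genotype and
#'   allele percentages, SNP genotype percentages.  `hgdp31` columns:
#'   `region`, `population`, `n`, `hwe_chi2`, `hwe_p`, CNV allele
#'   percentages, SNP genotype percentages, `ld_r2`.
#' @examples
#' pools <- lce_survey_fixture("pools13")
#' nrow(pools)  # 13
#' @export
lce_survey_fixture <- function(which = c("pools13", "hgdp31")) {
  which <- match.arg(which)
  file <- c(pools13 = "acgh_pools_13pop.tsv", hgdp31 = "hgdp_31pop.tsv")[[which]]
  path <- system.file("extdata", file, package = "lcepop", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Sample sizes for the pooled-survey populations
#'
#' Convenience join: the 13 pooled-survey populations with their
#' individual-genotyping sample sizes from the 31-population survey
#' (both fixtures share population codes).
#'
#' @return data.frame: `pools13` columns plus `n`, `hwe_chi2`, `hwe_p`,
#'   `ld_r2`.
#' @export
lce_survey_joined <- function() {
  pools <- lce_survey_fixture("pools13")
  hgdp <- lce_survey_fixture("hgdp31")
  merge(pools, hgdp[, c("population", "n", "hwe_chi2", "hwe_p", "ld_r2")],
        by = "population", sort = FALSE)
}
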