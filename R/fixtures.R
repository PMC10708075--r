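#' Packaged Rosa fruit VOC data
#'
#' The package ships the published two-group VOC study of *Rosa roxburghii*
#' Tratt. and *Rosa sterilis* fruit as plain-text fixtures: group-level
#' relative contents (mean +/- SD over four analytical replicates per
#' group), the odor-threshold table for the twelve ROAV-qualified key
#' flavor compounds, and the printed OPLS-DA VIP and random-forest Gini
#' importances for those compounds.  Greek letters in compound names are
#' transliterated (`beta-ocimene`).
#'
#' Note that these are report-scale data: contents were rounded to two
#' decimals before publication, so group means sum to ~100 rather than
#' exactly 100 and recomputed ROAVs can differ from printed ones by a few
#' hundredths.
#'
#' @return `rosa_group_profiles()`: a named list of two `group_profile`
#'   objects (`RS`, `RR`).  `rosa_compound_metadata()`: data.frame of
#'   compound, formula, retention time, CAS and chemical class.
#'   `rosa_odor_thresholds()`: a threshold table (see
#'   [read_threshold_table()]).  `rosa_vip_gini()`: data.frame with
#'   `compound`, `vip`, `gini`.
#' @name rosa_fixtures
NULL

rosa_file <- function(name) {
  system.file("extdata", name, package = "flavoromics", mustWork = TRUE)
}

#' @rdname rosa_fixtures
#' @export
rosa_compound_metadata <- function() {
  df <- utils::read.csv(rosa_file("rosa_voc_contents.csv"),
                        stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  df$compound <- canonical_name(df$compound)
  df[c("compound", "formula", "retention_time_min", "cas", "chem_class")]
}

#' @rdname rosa_fixtures
#' @export
rosa_group_profiles <- function() {
  df <- utils::read.csv(rosa_file("rosa_voc_contents.csv"),
                        stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  df$compound <- canonical_name(df$compound)
  # printed 2-decimal means: closure only holds loosely
  lapply(stats::setNames(c("RS", "RR"), c("RS", "RR")), function(g) {
    new_group_profile(compound = df$compound,
                      mean_content = df[[paste0("mean_", g)]],
                      sd_content = df[[paste0("sd_", g)]],
                      n = 4L, group = g, closure_tol = 0.5)
  })
}

#' @rdname rosa_fixtures
#' @export
rosa_odor_thresholds <- function() {
  read_threshold_table(rosa_file("rosa_odor_thresholds.csv"))
}

#' @rdname rosa_fixtures
#' @export
rosa_vip_gini <- function() {
  df <- utils::read.csv(rosa_file("rosa_vip_gini.csv"),
                        stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  df$compound <- canonical_name(df$compound)
  df
}
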