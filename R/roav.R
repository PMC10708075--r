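#' Read an odor-threshold table
#'
#' Thresholds are perception limits in water (mg/kg).  The CSV must contain
#' columns `compound` and `threshold_mg_per_kg`; optional columns `cas`,
#' `odor_descriptors` (semicolon-separated tags) and `source`.
#'
#' @param path CSV path.
#' @return data.frame of class `threshold_table` with columns `compound`,
#'   `cas`, `threshold`, `descriptors` (list column of canonical tags) and
#'   `source`.
#' @export
read_threshold_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  threshold_table(df$compound, df$threshold_mg_per_kg,
                  descriptors = df$odor_descriptors,
                  cas = df$cas, source = df$source)
}

#' @rdname read_threshold_table
#' @param compound compound names.
#' @param threshold odor thresholds in mg/kg, strictly positive and finite.
#' @param descriptors per-compound odor descriptors: a character vector of
#'   semicolon-separated tags or a list of character vectors.  May be empty
#'   (the compound then contributes no flavor-network edges).
#' @param cas,source optional character vectors.
#' @export
threshold_table <- function(compound, threshold, descriptors = NULL,
                            cas = NULL, source = NULL) {
  compound <- canonical_name(compound)
  threshold <- as.numeric(threshold)
  bad <- !is.finite(threshold) | threshold <= 0
  if (any(bad))
    stop("non-positive or non-finite odor threshold for: ",
         paste(compound[bad], collapse = ", "))
  if (is.null(descriptors)) descriptors <- rep("", length(compound))
  if (!is.list(descriptors))
    descriptors <- strsplit(as.character(descriptors), ";", fixed = TRUE)
  descriptors <- lapply(descriptors, function(d) {
    d <- canonical_name(d)
    unique(d[nzchar(d)])
  })
  df <- data.frame(compound = compound, threshold = threshold,
                   stringsAsFactors = FALSE)
  df$cas <- if (is.null(cas)) NA_character_ else as.character(cas)
  df$source <- if (is.null(source)) NA_character_ else as.character(source)
  df$descriptors <- descriptors
  class(df) <- c("threshold_table", "data.frame")
  df
}

#' Odor activity values for one group profile
#'
#' OAV = C / T with C the group mean relative content (%) and T the odor
#' threshold in water (mg/kg).  Compounds without a threshold entry are
#' kept and flagged `no_threshold` (OAV = NA); absent compounds (C = 0)
#' have OAV 0.
#'
#' @param profile a `group_profile`.
#' @param thresholds a `threshold_table`.
#' @return data.frame with `compound`, `content`, `threshold`, `oav`,
#'   `has_threshold`.
#' @export
compute_oav <- function(profile, thresholds) {
  stopifnot(inherits(profile, "group_profile"),
            inherits(thresholds, "threshold_table"))
  i <- match(profile$compound, thresholds$compound)
  thr <- thresholds$threshold[i]
  data.frame(compound = profile$compound,
             content = profile$mean_content,
             threshold = thr,
             oav = ifelse(is.na(thr), NA_real_, profile$mean_content / thr),
             has_threshold = !is.na(thr),
             stringsAsFactors = FALSE)
}

#' Relative odor activity values (ROAV) for one group
#'
#' ROAV_i = 100 x OAV_i / OAV_max, computed within a group over the
#' compounds that have an odor threshold.  The most odor-active compound
#' gets exactly 100; compounds with ROAV >= 1 are key flavor compounds,
#' 0 < ROAV < 1 flavor modifiers.  Compounds without a threshold cannot be
#' ranked and are categorized `no_threshold`.
#'
#' @param profile a `group_profile`.
#' @param thresholds a `threshold_table`.
#' @param keep_no_threshold keep unthresholded compounds in the output
#'   (default TRUE; they never enter the ROAV ranking).
#' @return data.frame of class `roav_result` with columns `compound`,
#'   `content`, `threshold`, `oav`, `roav`, `category` and attribute
#'   `group`.
#' @export
compute_roav <- function(profile, thresholds, keep_no_threshold = TRUE) {
  oav <- compute_oav(profile, thresholds)
  ranked <- oav[oav$has_threshold, , drop = FALSE]
  if (nrow(ranked) == 0 || all(ranked$oav == 0))
    stop("no odor-active compounds in group '", attr(profile, "group"), "'")
  oav_max <- max(ranked$oav)
  oav$roav <- ifelse(oav$has_threshold, 100 * oav$oav / oav_max, NA_real_)
  oav$category <- ifelse(!oav$has_threshold, "no_threshold",
                  ifelse(oav$roav >= 1, "key",
                  ifelse(oav$roav > 0, "modifier", "negligible")))
  if (!keep_no_threshold)
    oav <- oav[oav$has_threshold, , drop = FALSE]
  oav <- oav[order(-replace(oav$roav, is.na(oav$roav), -Inf),
                   oav$compound), , drop = FALSE]
  rownames(oav) <- NULL
  structure(oav, group = attr(profile, "group"),
            class = c("roav_result", "data.frame"))
}

#' @export
print.roav_result <- function(x, ...) {
  cat("roav_result '", attr(x, "group"), "': ",
      sum(x$category == "key"), " key, ",
      sum(x$category == "modifier"), " modifier, ",
      sum(x$category == "no_threshold"), " without threshold\n", sep = "")
  NextMethod()
}

#' Key-flavor / modifier classification
#'
#' @param result a `roav_result`.
#' @return list with `key` (data.frame sorted by decreasing ROAV),
#'   `modifier`, and `counts`.
#' @export
classify_roav <- function(result) {
  stopifnot(inherits(result, "roav_result"))
  key <- result[result$category == "key", , drop = FALSE]
  key <- key[order(-key$roav, key$compound), , drop = FALSE]
  modifier <- result[result$category == "modifier", , drop = FALSE]
  list(key = key, modifier = modifier,
       counts = c(key = nrow(key), modifier = nrow(modifier)))
}

#' Format ROAVs the way flavor tables print them
#'
#' Values below 0.1 (including 0 for absent compounds) print as `"<0.1"`;
#' others at two decimals.  Display only -- all computation stays at full
#' precision.
#'
#' @param roav numeric vector of ROAVs.
#' @return character vector.
#' @export
format_roav <- function(roav) {
  ifelse(is.na(roav), "-",
         ifelse(roav < 0.1, "<0.1", sprintf("%.2f", roav)))
}

#' Export a per-group ROAV report
#'
#' CSV in the usual key-flavor table layout: compound, threshold, odor
#' descriptors, one formatted ROAV column per group.
#'
#' @param results named list of `roav_result`s.
#' @param thresholds the `threshold_table` used.
#' @param path output CSV path.
#' @return invisibly, the exported data.frame.
#' @export
write_roav_report <- function(results, thresholds, path) {
  out <- data.frame(compound = thresholds$compound,
                    threshold_mg_per_kg = thresholds$threshold,
                    odor_description = vapply(thresholds$descriptors,
                                              paste, "", collapse = "; "),
                    stringsAsFactors = FALSE)
  for (g in names(results)) {
    r <- results[[g]]
    out[[paste0("roav_", g)]] <- format_roav(r$roav[match(out$compound,
                                                          r$compound)])
  }
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(out)
}
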