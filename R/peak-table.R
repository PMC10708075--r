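CHEM_CLASSES <- c("alcohol", "ether", "aldehyde", "acid", "ester",
                  "alkane", "terpenoid", "aromatic", "other")

#' Canonicalize compound names
#'
#' Trims surrounding whitespace, collapses internal runs of whitespace and
#' case-folds to lower case.  All joins between peak tables, threshold tables
#' and importance tables go through this canonical form.
#'
#' @param x character vector of compound names.
#' @return character vector of canonical names.
#' @export
canonical_name <- function(x) {
  x <- gsub("[[:space:]]+", " ", trimws(as.character(x)))
  tolower(x)
}

#' Construct a replicate-level peak table
#'
#' A `peak_table` holds raw GC-MS peak areas for every replicate sample
#' (rows) and compound (columns), together with group labels and optional
#' compound metadata.  Compounds absent from a sample carry area 0.
#'
#' @param areas numeric matrix, samples x compounds, finite and >= 0.
#'   Column names are compound names (canonicalized on construction).
#' @param groups character/factor vector of group labels, one per row.
#' @param sample_ids optional sample identifiers (default `S1..Sn`).
#' @param compounds optional data.frame of compound metadata with at least a
#'   `compound` column; recognised columns: `cas`, `formula`,
#'   `retention_time_min`, `chem_class`.  `chem_class` must be one of
#'   `r paste(CHEM_CLASSES, collapse = ", ")`.
#' @return an object of class `peak_table`.
#' @export
peak_table <- function(areas, groups, sample_ids = NULL, compounds = NULL) {
  areas <- as.matrix(areas)
  storage.mode(areas) <- "double"
  if (is.null(colnames(areas)))
    stop("`areas` must have compound names as column names")
  colnames(areas) <- canonical_name(colnames(areas))
  if (anyDuplicated(colnames(areas)))
    stop("duplicate compound names after canonicalization: ",
         paste(unique(colnames(areas)[duplicated(colnames(areas))]),
               collapse = ", "))
  if (any(!is.finite(areas)) || any(areas < 0))
    stop("peak areas must be finite and >= 0")
  if (length(groups) != nrow(areas))
    stop("`groups` must have one label per sample row")
  zero_rows <- rowSums(areas) <= 0
  if (any(zero_rows)) {
    ids <- if (is.null(sample_ids)) which(zero_rows) else sample_ids[zero_rows]
    stop("sample(s) with zero total peak area: ", paste(ids, collapse = ", "))
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(areas)))
  rownames(areas) <- sample_ids

  meta <- data.frame(compound = colnames(areas), stringsAsFactors = FALSE)
  if (!is.null(compounds)) {
    compounds$compound <- canonical_name(compounds$compound)
    if ("chem_class" %in% names(compounds)) {
      bad <- setdiff(unique(compounds$chem_class), CHEM_CLASSES)
      if (length(bad))
        stop("unknown chem_class value(s): ", paste(bad, collapse = ", "))
    }
    meta <- merge(meta, compounds, by = "compound", all.x = TRUE, sort = FALSE)
    meta <- meta[match(colnames(areas), meta$compound), , drop = FALSE]
    rownames(meta) <- NULL
  }

  structure(list(areas = areas,
                 samples = data.frame(sample_id = sample_ids,
                                      group = as.character(groups),
                                      stringsAsFactors = FALSE),
                 compounds = meta),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  tab <- table(x$samples$group)
  cat("peak_table: ", nrow(x$areas), " samples x ", ncol(x$areas),
      " compounds\n", sep = "")
  cat("groups: ", paste(names(tab), " (n=", tab, ")",
                        sep = "", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a peak table from CSV/TSV
#'
#' Accepts either a wide layout (one row per sample; columns `sample_id`,
#' `group`, then one column per compound) or a long layout (columns
#' `sample_id`, `group`, `compound`, `area`, optionally `cas`).  The layout
#' is auto-detected from the header; the delimiter from the file extension
#' (`.tsv` -> tab) or the header line.
#'
#' @param path file path.
#' @param compounds optional compound metadata data.frame or path to a
#'   metadata CSV (columns `compound`, `cas`, `formula`,
#'   `retention_time_min`, `chem_class`).
#' @return a [peak_table()].
#' @export
read_peak_table <- function(path, compounds = NULL) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8", comment.char = "")
  names(df)[1:2] <- tolower(names(df)[1:2])
  if (!all(c("sample_id", "group") %in% tolower(names(df))))
    stop("peak table must contain 'sample_id' and 'group' columns")
  names(df) <- ifelse(tolower(names(df)) %in%
                        c("sample_id", "group", "compound", "area", "cas"),
                      tolower(names(df)), names(df))
  if (is.character(compounds)) compounds <- read_compound_metadata(compounds)

  if (all(c("compound", "area") %in% names(df))) {      # long layout
    df$compound <- canonical_name(df$compound)
    wide <- stats::reshape(df[c("sample_id", "group", "compound", "area")],
                           idvar = c("sample_id", "group"),
                           timevar = "compound", direction = "wide")
    colnames(wide) <- sub("^area\\.", "", colnames(wide))
    areas <- as.matrix(wide[, -(1:2), drop = FALSE])
    areas[is.na(areas)] <- 0
    if (is.null(compounds) && "cas" %in% names(df)) {
      compounds <- unique(df[c("compound", "cas")])
    }
    peak_table(areas, wide$group, wide$sample_id, compounds)
  } else {                                              # wide layout
    value_cols <- setdiff(names(df), c("sample_id", "group"))
    areas <- as.matrix(df[, value_cols, drop = FALSE])
    peak_table(areas, df$group, df$sample_id, compounds)
  }
}

#' @rdname read_peak_table
#' @export
read_compound_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", check.names = TRUE)
  df$compound <- canonical_name(df$compound)
  df
}

detect_sep <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) return("\t")
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  if (grepl("\t", header)) "\t" else ","
}

#' Per-sample relative contents by area normalization
#'
#' The relative content of a compound in a sample is its peak area as a
#' percentage of the sample's total peak area, so each sample row sums to
#' 100.
#'
#' @param table a [peak_table()].
#' @return numeric matrix (samples x compounds) of contents in percent.
#' @export
relative_content <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  totals <- rowSums(table$areas)
  if (any(totals <= 0))
    stop("sample(s) with zero total peak area: ",
         paste(rownames(table$areas)[totals <= 0], collapse = ", "))
  100 * sweep(table$areas, 1, totals, "/")
}

#' Aggregate per-sample contents into a group profile
#'
#' Computes per-compound mean and sample SD (n - 1 denominator) of relative
#' contents within one group of replicates.  With a single replicate the SD
#' is reported as 0 with a warning.  Group mean contents sum to 100 by
#' construction.
#'
#' @param content numeric content matrix from [relative_content()], or a
#'   [peak_table()] (contents are then computed internally).
#' @param groups group label per row; taken from the peak table when
#'   `content` is one.
#' @return a named list of `group_profile` objects, one per group.  Each is
#'   a data.frame with columns `compound`, `mean_content`, `sd_content`,
#'   `n`, `detected`, plus attributes `group` and `n_replicates`.
#' @export
group_profile <- function(content, groups = NULL) {
  if (inherits(content, "peak_table")) {
    groups <- content$samples$group
    content <- relative_content(content)
  }
  stopifnot(is.matrix(content), length(groups) == nrow(content))
  lapply(split_named(seq_len(nrow(content)), groups), function(idx) {
    sub <- content[idx, , drop = FALSE]
    n <- nrow(sub)
    if (n == 1L) {
      warning("single replicate in group; SD reported as 0")
      sds <- rep(0, ncol(sub))
    } else {
      sds <- apply(sub, 2, stats::sd)
    }
    new_group_profile(
      compound = colnames(content),
      mean_content = colMeans(sub),
      sd_content = sds,
      n = n,
      group = attr(idx, "group_label"))
  })
}

split_named <- function(x, f) {
  out <- split(x, f)
  for (g in names(out)) attr(out[[g]], "group_label") <- g
  out
}

new_group_profile <- function(compound, mean_content, sd_content, n, group,
                              closure_tol = 0.01) {
  stopifnot(all(sd_content >= 0), all(n >= 1))
  total <- sum(mean_content)
  if (is.finite(closure_tol) && abs(total - 100) > closure_tol)
    stop(sprintf("group '%s': mean contents sum to %.4f, not 100", group,
                 total))
  df <- data.frame(compound = canonical_name(compound),
                   mean_content = unname(mean_content),
                   sd_content = unname(sd_content),
                   n = n,
                   detected = unname(mean_content > 0),
                   stringsAsFactors = FALSE)
  structure(df, group = group, class = c("group_profile", "data.frame"))
}

#' @export
print.group_profile <- function(x, ...) {
  cat("group_profile '", attr(x, "group"), "': ", sum(x$detected), "/",
      nrow(x), " compounds detected (n=", x$n[1], " replicates)\n", sep = "")
  NextMethod()
}

#' Compound accounting between two group profiles
#'
#' Counts compounds detected (group mean content > 0) in each group, in
#' both, and in either; satisfies inclusion-exclusion.
#'
#' @param profile1,profile2 `group_profile` objects over a shared compound
#'   universe.
#' @return named numeric vector `n1`, `n2`, `n_common`, `n_union`.
#' @export
venn_counts <- function(profile1, profile2) {
  stopifnot(inherits(profile1, "group_profile"),
            inherits(profile2, "group_profile"))
  d1 <- profile1$compound[profile1$detected]
  d2 <- profile2$compound[profile2$detected]
  c(n1 = length(d1), n2 = length(d2),
    n_common = length(intersect(d1, d2)),
    n_union = length(union(d1, d2)))
}

#' Chemical-class composition of a group profile
#'
#' Sums group mean contents over the nine structural classes.  The class
#' sums conserve the profile total (~100% for a complete profile).
#'
#' @param profile a `group_profile`.
#' @param classes data.frame mapping `compound` to `chem_class`.
#' @return data.frame with `chem_class` and `total_content`, sorted
#'   decreasing.
#' @export
class_composition <- function(profile, classes) {
  stopifnot(inherits(profile, "group_profile"))
  classes$compound <- canonical_name(classes$compound)
  cls <- classes$chem_class[match(profile$compound, classes$compound)]
  if (anyNA(cls))
    stop("compounds without a chem_class: ",
         paste(profile$compound[is.na(cls)], collapse = ", "))
  agg <- tapply(profile$mean_content, cls, sum)
  out <- data.frame(chem_class = names(agg),
                    total_content = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out[order(-out$total_content), , drop = FALSE]
}

#' Presence-pattern classification of compounds across two groups
#'
#' A rule-based analogue of a two-group abundance heat map: label I means
#' high in group 1 only, II low in both, III high in group 2 only, IV high
#' in both.  "High" means group mean content above `high_threshold`.  This
#' is a descriptive convenience classifier, not part of the ROAV or
#' screening statistics.
#'
#' @param profile1,profile2 `group_profile` objects over the same compounds.
#' @param high_threshold percent content above which a compound counts as
#'   high (default 3).
#' @return data.frame with `compound`, per-group means and `pattern` in
#'   `c("I","II","III","IV")`.
#' @export
presence_pattern <- function(profile1, profile2, high_threshold = 3) {
  stopifnot(high_threshold > 0)
  m <- merge(profile1[c("compound", "mean_content")],
             profile2[c("compound", "mean_content")],
             by = "compound", suffixes = c("_1", "_2"))
  hi1 <- m$mean_content_1 > high_threshold
  hi2 <- m$mean_content_2 > high_threshold
  m$pattern <- ifelse(hi1 & hi2, "IV",
               ifelse(hi1, "I", ifelse(hi2, "III", "II")))
  m
}

#' Export a group-profile report
#'
#' Writes a CSV mirroring the printed layout of a VOC relative-content
#' table: compound metadata plus `mean +/- sd` per group, rounded to two
#' decimals for display.
#'
#' @param profiles named list of `group_profile`s (as from [group_profile()]).
#' @param path output CSV path.
#' @param compounds optional compound metadata to prepend.
#' @return invisibly, the exported data.frame.
#' @export
write_group_profile <- function(profiles, path, compounds = NULL) {
  base <- data.frame(compound = profiles[[1]]$compound,
                     stringsAsFactors = FALSE)
  if (!is.null(compounds)) {
    compounds$compound <- canonical_name(compounds$compound)
    base <- merge(base, compounds, by = "compound", all.x = TRUE, sort = FALSE)
  }
  for (g in names(profiles)) {
    p <- profiles[[g]]
    i <- match(base$compound, p$compound)
    base[[g]] <- ifelse(p$detected[i],
                        sprintf("%.2f +/- %.2f", p$mean_content[i],
                                p$sd_content[i]), "-")
  }
  utils::write.csv(base, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(base)
}
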