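#' Min-max normalization to the unit interval
#'
#' Affine map sending the column minimum to 0 and maximum to 1
#' (order-preserving, idempotent).  All values tied at the extremes map to
#' 0 or 1.  A column with no spread has no defined map and errors.
#'
#' @param values numeric vector with at least two distinct finite values.
#' @return numeric vector in `[0, 1]`.
#' @export
minmax_normalize <- function(values) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  rng <- range(values)
  if (diff(rng) <= 0)
    stop("degenerate range: all values equal; min-max normalization undefined")
  (values - rng[1]) / diff(rng)
}

#' Fuse VIP and Gini importance into a single score
#'
#' Min-max normalizes the OPLS-DA VIP column and the raw random-forest
#' Gini column over the same candidate compounds and averages them into
#' the fused score X_A in `[0, 1]`.  A compound is flagged as a signature
#' differential compound when its (unnormalized) VIP is >= `vip_cut` and
#' its fused score exceeds `xa_cut`; screening always uses full precision
#' (rounding is display-only).
#'
#' @param vip data.frame with `compound` and `vip` (e.g. a `vip_table`).
#' @param gini data.frame with `compound` and a Gini column (`gini` or
#'   `gini_raw`).
#' @param vip_cut VIP criterion, inclusive (default 1).
#' @param xa_cut fused-score criterion, exclusive (default 0.5).
#' @return data.frame of class `fusion_table` with `compound`, `vip`,
#'   `gini`, `x_vnom`, `x_gnom`, `x_a`, `is_signature`, sorted by
#'   decreasing `x_a`.
#' @export
fuse_importance <- function(vip, gini, vip_cut = 1, xa_cut = 0.5) {
  vip <- as.data.frame(vip)
  gini <- as.data.frame(gini)
  if (!"gini" %in% names(gini) && "gini_raw" %in% names(gini))
    gini$gini <- gini$gini_raw
  vip$compound <- canonical_name(vip$compound)
  gini$compound <- canonical_name(gini$compound)
  only_v <- setdiff(vip$compound, gini$compound)
  only_g <- setdiff(gini$compound, vip$compound)
  if (length(only_v) || length(only_g))
    stop("VIP and Gini tables cover different compounds; VIP only: {",
         paste(only_v, collapse = ", "), "}; Gini only: {",
         paste(only_g, collapse = ", "), "}")
  m <- merge(vip[c("compound", "vip")], gini[c("compound", "gini")],
             by = "compound")
  m$x_vnom <- minmax_normalize(m$vip)
  m$x_gnom <- minmax_normalize(m$gini)
  m$x_a <- (m$x_vnom + m$x_gnom) / 2
  m$is_signature <- m$vip >= vip_cut & m$x_a > xa_cut
  m <- m[order(-m$x_a, m$compound), , drop = FALSE]
  rownames(m) <- NULL
  structure(m, vip_cut = vip_cut, xa_cut = xa_cut,
            class = c("fusion_table", "data.frame"))
}

#' @export
print.fusion_table <- function(x, ...) {
  cat("fusion_table: ", nrow(x), " compounds, ",
      sum(x$is_signature), " signature (VIP >= ", attr(x, "vip_cut"),
      " & X_A > ", attr(x, "xa_cut"), ")\n", sep = "")
  NextMethod()
}

#' Screen signature differential flavor compounds
#'
#' Applies the joint criterion VIP >= `vip_cut` (inclusive) and fused
#' score X_A > `xa_cut` (strict) and returns the qualifying compounds
#' sorted by decreasing X_A.
#'
#' @param fusion a `fusion_table` (or data.frame with `compound`, `vip`,
#'   `x_a`).
#' @param vip_cut,xa_cut screening criteria (defaults 1 and 0.5).
#' @return data.frame of signature compounds (possibly empty).
#' @export
screen_signature <- function(fusion, vip_cut = 1, xa_cut = 0.5) {
  fusion <- as.data.frame(fusion)
  if (nrow(fusion) == 0) return(fusion)
  hits <- fusion[fusion$vip >= vip_cut & fusion$x_a > xa_cut, , drop = FALSE]
  hits <- hits[order(-hits$x_a, hits$compound), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Export the fusion report
#'
#' CSV mirroring the usual signature-screen table (compound, VIP, Gini,
#' X_A at two decimals, signature flag) plus an optional JSON summary of
#' the signature list.
#'
#' @param fusion a `fusion_table`.
#' @param csv_path output CSV (NULL to skip).
#' @param json_path output JSON summary (NULL to skip).
#' @return invisibly, the report data.frame.
#' @export
write_fusion_report <- function(fusion, csv_path = NULL, json_path = NULL) {
  rep <- data.frame(compound = fusion$compound,
                    vip = fusion$vip, gini = fusion$gini,
                    x_a = round(fusion$x_a, 2),
                    is_signature = fusion$is_signature,
                    stringsAsFactors = FALSE)
  if (!is.null(csv_path))
    utils::write.csv(rep, csv_path, row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(json_path))
    jsonlite::write_json(
      list(signature_compounds = fusion$compound[fusion$is_signature],
           criteria = list(vip_cut = attr(fusion, "vip_cut"),
                           xa_cut = attr(fusion, "xa_cut"))),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(rep)
}
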