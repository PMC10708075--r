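#' Run the full flavoromics pipeline
#'
#' Orchestrates profile -> ROAV -> flavor network -> OPLS-DA -> random
#' forest -> fusion screen for a two-group experiment and returns a
#' self-describing report.  Two input routes are supported:
#'
#' * replicate route: `peak_table` is a replicate-level [peak_table()] (or
#'   CSV path); the discriminant models run on the per-replicate relative
#'   contents of the ROAV-qualified key compounds (the union of the
#'   per-group key sets).
#' * report route: `profiles` is a named list of two `group_profile`s and
#'   `importance` a data.frame with printed `vip` and `gini` columns; the
#'   fusion screen then runs directly on those importances.  This is the
#'   route for published tables whose replicate-level data are not
#'   available.
#'
#' On the replicate route the signature screen is gated on model validity,
#' mirroring the usual chemometric workflow of validating an OPLS-DA model
#' before interpreting its VIPs: the cross-validated Q2 must exceed
#' `q2_min` and, when the permutation test is enabled, its empirical
#' p-value must fall below `perm_alpha`.  For an invalid model no compound
#' is reported as signature (the fusion table is still returned).
#'
#' @param peak_table a [peak_table()] or CSV path (replicate route).
#' @param thresholds a `threshold_table` or CSV path.
#' @param profiles named list of two `group_profile`s (report route).
#' @param importance data.frame with `compound`, `vip`, `gini` (report
#'   route).
#' @param compounds optional compound metadata (data.frame or CSV path).
#' @param config list of stage settings; recognised keys (with defaults):
#'   `scaling` ("uv"), `n_ortho` (1), `n_folds` (7), `n_permutations` (50;
#'   0 skips the permutation test), `perm_alpha` (0.05), `n_trees` (500),
#'   `vip_cut` (1), `xa_cut` (0.5), `q2_min` (0.5), `high_threshold` (3).
#' @param outdir optional directory; when given, every stage writes its
#'   CSV/JSON/GraphML outputs there.
#' @param seed seed for the stochastic stages (random forest, permutation
#'   test).
#' @return object of class `pipeline_report`: list with `provenance`,
#'   `profiles`, `venn`, `class_composition`, `roav`, `key`, `networks`,
#'   `pca`, `opls` (model summary, q2, optional permutation), `rf`,
#'   `fusion`, `signature`, `warnings`.
#' @export
run_pipeline <- function(peak_table = NULL, thresholds = NULL,
                         profiles = NULL, importance = NULL,
                         compounds = NULL, config = list(),
                         outdir = NULL, seed = 1) {
  cfg <- utils::modifyList(list(scaling = "uv", n_ortho = 1, n_folds = 7,
                                n_permutations = 50, perm_alpha = 0.05,
                                n_trees = 500,
                                vip_cut = 1, xa_cut = 0.5, q2_min = 0.5,
                                high_threshold = 3), config)
  warns <- character()
  note <- function(stage, w) sprintf("[%s] %s", stage, w)
  catch <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             call. = FALSE)),
      warning = function(w) {
        warns <<- c(warns, note(stage, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  out_path <- function(f) if (is.null(outdir)) NULL else file.path(outdir, f)
  emit <- function(expr) if (!is.null(outdir)) expr

  if (is.character(compounds)) compounds <- read_compound_metadata(compounds)

  ## ---- profile stage -------------------------------------------------
  content <- NULL
  if (!is.null(peak_table)) {
    pt <- catch("profile", {
      if (is.character(peak_table)) read_peak_table(peak_table, compounds)
      else peak_table
    })
    if (is.null(compounds) && "chem_class" %in% names(pt$compounds))
      compounds <- pt$compounds
    content <- catch("profile", relative_content(pt))
    profiles <- catch("profile", group_profile(content, pt$samples$group))
  }
  if (is.null(profiles) || length(profiles) != 2)
    stop("stage 'profile' failed: need a replicate peak table or exactly ",
         "two group profiles")
  venn <- venn_counts(profiles[[1]], profiles[[2]])
  comp_cls <- if (!is.null(compounds) && "chem_class" %in% names(compounds))
    lapply(profiles, class_composition, classes = compounds)
  patterns <- presence_pattern(profiles[[1]], profiles[[2]],
                               high_threshold = cfg$high_threshold)
  emit(write_group_profile(profiles, out_path("group_profile.csv"),
                           compounds))

  ## ---- roav stage ----------------------------------------------------
  thr <- catch("roav", {
    if (is.null(thresholds)) stop("no threshold table supplied")
    if (is.character(thresholds)) read_threshold_table(thresholds)
    else thresholds
  })
  roav <- catch("roav", lapply(profiles, compute_roav, thresholds = thr))
  key <- lapply(roav, classify_roav)
  key_union <- sort(unique(unlist(lapply(key, function(k) k$key$compound))))
  emit(write_roav_report(roav, thr, out_path("roav_report.csv")))

  ## ---- network stage -------------------------------------------------
  networks <- catch("network", lapply(roav, build_flavor_network,
                                      thresholds = thr))
  emit(for (g in names(networks))
    write_flavor_network(networks[[g]],
                         out_path(sprintf("network_%s_edges.csv", g)),
                         out_path(sprintf("network_%s.graphml", g))))

  ## ---- discriminant stages (replicate route only) --------------------
  pca <- opls <- rf <- NULL
  model_valid <- NA
  if (!is.null(content)) {
    Xk <- content[, key_union, drop = FALSE]
    grp <- pt$samples$group
    pca <- catch("pca", fit_pca(content, n_components = 2))
    opls_fit <- catch("oplsda", fit_oplsda(Xk, grp, n_ortho = cfg$n_ortho,
                                           scaling = cfg$scaling))
    q2 <- catch("oplsda", cross_validate(Xk, grp, n_ortho = cfg$n_ortho,
                                         n_folds = cfg$n_folds,
                                         scaling = cfg$scaling))
    vip <- compute_vip(opls_fit)
    perm <- NULL
    if (cfg$n_permutations > 0)
      perm <- catch("oplsda",
                    permutation_test(Xk, grp,
                                     n_permutations = cfg$n_permutations,
                                     seed = seed, n_ortho = cfg$n_ortho,
                                     n_folds = cfg$n_folds,
                                     scaling = cfg$scaling))
    opls <- list(r2x = opls_fit$r2x, r2y = opls_fit$r2y, q2 = q2,
                 n_ortho = opls_fit$n_ortho, vip = vip,
                 permutation = perm)
    model_valid <- q2 > cfg$q2_min &&
      (is.null(perm) || perm$p_value < cfg$perm_alpha)
    if (!model_valid)
      warns <- c(warns, note("oplsda", sprintf(
        "model not validated (Q2 = %.3f, cut %.2f%s): signature screen suppressed",
        q2, cfg$q2_min,
        if (!is.null(perm)) sprintf("; permutation p = %.3f", perm$p_value)
        else "")))
    rf <- catch("rf", rf_importance(Xk, grp, n_trees = cfg$n_trees,
                                    seed = seed))
    importance <- merge(vip[c("compound", "vip")],
                        data.frame(compound = rf$compound,
                                   gini = rf$gini_raw),
                        by = "compound")
  }

  ## ---- fusion stage --------------------------------------------------
  if (is.null(importance))
    stop("stage 'screen' failed: no importance table available ",
         "(supply replicate data or printed VIP/Gini columns)")
  importance$compound <- canonical_name(importance$compound)
  cand <- importance[importance$compound %in% key_union, , drop = FALSE]
  fusion <- catch("screen",
                  fuse_importance(cand[c("compound", "vip")],
                                  cand[c("compound", "gini")],
                                  vip_cut = cfg$vip_cut,
                                  xa_cut = cfg$xa_cut))
  signature <- if (isFALSE(model_valid)) fusion[0, , drop = FALSE]
               else screen_signature(fusion, cfg$vip_cut, cfg$xa_cut)
  emit(write_fusion_report(fusion, out_path("fusion_report.csv"),
                           out_path("signature.json")))

  report <- structure(list(
    provenance = list(
      seed = seed, config = cfg, timestamp = format(Sys.time(), tz = "UTC"),
      config_hash = config_hash(cfg),
      inputs = list(peak_table = if (is.character(peak_table)) peak_table,
                    thresholds = if (is.character(thresholds)) thresholds)),
    profiles = profiles, venn = venn, class_composition = comp_cls,
    presence_patterns = patterns,
    roav = roav, key = key, key_union = key_union, networks = networks,
    pca = pca, opls = opls, rf = rf,
    fusion = fusion, signature = signature,
    model_valid = model_valid, warnings = warns), class = "pipeline_report")
  emit(jsonlite::write_json(report_summary(report),
                            out_path("report.json"),
                            auto_unbox = TRUE, digits = NA))
  report
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE),
             f)
  unname(tools::md5sum(f))
}

report_summary <- function(report) {
  list(schema = "flavoromics-report/1",
       provenance = report$provenance,
       venn = as.list(report$venn),
       key_counts = lapply(report$key, function(k) unname(k$counts["key"])),
       key_union = report$key_union,
       opls = if (!is.null(report$opls))
         list(r2x = report$opls$r2x, r2y = report$opls$r2y,
              q2 = report$opls$q2, n_ortho = report$opls$n_ortho),
       model_valid = report$model_valid,
       signature_compounds = report$signature$compound,
       warnings = report$warnings)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("flavoromics pipeline report\n")
  cat(sprintf("  compounds: %d total, %d / %d detected, %d common\n",
              x$venn["n_union"], x$venn["n1"], x$venn["n2"],
              x$venn["n_common"]))
  for (g in names(x$key))
    cat(sprintf("  %s: %d key flavor compounds\n", g,
                x$key[[g]]$counts["key"]))
  if (!is.null(x$opls))
    cat(sprintf("  OPLS-DA: R2X = %.3f, R2Y = %.3f, Q2 = %.3f\n",
                x$opls$r2x, x$opls$r2y, x$opls$q2))
  cat(sprintf("  signature compounds (%d): %s\n", nrow(x$signature),
              paste(x$signature$compound, collapse = ", ")))
  if (length(x$warnings))
    cat("  warnings:\n", paste0("   - ", x$warnings, "\n"), sep = "")
  invisible(x)
}
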