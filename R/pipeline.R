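#' Run the full FLIM-FRET analysis pipeline
#'
#' End-to-end analysis of a dataset directory (as produced by
#' [simulate_experiment()] or hand-assembled in the same plain-text
#' layout): every histogram is fit by drift-corrected reconvolution, cells
#' are summarized per group with 95% CIs, groups are compared against the
#' control (Welch t-tests, plus ANOVA with Dunnett-style comparisons when
#' three or more groups are present), and FRET efficiencies are computed
#' against the designated donor-only group. Unfittable cells are excluded
#' with a machine-readable reason code, never silently dropped. All outputs
#' (TSV tables plus a JSON manifest capturing the config, seed and package
#' version) go to `output_dir`; identical config and seed reproduce them
#' byte for byte.
#'
#' @param config A named list, or path to a JSON file, with fields:
#'   `dataset_dir` (directory holding `irf.txt` and per-cell histogram
#'   `.txt` files), `control_group` (label; defaults to the first group
#'   found), `donor_only_group` (label of the unquenched reference;
#'   defaults to `control_group`), `fit` (optional named list of
#'   [fit_config()] arguments), `seed` (integer, default 1), `output_dir`
#'   (default `file.path(dataset_dir, "results")`).
#' @return Invisibly, a `flim_report` list: `cells` (per-cell fit table),
#'   `groups` (list of [group_ci95()] results), `comparisons`,
#'   `fret`, `excluded`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$dataset_dir))
    stop("run_pipeline: config must name 'dataset_dir'", call. = FALSE)
  dir <- config$dataset_dir
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- if (is.null(config$output_dir)) file.path(dir, "results") else config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  fit_args <- if (is.null(config$fit)) list() else config$fit
  fit_args$seed <- seed
  fc <- do.call(fit_config, fit_args)

  irf_path <- file.path(dir, "irf.txt")
  if (!file.exists(irf_path))
    stop(sprintf("run_pipeline: no IRF at %s", irf_path), call. = FALSE)
  irf <- read_irf(irf_path)

  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  files <- files[basename(files) != "irf.txt"]
  if (length(files) == 0)
    stop(sprintf("run_pipeline: no histogram files in %s", dir), call. = FALSE)

  rows <- list()
  excluded <- list()
  for (f in files) {
    res <- tryCatch({
      h <- read_histogram(f)
      if (!same_binning(h$binning, irf$binning))
        stop("binning_mismatch")
      dc <- suppressWarnings(correct_irf_drift(h, irf, fc))
      fit <- dc$fit
      if (!fit$converged) stop("fit_not_converged")
      if (isTRUE(fit$degenerate)) stop("degenerate_amplitude")
      data.frame(
        file = basename(f),
        cell_id = if (!is.null(h$meta$cell_id)) h$meta$cell_id else basename(f),
        group = if (!is.null(h$meta$group)) h$meta$group else "ungrouped",
        n_photons = fit$n_photons,
        tau_amp_ns = fit$mean_lifetime_amp_ns,
        tau_int_ns = fit$mean_lifetime_int_ns,
        tau1_ns = fit$params$tau1_ns, tau2_ns = fit$params$tau2_ns,
        fraction = fit$params$fraction,
        irf_shift_ps = fit$irf_shift_ps,
        objective = fit$objective_value,
        stringsAsFactors = FALSE)
    }, error = function(e) {
      structure(list(file = basename(f), reason = conditionMessage(e)),
                class = "pipeline_exclusion")
    })
    if (inherits(res, "pipeline_exclusion")) {
      reason <- res$reason
      code <- if (reason %in% c("binning_mismatch", "fit_not_converged",
                                "degenerate_amplitude")) reason else "unreadable_file"
      message(sprintf("run_pipeline: excluding %s [%s]", res$file, code))
      excluded[[length(excluded) + 1L]] <-
        data.frame(file = res$file, reason_code = code, detail = reason,
                   stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0)
    stop("run_pipeline: every histogram was excluded", call. = FALSE)
  cells <- do.call(rbind, rows)
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(file = character(0), reason_code = character(0),
               detail = character(0))

  labels <- unique(cells$group)
  control <- if (is.null(config$control_group)) labels[1] else config$control_group
  donor0 <- if (is.null(config$donor_only_group)) control else config$donor_only_group
  if (!control %in% labels)
    stop(sprintf("run_pipeline: control group '%s' not present", control), call. = FALSE)
  if (!donor0 %in% labels)
    stop(sprintf("run_pipeline: donor-only group '%s' not present", donor0), call. = FALSE)

  by_group <- split(cells$tau_amp_ns, factor(cells$group, levels = labels))
  groups <- lapply(labels, function(l) group_ci95(by_group[[l]], label = l))
  names(groups) <- labels

  comparisons <- list()
  for (l in setdiff(labels, control)) {
    if (length(by_group[[l]]) >= 2 && length(by_group[[control]]) >= 2)
      comparisons[[paste0("welch:", l, "_vs_", control)]] <-
        welch_t_test(by_group[[l]], by_group[[control]])
  }
  if (length(labels) >= 3 && all(lengths(by_group) >= 2)) {
    comparisons[["anova_dunnett"]] <- oneway_anova_dunnett(
      by_group, control_index = match(control, labels), seed = seed)
  }

  fret <- list()
  for (l in setdiff(labels, donor0)) {
    fret[[paste0(l, "_vs_", donor0)]] <-
      estimate_group_fret(by_group[[donor0]], by_group[[l]])
  }

  # -- write outputs ---------------------------------------------------------
  utils::write.table(cells, file.path(out_dir, "cells.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  gtab <- data.frame(
    group = labels,
    n = vapply(groups, function(g) g$n, 0L),
    mean_tau_ns = vapply(groups, function(g) g$mean, 0),
    ci95_half_width_ns = vapply(groups, function(g) g$ci95_half_width, 0))
  utils::write.table(gtab, file.path(out_dir, "groups.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  ftab <- data.frame(
    comparison = names(fret),
    tau0_ns = vapply(fret, function(x) x$tau0_ns, 0),
    tau_ns = vapply(fret, function(x) x$tau_ns, 0),
    efficiency = vapply(fret, function(x) x$efficiency, 0),
    note = vapply(fret, function(x) if (is.null(x$note)) "" else x$note, ""))
  utils::write.table(ftab, file.path(out_dir, "fret.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(excluded, file.path(out_dir, "excluded.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(
    dataset_dir = dir, control_group = control, donor_only_group = donor0,
    fit = unclass(fc)[setdiff(names(unclass(fc)), "init")],
    seed = seed,
    n_cells_analyzed = nrow(cells),
    excluded = excluded$file,
    package = "flimreach",
    package_version = as.character(utils::packageVersion("flimreach")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(structure(
    list(cells = cells, groups = groups, comparisons = comparisons,
         fret = fret, excluded = excluded, manifest = manifest,
         output_dir = out_dir),
    class = "flim_report"))
}

#' @export
print.flim_report <- function(x, ...) {
  cat(sprintf("<flim_report> %d cells analyzed, %d excluded\n",
              nrow(x$cells), nrow(x$excluded)))
  for (g in x$groups)
    cat(sprintf("  %-16s n = %3d  tau = %.3f +/- %.3f ns (95%% CI)\n",
                g$label, g$n, g$mean, g$ci95_half_width))
  for (nm in names(x$fret)) {
    f <- x$fret[[nm]]
    cat(sprintf("  FRET %-24s E = %.1f%%%s\n", nm, 100 * f$efficiency,
                if (!is.null(f$note)) paste0(" [", f$note, "]") else ""))
  }
  for (nm in names(x$comparisons)) {
    cmp <- x$comparisons[[nm]]
    if (cmp$kind == "welch_t")
      cat(sprintf("  %-28s t = %.3f, df = %.1f, p = %.3g\n",
                  nm, cmp$statistic, cmp$df, cmp$p))
    else
      cat(sprintf("  ANOVA F = %.2f, p = %.3g; Dunnett-adjusted p: %s\n",
                  cmp$statistic, cmp$p,
                  paste(sprintf("%s = %.3g", names(cmp$p_adjusted),
                                cmp$p_adjusted), collapse = ", ")))
  }
  invisible(x)
}
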