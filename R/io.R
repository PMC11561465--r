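# Formats, configuration and the end-to-end pipeline driver.
#
# CSV dialect is fixed: UTF-8, comma separator, "." decimal, mandatory
# header, coordinates in micrometres.

cell_required_cols <- c("specimen_id", "cell_id", "x_um", "y_um", "z_um",
                        "ki67", "dcx", "sox9", "brdu", "reporter", "kc_id")

#' Read and write the canonical cell table
#'
#' The canonical cell-table CSV has columns `specimen_id`, `cell_id`,
#' `x_um`, `y_um`, `z_um`, `ki67`, `dcx`, `sox9`, `brdu`, `reporter`,
#' `kc_id`. Marker columns must be boolean (logical or 0/1); coordinates
#' numeric and finite. Unknown columns are preserved.
#'
#' @param path File path.
#' @return `read_cell_table()`: validated data frame of cell records.
#' @examples
#' sp <- gen_specimen(specimen_config(n_kc = 5, seed = 1))
#' tf <- tempfile(fileext = ".csv")
#' write_cell_table(sp$cells, tf)
#' nrow(read_cell_table(tf))
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  cells <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(cell_required_cols, names(cells))
  if (length(miss))
    stopf("cell table is missing required column `%s`", miss[1])
  cells <- validate_cells(cells, need = cell_required_cols)
  cells$kc_id[cells$kc_id %in% c("", "NA")] <- NA_character_
  cells
}

#' @rdname read_cell_table
#' @param cells Cell table (data frame).
#' @export
write_cell_table <- function(cells, path) {
  miss <- setdiff(cell_required_cols, names(cells))
  if (length(miss)) stopf("cell table is missing column `%s`", miss[1])
  write.csv(cells, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write KC tables
#'
#' @param path File path.
#' @param kcs KC table (data frame with at least `kc_id`, `n_tap`,
#'   `n_prnb`).
#' @return `read_kc_table()`: data frame of KC records.
#' @export
read_kc_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  kcs <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("kc_id", "n_tap", "n_prnb"), names(kcs))
  if (length(miss)) stopf("KC table is missing required column `%s`", miss[1])
  kcs
}

#' @rdname read_kc_table
#' @export
write_kc_table <- function(kcs, path) {
  write.csv(kcs, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Pipeline run configuration
#'
#' Assembles a fully serializable run configuration: a run is reproducible
#' from the configuration and its seed alone. `read_run_config()` loads
#' the same structure from YAML.
#'
#' @param seed Integer seed for the whole run.
#' @param n_kc KC count of the simulated specimen.
#' @param region_upper Upper corner of the box region (um).
#' @param contact_radius Contact radius for cell placement and KC
#'   detection (um).
#' @param modality Optional labeling modality (see [label_design()]) or
#'   `NULL` for an unlabeled specimen.
#' @param analyses Character subset of `c("spatial", "turnover", "clone")`
#'   to run after detection (detection itself always runs).
#' @param n_sim CSR envelope simulations.
#' @param n_perm Moran permutations.
#' @param clone_n Snapshot clones for the clone stage.
#' @param output_dir Output directory.
#' @return Object of class `kc_run_config`.
#' @export
run_config <- function(seed = 1L, n_kc = 288,
                       region_upper = c(1200, 1200, 1200),
                       contact_radius = 12, modality = NULL,
                       analyses = c("spatial", "turnover", "clone"),
                       n_sim = 199L, n_perm = 199L, clone_n = 2000L,
                       output_dir = "kcdyn_run") {
  analyses <- match.arg(analyses, several.ok = TRUE)
  structure(list(schema_version = kcdyn_schema_version(),
                 seed = as.integer(seed), n_kc = as.integer(n_kc),
                 region_upper = as.numeric(region_upper),
                 contact_radius = contact_radius, modality = modality,
                 analyses = analyses, n_sim = as.integer(n_sim),
                 n_perm = as.integer(n_perm), clone_n = as.integer(clone_n),
                 output_dir = output_dir),
            class = "kc_run_config")
}

#' @rdname run_config
#' @param path YAML file with the fields of [run_config()].
#' @examples
#' cfg <- read_run_config(system.file("extdata", "example_config.yaml",
#'                                    package = "kcdyn"))
#' cfg$n_kc
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config not found: %s", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stopf("unknown config field `%s`", unknown[1])
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Chains synthetic generation, KC detection/classification, and the
#' spatial, turnover, and clone analyses into one reproducible run.
#' Results are written as tidy CSVs plus a JSON provenance manifest
#' (seed, configuration, package version, per-stage status, and the md5
#' of every output). A failure in one stage is recorded in the manifest
#' and does not corrupt the other stages' outputs.
#'
#' @param config A [run_config()] object (or path to a YAML config).
#' @param output_dir Overrides `config$output_dir`.
#' @return Invisibly, a list with the in-memory results of each stage and
#'   the manifest.
#' @examples
#' \donttest{
#' cfg <- run_config(seed = 1, n_kc = 30, analyses = "spatial",
#'                   n_sim = 39, output_dir = tempfile())
#' res <- run_pipeline(cfg)
#' names(res$manifest$stages)
#' }
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "kc_run_config"))
  out_dir <- output_dir %||% config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(schema_version = config$schema_version,
                   seed = config$seed,
                   package_version = as.character(packageVersion("kcdyn")),
                   config = unclass(config), stages = list(),
                   outputs = list())
  results <- list()
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(list(value = fun(), status = "ok", error = NULL),
                    error = function(e)
                      list(value = NULL, status = "failed",
                           error = conditionMessage(e)))
    manifest$stages[[name]] <<- list(
      status = res$status, error = res$error,
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
    res$value
  }
  emit <- function(obj, file) {
    path <- file.path(out_dir, file)
    write.csv(obj, path, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
    manifest$outputs[[file]] <<- unname(tools::md5sum(path))
    path
  }

  renewal <- renewal_params()
  results$specimen <- run_stage("simulate", function() {
    design <- if (!is.null(config$modality))
      label_design(config$modality) else NULL
    sp <- gen_specimen(specimen_config(
      n_kc = config$n_kc,
      region = region_box(upper = config$region_upper),
      renewal = if (!is.null(design)) renewal else NULL,
      design = design, contact_radius = config$contact_radius,
      seed = config$seed))
    emit(sp$cells, "cells.csv")
    emit(sp$kcs, "kcs_true.csv")
    sp
  })
  sp <- results$specimen
  results$detection <- run_stage("detect", function() {
    if (is.null(sp)) stopf("no specimen available")
    det <- detect_kcs(sp$cells, config$contact_radius)
    emit(det$kcs, "kcs_detected.csv")
    emit(det$small_groups, "small_groups.csv")
    det
  })
  det <- results$detection
  if ("spatial" %in% config$analyses) {
    results$spatial <- run_stage("spatial", function() {
      if (is.null(det) || nrow(det$kcs) < 3) stopf("too few detected KCs")
      pat <- point_pattern(det$kcs[, c("x", "y", "z")], sp$region)
      env <- csr_envelope(pat, n_sim = config$n_sim,
                          seed = config$seed + 1L)
      rows <- data.frame(test = "g_envelope", variable = "centroids",
                         statistic = env$t_obs, p = env$p)
      for (v in c("size", "prnb_frac", "pmnb_assoc")) {
        marks <- det$kcs[[v]]
        if (is.logical(marks)) marks <- as.numeric(marks)
        if (sd(marks) == 0) next
        mi <- morans_i(pat, marks = marks, n_perm = config$n_perm,
                       seed = config$seed + 2L)
        rows <- rbind(rows, data.frame(test = "morans_i", variable = v,
                                       statistic = mi$i, p = mi$p))
      }
      emit(rows, "spatial_summary.csv")
      rows
    })
  } else manifest$stages$spatial <- list(status = "skipped", error = NULL)
  if ("turnover" %in% config$analyses) {
    results$turnover <- run_stage("turnover", function() {
      if (is.null(det)) stopf("no detection available")
      label_col <- if (!is.null(config$modality) &&
                       config$modality == "brdu-pulse") "n_brdu"
                   else "n_reporter"
      li <- labeling_index(det$kcs, n_labeled_col = label_col)
      rows <- data.frame(
        quantity = c("li", "fully_labeled_frac", "expected_unlabeled_4d",
                     "lifetime_days", "turnover_rate_per_day"),
        value = c(li$li, li$fully_labeled_frac,
                  expected_unlabeled_fraction(4, renewal),
                  renewal$lifetime, renewal$rate))
      emit(rows, "turnover_summary.csv")
      rows
    })
  } else manifest$stages$turnover <- list(status = "skipped", error = NULL)
  if ("clone" %in% config$analyses) {
    results$clone <- run_stage("clone", function() {
      snap <- sample_kc_snapshot(clone_params(), config$clone_n,
                                 seed = config$seed + 3L)
      rows <- data.frame(
        quantity = c("n_kc_snapshots", "mean_size", "mean_prnb_frac",
                     "frac_taps_only", "frac_prnbs_only"),
        value = c(nrow(snap), mean(snap$size), mean(snap$prnb_frac),
                  mean(snap$prnb_frac == 0), mean(snap$prnb_frac == 1)))
      emit(rows, "clone_summary.csv")
      rows
    })
  } else manifest$stages$clone <- list(status = "skipped", error = NULL)

  if (!is.null(sp) && length(sp$meta$warnings))
    manifest$warnings <- sp$meta$warnings
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  results$manifest <- manifest
  invisible(results)
}
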