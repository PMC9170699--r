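# CSV readers/writers, run configuration and report assembly.
# Dialect: comma-separated, "." decimal, mandatory header row; units live
# in the column names, never implicitly.

.plate_schemas <- list(
  survival = list(required = c("batch", "material", "conc_ug_mL",
                               "dose_Gy", "dmso_M", "replicate",
                               "luminescence"),
                  numeric = c("conc_ug_mL", "dose_Gy", "dmso_M",
                              "replicate", "luminescence")),
  ros = list(required = c("material", "sa_conc_cm2_mL", "dose_Gy",
                          "replicate", "fi"),
             numeric = c("sa_conc_cm2_mL", "dose_Gy", "replicate", "fi")),
  uptake = list(required = c("material", "conc_ug_mL", "replicate",
                             "metal_ng_total", "cells_counted"),
                numeric = c("conc_ug_mL", "replicate", "metal_ng_total",
                            "cells_counted"))
)

#' Read a measurement table
#'
#' Header-keyed CSV parsing (column order is irrelevant; unknown columns
#' are preserved) with schema validation: missing columns, non-numeric
#' cells and duplicate well keys are rejected with the offending line
#' numbers. Round-trips losslessly through [write_report()] outputs.
#'
#' @param path CSV file path.
#' @param schema `"survival"`, `"ros"` or `"uptake"`.
#' @return A validated data.frame.
#' @export
read_plate <- function(path, schema = c("survival", "ros", "uptake")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop_format("file not found: ", path)
  sc <- .plate_schemas[[schema]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(sc$required, names(df))
  if (length(miss))
    stop_format("missing column(s) in ", basename(path), ": ",
                paste(miss, collapse = ", "))
  for (cn in sc$numeric) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "")
      if (length(bad))
        stop_format("non-numeric value(s) in column '", cn, "' of ",
                    basename(path), " at data line(s) ",
                    paste(utils::head(bad, 5), collapse = ", "))
      df[[cn]] <- vn
    }
  }
  key_cols <- setdiff(sc$required,
                      c("luminescence", "fi", "metal_ng_total",
                        "cells_counted"))
  key <- do.call(paste, c(df[key_cols], sep = "\r"))
  if (anyDuplicated(key))
    stop_format("duplicate well key(s) in ", basename(path),
                " at data line(s) ",
                paste(utils::head(which(duplicated(key)), 5),
                      collapse = ", "))
  df
}

#' Read a run configuration
#'
#' YAML (or JSON) configuration with an optional `materials` section
#' (`name: {formula, density_g_cm3, ssa_m2_g}`) overriding or extending
#' the built-in registry, plus free-form analysis settings returned as-is.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `materials` (registry list) and `settings`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_format("config not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop_format("jsonlite required for JSON configs")
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_format("yaml package required for YAML configs")
    yaml::read_yaml(path)
  }
  registry <- default_materials()
  if (!is.null(cfg$materials)) {
    for (nm in names(cfg$materials)) {
      m <- cfg$materials[[nm]]
      if (is.null(m$formula) || is.null(m$density_g_cm3))
        stop_format("material '", nm,
                    "' needs 'formula' and 'density_g_cm3'")
      registry[[nm]] <- material_spec(
        nm, unlist(m$formula), m$density_g_cm3,
        ssa = m$ssa_m2_g,
        metal_elements = m$metal_elements)
    }
  }
  list(materials = registry,
       settings = cfg[setdiff(names(cfg), "materials")])
}

#' Write an analysis report
#'
#' Writes each table of a results list (e.g. the output of
#' [run_survival_pipeline()], [analyze_ros_plate()] or
#' [analyze_uptake_table()]) as `<name>.csv` under `dir`, plus a
#' `summary.txt` provenance block (package version, seed, input hashes,
#' non-default analysis choices actually exercised).
#'
#' @param results Named list of data.frames (non-data.frame elements are
#'   summarized in the text file).
#' @param dir Output directory (created if needed).
#' @param seed Seed used for the run, recorded in the provenance block.
#' @param notes Extra provenance lines (e.g. decisions exercised).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, dir, seed = NA, notes = character()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x) && nrow(x) > 0) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(x, p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  sm <- file.path(dir, "summary.txt")
  lines <- c(
    paste0("radnano ", as.character(utils::packageVersion("radnano"))),
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("seed: ", seed),
    paste0("tables: ", paste(basename(paths), collapse = ", ")),
    notes)
  qc <- results$qc
  if (length(qc)) lines <- c(lines, "qc:", paste0("  ", qc))
  writeLines(lines, sm)
  invisible(c(paths, sm))
}
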