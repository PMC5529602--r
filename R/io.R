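## Readers, writers and fixtures: the species morphometrics CSV schema,
## full-precision field exports (CSV and legacy ASCII VTK), shape-constant
## sweep tables, and regime-report serialization.

.species_cols <- c("species", "proboscis_length_mm", "food_canal_diameter_um",
                   "pump_length_um", "pump_width_um", "pump_height_um")

#' Read a species morphometrics table
#'
#' Expected header: `species, proboscis_length_mm, food_canal_diameter_um,
#' pump_length_um, pump_width_um, pump_height_um[, shape][, galeae]` with
#' units as suffixed (mm for the proboscis, micrometres for the pump).
#' `shape` is optional (`"rect"` or `"circ"`; default `"rect"`, which uses
#' both measured pump dimensions), as is `galeae` (`"linked"` default, or
#' `"separated"` for species whose galeae do not meet and therefore form no
#' closed food canal). Row-level problems (non-numeric cells, non-positive
#' lengths) are collected and reported together with their row numbers.
#'
#' @param path CSV file path.
#' @return List of [species_record()]s (empty for a header-only file).
#' @export
#' @examples
#' tab <- read_species_csv(pumpflow_example("table1_lepidoptera.csv"))
#' length(tab)  # 5
read_species_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, strip.white = TRUE)
  missing_cols <- setdiff(.species_cols, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!nrow(df)) return(list())
  has_shape <- "shape" %in% names(df)
  errors <- character(0)
  records <- vector("list", nrow(df))
  numcols <- setdiff(.species_cols, "species")
  for (i in seq_len(nrow(df))) {
    row_err <- character(0)
    vals <- suppressWarnings(as.numeric(df[i, numcols]))
    names(vals) <- numcols
    bad <- numcols[is.na(vals)]
    if (length(bad))
      row_err <- c(row_err, paste0("non-numeric ", bad))
    pos_needed <- c("food_canal_diameter_um", "pump_length_um",
                    "pump_width_um", "pump_height_um")
    nonpos <- pos_needed[!is.na(vals[pos_needed]) & vals[pos_needed] <= 0]
    if (length(nonpos))
      row_err <- c(row_err, paste0("non-positive ", nonpos))
    if (!is.na(vals[["proboscis_length_mm"]]) &&
        vals[["proboscis_length_mm"]] < 0)
      row_err <- c(row_err, "negative proboscis_length_mm")
    shape <- if (has_shape && nzchar(df$shape[i])) df$shape[i] else "rect"
    if (!shape %in% c("rect", "circ"))
      row_err <- c(row_err, paste0("unknown shape '", shape, "'"))
    galeae <- if ("galeae" %in% names(df) && nzchar(df$galeae[i]))
      df$galeae[i] else "linked"
    if (!galeae %in% c("linked", "separated"))
      row_err <- c(row_err, paste0("unknown galeae state '", galeae, "'"))
    if (length(row_err)) {
      errors <- c(errors, sprintf("row %d (%s): %s", i,
                                  df$species[i],
                                  paste(row_err, collapse = "; ")))
      next
    }
    records[[i]] <- species_record(
      name = df$species[i],
      proboscis = proboscis_geometry(
        l_p = vals[["proboscis_length_mm"]] * 1e-3,
        d_p = vals[["food_canal_diameter_um"]] * 1e-6),
      L = vals[["pump_length_um"]] * 1e-6,
      W = vals[["pump_width_um"]] * 1e-6,
      h_max = vals[["pump_height_um"]] * 1e-6,
      shape = if (shape == "circ") "circular" else "rectangular",
      galeae = galeae,
      provenance = path)
  }
  if (length(errors))
    stop("invalid rows in ", path, ":\n  ",
         paste(errors, collapse = "\n  "))
  records
}

#' Path to a packaged example data file
#'
#' @param file File name under the package's `extdata` (default lists them).
#' @return Full path.
#' @export
pumpflow_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "pumpflow")))
  p <- system.file("extdata", file, package = "pumpflow")
  if (p == "") stop("no packaged file named ", file)
  p
}

#' Load the packaged lepidopteran morphometrics table
#'
#' Five species of Lepidoptera spanning proboscis lengths from 0.35 mm
#' (a prominent moth with unlinked galeae) to 50 mm (Carolina sphinx moth),
#' with sucking-pump chamber dimensions measured from micro-CT imaging.
#' Where a length range is reported for Manduca sexta (50-70 mm) the table
#' carries the lower endpoint.
#'
#' @return List of [species_record()]s.
#' @export
lepidoptera_records <- function() {
  read_species_csv(pumpflow_example("table1_lepidoptera.csv"))
}

## ---- field export -------------------------------------------------------

#' Write a nodal scalar field to CSV (full precision)
#'
#' Columns `node_index, x, y, value`, preceded by a `# unit:` comment line.
#' Values are written with 17 significant digits so a read/write cycle is
#' bit-exact.
#'
#' @param field A `"scalar_field"`.
#' @param path Output path.
#' @param unit `"dimensionless"` or `"Pa"` (defaults to the field's own
#'   unit attribute if present).
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path,
                            unit = attr(field, "unit") %||% "dimensionless") {
  stopifnot(inherits(field, "scalar_field"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit: %s", unit), con)
  writeLines("node_index,x,y,value", con)
  writeLines(sprintf("%d,%.17g,%.17g,%.17g",
                     seq_len(nrow(field$mesh$nodes)),
                     field$mesh$nodes[, 1L], field$mesh$nodes[, 2L],
                     field$values), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a nodal scalar field CSV written by [write_field_csv()]
#'
#' @param path CSV path.
#' @return Data frame `node_index, x, y, value` with attribute `unit`.
#' @export
read_field_csv <- function(path) {
  first <- readLines(path, n = 1L)
  unit <- sub("^# unit: ", "", first)
  df <- utils::read.csv(path, skip = 1L)
  attr(df, "unit") <- unit
  df
}

#' Write a mesh + field as a legacy ASCII VTK unstructured grid
#'
#' For visualization in ParaView and kin.
#'
#' @param field A `"scalar_field"`.
#' @param path Output `.vtk` path.
#' @param name Scalar array name in the file.
#' @return `path`, invisibly.
#' @export
write_field_vtk <- function(field, path, name = "pressure") {
  stopifnot(inherits(field, "scalar_field"))
  mesh <- field$mesh
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "pumpflow chamber field",
               "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.17g %.17g 0", mesh$nodes[, 1L], mesh$nodes[, 2L]),
             con)
  writeLines(sprintf("CELLS %d %d", m, 4L * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1L] - 1L,
                     mesh$tri[, 2L] - 1L, mesh$tri[, 3L] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  writeLines(c(sprintf("POINT_DATA %d", n),
               sprintf("SCALARS %s double 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.17g", field$values), con)
  invisible(path)
}

#' Write a shape-constant sweep table as CSV
#'
#' @param sweep Data frame from [cc_sweep()] / [cr_sweep()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_constants_csv <- function(sweep, path) {
  utils::write.csv(sweep, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- regime reports -----------------------------------------------------

.report_fields <- c("species", "shape", "f", "g", "theta", "aspect", "C",
                    "f_boundary", "Ec_over_Ep", "total_over_Ep", "regime",
                    "B", "K", "Wo", "l_p_used", "converged")

#' Regime reports as a data frame
#'
#' @param reports List of `"regime_report"`s (or a single one).
#' @return One row per report.
#' @export
reports_to_df <- function(reports) {
  if (inherits(reports, "regime_report")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r)
    as.data.frame(r[.report_fields], stringsAsFactors = FALSE)))
}

#' Serialize regime reports to JSON
#'
#' One object per species, all numeric fields at full precision.
#'
#' @param reports List of `"regime_report"`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reports_json <- function(reports, path) {
  if (inherits(reports, "regime_report")) reports <- list(reports)
  payload <- lapply(reports, function(r) r[.report_fields])
  names(payload) <- NULL
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Write a regime-report summary CSV
#'
#' Full numeric precision (15 significant digits); display rounding is left
#' to the caller.
#'
#' @param reports List of `"regime_report"`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reports_csv <- function(reports, path) {
  df <- reports_to_df(reports)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- fixture generation --------------------------------------------------

#' Generate the packaged and synthetic fixture files
#'
#' Writes (a) the measured lepidopteran morphometrics table, (b) a synthetic
#' morphometrics sweep spanning f-factors from 1e-2 to 1e7 on a log grid
#' with deterministic jitter from `seed` (so points fall on both sides of
#' every regime boundary), and (c) the dimensionless geometry configuration
#' grids used for the field comparisons. A manifest (file, bytes, md5) makes
#' the determinism auditable: the same seed reproduces identical bytes.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the jitter.
#' @return Data frame manifest, invisibly; also written as `manifest.csv`.
#' @export
generate_fixtures <- function(out_dir, seed = 1L) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (file.access(out_dir, mode = 2L) != 0L)
    stop("output directory not writable: ", out_dir)
  files <- character(0)

  tab <- file.path(out_dir, "table1_lepidoptera.csv")
  file.copy(pumpflow_example("table1_lepidoptera.csv"), tab,
            overwrite = TRUE)
  files <- c(files, tab)

  set.seed(seed)
  n <- 36L
  f_target <- 10^seq(-2, 7, length.out = n) * exp(stats::rnorm(n, 0, 0.05))
  ## factor f = (l_p/d_p) * (h/d_p)^3: split between a plausible proboscis
  ## slenderness and the gap ratio
  slender <- pmin(1500, pmax(8, sqrt(f_target))) *
    exp(stats::rnorm(n, 0, 0.1))
  hratio <- (f_target / slender)^(1 / 3)
  d_p_um <- exp(stats::runif(n, log(20), log(300)))
  h_um <- hratio * d_p_um
  l_p_mm <- slender * d_p_um * 1e-3
  L_um <- pmax(3 * d_p_um, h_um * exp(stats::runif(n, log(1.5), log(5))))
  W_um <- pmax(1.2 * d_p_um, L_um * exp(stats::runif(n, log(0.5), log(1.5))))
  sweep <- data.frame(
    species = sprintf("synthetic_%02d", seq_len(n)),
    proboscis_length_mm = sprintf("%.6g", l_p_mm),
    food_canal_diameter_um = sprintf("%.6g", d_p_um),
    pump_length_um = sprintf("%.6g", L_um),
    pump_width_um = sprintf("%.6g", W_um),
    pump_height_um = sprintf("%.6g", h_um),
    shape = rep(c("rect", "circ"), length.out = n))
  sw <- file.path(out_dir, "synthetic_sweep.csv")
  utils::write.csv(sweep, sw, row.names = FALSE, quote = FALSE)
  files <- c(files, sw)

  rectgrid <- expand.grid(aspect = c(1.24, 1, 0.4), g = c(0.05, 0.1, 0.3))
  rg <- file.path(out_dir, "fig_grid_rectangular.csv")
  utils::write.csv(data.frame(shape = "rectangular", rectgrid),
                   rg, row.names = FALSE, quote = FALSE)
  files <- c(files, rg)
  cg <- file.path(out_dir, "fig_grid_circular.csv")
  utils::write.csv(data.frame(shape = "circular",
                              theta = c(0.05, 0.3, 1.0)),
                   cg, row.names = FALSE, quote = FALSE)
  files <- c(files, cg)

  manifest <- data.frame(
    file = basename(files),
    bytes = file.size(files),
    md5 = unname(tools::md5sum(files)),
    seed = seed)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
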