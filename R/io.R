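# Plain-text exchange formats: VTK legacy unstructured grids, node/element
# tables, drive profiles as CSV, and YAML scenario configuration.

#' Write a mesh (with optional element fields) as legacy VTK
#'
#' ASCII VTK unstructured grid with one CELL_DATA scalar array per entry
#' of `cell_data`, plus the region labels as an integer array.
#'
#' @param mesh a `mesh2d`
#' @param path output file path
#' @param cell_data named list of numeric per-element vectors
#' @return `path`, invisibly
#' @export
write_vtk <- function(mesh, path, cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  writeLines(c("# vtk DataFile Version 2.0",
               "peckmech mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  Q <- nrow(mesh$quads); Tr <- nrow(mesh$tris)
  writeLines(paste("CELLS", Q + Tr, Q * 5 + Tr * 4), con)
  if (Q) writeLines(paste(4, mesh$quads[, 1] - 1, mesh$quads[, 2] - 1,
                          mesh$quads[, 3] - 1, mesh$quads[, 4] - 1), con)
  if (Tr) writeLines(paste(3, mesh$tris[, 1] - 1, mesh$tris[, 2] - 1,
                           mesh$tris[, 3] - 1), con)
  writeLines(paste("CELL_TYPES", Q + Tr), con)
  writeLines(as.character(c(rep(9L, Q), rep(5L, Tr))), con)
  writeLines(paste("CELL_DATA", Q + Tr), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(factor(mesh$elem_region))), con)
  for (nm in names(cell_data)) {
    writeLines(c(paste("SCALARS", nm, "double 1"), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", cell_data[[nm]]), con)
  }
  invisible(path)
}

#' Write a field history as a VTK frame series
#'
#' One legacy VTK file per saved frame (`basename_0000.vtk`, ...), each
#' carrying MSS, MPS and von Mises element fields.
#'
#' @param history a `fieldhistory`
#' @param dir output directory
#' @param basename file name stem
#' @return character vector of written paths, invisibly
#' @export
write_vtk_series <- function(history, dir, basename = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nf <- length(history$times)
  paths <- character(nf)
  for (i in seq_len(nf)) {
    Ff <- history$F_frames[, , i, drop = TRUE]
    Sf <- history$stress_frames[, , i, drop = TRUE]
    paths[i] <- file.path(dir, sprintf("%s_%04d.vtk", basename, i - 1))
    write_vtk(history$mesh, paths[i],
              cell_data = list(MSS = max_shear_strain(Ff),
                               MPS = principal_strains(Ff)[, 1],
                               VM = von_mises(Sf)))
  }
  invisible(paths)
}

#' Export a mesh as plain-text node / element / region tables
#'
#' Writes `<stem>_nodes.csv` (id, x, y), `<stem>_elements.csv`
#' (id, n1..n4 with n4 = NA for triangles, region) and returns the stem.
#'
#' @param mesh a `mesh2d`
#' @param stem output path stem
#' @return `stem`, invisibly
#' @export
write_mesh_text <- function(mesh, stem) {
  nd <- data.frame(id = seq_len(nrow(mesh$nodes)),
                   x = mesh$nodes[, 1], y = mesh$nodes[, 2])
  write.csv(nd, paste0(stem, "_nodes.csv"), row.names = FALSE)
  Q <- nrow(mesh$quads)
  els <- rbind(
    if (Q) data.frame(n1 = mesh$quads[, 1], n2 = mesh$quads[, 2],
                      n3 = mesh$quads[, 3], n4 = mesh$quads[, 4]),
    if (nrow(mesh$tris)) data.frame(n1 = mesh$tris[, 1], n2 = mesh$tris[, 2],
                                    n3 = mesh$tris[, 3], n4 = NA))
  els <- cbind(id = seq_len(nrow(els)), els, region = mesh$elem_region)
  write.csv(els, paste0(stem, "_elements.csv"), row.names = FALSE)
  invisible(stem)
}

#' Export / import a pecking profile as two-column CSV
#'
#' @param profile a `pecking_profile`
#' @param path CSV path (columns t, theta)
#' @return `path` invisibly
#' @export
write_profile_csv <- function(profile, path) {
  write.csv(profile$samples[, c("t", "theta")], path, row.names = FALSE)
  invisible(path)
}

#' Read a scenario configuration file (YAML)
#'
#' Structured text configuration: geometry parameters, material variant,
#' drive anchors/overrides, solver settings. Unknown keys are carried
#' through untouched.
#'
#' @param path YAML file
#' @return named list
#' @export
read_scenario_config <- function(path) {
  yaml::read_yaml(path)
}

#' Materialise a scenario configuration into model objects
#'
#' Builds the mesh, material library, drive profile and solver config
#' described by a configuration list (as from [read_scenario_config()]).
#'
#' @param cfg configuration list with optional sections `geometry`
#'   (species, scale, element_size, include_hyoid, include_beak),
#'   `materials` (variant, nu_eff), `drive` (frequency_factor, n_cycles,
#'   pulse_duration), `solver` (safety, hourglass, bulk_visc, output_dt,
#'   window)
#' @return list with mesh, library, drive, solver_config
#' @export
build_scenario <- function(cfg) {
  g <- cfg$geometry %||% list()
  species <- g$species %||% "woodpecker"
  mesh <- if (species == "human") {
    build_simplified_human(scale = g$scale %||% 1,
                           element_size = g$element_size %||% 5e-3)
  } else {
    build_simplified_woodpecker(scale = g$scale %||% 1,
                                include_hyoid = g$include_hyoid %||% TRUE,
                                include_beak = g$include_beak %||% TRUE,
                                element_size = g$element_size %||% 1e-3)
  }
  mcf <- cfg$materials %||% list()
  library <- material_library(variant = mcf$variant %||% "baseline",
                              nu_eff = mcf$nu_eff %||% 0.499)
  d <- cfg$drive %||% list()
  drive <- build_pecking_profile(
    impact_pulse_duration = d$pulse_duration %||% NULL)
  if (!is.null(d$frequency_factor) && d$frequency_factor != 1)
    drive <- scale_frequency(drive, d$frequency_factor)
  if (!is.null(d$n_cycles) && d$n_cycles > 1)
    drive <- repeat_cycles(drive, d$n_cycles)
  s <- cfg$solver %||% list()
  sc <- solver_config(safety = s$safety %||% 0.9,
                      hg_stiff = s$hg_stiff %||% 0.05,
                      hg_visc = s$hg_visc %||% 0.02,
                      bulk_visc = s$bulk_visc %||% 0.06,
                      output_dt = s$output_dt %||% 5e-4,
                      window = s$window %||% NULL,
                      amplitude = s$amplitude %||% 1)
  list(mesh = mesh, library = library, drive = drive, solver_config = sc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
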