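#' Validate a run configuration
#'
#' Reads a YAML or JSON configuration (or takes a named list), fills in the
#' default parameter set — interplanar distance `d = 1` mm, spatial step
#' `max_step = 2.09` mm, repeatability `eps = 0.05` mm, benchmark circle
#' diameter `D = 20` mm — and rejects unknown or invalid keys. An empty or
#' missing configuration therefore reproduces the reference parameter set
#' out of the box.
#'
#' @param config path to a `.yaml`/`.yml`/`.json` file, a named list, or
#'   `NULL` for all defaults.
#' @return A validated named list of class `run_config` with elements
#'   `fixture`, `d`, `max_step`, `eps`, `D`, `benchmark_N`, `mode`, `M`,
#'   `arm` (link lengths), `seed`.
#' @export
#' @examples
#' validate_config(NULL)           # the full default parameter set
#' validate_config(list(d = 0.5))  # override one key
validate_config <- function(config = NULL) {
  defaults <- list(
    fixture = list(kind = "spherical_cap", cap_diameter = 20,
                   sphere_radius = 25, extent = 20, amplitude = 1,
                   wavelength = 10, resolution = 0.5),
    input_stl = NULL,
    d = 1,
    max_step = 2.09,
    eps = 0.05,
    D = 20,
    benchmark_N = c(5L, 10L, 20L, 30L),
    mode = "cartesian_chord",
    M = 200L,
    arm = list(L1 = 140, L2 = 175, L3 = 175, L4 = 66),
    seed = 0L
  )
  raw <- if (is.null(config)) {
    list()
  } else if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config) %||% list()
    else jsonlite::read_json(config, simplifyVector = TRUE)
  } else if (is.list(config)) {
    config
  } else {
    stop("`config` must be a file path, a named list, or NULL", call. = FALSE)
  }
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, raw)
  if (!is.numeric(cfg$d) || cfg$d <= 0) {
    stop("configuration key `d` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(cfg$max_step) || cfg$max_step <= 0) {
    stop("configuration key `max_step` must be a positive number",
         call. = FALSE)
  }
  if (!is.numeric(cfg$eps) || cfg$eps <= 0) {
    stop("configuration key `eps` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(cfg$D) || cfg$D <= 0) {
    stop("configuration key `D` must be a positive number", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

config_mesh <- function(cfg) {
  if (!is.null(cfg$input_stl)) return(read_stl(cfg$input_stl))
  f <- cfg$fixture
  switch(f$kind,
         spherical_cap = make_spherical_cap(f$cap_diameter, f$sphere_radius,
                                            f$resolution),
         wavy = make_wavy_patch(f$extent, f$amplitude, f$wavelength,
                                f$resolution, seed = cfg$seed),
         flat_plate = make_flat_plate(f$extent, f$resolution),
         stop("unknown fixture kind: ", f$kind, call. = FALSE))
}

config_arm <- function(cfg) {
  arm_model(L1 = cfg$arm$L1, L2 = cfg$arm$L2, L3 = cfg$arm$L3,
            L4 = cfg$arm$L4, repeatability_eps = cfg$eps)
}

#' Run the full path-generation pipeline
#'
#' End-to-end wiring of the toolchain: obtain the patch surface (an input
#' STL or a synthetic fixture), slice it into the conformal lattice path,
#' execute the path with the arm model, run the circular discretization
#' benchmark, and write all artifacts — mesh report, lattice path CSV/JSON,
#' executed-trajectory CSV, benchmark CSV, and a JSON manifest recording
#' inputs, parameters and seed. Identical configurations produce
#' byte-identical artifacts.
#'
#' @param config anything accepted by [validate_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a named list of artifact paths plus the in-memory
#'   results (`mesh`, `path`, `report`).
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("patchpath_run_")) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mesh <- config_mesh(cfg)
  arm <- config_arm(cfg)

  path <- generate_lattice_path(mesh, d = cfg$d, max_step = cfg$max_step)
  report <- discretization_report(arm, N_list = cfg$benchmark_N, D = cfg$D,
                                  mode = cfg$mode, M = cfg$M)
  traj <- execute_path(path, arm, mode = "cartesian_chord",
                       samples_per_segment = 1L)

  paths <- list(
    mesh_report = file.path(out_dir, "mesh_report.csv"),
    lattice_csv = file.path(out_dir, "lattice_path.csv"),
    lattice_json = file.path(out_dir, "lattice_path.json"),
    trajectory_csv = file.path(out_dir, "trajectory.csv"),
    benchmark_csv = file.path(out_dir, "benchmark.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  utils::write.csv(mesh_summary(mesh), paths$mesh_report, row.names = FALSE)
  write_path_csv(path, paths$lattice_csv)
  write_path_json(path, paths$lattice_json)
  write_path_csv(traj, paths$trajectory_csv)
  write_report_csv(report, paths$benchmark_csv)
  manifest <- list(
    tool = "patchpath",
    version = as.character(utils::packageVersion("patchpath")),
    parameters = unclass(cfg),
    artifacts = lapply(paths, basename)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(c(paths, list(mesh = mesh, path = path, report = report)))
}
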