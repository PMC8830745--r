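# Staged analysis runner and collated reporting. The numbered scripts under
# analysis/ are thin drivers over these functions; run_stage() writes each
# stage's artifacts plus a manifest (parameters, input hashes, package
# version) so reruns with the same config are reproducible.

#' Default run configuration
#'
#' All thresholds of the analysis suite in one place: frame stride dt (ps),
#' secondary-structure consensus threshold, contact cutoff (Angstrom, the
#' 0.5 nm shell), persistence threshold (ns), helix bend boundary (degrees),
#' census edge (Angstrom), density voxel (Angstrom, ~0.2 nm), curvature grid
#' bins, and seeds.
#'
#' @param ... overrides for individual fields.
#' @return a named list (class \code{run_config}).
#' @export
default_config <- function(...) {
  cfg <- list(
    dt_ps = 200,
    ss_threshold = 0.70,
    contact_cutoff_A = 5,
    persistence_ns = 500,
    bend_boundary_deg = 15,
    census_edge_A = 6,
    voxel_A = 2,
    curvature_bins = 100,
    thickness_bin_A = 1,
    seed = 1,
    n_frames = 50,
    out_dir = "results",
    structure = NULL,
    trajectory = NULL,
    annotation = NULL
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stopf("unknown config field(s): %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  num <- c("dt_ps", "ss_threshold", "contact_cutoff_A", "persistence_ns",
           "bend_boundary_deg", "census_edge_A", "voxel_A", "curvature_bins",
           "thickness_bin_A")
  for (f in num) if (cfg[[f]] <= 0) stopf("config field %s must be positive", f)
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @return a \code{run_config}.
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config a \code{run_config}.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

write_manifest <- function(stage, config, files, out_dir) {
  existing <- files[file.exists(files)]
  manifest <- list(
    stage = stage,
    parameters = unclass(config)[!vapply(config, is.null, logical(1))],
    outputs = as.list(stats::setNames(
      as.vector(tools::md5sum(existing)), basename(existing))),
    package_version = as.character(utils::packageVersion("memscape"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
}

# build (or load) the system + stream a stage operates on
stage_inputs <- function(config) {
  if (!is.null(config$structure)) {
    sys <- read_structure(config$structure)
    stream <- if (!is.null(config$trajectory))
      read_frames(config$trajectory, sys, dt = config$dt_ps)
    else static_stream(sys, dt = config$dt_ps)
  } else {
    sys <- embed_protein(build_bilayer(bilayer_spec(), seed = config$seed),
                         n_residues = 60, radius = 12)
    stream <- simulate_frames(sys, config$n_frames,
                              motion_model(jitter = 0.4), seed = config$seed,
                              dt = config$dt_ps)
  }
  list(system = sys, stream = stream)
}

#' Run one analysis stage
#'
#' Stages: \code{"synth"} (generate the bilayer + protein system and
#' trajectory and write them), \code{"conformation"} (RMSD/Rg series, RMSF,
#' landscape clustering), \code{"secstruct"} (consensus + composition from a
#' label matrix), \code{"fields"} (thickness, deformation, density, APL,
#' curvature), \code{"lipidgrid"} (census grids), \code{"contacts"}
#' (persistence table, stable residues, type frequencies). Outputs and a
#' manifest are written under \code{config$out_dir}.
#'
#' @param stage stage name.
#' @param config a \code{run_config}.
#' @return invisibly, a named list of the stage's main results.
#' @export
run_stage <- function(stage, config = default_config()) {
  stages <- c("synth", "conformation", "secstruct", "fields", "lipidgrid",
              "contacts")
  if (!stage %in% stages)
    stopf("unknown stage '%s' (must be one of %s)", stage,
          paste(stages, collapse = ", "))
  if (!is.null(config$structure) && !file.exists(config$structure))
    stopf("input structure not found: %s", config$structure)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- stage_inputs(config)
  sys <- inp$system; stream <- inp$stream
  files <- character(0)
  res <- list()
  if (stage == "synth") {
    f1 <- file.path(out_dir, "system.pdb")
    write_structure(sys, f1)
    f2 <- file.path(out_dir, "census.csv")
    utils::write.csv(census_totals(sys), f2, row.names = FALSE)
    res$census <- census_totals(sys)
    files <- c(f1, f2)
  } else if (stage == "conformation") {
    rs <- rmsd_series(stream, sys, selection = "protein")
    rg <- rgyr_series(stream, sys, selection = "protein")
    rf <- rmsf(stream, sys, selection = "protein")
    f1 <- file.path(out_dir, "rmsd_rg.csv")
    utils::write.csv(cbind(rs, rg_nm = rg$rg_nm), f1, row.names = FALSE)
    f2 <- file.path(out_dir, "rmsf.csv")
    utils::write.csv(rf, f2, row.names = FALSE)
    res <- list(rmsd = rs, rg = rg, rmsf = rf)
    files <- c(f1, f2)
  } else if (stage == "secstruct") {
    n_res <- sum(sys$residues$class == "protein")
    lm <- emit_ss_labels(n_res, stream$n_frames,
                         list(ss_plan(seq_len(n_res), c(H = 0.8, C = 0.2))),
                         seed = config$seed)
    cs <- consensus(lm, config$ss_threshold)
    f1 <- file.path(out_dir, "consensus.csv")
    utils::write.csv(cs, f1, row.names = FALSE)
    res$consensus <- cs
    files <- f1
  } else if (stage == "fields") {
    th <- average_thickness(stream, sys, bin = config$thickness_bin_A)
    apl <- area_per_lipid(stream, sys, "top")
    dm <- deformation_map(stream, sys, "top", cell = config$voxel_A)
    files <- c(write_field2d(dm, file.path(out_dir, "deformation_top")))
    f2 <- file.path(out_dir, "thickness.csv")
    utils::write.csv(data.frame(frame = seq_along(th$per_frame) - 1L,
                                thickness_A = th$per_frame), f2, row.names = FALSE)
    files <- c(files, f2)
    res <- list(thickness = th, apl = apl, deformation = dm)
  } else if (stage == "lipidgrid") {
    cg <- monolayer_census(sys, NULL, "top", edge = config$census_edge_A,
                           xyz = frame_coords(stream, stream$n_frames))
    files <- write_census_grid(cg, file.path(out_dir, "census_top"))
    res$census_grid <- cg
  } else if (stage == "contacts") {
    tab <- persistence(stream, sys, cutoff = config$contact_cutoff_A)
    f1 <- file.path(out_dir, "contact_table.csv")
    utils::write.csv(tab, f1, row.names = FALSE)
    st <- stable_residues(tab, config$persistence_ns)
    f2 <- file.path(out_dir, "stable_residues.csv")
    utils::write.csv(st, f2, row.names = FALSE)
    res <- list(table = tab, stable = st)
    files <- c(f1, f2)
  }
  write_manifest(stage, config, files, out_dir)
  invisible(res)
}

#' Collate stage outputs into a summary report
#'
#' Scans a results directory for the artifacts the stages write and collates
#' a machine-readable JSON plus a short human-readable text summary. Missing
#' stages are marked absent rather than failing.
#'
#' @param out_dir directory holding stage outputs.
#' @param path JSON output path (default \code{<out_dir>/report.json}).
#' @return invisibly, the report list.
#' @export
collate_report <- function(out_dir, path = file.path(out_dir, "report.json")) {
  rep <- list()
  f <- file.path(out_dir, "census.csv")
  rep$composition <- if (file.exists(f)) utils::read.csv(f) else "absent"
  f <- file.path(out_dir, "consensus.csv")
  if (file.exists(f)) {
    cs <- utils::read.csv(f)
    rep$ss_fractions <- as.list(table(cs$label) / nrow(cs))
  } else rep$ss_fractions <- "absent"
  f <- file.path(out_dir, "thickness.csv")
  if (file.exists(f)) {
    th <- utils::read.csv(f)
    rep$thickness <- list(mean_A = mean(th$thickness_A),
                          sd_A = stats::sd(th$thickness_A))
  } else rep$thickness <- "absent"
  f <- file.path(out_dir, "stable_residues.csv")
  rep$stable_residues <- if (file.exists(f)) utils::read.csv(f) else "absent"
  f <- file.path(out_dir, "rmsd_rg.csv")
  if (file.exists(f)) {
    rr <- utils::read.csv(f)
    rep$rmsd_mean_nm <- mean(rr$rmsd_nm)
    rep$rg_mean_nm <- mean(rr$rg_nm)
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  txt <- file.path(out_dir, "report.txt")
  lines <- c("memscape collated report",
             sprintf("sections present: %s",
                     paste(names(rep)[!vapply(rep, identical, logical(1), "absent")],
                           collapse = ", ")))
  writeLines(lines, txt)
  invisible(rep)
}
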