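# End-to-end orchestration: simulate -> (optional STA) -> surface fit ->
# orientation analysis -> report.
#
# Seed policy: one global seed `s` fans out as s (scene), s + 1 (rendering
# noise), s + 2 (subtomogram averaging), so stages can be rerun
# independently yet reproducibly.

#' Fit one interface per (tomogram, meniscus) group
#'
#' The two menisci are geometrically distinct surfaces; mixing them in one
#' height field would be invalid, so one thin-plate spline is fitted per
#' tomogram and per meniscus through the centers of that group's particles.
#' Bulk particles are ignored.
#'
#' @param particles particle data.frame (schema of [read_particles()]).
#' @param lambda smoothing parameter passed to [fit_surface()].
#' @return named list of [tps_surface][fit_surface] objects keyed by
#'   [surface_key()].
#' @export
fit_scene_surfaces <- function(particles, lambda = 0) {
  sel <- particles$meniscus %in% c("upper", "lower")
  p <- particles[sel, , drop = FALSE]
  if (nrow(p) == 0) stop("no surface-adsorbed particles to fit")
  keys <- unique(surface_key(p$tomogram, p$meniscus))
  out <- list()
  for (key in keys) {
    g <- p[surface_key(p$tomogram, p$meniscus) == key, , drop = FALSE]
    side <- sub("^.*/", "", key)
    out[[key]] <- fit_surface(cbind(g$x, g$y, g$z), lambda = lambda,
                              side = side)
  }
  out
}

#' Orientation analysis on fitted surfaces
#'
#' The analysis stage of the pipeline, re-entrant: it accepts in-memory
#' objects or files written by an earlier run and produces byte-identical
#' outputs for identical inputs. Emits the per-particle displacement
#' angles, the 7.5-degree histogram and a BILD arrow file of the
#' denaturation vectors anchored at the particle centers.
#'
#' @param particles particle data.frame or path to a particle TSV.
#' @param surfaces named list of surfaces (keyed by [surface_key()]) or a
#'   directory containing `surface_<tomogram>_<meniscus>.tsv` files.
#' @param p_ref reference-frame denaturation unit vector.
#' @param out_dir output directory (created if missing).
#' @param bin_width histogram bin width in degrees.
#' @param arrow_scale BILD arrow length in Angstrom.
#' @return list with `deltas` (data.frame), `histogram`
#'   (`angle_distribution`), `vectors`, `files`.
#' @export
analyze_orientation <- function(particles, surfaces, p_ref, out_dir,
                                bin_width = 7.5, arrow_scale = 200) {
  if (is.character(particles)) particles <- read_particles(particles)
  if (is.character(surfaces)) surfaces <- read_surface_dir(surfaces)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vectors <- particle_denaturation_vectors(particles, p_ref)
  deltas <- displacement_angles(particles, vectors, surfaces)
  hist <- angle_histogram(deltas$delta, bin_width = bin_width)
  keep <- particles$meniscus != "bulk"
  files <- c(deltas = file.path(out_dir, "deltas.tsv"),
             histogram = file.path(out_dir, "histogram.tsv"),
             bild = file.path(out_dir, "vectors.bild"))
  writeLines(c("id\ttomogram\tmeniscus\tdelta",
               paste(deltas$id, deltas$tomogram, deltas$meniscus,
                     fmt_num(deltas$delta, 15), sep = "\t")),
             files[["deltas"]])
  write_histogram_tsv(hist, files[["histogram"]])
  write_bild(vectors[keep, , drop = FALSE], files[["bild"]],
             scale = arrow_scale,
             anchors = cbind(particles$x, particles$y, particles$z)[keep, ,
                                                                    drop = FALSE])
  list(deltas = deltas, histogram = hist, vectors = vectors, files = files)
}

surface_file_name <- function(key) {
  paste0("surface_", gsub("/", "_", key), ".tsv")
}

write_surface_dir <- function(surfaces, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(surfaces))
    write_surface(surfaces[[key]], file.path(dir, surface_file_name(key)))
  invisible(dir)
}

read_surface_dir <- function(dir) {
  files <- list.files(dir, pattern = "^surface_.*\\.tsv$", full.names = TRUE)
  if (length(files) == 0)
    stop(sprintf("no fitted surface files found in '%s'", dir))
  out <- list()
  for (f in files) {
    key <- sub("^surface_(.*)\\.tsv$", "\\1", basename(f))
    key <- sub("_(upper|lower)$", "/\\1", key)
    out[[key]] <- read_surface(f)
  }
  out
}

#' Run the full recovery experiment
#'
#' Executes the five analysis steps end to end on a simulated scene:
#' (i) fit the interface through particle centers, (ii) interface normals
#' at each particle, (iii) reference denaturation direction from the
#' intact/damaged phantom difference map, (iv) per-particle denaturation
#' vectors, (v) displacement angles binned at 7.5 degrees. Orientations
#' come from the scene ground truth (`orientation_source = "truth"`) or are
#' re-derived by subtomogram averaging of rendered subtomograms
#' (`orientation_source = "sta"`).
#'
#' @param config a [scene_config()], a list of `scene_config` arguments
#'   optionally with an `analysis` sub-list (`lambda`, `bin_width`,
#'   `orientation_source`, `box`, `voxel_size`, `angular_step`,
#'   `iterations`), or the path of a YAML file with the same layout.
#' @param out_dir output directory.
#' @param seed optional integer overriding the config seed.
#' @return a `run_report` list: parameters, particle counts, displacement
#'   summary (median, fraction below 30 degrees, per-bin fractions), file
#'   manifest, seeds. Also written to `report.json`.
#' @export
run_recovery_experiment <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (inherits(config, "scene_config")) config <- unclass(config)
  analysis <- config$analysis %||% list()
  config$analysis <- NULL
  scene_args <- config[intersect(names(config), names(formals(scene_config)))]
  if (!is.null(seed)) scene_args$seed <- as.integer(seed)
  cfg <- do.call(scene_config, scene_args)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  lambda <- analysis$lambda %||% 0
  bin_width <- analysis$bin_width %||% 7.5
  source <- analysis$orientation_source %||% "truth"
  box <- analysis$box %||% 32
  voxel_size <- analysis$voxel_size %||% 8

  scene <- simulate_scene(cfg)
  particles <- scene$particles
  intact <- make_phantom("intact", box = box, voxel_size = voxel_size)
  damaged <- make_phantom("damaged", box = box, voxel_size = voxel_size)
  p_ref <- reference_denaturation_vector(intact, damaged)

  if (identical(source, "sta")) {
    stack <- render_subtomograms(scene, intact, damaged,
                                 seed = cfg$seed + 1L)
    gs <- gold_standard_average(stack,
                                n_seed = min(20, length(stack$volumes) %/% 2),
                                iterations = analysis$iterations %||% 2,
                                angular_step = analysis$angular_step %||% 30,
                                seed = cfg$seed + 2L)
    al <- gs$alignments[match(particles$id, gs$alignments$particle_id), ]
    particles$rot <- al$rot
    particles$tilt <- al$tilt
    particles$psi <- al$psi
  }

  gt_file <- file.path(out_dir, "ground_truth.tsv")
  export_ground_truth(scene, gt_file)
  particles_file <- file.path(out_dir, "particles.tsv")
  write_particles(particles, particles_file)

  surfaces <- fit_scene_surfaces(particles, lambda = lambda)
  surf_dir <- file.path(out_dir, "surfaces")
  write_surface_dir(surfaces, surf_dir)

  ana <- analyze_orientation(particles, surfaces, p_ref, out_dir,
                             bin_width = bin_width)
  hist <- ana$histogram
  deltas <- ana$deltas

  report <- list(
    parameters = c(unclass(cfg),
                   list(lambda = lambda, bin_width = bin_width,
                        orientation_source = source, box = box,
                        voxel_size = voxel_size)),
    seeds = list(scene = cfg$seed, render = cfg$seed + 1L, sta = cfg$seed + 2L),
    counts = list(total = nrow(particles),
                  analyzed = nrow(deltas),
                  bulk_excluded = attr(deltas, "n_bulk_excluded")),
    delta_summary = list(
      median_deg = median(deltas$delta),
      fraction_below_30deg = mean(deltas$delta < 30),
      bin_fraction = hist$count / sum(hist$count)),
    files = c(ground_truth = gt_file, particles = particles_file,
              surfaces = surf_dir, ana$files))
  report_file <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  report$files <- c(report$files, report = report_file)
  for (f in report$files)
    if (!file.exists(f)) stop(sprintf("pipeline output missing: %s", f))
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d particles analyzed (%d bulk excluded)\n",
              x$counts$analyzed, x$counts$bulk_excluded))
  cat(sprintf("  median displacement angle: %.2f deg\n",
              x$delta_summary$median_deg))
  cat(sprintf("  fraction below 30 deg: %.3f\n",
              x$delta_summary$fraction_below_30deg))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Command-line interface (function level; see inst/scripts/awiorient-cli.R
# for the executable wrapper).

cli_usage <- function() {
  paste(
    "usage: awiorient <subcommand> [--flag value ...]",
    "subcommands:",
    "  simulate     --config c.yaml --out dir [--seed n]",
    "  fit-surface  --particles p.tsv --out dir [--lambda x]",
    "  analyze      --particles p.tsv --surfaces dir --out dir",
    "  fsc          --half1 a.mrc --half2 b.mrc --out fsc.tsv [--mask m.mrc]",
    "  sta          --stack dir --out dir [--seed n] [--step deg] [--iterations n]",
    "  run-all      --config c.yaml --out dir [--seed n]",
    sep = "\n")
}

parse_cli_flags <- function(argv, allowed) {
  flags <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--") || !(substring(a, 3) %in% allowed))
      stop(sprintf("unknown flag: %s", a), call. = FALSE)
    if (i + 1 > length(argv))
      stop(sprintf("flag %s needs a value", a), call. = FALSE)
    flags[[substring(a, 3)]] <- argv[i + 1]
    i <- i + 2
  }
  flags
}

#' Command-line entry point
#'
#' Thin dispatcher mapping subcommands 1:1 onto package operations;
#' structured messages go to stderr, data to files only. Returns the
#' process exit code instead of calling `quit()`, so it is testable
#' in-process; the installed script `inst/scripts/awiorient-cli.R` wraps it.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return integer exit code: 0 on success, 1 on a stage failure, 2 on a
#'   usage error.
#' @export
awi_cli <- function(argv) {
  if (length(argv) == 0) {
    message(cli_usage())
    return(2L)
  }
  sub <- argv[1]
  rest <- argv[-1]
  known <- c("simulate", "fit-surface", "analyze", "fsc", "sta", "run-all")
  if (!(sub %in% known)) {
    message(sprintf("unknown subcommand: %s", sub))
    message(cli_usage())
    return(2L)
  }
  flags <- tryCatch(
    parse_cli_flags(rest, c("config", "out", "seed", "particles", "surfaces",
                            "half1", "half2", "mask", "stack", "lambda",
                            "step", "iterations")),
    error = function(e) e)
  if (inherits(flags, "error")) {
    message(conditionMessage(flags))
    message(cli_usage())
    return(2L)
  }
  need <- function(name) {
    if (is.null(flags[[name]]))
      stop(sprintf("missing required flag --%s", name), call. = FALSE)
    flags[[name]]
  }
  run <- function(expr) {
    tryCatch({ expr; 0L }, error = function(e) {
      message(sprintf("[awiorient:%s] error: %s", sub, conditionMessage(e)))
      1L
    })
  }
  seed <- if (!is.null(flags$seed)) as.integer(flags$seed) else NULL
  switch(sub,
    "simulate" = run({
      config <- yaml::read_yaml(need("config"))
      if (!is.null(seed)) config$seed <- seed
      out <- need("out")
      args <- config[intersect(names(config), names(formals(scene_config)))]
      cfg <- do.call(scene_config, args)
      scene <- simulate_scene(cfg)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      export_ground_truth(scene, file.path(out, "ground_truth.tsv"))
      write_particles(scene$particles, file.path(out, "particles.tsv"))
      analysis <- config$analysis %||% list()
      box <- analysis$box %||% 32
      voxel_size <- analysis$voxel_size %||% 8
      intact <- make_phantom("intact", box = box, voxel_size = voxel_size)
      damaged <- make_phantom("damaged", box = box, voxel_size = voxel_size)
      stack <- render_subtomograms(scene, intact, damaged,
                                   seed = cfg$seed + 1L)
      stack_dir <- file.path(out, "stack")
      dir.create(stack_dir, showWarnings = FALSE)
      for (i in seq_along(stack$volumes))
        write_mrc(stack$volumes[[i]],
                  file.path(stack_dir, sprintf("particle_%04d.mrc",
                                               stack$particle_ids[i])))
      message(sprintf("[awiorient:simulate] %d particles -> %s",
                      nrow(scene$particles), out))
    }),
    "fit-surface" = run({
      particles <- read_particles(need("particles"))
      lambda <- as.numeric(flags$lambda %||% 0)
      surfaces <- fit_scene_surfaces(particles, lambda = lambda)
      write_surface_dir(surfaces, need("out"))
      message(sprintf("[awiorient:fit-surface] fitted %d surface(s)",
                      length(surfaces)))
    }),
    "analyze" = run({
      particles <- read_particles(need("particles"))
      surfaces <- read_surface_dir(need("surfaces"))
      intact <- make_phantom("intact")
      damaged <- make_phantom("damaged")
      p_ref <- reference_denaturation_vector(intact, damaged)
      analyze_orientation(particles, surfaces, p_ref, need("out"))
      message("[awiorient:analyze] done")
    }),
    "fsc" = run({
      v1 <- read_mrc(need("half1"))
      v2 <- read_mrc(need("half2"))
      mask <- if (!is.null(flags$mask)) read_mrc(flags$mask) else NULL
      curve <- fsc(v1, v2, mask = mask)
      write_fsc_tsv(curve, need("out"))
      res <- resolution_at(curve, 0.143)
      message(sprintf("[awiorient:fsc] resolution at FSC=0.143: %.3g A%s",
                      as.numeric(res),
                      if (attr(res, "limit")) " (limit)" else ""))
    }),
    "sta" = run({
      stack_dir <- need("stack")
      files <- sort(list.files(stack_dir, pattern = "\\.mrc$",
                               full.names = TRUE))
      if (length(files) == 0) stop("no MRC files in --stack directory")
      vols <- lapply(files, read_mrc)
      stack <- subtomo_stack(vols)
      gs <- gold_standard_average(
        stack, n_seed = min(20L, length(vols) %/% 2),
        iterations = as.integer(flags$iterations %||% 2),
        angular_step = as.numeric(flags$step %||% 30),
        seed = seed %||% 1L)
      out <- need("out")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_mrc(gs$half_a, file.path(out, "half_a.mrc"))
      write_mrc(gs$half_b, file.path(out, "half_b.mrc"))
      final <- average_volumes(list(gs$half_a, gs$half_b))
      # display-convention band-pass, applied only to the emitted final map
      final <- bandpass_filter(final, low_res = 308, high_res = max(
        12, 2 * final$voxel_size))
      write_mrc(final, file.path(out, "map_final.mrc"))
      write_fsc_tsv(gs$fsc, file.path(out, "fsc.tsv"))
      write.table(gs$alignments, file.path(out, "alignments.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      message(sprintf("[awiorient:sta] averaged %d particles", length(vols)))
    }),
    "run-all" = run({
      report <- run_recovery_experiment(need("config"), need("out"),
                                        seed = seed)
      message(sprintf("[awiorient:run-all] median delta %.2f deg (%d particles)",
                      report$delta_summary$median_deg, report$counts$analyzed))
    }))
}
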