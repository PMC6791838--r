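#' Default run configuration
#'
#' One structured list holding every tunable of the pipeline, mirroring the
#' module parameter objects. The pipeline's named constants live here:
#' 5 mm tail pruning, 2 mm junction trim, the score floors (1.0 mm, 0.5 mm,
#' 0.1) with exponent 3, the 10 percent zero-thickness cleanup threshold,
#' and the segmentation cutoffs 28/24.
#'
#' @param input path to a stack (multi-page TIFF or slice directory), or
#'   `NULL` to run on a generated phantom.
#' @param spacing voxel spacing (dz, dy, dx) in mm.
#' @param out_dir output directory for artifacts, or `NULL` to skip writing.
#' @param seed seed for the phantom generator.
#' @return A `run_config` list.
#' @export
default_config <- function(input = NULL, spacing = c(0.1, 0.5, 0.5),
                           out_dir = NULL, seed = 1L) {
  structure(list(
    input = input,
    spacing = as.numeric(spacing),
    out_dir = out_dir,
    seed = as.integer(seed),
    preprocess = unclass(preprocess_params()),
    graph = list(prune_len_mm = 5, junction_trim_mm = 2),
    score = unclass(score_params()),
    morphometry = list(contact_tol_mm = 0.5, max_zero_frac = 0.10,
                       merge_arc_mm = 2, min_branch_len_mm = 12),
    simulation = list(density_g_cm3 = 0.7, scaffold_percentile = 95,
                      gravity = c(0, 0, -1)),
    phantom = unclass(phantom_spec(seed = seed))
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' @param config a `run_config`.
#' @return Character vector of problems (empty when the config is valid);
#'   each entry names the offending field and the violated constraint.
#' @export
validate_config <- function(config) {
  p <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) p <<- c(p, msg)
  chk(length(config$spacing) == 3 && all(config$spacing > 0),
      "spacing: three strictly positive values required")
  pp <- config$preprocess
  chk(pp$z_sigma_slices >= 0, "preprocess$z_sigma_slices: must be >= 0")
  chk(pp$gauss_sigma_vox_skel >= 0, "preprocess$gauss_sigma_vox_skel: must be >= 0")
  chk(pp$gauss_sigma_vox_thick >= 0, "preprocess$gauss_sigma_vox_thick: must be >= 0")
  chk(pp$threshold_skel >= 0 && pp$threshold_skel <= 255,
      "preprocess$threshold_skel: must lie in [0, 255]")
  chk(pp$threshold_thick >= 0 && pp$threshold_thick <= 255,
      "preprocess$threshold_thick: must lie in [0, 255]")
  chk(config$graph$prune_len_mm >= 0, "graph$prune_len_mm: must be >= 0")
  chk(config$graph$junction_trim_mm >= 0, "graph$junction_trim_mm: must be >= 0")
  sc <- config$score
  chk(all(c(sc$floor_D, sc$floor_d, sc$floor_ratio) >= 0),
      "score floors: must be >= 0")
  chk(sc$exponent_T > 0, "score$exponent_T: must be > 0")
  chk(sc$search_radius_mm > 0, "score$search_radius_mm: must be > 0")
  chk(sc$L_dir_mm > 0, "score$L_dir_mm: must be > 0")
  mo <- config$morphometry
  chk(mo$contact_tol_mm >= 0, "morphometry$contact_tol_mm: must be >= 0")
  chk(mo$max_zero_frac >= 0 && mo$max_zero_frac < 1,
      "morphometry$max_zero_frac: must lie in [0, 1)")
  chk(config$simulation$density_g_cm3 > 0, "simulation$density_g_cm3: must be > 0")
  ph <- config$phantom
  chk(ph$n_branches >= 1, "phantom$n_branches: must be >= 1")
  chk(all(ph$box > 0), "phantom$box: must be positive")
  chk(ph$fg >= 0 && ph$fg <= 255 && ph$bg >= 0 && ph$bg <= 255,
      "phantom intensities: must lie in [0, 255]")
  chk(ph$noise_sd >= 0, "phantom$noise_sd: must be >= 0")
  p
}

#' Write / read a run configuration as YAML
#'
#' The config round-trips losslessly, and every completed run writes its
#' fully resolved configuration next to the outputs.
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (nm in names(base)) {
    if (is.null(cfg[[nm]])) next
    if (is.list(base[[nm]])) {
      for (sub in names(cfg[[nm]])) base[[nm]][[sub]] <- cfg[[nm]][[sub]]
    } else base[[nm]] <- cfg[[nm]]
  }
  base$spacing <- as.numeric(base$spacing)
  base
}

config_score_params <- function(config) {
  sc <- config$score
  score_params(floor_D = sc$floor_D, floor_d = sc$floor_d,
               floor_ratio = sc$floor_ratio, exponent_T = sc$exponent_T,
               floor_angle_deg = sc$floor_angle_deg,
               search_radius_mm = sc$search_radius_mm,
               link_threshold = sc$link_threshold, L_dir_mm = sc$L_dir_mm,
               endpoint_thickness_samples = sc$endpoint_thickness_samples,
               stub_len_mm = sc$stub_len_mm, mode = sc$mode)
}

config_preprocess_params <- function(config) {
  pp <- config$preprocess
  preprocess_params(z_sigma_slices = pp$z_sigma_slices,
                    gauss_sigma_vox_skel = pp$gauss_sigma_vox_skel,
                    threshold_skel = pp$threshold_skel,
                    gauss_sigma_vox_thick = pp$gauss_sigma_vox_thick,
                    threshold_thick = pp$threshold_thick,
                    z_kernel = pp$z_kernel)
}

#' Run the complete digitization pipeline
#'
#' Executes all stages on one input stack (or on a generated phantom when
#' the config names no input): two-track preprocessing, thinning, skeleton
#' graph construction, tail pruning, junction elimination, fragment
#' linking, short-edge removal, thickness assignment with zero-thickness
#' cleanup and interpolation, contact detection, morphometric summary, and
#' both construction simulations. Per-stage timings and counts are logged
#' to stderr; when `out_dir` is set, every intermediate artifact plus a
#' manifest (parameters, package version, seed, timings) is written there,
#' and artifacts of completed stages survive a later failure. Identical
#' config and input give identical outputs.
#'
#' @param config a `run_config` (see [default_config()]).
#' @param input_volume optional grayscale [volume]; overrides both
#'   `config$input` and the phantom generator.
#' @return List with the phantom truth (if generated), branches, contacts,
#'   summary, network, both build sequences and the manifest.
#' @export
run_all <- function(config = default_config(), input_volume = NULL) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  manifest <- list()
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    dt <- proc.time()[["elapsed"]] - t0
    manifest[[length(manifest) + 1L]] <<- list(stage = name,
                                               seconds = round(dt, 2))
    message(sprintf("[%s] %.1fs", name, dt))
    res
  }
  emit <- function(name, value) {
    manifest[[length(manifest)]][[name]] <<- value
    message(sprintf("    %s: %s", name, paste(value, collapse = ", ")))
  }

  nest <- NULL
  if (!is.null(input_volume)) {
    vol <- input_volume
  } else if (!is.null(config$input)) {
    vol <- read_stack(config$input, config$spacing)
  } else {
    ph <- config$phantom
    ph$seed <- config$seed
    spec <- do.call(phantom_spec, ph[names(ph) %in% names(formals(phantom_spec))])
    nest <- make_nest(spec)
    vol <- voxelize(nest)
  }

  pp <- config_preprocess_params(config)
  skel_in <- t_stage("preprocess_skeleton", make_skeleton_input(vol, pp))
  thick_in <- t_stage("preprocess_thickness", make_thickness_input(vol, pp))
  rm(vol); gc(verbose = FALSE)

  skel <- t_stage("thin", thin(skel_in))
  emit("skeleton_voxels", sum(skel$data))
  if (!is.null(out_dir)) write_stack(skel, file.path(out_dir, "skeleton.tif"))
  rm(skel_in); gc(verbose = FALSE)

  g <- t_stage("build_graph", build_graph(skel))
  emit("edges", length(g$edges))
  rm(skel); gc(verbose = FALSE)

  g <- t_stage("prune_tails", prune_tails(g, config$graph$prune_len_mm))
  emit("edges", length(g$edges))

  rmap <- radius_map(thick_in)
  rm(thick_in); gc(verbose = FALSE)

  frags <- t_stage("break_junctions",
                   break_junctions(g, config$graph$junction_trim_mm))
  emit("fragments", length(frags))
  if (!is.null(out_dir)) write_edges_json(frags, file.path(out_dir, "fragments.json"))
  sp <- config_score_params(config)
  linked <- t_stage("link_edges", link_edges(frags, rmap, sp))
  emit("branches", length(linked))
  emit("merges", nrow(attr(linked, "merges")))
  if (!is.null(out_dir)) {
    write_edges_json(linked, file.path(out_dir, "branches.json"))
    audit <- attr(linked, "audit")
    if (!is.null(audit))
      write.csv(audit, file.path(out_dir, "score_audit.csv"), row.names = FALSE)
  }

  # eliminating contact-zone stubs exposes facing ends of long fragments
  # whose directions are reliable, so linking is rerun once after removal
  linked <- t_stage("consolidate", {
    kept <- drop_short(linked, config$morphometry$min_branch_len_mm)
    sp2 <- sp
    # wide enough to span a dropped stub plus both junction trims, but not
    # so wide that coincidentally aligned distinct branches come in range
    sp2$search_radius_mm <- max(sp$search_radius_mm,
                                config$morphometry$min_branch_len_mm +
                                  2 * config$graph$junction_trim_mm)
    drop_short(link_edges(kept, rmap, sp2),
               config$morphometry$min_branch_len_mm)
  })
  emit("branches", length(linked))

  branches <- t_stage("thickness", {
    br <- edges_to_branches(linked)
    br <- lapply(br, assign_thickness, rmap = rmap)
    br <- clean_zero_thickness(br, config$morphometry$max_zero_frac)
    lapply(br, interpolate_zero)
  })
  emit("branches", length(branches))
  rm(rmap); gc(verbose = FALSE)

  contacts <- t_stage("contacts",
                      detect_contacts(branches,
                                      config$morphometry$contact_tol_mm,
                                      config$morphometry$merge_arc_mm))
  emit("contacts", nrow(contacts))
  if (!is.null(out_dir))
    write.csv(contacts, file.path(out_dir, "contacts.csv"), row.names = FALSE)

  gravity <- config$simulation$gravity
  net0 <- build_network(branches, contacts,
                        density_g_cm3 = config$simulation$density_g_cm3)
  scaffold <- identify_scaffold(net0, config$simulation$scaffold_percentile)
  summary <- t_stage("summarize",
                     summarize_nest(branches, contacts, gravity, scaffold))
  if (!is.null(out_dir)) {
    write_branch_table(summary$branch_table[, branch_table_columns],
                       file.path(out_dir, "branch_table.csv"))
    jsonlite::write_json(summary$global, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    plot_summary(summary, file.path(out_dir, "morphometry.png"))
  }

  sims <- t_stage("simulate", {
    net <- build_network(branches, contacts, scaffold,
                         config$simulation$density_g_cm3)
    if (nrow(net$edges) == 0 && nrow(net$nodes) > 1)
      stop("contact network has no edges; construction cannot be simulated")
    list(network = net,
         greedy = simulate_greedy(net, gravity, scaffold),
         gradual = simulate_gradual(net, gravity, scaffold))
  })
  if (!is.null(out_dir)) {
    write_network(sims$network, file.path(out_dir, "network.graphml"))
    write_sequence(sims$greedy, file.path(out_dir, "sequence_greedy.csv"))
    write_sequence(sims$gradual, file.path(out_dir, "sequence_gradual.csv"))
  }

  manifest_out <- list(
    package_version = as.character(utils::packageVersion("nestweave")),
    r_version = R.version.string,
    seed = config$seed,
    stages = manifest)
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest_out, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    write_config(config, file.path(out_dir, "config_resolved.yaml"))
  }
  list(nest = nest, fragments = frags, branches = branches,
       contacts = contacts, summary = summary, network = sims$network,
       greedy = sims$greedy, gradual = sims$gradual,
       scaffold = scaffold, manifest = manifest_out)
}
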