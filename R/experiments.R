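#' Reproducible experiment presets
#'
#' Each preset encodes one of the package's reference protocols with its
#' standard settings, writes its outputs (snapshot/branch CSVs, summary
#' JSON) into `out_dir` and records a manifest. Available presets:
#'
#' * `"nicd_dose_response"`: tissue mean NICD (relative to the zero-signal
#'   reference) across a grid of the EMT-inducing signal `I_ext`, measured
#'   at 120 h on a hexagonal lattice.
#' * `"jext_bifurcation"` / `"dext_bifurcation"`: one-cell stable-state
#'   branches against external Jagged / Delta at `N_ext = 5000`.
#' * `"nullcline_plane"`: Notch/Delta nullclines and classified fixed
#'   points at the reference bistable point (`J_ext = 600`).
#' * `"phase_diagram"`: coexisting-phenotype map over the
#'   `(D_ext, J_ext)` plane.
#' * `"patterning"`: Delta-dominated (`g_D = 70, g_J = 20`) versus
#'   Jagged-dominated (`g_D = 20, g_J = 70`) tissues from seeded random
#'   initial conditions, snapshots at 120 h and 240 h plus pattern
#'   summaries.
#' * `"external_signals"`: effect of `I_ext` and of soluble Jagged
#'   `sJ_ext` on the phenotype fractions of the Jagged-dominated tissue.
#' * `"phenotypic_stability"`: persistence of a mesenchymal/hybrid tissue
#'   under Jagged-dominated signalling through 360 h.
#'
#' @param name Preset name (see above).
#' @param out_dir Output directory (created if missing).
#' @param seed Seed for every random initial condition involved.
#' @param size Lattice edge for tissue presets (even; default 50).
#' @param params Base parameter set; presets override production rates as
#'   their protocol requires.
#' @param sweep_points Grid resolution for bifurcation sweeps.
#' @param grid_points Per-axis resolution of the phase diagram.
#' @return The run manifest (list with `name`, `seed`, `config_hash`,
#'   `started`, `finished` timestamps and `outputs` file vector),
#'   invisibly.
#' @export
run_experiment <- function(name = c("nicd_dose_response", "jext_bifurcation",
                                    "dext_bifurcation", "nullcline_plane",
                                    "phase_diagram", "patterning",
                                    "external_signals", "phenotypic_stability"),
                           out_dir = tempfile("notchemt_run_"), seed = 1,
                           size = 50, params = default_parameters(),
                           sweep_points = 60, grid_points = 40) {
  name <- match.arg(name)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(name = name, seed = seed,
                   config_hash = params_hash(params),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   outputs = character(0))
  th <- default_thresholds(params)
  add <- function(file, obj, writer) {
    path <- file.path(out_dir, file)
    writer(obj, path)
    manifest$outputs <<- c(manifest$outputs, path)
    path
  }
  wcsv <- function(obj, path) utils::write.csv(obj, path, row.names = FALSE)
  wjson <- function(obj, path) jsonlite::write_json(obj, path,
                                                    auto_unbox = TRUE,
                                                    digits = NA, pretty = TRUE)
  env0 <- cell_environment(N_ext = 5000)

  if (name == "nicd_dose_response") {
    lat <- build_lattice(size, size, "periodic")
    p <- apply_overrides(params, list(gD = 20, gJ = 20))
    st0 <- random_initial_states(lat, p, seed = seed)
    levels <- c(0, 25, 50, 75, 100)
    nicd <- vapply(levels, function(iext) {
      run <- simulate_tissue(lat, st0, p, t_end = 120, snapshot_times = 120,
                             I_ext = iext, thresholds = th)
      mean_nicd(run[[1]])
    }, numeric(1))
    out <- data.frame(I_ext = levels, mean_nicd = nicd,
                      relative_nicd = nicd / nicd[1])
    add("nicd_dose_response.csv", out, wcsv)
  } else if (name %in% c("jext_bifurcation", "dext_bifurcation")) {
    swept <- if (name == "jext_bifurcation") "J_ext" else "D_ext"
    hi <- if (swept == "J_ext") 3600 else 6000
    sw <- suppressWarnings(
      sweep_parameter(swept, seq(0, hi, length.out = sweep_points), env0,
                      params, seed = seed, thresholds = th))
    add(paste0(name, ".csv"), sw, wcsv)
  } else if (name == "nullcline_plane") {
    nc <- nullclines_nd(cell_environment(N_ext = 5000, J_ext = 600), params)
    add("curve_dN.csv", nc$curve_dN, wcsv)
    add("curve_dD.csv", nc$curve_dD, wcsv)
    add("fixed_points.csv", nc$intersections, wcsv)
  } else if (name == "phase_diagram") {
    pd <- phase_diagram(seq(0, 6000, length.out = grid_points),
                        seq(0, 3600, length.out = grid_points),
                        env0, params, seed = seed, thresholds = th)
    add("phase_diagram.csv", pd, wcsv)
  } else if (name == "patterning") {
    lat <- build_lattice(size, size, "periodic")
    summaries <- list()
    for (cfg in list(delta_dominated = c(gD = 70, gJ = 20),
                     jagged_dominated = c(gD = 20, gJ = 70))) {
      regime <- if (cfg[["gD"]] > cfg[["gJ"]]) "delta_dominated" else "jagged_dominated"
      p <- apply_overrides(params, as.list(cfg))
      st0 <- random_initial_states(lat, p, seed = seed)
      run <- simulate_tissue(lat, st0, p, t_end = 240,
                             snapshot_times = c(120, 240), thresholds = th)
      for (sn in run) {
        add(sprintf("%s_t%03d.csv", regime, round(sn$time_h[1])),
            as.data.frame(sn), wcsv)
        ps <- pattern_summary(sn)
        summaries[[sprintf("%s_t%03d", regime, round(sn$time_h[1]))]] <-
          c(as.list(ps$fractions),
            mean_cluster_non_e = ps$mean_cluster_non_e,
            max_cluster_non_e = ps$max_cluster_non_e,
            unlike_neighbour_fraction = ps$unlike_neighbour_fraction,
            mean_nicd = ps$mean_nicd)
      }
    }
    add("pattern_summaries.json", summaries, wjson)
  } else if (name == "external_signals") {
    lat <- build_lattice(size, size, "periodic")
    p <- apply_overrides(params, list(gD = 20, gJ = 70))
    st0 <- random_initial_states(lat, p, seed = seed)
    base <- simulate_tissue(lat, st0, p, t_end = 120, snapshot_times = 120,
                            thresholds = th)
    stA <- snapshot_states(base[[1]])
    rows <- list()
    for (iext in c(0, 35, 70)) {
      run <- simulate_tissue(lat, stA, p, t_end = 120, snapshot_times = 120,
                             I_ext = iext, thresholds = th)
      rows[[length(rows) + 1]] <- data.frame(signal = "I_ext", level = iext,
                                             t(phenotype_fractions(run[[1]])))
    }
    for (sj in c(0, 2000, 4000)) {
      run <- simulate_tissue(lat, stA, p, t_end = 120, snapshot_times = 120,
                             sJ_ext = sj, thresholds = th)
      rows[[length(rows) + 1]] <- data.frame(signal = "sJ_ext", level = sj,
                                             t(phenotype_fractions(run[[1]])))
    }
    out <- do.call(rbind, rows)
    names(out) <- c("signal", "level", "f_E", "f_EM", "f_M")
    add("external_signals.csv", out, wcsv)
  } else if (name == "phenotypic_stability") {
    lat <- build_lattice(size, size, "periodic")
    p <- apply_overrides(params, list(gD = 20, gJ = 70))
    m <- find_stable_states(cell_environment(N_ext = 5000, J_ext = 2600), p,
                            n_starts = 24, seed = seed)
    m <- m[which.min(m$miR200), species_names()]
    st0 <- matrix(rep(as.numeric(m), each = lat$n_cells), lat$n_cells,
                  length(species_names()),
                  dimnames = list(NULL, species_names()))
    run <- simulate_tissue(lat, st0, p, t_end = 360,
                           snapshot_times = c(0, 120, 240, 360),
                           thresholds = th)
    fr <- do.call(rbind, lapply(run, function(sn) {
      data.frame(time_h = sn$time_h[1], t(phenotype_fractions(sn)))
    }))
    names(fr) <- c("time_h", "f_E", "f_EM", "f_M")
    add("stability_fractions.csv", fr, wcsv)
    add("stability_final.csv", as.data.frame(run[[length(run)]]), wcsv)
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# small FNV-1a style hash of the serialised parameter set, base R only
params_hash <- function(params) {
  s <- paste(utils::capture.output(utils::str(unclass(params),
                                              digits.d = 12)), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}
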