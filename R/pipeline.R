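# End-to-end orchestration: YAML configuration, staged execution
# (search -> extract -> purge -> relax -> vibrations -> deltas ->
# hierarchy), plain-text outputs and a reproducible run manifest.

tbo_config_error <- function(msg)
  stop(errorCondition(msg, class = "tbo_config_error"))

default_config <- function() {
  list(
    backend = "analytic",
    pes = list(file = NULL, dimension = 2, seed = 7,
               minima_range = c(3, 8)),
    molecule = list(xyz = NULL, dihedrals = NULL, bonds = NULL),
    mm = list(amplitudes = NULL, phases = NULL, bond_k = 30, angle_k = 3),
    search = list(budget = 100, n_init = NULL, e_cut = 2.0, seed = 1,
                  de_tol = 0.025, dd_tol = 10, window = 10),
    purge = list(d_tol = 15, e_tol = 0.01),
    relax = list(enabled = TRUE, fmax = 0.01),
    vibrations = list(enabled = NULL, temperature = 300, delta = 0.0025),
    deltas = list(csv = NULL),
    output = "tbo_run"
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Read a pipeline configuration
#'
#' Loads a YAML file (or takes a list) and fills in package defaults.
#' Dihedral definitions in config files are 0-based atom index quadruples;
#' they are converted to R's 1-based indexing internally.
#'
#' @param config Path to a YAML file, or a (possibly partial) config list.
#' @return A complete configuration list.
#' @export
read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      tbo_config_error(paste("config file not found:", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) tbo_config_error("config must be a list or a path")
  merge_config(default_config(), config)
}

build_backend <- function(cfg) {
  if (cfg$backend == "analytic") {
    pes <- if (!is.null(cfg$pes$file)) {
      if (!file.exists(cfg$pes$file))
        tbo_config_error(paste("PES file not found:", cfg$pes$file))
      read_pes_json(cfg$pes$file)
    } else {
      generate_test_pes(cfg$pes$dimension, cfg$pes$seed,
                        unlist(cfg$pes$minima_range))
    }
    list(calculator = pes, model = NULL)
  } else if (cfg$backend == "mm") {
    m <- cfg$molecule
    if (is.null(m$xyz) || !file.exists(m$xyz %||% ""))
      tbo_config_error(paste("molecule file not found:", m$xyz))
    if (is.null(m$dihedrals))
      tbo_config_error("molecule.dihedrals (0-based quadruples) is required")
    fr <- read_xyz(m$xyz)[[1]]
    dih <- lapply(m$dihedrals, function(q) as.integer(unlist(q)) + 1L)
    bonds <- if (!is.null(m$bonds))
      matrix(as.integer(unlist(m$bonds)), ncol = 2, byrow = TRUE) + 1L
    model <- molecule_model(fr$elements, fr$coords, dih, bonds = bonds)
    if (is.null(cfg$mm$amplitudes))
      tbo_config_error("mm.amplitudes (N x 3) are required for backend 'mm'")
    n <- length(dih)
    calc <- mm_calculator(
      model,
      matrix(unlist(cfg$mm$amplitudes), n, 3, byrow = TRUE),
      matrix(unlist(cfg$mm$phases %||% rep(0, 3 * n)), n, 3, byrow = TRUE),
      bond_k = cfg$mm$bond_k, angle_k = cfg$mm$angle_k)
    list(calculator = calc, model = model)
  } else {
    tbo_config_error(paste("unknown backend:", cfg$backend))
  }
}

#' Run the full conformer-search pipeline
#'
#' Executes search, surrogate minima extraction, duplicate purging,
#' relaxation (full Cartesian relaxation for molecule-backed calculators;
#' torsion-space minimization of the true potential for the analytic
#' backend), harmonic vibrational analysis (molecule backends), optional
#' high-level single-point deltas, and hierarchy assembly. All stage
#' outputs are written as plain text under the configured output
#' directory, together with a JSON run manifest; the same configuration
#' and seed reproduce the same manifest counts.
#'
#' @param config Path to a YAML config file or a config list (see
#'   [read_config()]).
#' @param output Optional output directory overriding the config value.
#' @return The run manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, output = NULL) {
  cfg <- read_config(config)
  if (!is.null(output)) cfg$output <- output
  be <- build_backend(cfg)
  calc <- be$calculator
  model <- be$model
  outdir <- cfg$output
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  sc <- search_config(budget = cfg$search$budget, n_init = cfg$search$n_init,
                      e_cut = cfg$search$e_cut, de_tol = cfg$search$de_tol,
                      dd_tol = cfg$search$dd_tol, window = cfg$search$window,
                      seed = cfg$search$seed)
  sr <- run_search(calc, sc, model = model)
  base <- min(sr$E_raw[is.finite(sr$E_raw)])

  cand <- extract_minima(sr$gp)
  purged <- purge_duplicates(cand, d_tol = cfg$purge$d_tol,
                             e_tol = cfg$purge$e_tol)
  dc <- torsion_columns(purged)

  # relaxation + (optionally) vibrations
  records <- NULL
  frames <- list()
  n_relax <- 0L
  vib_on <- cfg$vibrations$enabled %||% !is.null(model)
  for (i in seq_len(nrow(purged))) {
    t0 <- as.numeric(purged[i, dc])
    surr_raw <- inverse_transform_energy(purged$energy[i], sc$e_cut) + base
    if (!isTRUE(cfg$relax$enabled)) {
      rec <- data.frame(E_opt = surr_raw, E_surrogate = surr_raw)
      tfin <- t0
    } else if (is.null(model)) {
      rl <- relax_torsions(calc, t0)
      n_relax <- n_relax + 1L
      tfin <- rl$torsions
      rec <- data.frame(E_opt = rl$energy, E_surrogate = surr_raw)
    } else {
      geo <- set_torsions(model, t0)
      rl <- relax_structure(calc, geo, fmax = cfg$relax$fmax)
      n_relax <- n_relax + 1L
      tfin <- measure_torsions(rl$coords, model$dihedrals)
      rec <- data.frame(E_opt = rl$energy, E_surrogate = surr_raw)
      if (isTRUE(vib_on)) {
        va <- vibrational_analysis(calc, rl$coords, model$masses,
                                   temperature = cfg$vibrations$temperature,
                                   delta = cfg$vibrations$delta)
        rec$zpe <- va$zpe
        rec$f_vib <- va$f_vib
        rec$n_imaginary <- va$n_imaginary
      }
      frames[[i]] <- list(elements = model$elements, coords = rl$coords)
    }
    for (j in seq_along(tfin)) rec[[paste0("d", j)]] <- tfin[j]
    records <- rbind(records, rec)
  }

  # merge basins that collapsed onto one another during relaxation
  if (nrow(records) > 1) {
    records <- records[order(records$E_opt), , drop = FALSE]
    records <- records[!duplicated_basins(records, dc, cfg$purge$d_tol,
                                          cfg$purge$e_tol), , drop = FALSE]
  }
  records$label <- sprintf("c%03d", seq_len(nrow(records)))

  if (!is.null(cfg$deltas$csv))
    records <- apply_singlepoint_delta(records, cfg$deltas$csv)

  hier <- assemble_hierarchy(records)

  paths <- list(trace = file.path(outdir, "trace.csv"),
                minima = file.path(outdir, "minima.csv"),
                hierarchy_csv = file.path(outdir, "hierarchy.csv"),
                hierarchy_json = file.path(outdir, "hierarchy.json"),
                manifest = file.path(outdir, "manifest.json"))
  utils::write.csv(sr$trace, paths$trace, row.names = FALSE)
  utils::write.csv(purged, paths$minima, row.names = FALSE)
  utils::write.csv(hier$table, paths$hierarchy_csv, row.names = FALSE)
  jsonlite::write_json(list(stages = hier$stages, table = hier$table),
                       paths$hierarchy_json, dataframe = "rows",
                       digits = NA, auto_unbox = TRUE)
  if (length(frames) && !is.null(model)) {
    paths$conformers <- file.path(outdir, "conformers.xyz")
    write_xyz(Filter(Negate(is.null), frames), paths$conformers,
              comments = records$label)
  }

  manifest <- list(
    tool = "torsionbo",
    version = as.character(utils::packageVersion("torsionbo")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$search$seed,
    config = cfg,
    counts = list(
      n_evaluations = nrow(sr$X),
      n_failed_evaluations = sr$n_failed,
      n_minima_candidates = nrow(cand),
      n_minima_after_purge = nrow(purged),
      n_relaxations = n_relax,
      n_conformers = nrow(records)),
    converged_at = if (is.na(sr$converged_at)) NULL else sr$converged_at,
    fraction_transformed = sr$fraction_transformed,
    outputs = paths)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

# TRUE for rows that duplicate an earlier (lower-energy) basin; input
# must be sorted ascending by E_opt.
duplicated_basins <- function(records, dc, d_tol, e_tol) {
  n <- nrow(records)
  dup <- logical(n)
  for (i in seq_len(n)) {
    if (i == 1) next
    for (k in seq_len(i - 1)) {
      if (dup[k]) next
      if (all(periodic_distance(as.numeric(records[i, dc]),
                                as.numeric(records[k, dc])) < d_tol) &&
          abs(records$E_opt[i] - records$E_opt[k]) < e_tol) {
        dup[i] <- TRUE; break
      }
    }
  }
  dup
}
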