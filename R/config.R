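#' Full run configuration
#'
#' Aggregates every tunable of the workflow with defaults equal to the
#' published protocol wherever it states one: 24-unit chain with a 10 A gap,
#' 6 units per turn, stage schedule 0.001/0.01/0.1/1.1 pN/A for 5/15/30/30
#' ps, collisional thermostat (lambda 5 per ps, m0 = 1 a.m.u., 300 K), time
#' step 0.001 ps, first atom fixed, Calpha normalization exponent k = 5.
#' Round-trips losslessly through JSON (see [write_config()],
#' [read_config()]).
#'
#' @param ... named overrides of any top-level field.
#' @return A nested list of class `RunConfig`.
#' @export
RunConfig <- function(...) {
  cfg <- list(
    chirality_type = "L",
    n_units = 24L,
    gap = 10,
    helix = list(units_per_turn = 6L, rise_per_turn = 6, radius = 9,
                 handedness = "right"),
    scaffold = list(inner_offset = 2, outer_offset = 2),
    schedule = list(stiffness = c(0.001, 0.01, 0.1, 1.1),
                    duration = c(5, 15, 30, 30)),
    thermostat = list(lambda_rate = 5, m0 = 1, temperature = 300),
    integrator = list(dt = 0.001, fixed_atoms = 1L,
                      relaxation_duration = 30, save_every_ps = 1),
    chirality = list(k = 5L, window = 12L),
    base_seed = 1L,
    n_runs = 32L,
    out_dir = "pnt_out"
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config field: ", nm)
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      utils::modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  structure(cfg, class = "RunConfig")
}

#' @rdname RunConfig
#' @param config a `RunConfig`.
#' @param path file path (JSON).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname RunConfig
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(RunConfig, raw)
}

# materialize parameter objects from a config
.cfg_objects <- function(cfg) {
  list(
    helix = HelixParams(units_per_turn = cfg$helix$units_per_turn,
                        rise_per_turn = cfg$helix$rise_per_turn,
                        radius = cfg$helix$radius,
                        handedness = cfg$helix$handedness,
                        n_units = cfg$n_units),
    schedule = SpringSchedule(cfg$schedule$stiffness, cfg$schedule$duration),
    thermostat = ThermostatParams(cfg$thermostat$lambda_rate,
                                  cfg$thermostat$m0,
                                  cfg$thermostat$temperature,
                                  cfg$base_seed),
    integrator = IntegratorParams(cfg$integrator$dt,
                                  cfg$integrator$fixed_atoms,
                                  cfg$integrator$relaxation_duration,
                                  cfg$integrator$save_every_ps)
  )
}

#' Full desk-scale pipeline: build, assemble in batch, score, aggregate
#'
#' Builds the linear chain, constructs the scaffold, runs `n_runs`
#' independent assembly realizations (seeds `base_seed + 0 .. n_runs-1`),
#' scores each final structure with the Calpha index and windowed profile,
#' and aggregates the outcomes in the shape of the published statistics
#' table.  Deterministic given the config.
#'
#' @param config a [RunConfig].
#' @param mirror_run also negate the monomer chirality and mirror the
#'   collision impulses (parity experiment).
#' @param write_outputs write per-run PDBs, the batch TSV, the resolved
#'   config and a summary to `config$out_dir`.
#' @return A list: `outcomes` (per-run data.frame), `totals`
#'   (=[stats_table()]), `config`.
#' @export
run_pipeline <- function(config = RunConfig(), mirror_run = FALSE,
                         write_outputs = FALSE) {
  if (config$n_runs < 1) stop("configuration error: n_runs must be >= 1")
  obj <- .cfg_objects(config)
  chain <- build_linear_chain(config$chirality_type, config$n_units,
                              config$gap)
  if (mirror_run) chain <- mirror(chain)
  scaffold <- build_scaffold(chain, obj$helix,
                             inner_offset = config$scaffold$inner_offset,
                             outer_offset = config$scaffold$outer_offset)
  out_dir <- NULL
  if (write_outputs) {
    out_dir <- config$out_dir
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, file.path(out_dir, "resolved_config.json"))
  }
  outcomes <- run_batch(chain, scaffold, obj$schedule, obj$thermostat,
                        obj$integrator, n_runs = config$n_runs,
                        base_seed = config$base_seed,
                        window = config$chirality$window,
                        out_dir = out_dir, mirror_impulses = mirror_run)
  totals <- stats_table(outcomes)
  if (write_outputs) {
    s <- totals
    writeLines(c(
      sprintf("runs\t%d", nrow(outcomes)),
      sprintf("formula_left\t%d (%d%%)", s$formula$n_left, s$formula$pct_left),
      sprintf("formula_right\t%d (%d%%)", s$formula$n_right,
              s$formula$pct_right),
      sprintf("expert_left\t%g (%d%%)", s$expert$sum_left, s$expert$pct_left),
      sprintf("expert_right\t%g (%d%%)", s$expert$sum_right,
              s$expert$pct_right)),
      file.path(out_dir, "stats_summary.tsv"))
  }
  list(outcomes = outcomes, totals = totals, config = config)
}
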