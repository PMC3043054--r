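# Pipeline orchestration, deterministic table output and packaged fixtures.

#' Load the packaged residence-time table
#'
#' Per-shell residence fit constants (fast and slow time constants and the
#' relative RMS error of the bi-exponential fit) for the eight-shell scheme,
#' shipped as a plain-text fixture.
#'
#' @return data.frame with `shell`, `d_lo`, `d_hi` (nm), `tau1`, `tau2`
#'   (ps), `rel_rms_error`.
#' @export
load_residence_table <- function() {
  utils::read.csv(system.file("extdata", "table1_residence.csv",
                              package = "ionshells"))
}

#' Load the packaged per-residue encounter table
#'
#' Total binding times and primary/secondary encounter counts per residue
#' for the wild-type protein and its E60D mutant (ten 100 ns runs each;
#' binding times in ps). Blank count cells in the source are `NA`.
#'
#' @return data.frame with `residue`, `wt_binding_time`, `wt_primary`,
#'   `wt_secondary`, `e60d_binding_time`, `e60d_primary`, `e60d_secondary`.
#' @export
load_encounter_table <- function() {
  utils::read.csv(system.file("extdata", "table2_encounters.csv",
                              package = "ionshells"))
}

validate_config <- function(config) {
  defaults <- list(shell_boundaries = c(0.35, 0.60, 0.85, 1.10, 1.35, 1.60,
                                        1.85, 2.10),
                   contact_cutoff = 0.35, grace_time = 2,
                   msd_fit_window = c(10, 100), min_fit_count = 10L,
                   heavy_atoms_only = TRUE, seed = 1L,
                   occupancy_bin_width = 0.01, occupancy_d_max = 1.2,
                   fit_order = 2L, min_events_for_fit = 30L,
                   granularity = "residue")
  config <- utils::modifyList(defaults, config)
  if (any(diff(config$shell_boundaries) <= 0))
    stop("config error: shell_boundaries must be strictly increasing")
  if (config$grace_time < 0) stop("config error: grace_time must be >= 0")
  if (config$contact_cutoff <= 0) stop("config error: contact_cutoff <= 0")
  if (is.null(config$input)) stop("config error: no input specified")
  config
}

#' Run the full shell/residence/diffusion/encounter pipeline
#'
#' Executes the stages distance -> shells -> occupancy -> residence ->
#' survival fits -> diffusion -> contacts -> encounter classification ->
#' summary on one trajectory, and optionally writes all result tables plus
#' a reproducibility manifest.
#'
#' @param config a list (or path to a YAML/JSON file) with an `input` entry
#'   and optional overrides of the analysis defaults. `input` is either
#'   `list(type = "internal", path = <file>)` for a trajectory in the
#'   internal tabular format, or `list(type = "langevin", params = <list>)`
#'   / `list(type = "free", params = <list>)` to generate data with
#'   [gen_langevin_surface()] / [gen_free_diffusion()].
#' @param out_dir if non-`NULL`, result tables (CSV + JSON) and
#'   `manifest.json` are written here.
#' @return list of class `"ionshells_run"` with `results` (named list of
#'   tables/objects) and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  inp <- config$input
  gen <- NULL
  traj <- switch(inp$type,
    internal = read_internal(inp$path),
    langevin = {
      gen <- do.call(gen_langevin_surface,
                     c(inp$params, list(seed = config$seed)))
      gen$trajectory
    },
    free = {
      gen <- do.call(gen_free_diffusion,
                     c(inp$params, list(seed = config$seed)))
      gen$trajectory
    },
    stop("config error: unknown input type ", inp$type))

  scheme <- shell_scheme(config$shell_boundaries)
  results <- list()
  dt <- time_step(traj)
  has_protein <- nrow(traj$atoms) > 0L

  if (has_protein) {
    ds <- min_distance_series(traj, heavy_only = config$heavy_atoms_only)
    shells <- assign_shells(ds, scheme)
    results$occupancy <- occupancy_histogram(ds, config$occupancy_bin_width,
                                             config$occupancy_d_max)
    events <- extract_residence_events(shells, traj$times, config$grace_time)
    results$residence_events <- events

    fits <- list()
    for (s in seq_len(scheme$n_shells)) {
      es <- events[events$shell == s, , drop = FALSE]
      if (nrow(es) < config$min_events_for_fit) next
      sc <- survival_curve(es$duration, dt)
      fit <- tryCatch(fit_exponential(sc, order = config$fit_order,
                                      min_count = config$min_fit_count),
                      error = function(e) NULL)
      if (!is.null(fit))
        fits[[length(fits) + 1L]] <- data.frame(
          shell = s, tau1 = fit$tau[1],
          tau2 = if (fit$order == 2L) fit$tau[2] else NA_real_,
          rel_rms_error = fit$rel_rms_error, n_events = nrow(es))
    }
    results$residence_fits <- if (length(fits)) do.call(rbind, fits) else NULL

    contacts <- detect_contacts(traj, cutoff = config$contact_cutoff,
                                granularity = config$granularity,
                                grace_time = config$grace_time,
                                heavy_only = config$heavy_atoms_only)
    first_shell <- shells == 1L
    cev <- classify_encounters(contacts, first_shell, traj$times,
                               config$grace_time)
    results$encounters <- cev
    results$binding_table <- binding_table(cev)
    results$transfers <- transfer_counts(cev)
    results$encounter_summary <- summary_stats(cev, traj$times)
  }

  xu <- unwrap_ion(traj)
  msd <- msd_curve(xu, dt = dt,
                   max_lag = min(n_frames(traj) - 1L,
                                 ceiling(config$msd_fit_window[2] / dt)))
  results$msd <- msd
  results$diffusion <- tryCatch(estimate_D(msd, config$msd_fit_window),
                                warning = function(w)
                                  suppressWarnings(
                                    estimate_D(msd, config$msd_fit_window)),
                                error = function(e) NULL)

  if (!is.null(config$kinetics)) {
    kp <- config$kinetics
    dsr <- ds_rate(ds_parameters(
      D_ion = kp$D_ion, D_protein = kp$D_protein %||% 0,
      contact_radius = kp$contact_radius,
      charge_product = kp$charge_product %||% 0,
      ionic_strength = kp$ionic_strength %||% 0.150))
    results$kinetics <- c(list(k_on = dsr$k_on, R_eff = dsr$R_eff),
                          if (!is.null(kp$concentration))
                            pseudo_first_order(dsr, kp$concentration))
  }

  manifest <- list(
    tool = "ionshells",
    version = as.character(utils::packageVersion("ionshells")),
    seed = config$seed,
    config = config[setdiff(names(config), "input")],
    input = if (identical(inp$type, "internal"))
      list(type = "internal", path = inp$path,
           md5 = unname(tools::md5sum(inp$path)))
    else inp,
    stages = names(results))

  run <- structure(list(results = results, manifest = manifest),
                   class = "ionshells_run")
  if (!is.null(out_dir)) write_report(run, out_dir)
  run
}

read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @export
print.ionshells_run <- function(x, ...) {
  cat("ionshells pipeline run (seed", x$manifest$seed, ")\n")
  cat("  stages:", paste(x$manifest$stages, collapse = ", "), "\n")
  invisible(x)
}

# deterministic number formatting for report files
fmt_num <- function(x) {
  if (is.numeric(x)) sapply(x, function(v)
    if (is.na(v)) "NA" else sprintf("%.8g", v)) else as.character(x)
}

#' Write pipeline result tables
#'
#' Every tabular result is written as CSV and JSON with a fixed column
#' order and fixed float precision (`%.8g`), so re-running an identical
#' pipeline produces byte-identical files. The manifest goes to
#' `manifest.json`.
#'
#' @param run an `ionshells_run` (or a bare named list of data.frames).
#' @param out_dir output directory, created if missing.
#' @param formats subset of `c("csv", "json")`.
#' @return invisibly, the paths written.
#' @export
write_report <- function(run, out_dir, formats = c("csv", "json")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- if (inherits(run, "ionshells_run")) run$results else run
  paths <- character(0)
  for (nm in names(results)) {
    obj <- results[[nm]]
    if (is.data.frame(obj)) {
      df <- as.data.frame(lapply(obj, fmt_num), stringsAsFactors = FALSE)
      names(df) <- names(obj)
      if ("csv" %in% formats) {
        p <- file.path(out_dir, paste0(nm, ".csv"))
        utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
        paths <- c(paths, p)
      }
      if ("json" %in% formats) {
        p <- file.path(out_dir, paste0(nm, ".json"))
        jsonlite::write_json(df, p, pretty = TRUE)
        paths <- c(paths, p)
      }
    } else if (is.list(obj)) {
      flat <- obj[vapply(obj, function(v)
        is.atomic(v) && length(v) == 1L, logical(1))]
      if (length(flat) && "json" %in% formats) {
        p <- file.path(out_dir, paste0(nm, ".json"))
        jsonlite::write_json(flat, p, auto_unbox = TRUE, pretty = TRUE,
                             digits = NA)
        paths <- c(paths, p)
      }
    }
  }
  if (inherits(run, "ionshells_run")) {
    p <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(run$manifest, p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
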