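#' Convert a tissue mass concentration to molarity
#'
#' `mass_conc` in micrograms per gram fresh weight, with tissue density
#' in g/mL, divided by the molar mass in g/mol gives millimolar:
#' ug/g * g/mL / (g/mol) = mmol/L. For 3-hydroxykynurenine
#' (molar mass 224.21 g/mol) a tissue level of 396 ug/g fresh weight is
#' about 1.7 mM.
#'
#' @param mass_conc Mass concentration, ug per g fresh weight.
#' @param molar_mass Molar mass, g/mol (> 0).
#' @param density Tissue density, g/mL (default 1).
#' @return Molar concentration in mM.
#' @export
#' @examples
#' tissue_conc_to_molar(396, 224.21)  # ~1.77 mM
tissue_conc_to_molar <- function(mass_conc, molar_mass, density = 1) {
  stop_if_not_scalar_finite(molar_mass, "molar_mass", positive = TRUE)
  if (any(!is.finite(mass_conc)) || any(mass_conc <= 0)) {
    stop("`mass_conc` must be positive", call. = FALSE)
  }
  stop_if_not_scalar_finite(density, "density", positive = TRUE)
  mass_conc * density / molar_mass
}

#' Molar mass of 3-hydroxykynurenine (g/mol)
#' @export
MOLAR_MASS_3HOK <- 224.21

# YAML 1.1 parses a bare `n:` mapping key as the boolean FALSE; restore
# the literal key so `n: 20` in a group spec means what it says.
restore_n_keys <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm)) names(x) <- ifelse(nm == "FALSE", "n", nm)
  lapply(x, restore_n_keys)
}

apply_overrides <- function(defaults, overrides) {
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  defaults
}

# Deterministic per-fly seed derived from the run seed; kept < 2^31.
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 7919 + counter * 104729) %% 2147483647)
}

#' Run a simulated (or stored-profile) cohort end to end
#'
#' Simulation mode generates per-fly walker trajectories per group,
#' quantizes them, computes SLA profiles, and writes `profiles.csv`,
#' `summary.csv` (mean +/- SEM per group and parameter),
#' `comparison.csv` (pairwise Mann-Whitney tests with tiers) and
#' `manifest.json` (seed, parameters, package version, MD5 checksum of
#' every output). Rerunning with the same config and seed reproduces
#' byte-identical tables. Profile mode skips simulation and compares an
#' existing per-fly profile CSV.
#'
#' Config (R list, or path to a YAML/JSON file):
#' \preformatted{
#' mode: simulate            # or "profiles"
#' seed: 1
#' groups:                   # simulate mode
#'   - label: CS
#'     n: 20
#'     age: 5                # optional
#'     walker: {run_speed_mean: 5}   # walker_params overrides
#'   - label: cd1
#'     n: 20
#'     walker: {run_speed_mean: 3}
#' walker_defaults: {duration: 300, frame_rate: 10}
#' analysis: {quantum: 1, rest_threshold: 1}
#' profiles: path/to/profiles.csv   # profiles mode
#' baseline_age: 5
#' }
#'
#' @param config List or path to a YAML/JSON config file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `profiles`, `summary`, `comparison`
#'   and `manifest`.
#' @export
run_cohort <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      restore_n_keys(yaml::read_yaml(config))
    }
  }
  mode <- config$mode %||% "simulate"
  seed <- config$seed %||% 1L
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if (mode == "simulate") {
    if (is.null(config$groups) || length(config$groups) == 0) {
      stop("simulate mode needs `groups`", call. = FALSE)
    }
    acfg <- do.call(analysis_config, as.list(config$analysis %||% list()))
    wdef <- as.list(config$walker_defaults %||% list())
    counter <- 0L
    profiles <- do.call(rbind, lapply(seq_along(config$groups), function(gi) {
      g <- config$groups[[gi]]
      if (is.null(g$label) || is.null(g$n)) {
        stop("each group needs `label` and `n`", call. = FALSE)
      }
      wargs <- apply_overrides(wdef, as.list(g$walker %||% list()))
      do.call(rbind, lapply(seq_len(g$n), function(j) {
        counter <<- counter + 1L
        wargs$seed <- derive_seed(seed, counter)
        wp <- do.call(walker_params, wargs)
        traj <- trajectory_from_truth(simulate_walker(wp))
        prof <- sla_profile(traj, acfg,
                            fly_id = sprintf("%s_%03d", g$label, j))
        prof$strain <- g$label
        prof$age <- g$age %||% NA
        prof
      }))
    }))
  } else if (mode == "profiles") {
    if (is.null(config$profiles) || !file.exists(config$profiles)) {
      stop("profiles mode needs an existing `profiles` CSV path",
           call. = FALSE)
    }
    profiles <- read.csv(config$profiles)
    if (!"strain" %in% names(profiles)) {
      stop("profile CSV must have a `strain` column", call. = FALSE)
    }
  } else {
    stop("unknown mode: ", mode, call. = FALSE)
  }

  summary_tab <- summarize_profiles(profiles)
  comparison <- tryCatch(
    build_comparison_table(profiles,
                           baseline_age = config$baseline_age %||% 5),
    error = function(e) NULL)

  paths <- c(profiles = file.path(out_dir, "profiles.csv"),
             summary = file.path(out_dir, "summary.csv"))
  write.csv(profiles, paths[["profiles"]], row.names = FALSE)
  write.csv(summary_tab, paths[["summary"]], row.names = FALSE)
  if (!is.null(comparison)) {
    paths <- c(paths, comparison = file.path(out_dir, "comparison.csv"))
    write.csv(comparison, paths[["comparison"]], row.names = FALSE)
  }
  manifest <- list(
    mode = mode, seed = seed,
    package_version = as.character(packageVersion("flysla")),
    config = config,
    outputs = lapply(as.list(paths), function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    }))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(profiles = profiles, summary = summary_tab,
                 comparison = comparison, manifest = manifest))
}
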