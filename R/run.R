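# Reproducible-run dispatcher: one entry point with subcommands tying the
# modules into on-disk runs (a thin Rscript wrapper ships in
# inst/scripts/polarflux.R). Every output directory gets a manifest with
# input hashes, the seed, and the package version.

run_manifest <- function(out_dir, config, inputs = character(0)) {
  hashes <- purrr::map_chr(inputs, function(f) {
    if (file.exists(f)) as.character(tools::md5sum(f)) else NA_character_
  })
  list(
    package = "polarflux",
    version = as.character(utils::packageVersion("polarflux")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed %||% NA,
    inputs = as.list(setNames(hashes, inputs)),
    config = config[setdiff(names(config), "out_dir")]
  )
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  path
}

#' Run a polarflux pipeline command
#'
#' Commands: `"efm"` (read network, enumerate or import modes, optionally
#' filter, export TSV), `"select"` (PSYA/YSA/CMOA selection to JSON),
#' `"physio"` (simulate or fit the physiology model), `"profiles"`
#' (render an exponential-phase profile from a selected mode), `"hcm"`
#' (simulate a two-family cybernetic model), `"empa"` (perturbation path +
#' report), `"synth"` (write a synthetic culture CSV). Configuration is a
#' named list or a JSON file path; all outputs land in `config$out_dir`
#' together with a `manifest.json`.
#'
#' @param command One of `"efm"`, `"select"`, `"physio"`, `"profiles"`,
#'   `"hcm"`, `"empa"`, `"synth"`.
#' @param config Named list or path to a JSON config.
#' @return Invisibly, a named list of the files written.
#' @export
run_polarflux <- function(command = c("efm", "select", "physio", "profiles",
                                      "hcm", "empa", "synth"),
                          config) {
  command <- match.arg(command)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  out_dir <- config$out_dir %||% abort("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  inputs <- character(0)

  load_net <- function() {
    if (!is.null(config$network)) {
      inputs <<- c(inputs, config$network)
      read_network(config$network, format = config$format %||% "tsv",
                   biomass = config$biomass)
    } else {
      toy_network(config$toy %||% "two_substrate_mini",
                  seed = config$seed %||% 1L)
    }
  }
  load_ems <- function(net) {
    if (!is.null(config$em_matrix)) {
      inputs <<- c(inputs, config$em_matrix)
      import_efms(config$em_matrix, net)
    } else {
      enumerate_efms(net)
    }
  }

  written <- list()
  if (command == "efm") {
    net <- load_net()
    ems <- load_ems(net)
    if (!is.null(config$constraints)) ems <- filter_efms(ems, unlist(config$constraints))
    written$modes <- export_efms(ems, file.path(out_dir, "modes.tsv"))
    written$summary <- write_json_out(
      list(n_modes = n_modes(ems), n_reactions = ncol(ems$modes),
           provenance = ems$provenance[[1]]),
      file.path(out_dir, "efm_summary.json"))
  } else if (command == "select") {
    net <- load_net()
    ems <- load_ems(net)
    if (!is.null(config$constraints)) ems <- filter_efms(ems, unlist(config$constraints))
    exp <- experimental_point(unlist(config$experimental_yields))
    method <- config$method %||% "psya"
    aset <- if (method == "ysa") ysa_select(ems, exp) else select_active_set(ems, exp)
    lumped <- lump_modes(aset, ems)
    written$selection <- write_json_out(
      list(method = method, members = aset$members, weights = aset$weights,
           upsilon = aset$scores, contains_point = aset$contains_point,
           residual = aset$residual,
           lumped_flux = as.list(unclass(lumped))),
      file.path(out_dir, "selection.json"))
  } else if (command == "physio") {
    p <- do.call(physio_params, config$params)
    if (!is.null(config$data)) {
      inputs <- c(inputs, config$data)
      data <- tibble::as_tibble(utils::read.csv(config$data))
      fit <- fit_physio(data, p, dt = config$dt %||% 0.1)
      written$params <- write_json_out(
        as.list(fit$params[PHYSIO_PAR_NAMES]),
        file.path(out_dir, "fitted_params.json"))
      written$report <- write_json_out(fit$report, file.path(out_dir, "fit_report.json"))
    } else {
      sim <- simulate_culture(p, t_end = config$t_end %||% 144,
                              dt = config$dt %||% 0.1)
      written$series <- file.path(out_dir, "culture.csv")
      utils::write.csv(sim, written$series, row.names = FALSE)
    }
  } else if (command == "profiles") {
    net <- load_net()
    ems <- load_ems(net)
    em <- setNames(ems$modes[config$mode %||% 1L, ], colnames(ems$modes))
    p <- do.call(physio_params, config$params)
    prof <- render_profiles(em, net, p, init = tibble::as_tibble(config$init),
                            horizon = config$horizon %||% 48,
                            dt = config$dt %||% 0.1)
    written$profiles <- file.path(out_dir, "profiles.csv")
    utils::write.csv(prof, written$profiles, row.names = FALSE)
  } else if (command == "hcm") {
    net <- load_net()
    ems <- load_ems(net)
    fams <- purrr::map(config$families, function(f) {
      hcm_family(setNames(ems$modes[f$mode, ], colnames(ems$modes)), net,
                 preferential = f$preferential, label = f$label %||% f$preferential)
    })
    cp <- cybernetic_params(k = unlist(config$k), K = unlist(config$K),
                            alpha = config$alpha %||% 0.01,
                            beta = config$beta %||% 0.05)
    traj <- simulate_hcm(fams, cp, init = unlist(config$init), net = net,
                         t_end = config$t_end %||% 144, dt = config$dt %||% 0.1)
    written$trajectory <- file.path(out_dir, "hcm_trajectory.csv")
    utils::write.csv(traj, written$trajectory, row.names = FALSE)
    if (!is.null(config$snapshot_times)) {
      snaps <- flux_snapshots(traj, unlist(config$snapshot_times), fams)
      written$snapshots <- file.path(out_dir, "flux_snapshots.tsv")
      utils::write.table(snaps, written$snapshots, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  } else if (command == "empa") {
    net <- load_net()
    ems <- load_ems(net)
    q <- perturbation_query(config$target,
                            direction = config$direction %||% "increase",
                            stop_rule = config$stop_rule %||% "fold_change",
                            fold = config$fold %||% 10)
    path <- perturbation_path(ems, start = config$start %||% 1L, query = q)
    written$path <- file.path(out_dir, "perturbation_path.tsv")
    utils::write.table(path, written$path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(config$tracked)) {
      rep <- path_report(path, ems, unlist(config$tracked))
      written$report <- file.path(out_dir, "path_report.tsv")
      utils::write.table(rep, written$report, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  } else if (command == "synth") {
    p <- do.call(physio_params, config$params)
    obs <- synth_culture(p, sigma = config$sigma %||% 0.05,
                         seed = config$seed %||% 1L)
    written$series <- file.path(out_dir, "synthetic_culture.csv")
    utils::write.csv(obs, written$series, row.names = FALSE)
  }
  write_json_out(run_manifest(out_dir, config, inputs),
                 file.path(out_dir, "manifest.json"))
  inform(paste0("[", command, "] wrote ", length(written), " artifact(s) to ", out_dir))
  invisible(written)
}
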