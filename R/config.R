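#' Read an experiment configuration file
#'
#' Experiments are described by a small YAML document with blocks `lattice`
#' (`rows`, `cols`), `fitness_A` and `fitness_B` (a `kind` plus that kind's
#' parameters, see [fitness_spec]), `motility` (`m_A`, `m_B`), `protocol`
#' (`n_iters`, `n_configs`, `seed`, optional `max_updates`, `cascade_cap`,
#' `verbose`) and an optional `sweep` block (`variable`, `values`). Bundled
#' examples live under `system.file("extdata", "configs", package = "moranfield")`.
#'
#' @param path Path to a YAML config file.
#' @return The validated configuration list (defaults filled in).
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  validate_config(yaml::read_yaml(path))
}

config_defaults <- list(
  motility = list(m_A = 0, m_B = 0),
  protocol = list(n_iters = 10000, n_configs = 10, seed = NULL,
                  max_updates = NULL, cascade_cap = 1e6, verbose = FALSE)
)

#' Validate an experiment configuration
#'
#' Checks structure and the model's hard constraints (positive lattice
#' dimensions, non-negative fitness supports, `x` in `[0, 1]`, non-negative
#' motilities), naming the offending key in every error. Missing optional
#' blocks are filled with defaults.
#'
#' @param config A configuration list as produced by [read_experiment_config()].
#' @return The normalised configuration, invisibly usable downstream.
#' @export
validate_config <- function(config) {
  if (!is.list(config)) abort("config must be a named list.")
  for (key in c("lattice", "fitness_A", "fitness_B")) {
    if (is.null(config[[key]])) {
      abort(sprintf("config is missing required block `%s`.", key),
            class = "moranfield_config_error")
    }
  }
  lat <- config$lattice
  for (key in c("rows", "cols")) {
    v <- lat[[key]]
    if (is.null(v) || !is.numeric(v) || v < 1 || v != floor(v)) {
      abort(sprintf("`lattice$%s` must be a positive integer.", key),
            class = "moranfield_config_error")
    }
  }
  if (lat$rows * lat$cols < 2) {
    abort("`lattice$rows * lattice$cols` must be at least 2.",
          class = "moranfield_config_error")
  }
  config$motility <- modifyList(config_defaults$motility,
                                config$motility %||% list())
  config$protocol <- modifyList(config_defaults$protocol,
                                config$protocol %||% list(),
                                keep.null = TRUE)
  for (key in c("m_A", "m_B")) {
    if (config$motility[[key]] < 0) {
      abort(sprintf("`motility$%s` must be non-negative.", key),
            class = "moranfield_config_error")
    }
  }
  # building the specs runs their own invariant checks; re-label failures
  # with the config key so the user knows which block is at fault
  for (key in c("fitness_A", "fitness_B")) {
    tryCatch(spec_from_config(config[[key]]),
             error = function(e) {
               abort(sprintf("invalid `%s` block: %s", key, conditionMessage(e)),
                     class = "moranfield_config_error")
             })
  }
  if (!is.null(config$sweep)) {
    sv <- config$sweep$variable
    if (is.null(sv) || !sv %in% c("delta", "x", "m_B", "r_B_mean")) {
      abort("`sweep$variable` must be one of delta, x, m_B, r_B_mean.",
            class = "moranfield_config_error")
    }
    if (length(config$sweep$values) == 0) {
      abort("`sweep$values` must be a non-empty numeric grid.",
            class = "moranfield_config_error")
    }
  }
  config
}

#' Build a fitness spec from a config block
#'
#' @param block Named list with a `kind` and the parameters of that kind.
#' @return A [fitness_spec].
#' @export
spec_from_config <- function(block) {
  kind <- block$kind
  if (is.null(kind)) abort("fitness block is missing `kind`.")
  get_par <- function(name) {
    v <- block[[name]]
    if (is.null(v)) abort(sprintf("fitness block `%s` is missing `%s`.", kind, name))
    v
  }
  switch(kind,
    constant = fitness_constant(get_par("mean")),
    uniform = fitness_uniform(get_par("mean"), get_par("width")),
    triangular = fitness_triangular(get_par("lower"), get_par("upper"),
                                    block$mode %||% 1),
    bimodal = fitness_bimodal(get_par("r1"), get_par("r2"), get_par("x")),
    checkerboard = fitness_checkerboard(get_par("r_low"), get_par("r_high")),
    abort(sprintf("unknown fitness kind `%s`.", kind))
  )
}

spec_label <- function(spec) {
  pars <- spec[setdiff(names(spec), "kind")]
  sprintf("%s(%s)", spec$kind,
          paste(names(pars), unlist(pars), sep = "=", collapse = ","))
}

#' Run a configured experiment and persist the results
#'
#' Executes the sweep (or single estimate) described by a configuration and
#' writes two files to `out_dir`: `<name>_results.csv` (one row per grid
#' point, with per-configuration fractions JSON-encoded so nothing is lost in
#' the flat table) and `<name>_manifest.json` (the full configuration, seed
#' and package version — everything needed to re-run the experiment exactly).
#'
#' @param config A config list or path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @param name Basename for the output files; defaults to `"experiment"`.
#' @return The result tibble, invisibly; paths of the written files are
#'   attached as attribute `"paths"`.
#' @export
run_experiment <- function(config, out_dir = ".", name = "experiment") {
  if (is.character(config)) config <- read_experiment_config(config)
  config <- validate_config(config)
  lat <- build_lattice(config$lattice$rows, config$lattice$cols)
  spec_A <- spec_from_config(config$fitness_A)
  spec_B <- spec_from_config(config$fitness_B)
  mot <- motility_params(config$motility$m_A, config$motility$m_B)
  prot <- config$protocol
  max_updates <- prot$max_updates %||% (100 * lat$n_sites^2)
  verbose <- isTRUE(prot$verbose)

  if (!is.null(config$sweep)) {
    res <- sweep_fixation(config$sweep$variable, config$sweep$values, lat,
                          spec_B = spec_B, spec_A = spec_A, motility = mot,
                          n_configs = prot$n_configs, n_iters = prot$n_iters,
                          seed = prot$seed, max_updates = max_updates,
                          cascade_cap = prot$cascade_cap, verbose = verbose)
  } else {
    est <- estimate_fixation(spec_B, spec_A, mot, lat,
                             n_configs = prot$n_configs, n_iters = prot$n_iters,
                             seed = prot$seed, max_updates = max_updates,
                             cascade_cap = prot$cascade_cap)
    if (verbose) {
      message(sprintf("  rho = %.5f (+/- %.5f)", est$rho, est$spread))
    }
    res <- tibble::tibble(variable = NA_character_, value = NA_real_,
                          rho = est$rho, spread = est$spread,
                          se_combined = combined_se(est),
                          n_configs = est$n_configs, n_iters = est$n_iters,
                          per_config = list(est$per_config))
  }

  flat <- dplyr::mutate(
    dplyr::as_tibble(res),
    per_config = purrr::map_chr(.data$per_config,
                                ~ as.character(jsonlite::toJSON(.x$fraction, digits = NA))),
    spec_B = spec_label(spec_B), spec_A = spec_label(spec_A),
    m_A = mot$m_A, m_B = mot$m_B,
    rows = lat$rows, cols = lat$cols,
    seed = prot$seed %||% NA_integer_
  )
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  csv_path <- file.path(out_dir, paste0(name, "_results.csv"))
  manifest_path <- file.path(out_dir, paste0(name, "_manifest.json"))
  utils::write.csv(flat, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(config = config,
         package = "moranfield",
         version = as.character(packageVersion("moranfield")),
         results_csv = basename(csv_path)),
    manifest_path, auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA)
  attr(res, "paths") <- c(results = csv_path, manifest = manifest_path)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line driver
#'
#' Thin shell entry point over the package's functions, used by the
#' `inst/cli/moranfield` script. Subcommands:
#' \describe{
#'   \item{estimate / sweep}{`--config <yaml>` plus optional `--out-dir`,
#'     `--name`, `--seed`, `--n-iters`, `--n-configs`, `--verbose` overrides;
#'     runs [run_experiment()].}
#'   \item{oracle}{`--rows --cols` with constant or checkerboard fitness
#'     options; prints the exact small-lattice fixation probabilities as JSON.}
#'   \item{analytic}{`--r --n` (well-mixed Moran) or `--r1 --r2 --x`
#'     (bimodal approximation); prints JSON.}
#' }
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: moranfield <estimate|sweep|oracle|analytic> [options]"
  if (length(args) < 1L) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1L]
  rest <- args[-1L]
  status <- tryCatch({
    switch(cmd,
      estimate = ,
      sweep = cli_run_experiment(cmd, rest),
      oracle = cli_oracle(rest),
      analytic = cli_analytic(rest),
      {
        message(usage)
        1L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_run_experiment <- function(cmd, args) {
  opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character"),
    optparse::make_option("--out-dir", type = "character", default = ".",
                          dest = "out_dir"),
    optparse::make_option("--name", type = "character", default = "experiment"),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--n-iters", type = "integer", default = NULL,
                          dest = "n_iters"),
    optparse::make_option("--n-configs", type = "integer", default = NULL,
                          dest = "n_configs"),
    optparse::make_option("--verbose", action = "store_true", default = FALSE)
  )), args = args)
  if (is.null(opts$config)) abort(sprintf("`%s` needs --config <yaml>.", cmd))
  config <- read_experiment_config(opts$config)
  if (cmd == "estimate") config$sweep <- NULL
  if (cmd == "sweep" && is.null(config$sweep)) {
    abort("`sweep` needs a sweep block in the config.")
  }
  for (key in c("seed", "n_iters", "n_configs")) {
    if (!is.null(opts[[key]])) config$protocol[[key]] <- opts[[key]]
  }
  if (opts$verbose) config$protocol$verbose <- TRUE
  res <- run_experiment(config, out_dir = opts$out_dir, name = opts$name)
  paths <- attr(res, "paths")
  message(sprintf("results: %s\nmanifest: %s", paths["results"], paths["manifest"]))
  0L
}

cli_oracle <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
    optparse::make_option("--rows", type = "integer"),
    optparse::make_option("--cols", type = "integer"),
    optparse::make_option("--r-a", type = "double", default = 1, dest = "r_a"),
    optparse::make_option("--r-b", type = "double", default = 1, dest = "r_b"),
    optparse::make_option("--checkerboard", type = "character", default = NULL,
                          help = "mutant checkerboard field as 'low,high'")
  )), args = args)
  if (is.null(opts$rows) || is.null(opts$cols)) {
    abort("`oracle` needs --rows and --cols.")
  }
  lat <- build_lattice(opts$rows, opts$cols)
  r_b <- if (!is.null(opts$checkerboard)) {
    v <- as.numeric(strsplit(opts$checkerboard, ",")[[1]])
    if (length(v) != 2 || anyNA(v)) abort("--checkerboard must be 'low,high'.")
    checkerboard_field(v[1], v[2], lat)
  } else {
    rep(opts$r_b, lat$n_sites)
  }
  res <- exact_fixation_probability(lat, fitness_field(rep(opts$r_a, lat$n_sites), r_b))
  cat(as.character(jsonlite::toJSON(res[c("per_site", "average", "n_sites")],
                                    auto_unbox = TRUE, digits = NA)), "\n")
  0L
}

cli_analytic <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
    optparse::make_option("--r", type = "double", default = NULL),
    optparse::make_option("--n", type = "integer", default = NULL),
    optparse::make_option("--r1", type = "double", default = NULL),
    optparse::make_option("--r2", type = "double", default = NULL),
    optparse::make_option("--x", type = "double", default = NULL)
  )), args = args)
  out <- list()
  if (!is.null(opts$r) && !is.null(opts$n)) {
    out$moran_fixation <- moran_fixation(opts$r, opts$n)
  }
  if (!is.null(opts$r1) && !is.null(opts$r2) && !is.null(opts$x)) {
    out$bimodal_moran_approx <- bimodal_moran_approx(opts$r1, opts$r2, opts$x)
  }
  if (length(out) == 0) {
    abort("`analytic` needs --r and --n, or --r1, --r2 and --x.")
  }
  cat(as.character(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA)), "\n")
  0L
}
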