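# Configuration, serialization and the command line -----------------------
#
# Run configurations are single YAML files with four blocks:
#
#   strategy:   name: pdne1            # + options/overrides
#   demography: Rm: 6                  # dd_exponent optional
#   release:    rho: 0.1               # cadence, start, stop optional
#   experiment: mode: simulate         # simulate | search | sweep | compare
#               horizon: 36            # + target, param, grid, strategies
#   seed:       null                   # reserved; the engine is
#                                      # deterministic and never draws
#
# CSV outputs use '.' as the decimal separator regardless of locale; every
# run writes a JSON manifest with the resolved parameters, the config file's
# md5 and the package version, so identical configs give byte-identical
# outputs.

#' Read and validate a run configuration
#'
#' @param path Path to a YAML run configuration.
#' @return An object of class `run_config`: validated list with resolved
#'   `strategy` (a `gd_strategy`), `lc`, `release` and `experiment` blocks.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (block in c("strategy", "demography", "release", "experiment"))
    if (is.null(cfg[[block]]))
      stop("config `", path, "`: missing block `", block, "`", call. = FALSE)
  sb <- cfg$strategy
  if (is.null(sb$name)) stop("config: strategy block needs `name`",
                             call. = FALSE)
  if (!tolower(sb$name) %in% STRATEGY_NAMES)
    stop("config: unknown strategy `", sb$name, "` (known: ",
         paste(STRATEGY_NAMES, collapse = ", "), ")", call. = FALSE)
  args <- sb[setdiff(names(sb), "name")]
  strategy <- do.call(make_strategy, c(list(name = sb$name), args))

  db <- cfg$demography
  if (is.null(db$Rm)) stop("config: demography block needs `Rm`",
                           call. = FALSE)
  lc <- life_cycle(db$Rm, db$dd_exponent %||% 1)

  rb <- cfg$release
  release <- release_schedule(rb$rho %||% 0,
                              cadence = rb$cadence %||% "every",
                              start = rb$start %||% 1L,
                              stop = rb$stop %||% Inf,
                              genotype = rb$genotype)

  eb <- cfg$experiment
  mode <- match.arg(eb$mode %||% "simulate",
                    c("simulate", "search", "sweep", "compare"))
  structure(list(strategy = strategy, lc = lc, release = release,
                 mode = mode, experiment = eb, raw = cfg, path = path),
            class = "run_config")
}

#' Execute a run configuration
#'
#' Dispatches on the experiment mode, writes the result CSV (plus a JSON
#' manifest) into `out_dir` and returns the result object invisibly.
#'
#' @param rc A `run_config` from [read_run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The result object (`gd_sim`, `gd_search` or a data frame).
#' @export
execute_run_config <- function(rc, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  eb <- rc$experiment
  horizon <- as.integer(eb$horizon %||% 36L)
  target <- eb$target %||% 0.95

  result <- switch(
    rc$mode,
    simulate = {
      sim <- simulate_release(rc$strategy, rc$lc, rc$release, horizon)
      write_timeseries_csv(sim, file.path(out_dir, "timeseries.csv"))
      sim
    },
    search = {
      r <- min_release_rate(rc$strategy, rc$lc, target = target,
                            horizon = horizon,
                            rho_max = eb$rho_max %||% 20,
                            tol = eb$tol %||% 1e-4,
                            metric = eb$metric %||% "first_passage")
      df <- data.frame(strategy = r$strategy_name, Rm = r$Rm,
                       target = r$target, horizon = r$horizon,
                       rho_star = r$rho_star, attainable = r$attainable,
                       achieved_generation = r$achieved_generation)
      write_csv_(df, file.path(out_dir, "search.csv"))
      r
    },
    sweep = {
      if (is.null(eb$param) || is.null(eb$grid))
        stop("config: sweep mode needs `param` and `grid`", call. = FALSE)
      df <- parameter_sweep(rc$strategy, eb$param, as.numeric(eb$grid),
                            rc$lc, target = target, horizon = horizon,
                            rho_max = eb$rho_max %||% 20,
                            tol = eb$tol %||% 1e-4)
      write_csv_(df, file.path(out_dir, "sweep.csv"))
      df
    },
    compare = {
      others <- as.character(eb$strategies %||%
                               setdiff(STRATEGY_NAMES, c("pdne2")))
      ref <- min_release_rate(rc$strategy, rc$lc, target = target,
                              horizon = horizon)
      rows <- lapply(others, function(nm) {
        r <- min_release_rate(make_strategy(nm), rc$lc, target = target,
                              horizon = horizon)
        data.frame(strategy = nm, Rm = rc$lc$Rm, target = target,
                   horizon = horizon, rho_star = r$rho_star,
                   attainable = r$attainable,
                   fold_vs_reference = if (r$attainable && ref$attainable)
                     fold_efficiency(r, ref) else NA_real_)
      })
      df <- do.call(rbind, rows)
      attr(df, "reference_rho") <- ref$rho_star
      write_csv_(df, file.path(out_dir, "compare.csv"))
      df
    })

  write_manifest(rc, out_dir)
  invisible(result)
}

write_csv_ <- function(df, path) {
  utils::write.csv(format(df, trim = TRUE, digits = 15, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulation time series as CSV
#'
#' Columns: generation, females_rel, males_rel, one column per allele
#' frequency, load.
#'
#' @param sim A `gd_sim`.
#' @param path Output file.
#' @export
write_timeseries_csv <- function(sim, path) {
  write_csv_(as.data.frame(sim), path)
}

write_manifest <- function(rc, out_dir) {
  manifest <- list(
    package = "drivebalance",
    version = as.character(utils::packageVersion("drivebalance")),
    config = rc$path,
    config_md5 = unname(tools::md5sum(rc$path)),
    strategy = rc$strategy$name,
    resolved_params = unclass(rc$strategy$params),
    Rm = rc$lc$Rm, dd_exponent = rc$lc$dd_exponent,
    mode = rc$mode,
    seed = rc$raw$seed,   # reserved: the engine is deterministic
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Write example configurations for every registered strategy
#'
#' Each fixture is a complete, valid YAML run configuration that
#' `simulate` mode accepts and that re-parses to an identical resolved
#' parameter set.
#'
#' @param out_dir Directory to write `<strategy>.yaml` files into.
#' @return Character vector of written paths.
#' @export
write_fixture_configs <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in STRATEGY_NAMES) {
    cfg <- list(strategy = list(name = nm),
                demography = list(Rm = 6, dd_exponent = 1),
                release = list(rho = 0.1, cadence = "every", start = 1),
                experiment = list(mode = "simulate", horizon = 20),
                seed = NULL)
    p <- file.path(out_dir, paste0(nm, ".yaml"))
    yaml::write_yaml(cfg, p)
    paths <- c(paths, p)
  }
  paths
}

# Command-line interface ---------------------------------------------------

#' Command-line entry point
#'
#' Subcommands: `simulate`, `search`, `sweep`, `compare` (each takes either
#' `--config FILE` or inline options) and `fixtures`.  Installed as the
#' executable script `drivebalance` under `inst/scripts`.
#'
#' @param args Character vector of command-line arguments (excluding the
#'   program name), e.g. `c("search", "--strategy", "pdne1", "--rm", "20",
#'   "--target", "0.95", "--horizon", "36", "--out", "results")`.
#' @return Exit status, invisibly (0 on success).
#' @export
gd_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1] %in% c("-h", "--help")) {
    cat("usage: drivebalance <simulate|search|sweep|compare|fixtures> [options]\n")
    return(invisible(0L))
  }
  sub <- match.arg(args[1],
                   c("simulate", "search", "sweep", "compare", "fixtures"))
  rest <- args[-1]

  if (sub == "fixtures") {
    opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
      optparse::make_option("--out", type = "character", default = "fixtures")
    )), args = rest)
    paths <- write_fixture_configs(opts$out)
    message("wrote ", length(paths), " fixture configs to ", opts$out)
    return(invisible(0L))
  }

  ol <- list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--strategy", type = "character", default = "pdne1"),
    optparse::make_option("--rm", type = "double", default = 6),
    optparse::make_option("--rho", type = "double", default = 0.1),
    optparse::make_option("--target", type = "double", default = 0.95),
    optparse::make_option("--horizon", type = "integer", default = 36L),
    optparse::make_option("--param", type = "character", default = NULL),
    optparse::make_option("--grid", type = "character", default = NULL),
    optparse::make_option("--strategies", type = "character", default = NULL),
    optparse::make_option("--out", type = "character", default = "results"))
  opts <- optparse::parse_args(optparse::OptionParser(option_list = ol),
                               args = rest)

  if (!is.null(opts$config)) {
    rc <- read_run_config(opts$config)
  } else {
    cfg <- list(
      strategy = list(name = opts$strategy),
      demography = list(Rm = opts$rm),
      release = list(rho = opts$rho),
      experiment = c(list(mode = sub, horizon = opts$horizon,
                          target = opts$target),
                     if (!is.null(opts$param)) list(param = opts$param),
                     if (!is.null(opts$grid))
                       list(grid = as.numeric(strsplit(opts$grid, ",")[[1]])),
                     if (!is.null(opts$strategies))
                       list(strategies = strsplit(opts$strategies, ",")[[1]])),
      seed = NULL)
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(cfg, tmp)
    rc <- read_run_config(tmp)
  }
  message("running `", rc$mode, "` for strategy `", rc$strategy$name,
          "` (Rm = ", rc$lc$Rm, ")")
  execute_run_config(rc, opts$out)
  message("results written to ", opts$out)
  invisible(0L)
}
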