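#' Population-labelled spike table
#'
#' The simulator's output and the analysis pipeline's input: one row per
#' spike with the population label, the within-population cell id and the
#' spike time in ms. Population sizes and the simulation duration travel as
#' attributes so rate normalization survives file round trips.
#'
#' @param population character vector of population labels.
#' @param cell_id integer vector of 1-based cell ids.
#' @param time_ms numeric vector of spike times (ms), nonnegative.
#' @param n_cells named integer vector: cells per population.
#' @param duration total simulated time (ms).
#' @return data.frame of class `spike_table`.
#' @export
spike_table <- function(population, cell_id, time_ms, n_cells = NULL,
                        duration = NULL) {
  if (length(time_ms) && any(time_ms < 0)) stop("spike times must be >= 0")
  if (length(cell_id) && any(cell_id < 0)) stop("cell ids must be nonnegative")
  df <- data.frame(population = as.character(population),
                   cell_id = as.integer(cell_id),
                   time_ms = as.numeric(time_ms))
  if (!is.null(duration) && nrow(df) && any(df$time_ms > duration))
    stop("spike times exceed the stated duration")
  attr(df, "n_cells") <- n_cells
  attr(df, "duration") <- duration
  class(df) <- c("spike_table", "data.frame")
  df
}

#' Write / read a spike table as TSV
#'
#' Plain-text format: optional metadata comment lines
#' (`# n_cells <population> <count>`, `# duration_ms <ms>`), a header line
#' `population  cell_id  time_ms`, then one row per spike with times printed
#' at 0.01 ms precision. `read_spikes(write_spikes(x))` is the identity at
#' that precision.
#'
#' @param table a [spike_table()].
#' @param path file path.
#' @return `write_spikes` returns `path` invisibly; `read_spikes` returns a
#'   `spike_table`.
#' @export
write_spikes <- function(table, path) {
  stopifnot(inherits(table, "spike_table"))
  con <- file(path, "w")
  on.exit(close(con))
  ncl <- attr(table, "n_cells")
  for (pn in names(ncl))
    writeLines(sprintf("# n_cells %s %d", pn, ncl[[pn]]), con)
  if (!is.null(attr(table, "duration")))
    writeLines(sprintf("# duration_ms %s",
                       format(attr(table, "duration"), scientific = FALSE)),
               con)
  writeLines("population\tcell_id\ttime_ms", con)
  if (nrow(table))
    writeLines(sprintf("%s\t%d\t%.2f", table$population, table$cell_id,
                       table$time_ms), con)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE, value = TRUE)
  n_cells <- NULL
  duration <- NULL
  for (m in meta) {
    f <- strsplit(trimws(sub("^#", "", m)), "\\s+")[[1]]
    if (f[1] == "n_cells") {
      v <- as.integer(f[3]); names(v) <- f[2]
      n_cells <- c(n_cells, v)
    } else if (f[1] == "duration_ms") duration <- as.numeric(f[2])
  }
  if (!length(body) || body[1] != "population\tcell_id\ttime_ms")
    stop("malformed spike file: missing header 'population\tcell_id\ttime_ms'")
  rows <- body[-1]
  if (!length(rows))
    return(spike_table(character(), integer(), numeric(),
                       n_cells = n_cells, duration = duration))
  parts <- strsplit(rows, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad))
    stop("malformed row at line ", bad[1] + length(meta) + 1)
  pop <- vapply(parts, `[`, character(1), 1)
  cid <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2)))
  tms <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 3)))
  bad <- which(is.na(cid) | is.na(tms))
  if (length(bad))
    stop("malformed row at line ", bad[1] + length(meta) + 1)
  if (any(tms < 0))
    stop("negative spike time at line ",
         which(tms < 0)[1] + length(meta) + 1)
  valid_pops <- union(c("PYR", "OLM", "PVBC"), names(n_cells))
  unknown <- setdiff(unique(pop), valid_pops)
  if (length(unknown))
    stop("unknown population label(s): ", paste(unknown, collapse = ", "),
         "; valid labels: ", paste(valid_pops, collapse = ", "))
  spike_table(pop, cid, tms, n_cells = n_cells, duration = duration)
}

#' Load a simulation + analysis configuration
#'
#' Reads a YAML file (or takes a list) and fills every unset key from the
#' default registry; unknown keys are rejected with the offending name. An
#' empty file yields the full default FM configuration.
#'
#' @param path YAML file path, or a named list.
#' @return list with a validated `network` ([network_config()]) element and
#'   the analysis options (`n_replicates`, `phase_band`, `amp_band`).
#' @export
load_config <- function(path) {
  raw <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  } else if (is.list(path)) path else stop("path must be a file or a list")
  defaults <- list(variant = "FM", scil = 140L, duration = 6300,
                   discard = 2000, dt = 0.05, seed = 1L,
                   n_replicates = 2L, overrides = list(),
                   phase_band = c(1, 8), amp_band = c(15, 50))
  bad <- setdiff(names(raw), names(defaults))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; valid keys: ", paste(names(defaults), collapse = ", "))
  cfg <- utils::modifyList(defaults, raw)
  net <- network_config(variant = cfg$variant, scil = cfg$scil,
                        duration = cfg$duration, discard = cfg$discard,
                        dt = cfg$dt, seed = cfg$seed,
                        overrides = cfg$overrides)
  list(network = net, n_replicates = as.integer(cfg$n_replicates),
       phase_band = as.numeric(cfg$phase_band),
       amp_band = as.numeric(cfg$amp_band))
}

#' Run a full replicate experiment
#'
#' Executes `n_replicates` simulations of the configured network (replicate
#' seeds fanned out from the master seed with [derive_seed()]), analyses
#' each, writes the spike tables, the aggregated metrics (mean and SEM
#' across replicates) and a run manifest with a checksum for every output
#' file.
#'
#' @param config a [load_config()] result (or a list acceptable to it).
#' @param out_dir output directory, created if needed.
#' @return the manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_experiment <- function(config, out_dir) {
  if (!inherits(config$network, "network_config")) config <- load_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  net_cfg <- config$network
  files <- character(0)
  t_start <- Sys.time()
  timings <- list()
  per_rep <- list()
  for (r in seq_len(config$n_replicates)) {
    t0 <- Sys.time()
    cfg_r <- net_cfg
    cfg_r$seed <- derive_seed(net_cfg$seed, r)
    spikes <- simulate_network(build_network(cfg_r))
    sp_path <- file.path(out_dir, sprintf("spikes_rep%d.tsv", r))
    write_spikes(spikes, sp_path)
    files <- c(files, sp_path)
    counts <- table(spikes$population)
    message("replicate ", r, ": ",
            paste(names(counts), as.integer(counts), collapse = ", "),
            " spikes")
    per_rep[[r]] <- network_metrics(spikes, discard = net_cfg$discard,
                                    phase_band = config$phase_band,
                                    amp_band = config$amp_band)
    timings[[sprintf("replicate_%d_s", r)]] <-
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  pops <- per_rep[[1]]$population
  metrics <- setdiff(names(per_rep[[1]]), "population")
  agg <- do.call(rbind, lapply(pops, function(pn) {
    do.call(rbind, lapply(metrics, function(m) {
      v <- vapply(per_rep, function(d) d[d$population == pn, m], numeric(1))
      data.frame(population = pn, metric = m, mean = mean(v),
                 sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                       else 0)
    }))
  }))
  met_path <- file.path(out_dir, "metrics.csv")
  utils::write.csv(agg, met_path, row.names = FALSE)
  files <- c(files, met_path)
  for (pn in pops) {
    th <- agg[agg$population == pn & agg$metric == "theta_peak_freq", "mean"]
    ga <- agg[agg$population == pn & agg$metric == "gamma_peak_freq", "mean"]
    message(pn, ": theta peak ", round(th, 2), " Hz, gamma peak ",
            round(ga, 2), " Hz")
  }
  manifest <- list(
    config = list(variant = net_cfg$variant, scil = net_cfg$scil,
                  duration = net_cfg$duration, discard = net_cfg$discard,
                  dt = net_cfg$dt, seed = net_cfg$seed,
                  n_replicates = config$n_replicates),
    software_version = as.character(utils::packageVersion("ca1pac")),
    timings_s = timings,
    files = lapply(stats::setNames(files, basename(files)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
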