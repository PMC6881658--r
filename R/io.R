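# CSV / config readers and the combined analysis report.

#' Read a well-sample CSV
#'
#' Expected header: `id,lon,lat,no3_mg_l`; `lon`/`lat` may be omitted
#' together, and a missing `id` column numbers the rows. Dialect is fixed:
#' comma separator, `"."` decimal point, UTF-8.
#'
#' @param path CSV file.
#' @return validated sample table (`id`, optional `lon`/`lat`, `cf`).
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  if (!"no3_mg_l" %in% names(raw)) {
    stop("missing concentration column: expected header ",
         "'id,lon,lat,no3_mg_l' (lon/lat optional), got '",
         paste(names(raw), collapse = ","), "'", call. = FALSE)
  }
  if (nrow(raw) == 0) {
    warning("empty sample file: ", path)
    return(data.frame(id = character(0), cf = numeric(0),
                      stringsAsFactors = FALSE))
  }
  to_num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(is.na(raw[[col]]) | raw[[col]] == ""))
    if (length(bad)) {
      stop("non-numeric value in column '", col, "' at data row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    v
  }
  out <- data.frame(
    id = if ("id" %in% names(raw)) raw$id else as.character(seq_len(nrow(raw))),
    stringsAsFactors = FALSE
  )
  if ("lon" %in% names(raw) || "lat" %in% names(raw)) {
    out$lon <- if ("lon" %in% names(raw)) to_num("lon") else NA_real_
    out$lat <- if ("lat" %in% names(raw)) to_num("lat") else NA_real_
  }
  out$cf <- to_num("no3_mg_l")
  validate_samples(out)
  out
}

#' Write a well-sample CSV
#'
#' Inverse of [read_samples()]: ids and concentrations round-trip exactly.
#'
#' @param samples sample table.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  samples <- validate_samples(samples)
  out <- data.frame(id = samples$id, stringsAsFactors = FALSE)
  if ("lon" %in% names(samples)) {
    out$lon <- samples$lon
    out$lat <- samples$lat
  }
  out$no3_mg_l <- num_exact(samples$cf)
  if ("lon" %in% names(out)) {
    out$lon <- num_exact(out$lon)
    out$lat <- num_exact(out$lat)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Convert a config list to a distribution spec
#'
#' Accepts the `{kind: ..., <params>...}` blocks of a run-configuration
#' file, e.g. `list(kind = "lognormal", meanlog = 2.65, sdlog = 0.34)`.
#'
#' @param x named list with a `kind` field and kind-specific parameters;
#'   optional `truncation = c(low, high)`.
#' @return a [dist_spec].
#' @export
as_dist_spec <- function(x) {
  if (inherits(x, "dist_spec")) return(x)
  chk(is.list(x) && !is.null(x$kind), "config block needs a 'kind' field")
  tr <- if (!is.null(x$truncation)) as.numeric(unlist(x$truncation))
  switch(x$kind,
    point      = dist_point(x$value),
    normal     = dist_normal(x$mean, x$sd, tr),
    lognormal  = dist_lognormal(x$meanlog, x$sdlog, tr),
    uniform    = dist_uniform(x$min, x$max, tr),
    triangular = dist_triangular(x$min, x$mode, x$max, tr),
    empirical  = dist_empirical(as.numeric(unlist(x$values)), tr),
    stop("unknown distribution kind: ", x$kind, call. = FALSE)
  )
}

#' Read a run-configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON, with optional blocks `monte_carlo:
#' {iterations, seed, percentiles}`, `distributions: {cf, cd, bw}` (each a
#' dist-spec block), `idw: {power, max_neighbors, search_radius}` and
#' `grid: {bbox, cell_size, nodata}`. Missing entries take the package
#' defaults. All randomness flows from the single `monte_carlo.seed`.
#'
#' @param path config file.
#' @return named list with `monte_carlo`, `distributions`, `idw`, `grid`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  mc <- cfg$monte_carlo
  out <- list(
    monte_carlo = list(
      iterations = if (is.null(mc$iterations)) 10000L else as.integer(mc$iterations),
      seed = if (is.null(mc$seed)) NULL else as.integer(mc$seed),
      percentiles = if (is.null(mc$percentiles)) {
        c(0.05, 0.25, 0.5, 0.75, 0.9, 0.95)
      } else as.numeric(unlist(mc$percentiles))
    ),
    distributions = lapply(cfg$distributions, as_dist_spec),
    idw = do.call(idw_params, as.list(cfg$idw %||% list())),
    grid = if (!is.null(cfg$grid)) {
      grid_spec(as.numeric(unlist(cfg$grid$bbox)), cfg$grid$cell_size,
                cfg$grid$nodata %||% -9999)
    }
  )
  chk(out$monte_carlo$iterations >= 1, "monte_carlo.iterations must be >= 1")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shortest decimal text that re-reads to the identical double
num_exact <- function(x) {
  s <- sprintf("%.15g", x)
  long <- !is.na(x) & suppressWarnings(as.numeric(s)) != x
  s[long] <- sprintf("%.17g", x[long])
  s[is.na(x)] <- NA_character_
  s
}

#' Write the combined analysis report
#'
#' Writes `samples_hq.csv` (one row per sample-group with EDI, HQ and the
#' exceedance flag), `summary.csv` (one row per group comparing the
#' deterministic and probabilistic mean, SD and P90 side by side; the
#' probabilistic columns are empty when no Monte-Carlo results are given)
#' and `run_log.txt` (seed, iteration count and parameters sufficient to
#' re-execute identically). Re-running with the same inputs and seed yields
#' byte-identical CSVs.
#'
#' @param results deterministic results from [assess()].
#' @param mc_results optional list of `mc_result` objects (one per group).
#' @param out_dir output directory, created if needed.
#' @param raster_paths optional character vector of raster files to record
#'   in the log.
#' @param threshold HQ acceptability threshold for the exceedance flag.
#' @return named character vector of the files written, invisibly.
#' @export
write_report <- function(results, mc_results = NULL, out_dir,
                         raster_paths = NULL, threshold = 1) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  flags <- exceedance_flags(results, threshold)
  per_sample <- data.frame(
    id = results$sample_id, group = results$group,
    edi = round_printed(results$edi), hq = round_printed(results$hq),
    exceeds = flags$exceeds, stringsAsFactors = FALSE
  )
  f_samples <- file.path(out_dir, "samples_hq.csv")
  utils::write.csv(per_sample, f_samples, row.names = FALSE, quote = FALSE,
                   eol = "\n")

  mc_by_group <- list()
  for (m in mc_results %||% list()) mc_by_group[[m$group_name]] <- m
  groups <- unique(results$group)
  summary_rows <- lapply(groups, function(g) {
    hq <- results$hq[results$group == g]
    m <- mc_by_group[[g]]
    data.frame(
      group = g,
      det_mean = round_printed(mean(hq)),
      det_sd = round_printed(stats::sd(hq)),
      det_p90 = round_printed(hq_percentile(hq, 0.9)),
      prob_mean = if (is.null(m)) NA else round_printed(m$mean),
      prob_sd = if (is.null(m)) NA else round_printed(m$sd),
      prob_p90 = if (is.null(m)) NA else round_printed(hq_percentile_of(m, 0.9)),
      prob_exceedance = if (is.null(m)) NA else round_printed(m$prob_exceedance),
      stringsAsFactors = FALSE
    )
  })
  f_summary <- file.path(out_dir, "summary.csv")
  utils::write.csv(do.call(rbind, summary_rows), f_summary,
                   row.names = FALSE, quote = FALSE, eol = "\n", na = "")

  f_log <- file.path(out_dir, "run_log.txt")
  seeds <- unique(unlist(lapply(mc_results %||% list(),
                                function(m) m$seed %||% NA)))
  iters <- unique(vapply(mc_results %||% list(), `[[`, integer(1),
                         "n_iterations"))
  writeLines(c(
    paste("nitrateRisk", as.character(utils::packageVersion("nitrateRisk"))),
    paste("R", paste(R.version$major, R.version$minor, sep = ".")),
    paste("hq_threshold", threshold),
    paste("mc_seed", paste(seeds, collapse = ",")),
    paste("mc_iterations", paste(iters, collapse = ",")),
    paste("rasters", paste(raster_paths %||% character(0), collapse = ",")),
    paste("groups", paste(groups, collapse = ","))
  ), f_log)

  invisible(c(samples = f_samples, summary = f_summary, log = f_log))
}

# P90 from a stored percentile table, falling back to recomputation from
# kept draws
hq_percentile_of <- function(m, p) {
  key <- sprintf("P%g", 100 * p)
  if (key %in% names(m$percentiles)) return(unname(m$percentiles[[key]]))
  if (!is.null(m$draws)) return(hq_percentile(m$draws$hq, p))
  NA_real_
}
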