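# Synthetic well networks with the statistical and spatial structure the
# analysis assumes.

# Lognormal parameters fitted by maximum likelihood to the 66 Iranshahr
# survey concentrations; frozen so the default generator emulates the
# right-skewed 6-49 mg/L distribution observed there.
.fixture_lognormal <- c(meanlog = 2.6518607, sdlog = 0.3436157)

# Approximate extent of the Iranshahr study area (around 27.2 N, 60.7 E).
.iranshahr_bbox <- c(60.5, 27.0, 60.9, 27.4)

#' Synthetic well-network configuration
#'
#' Two generating modes: `"random"` draws concentrations i.i.d. from
#' `conc_dist` (by default a lognormal fitted to the Iranshahr survey,
#' meanlog 2.652, sdlog 0.344); `"trend_plus_noise"` evaluates a smooth
#' bilinear surface over the bounding box and adds Gaussian noise, flooring
#' at zero — a stand-in for the spatially smooth concentration fields that
#' interpolation assumes. Well coordinates are uniform over the bounding
#' box in both modes.
#'
#' @param n_wells number of wells (>= 1).
#' @param seed optional integer seed; fixed seed implies identical output.
#' @param conc_dist [dist_spec] for `"random"` mode concentrations.
#' @param spatial_mode `"random"` or `"trend_plus_noise"`.
#' @param trend coefficients `c(b0, b_x, b_y, b_xy)` of the surface
#'   `b0 + b_x u + b_y v + b_xy u v` in mg/L, where `u`, `v` are lon/lat
#'   rescaled to \[0, 1\] over the bbox. The default spans roughly the
#'   6-43 mg/L range.
#' @param noise_sd Gaussian noise standard deviation, mg/L (>= 0).
#' @param bbox extent `c(lon_min, lat_min, lon_max, lat_max)`; defaults to
#'   the approximate Iranshahr study area.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_wells, seed = NULL,
                         conc_dist = dist_lognormal(.fixture_lognormal[["meanlog"]],
                                                    .fixture_lognormal[["sdlog"]]),
                         spatial_mode = c("random", "trend_plus_noise"),
                         trend = c(8, 15, 10, 10), noise_sd = 2,
                         bbox = .iranshahr_bbox) {
  chk(is.numeric(n_wells) && length(n_wells) == 1 && n_wells >= 1,
      "'n_wells' must be >= 1")
  chk(inherits(conc_dist, "dist_spec"), "'conc_dist' must be a dist_spec")
  chk(is.numeric(noise_sd) && length(noise_sd) == 1 && noise_sd >= 0,
      "'noise_sd' must be >= 0")
  chk(is.numeric(trend) && length(trend) == 4 && all(is.finite(trend)),
      "'trend' must be 4 finite coefficients")
  chk(is.numeric(bbox) && length(bbox) == 4 &&
        bbox[1] < bbox[3] && bbox[2] < bbox[4],
      "degenerate bbox: need lon_min < lon_max and lat_min < lat_max")
  structure(list(n_wells = as.integer(n_wells), seed = seed,
                 conc_dist = conc_dist,
                 spatial_mode = match.arg(spatial_mode),
                 trend = trend, noise_sd = noise_sd, bbox = bbox),
            class = "synth_config")
}

# the bilinear trend surface, in original lon/lat coordinates
trend_surface <- function(lon, lat, config) {
  b <- config$bbox
  u <- (lon - b[1]) / (b[3] - b[1])
  v <- (lat - b[2]) / (b[4] - b[2])
  t <- config$trend
  t[1] + t[2] * u + t[3] * v + t[4] * u * v
}

#' Generate a synthetic well network
#'
#' @param config a [synth_config()].
#' @return sample table with `id` (`"well_1"`, ...), `lon`, `lat`, `cf`;
#'   concentrations are non-negative by construction.
#' @examples
#' wells <- generate_wells(synth_config(66, seed = 1))
#' summary(wells$cf)
#' @export
generate_wells <- function(config) {
  chk(inherits(config, "synth_config"), "'config' must be a synth_config")
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_wells
  b <- config$bbox
  lon <- stats::runif(n, b[1], b[3])
  lat <- stats::runif(n, b[2], b[4])
  cf <- if (config$spatial_mode == "random") {
    draw_dist(config$conc_dist, n, lower = 0)$values
  } else {
    pmax(0, trend_surface(lon, lat, config) +
           stats::rnorm(n, 0, config$noise_sd))
  }
  data.frame(id = paste0("well_", seq_len(n)), lon = lon, lat = lat,
             cf = cf, stringsAsFactors = FALSE)
}
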