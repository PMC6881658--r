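# Inverse-distance-weighted interpolation of well concentrations.

#' Regular grid specification
#'
#' @param bbox numeric `c(lon_min, lat_min, lon_max, lat_max)` in decimal
#'   degrees.
#' @param cell_size cell edge in degrees (> 0).
#' @param nodata sentinel written for cells with no prediction.
#' @return object of class `grid_spec` with derived `ncols`/`nrows`.
#' @export
grid_spec <- function(bbox, cell_size, nodata = -9999) {
  chk(is.numeric(bbox) && length(bbox) == 4 &&
        bbox[1] < bbox[3] && bbox[2] < bbox[4],
      "'bbox' must be c(lon_min, lat_min, lon_max, lat_max) with min < max")
  chk(is.numeric(cell_size) && length(cell_size) == 1 && cell_size > 0,
      "'cell_size' must be a single positive number")
  ncols <- max(1L, as.integer(ceiling((bbox[3] - bbox[1]) / cell_size - 1e-9)))
  nrows <- max(1L, as.integer(ceiling((bbox[4] - bbox[2]) / cell_size - 1e-9)))
  structure(list(bbox = bbox, cell_size = cell_size, nodata = nodata,
                 ncols = ncols, nrows = nrows),
            class = "grid_spec")
}

# cell-center coordinates; row 1 is the northern edge (ESRI ASCII order)
grid_centers <- function(grid) {
  lon <- grid$bbox[1] + (seq_len(grid$ncols) - 0.5) * grid$cell_size
  lat <- grid$bbox[2] + (seq_len(grid$nrows) - 0.5) * grid$cell_size
  list(lon = lon, lat = rev(lat))
}

#' IDW parameters
#'
#' @param power distance-decay exponent p in weights d^(-p); 2 by default.
#' @param max_neighbors number of nearest samples used per prediction
#'   (`Inf` = all).
#' @param search_radius only samples within this distance contribute
#'   (`Inf` = unlimited); no sample in range yields nodata.
#' @param exact_tol distance below which a target is treated as coinciding
#'   with a sample and the sample's value is returned (ties among coincident
#'   samples averaged).
#' @param distance `"euclidean"` for planar distances in degree space
#'   (small-extent assumption) or `"equirectangular"` to scale longitude
#'   differences by cos(mean latitude).
#' @return object of class `idw_params`.
#' @export
idw_params <- function(power = 2, max_neighbors = Inf, search_radius = Inf,
                       exact_tol = 1e-9,
                       distance = c("euclidean", "equirectangular")) {
  chk(is.numeric(power) && length(power) == 1 && power > 0,
      "'power' must be > 0")
  chk(max_neighbors >= 1, "'max_neighbors' must be >= 1")
  chk(search_radius > 0, "'search_radius' must be > 0")
  structure(list(power = power, max_neighbors = max_neighbors,
                 search_radius = search_radius, exact_tol = exact_tol,
                 distance = match.arg(distance)),
            class = "idw_params")
}

# drop un-georeferenced samples, average duplicate coordinates
prepare_spatial_samples <- function(samples) {
  samples <- validate_samples(samples, require_coords = TRUE)
  miss <- is.na(samples$lon) | is.na(samples$lat)
  if (any(miss)) {
    warning(sum(miss), " sample(s) without coordinates excluded from ",
            "interpolation")
    samples <- samples[!miss, ]
  }
  if (nrow(samples) == 0) {
    stop("no georeferenced samples to interpolate", call. = FALSE)
  }
  key <- paste(samples$lon, samples$lat)
  if (anyDuplicated(key)) {
    warning("duplicate coordinates averaged before interpolation")
    agg <- stats::aggregate(samples["cf"], by = list(key = key), FUN = mean)
    first <- samples[!duplicated(key), ]
    first$cf <- agg$cf[match(paste(first$lon, first$lat), agg$key)]
    samples <- first
  }
  samples
}

#' IDW prediction at target points
#'
#' Predicts concentration at each target as the weighted mean of sample
#' values with weights proportional to distance^(-power) over the selected
#' neighborhood. Weights are normalized to sum to 1, so every prediction is
#' a convex combination of sample values (hence bounded by their range). A
#' target within `exact_tol` of a sample returns that sample's value.
#'
#' @param lon,lat target coordinates (vectors of equal length), decimal
#'   degrees.
#' @param samples georeferenced sample table; samples without coordinates
#'   are excluded with a warning, duplicated coordinates are averaged.
#' @param params an [idw_params()].
#' @return numeric vector of predictions (mg/L); `NA` where no sample lies
#'   within the search radius.
#' @export
idw_predict <- function(lon, lat, samples, params = idw_params()) {
  chk(length(lon) == length(lat), "'lon' and 'lat' must have equal length")
  chk(all(is.finite(lon)) && all(is.finite(lat)),
      "target coordinates must be finite")
  samples <- prepare_spatial_samples(samples)
  idw_core(lon, lat, samples$lon, samples$lat, samples$cf, params)
}

idw_core <- function(tx, ty, sx, sy, sv, params) {
  kx <- if (params$distance == "equirectangular") {
    cos(mean(sy) * pi / 180)
  } else 1
  vapply(seq_along(tx), function(i) {
    dx <- (sx - tx[i]) * kx
    dy <- sy - ty[i]
    d <- sqrt(dx * dx + dy * dy)
    hit <- d < params$exact_tol
    if (any(hit)) return(mean(sv[hit]))
    in_r <- d <= params$search_radius
    if (!any(in_r)) return(NA_real_)
    d <- d[in_r]; v <- sv[in_r]
    if (is.finite(params$max_neighbors) && length(d) > params$max_neighbors) {
      keep <- order(d)[seq_len(params$max_neighbors)]
      d <- d[keep]; v <- v[keep]
    }
    # scale by the nearest distance so large powers cannot underflow
    w <- (min(d) / d)^params$power
    sum(w * v) / sum(w)
  }, numeric(1))
}

#' Interpolate a sample table onto a regular grid
#'
#' Applies [idw_predict()] at every cell center of the grid. The result is
#' deterministic in its inputs.
#'
#' @param samples georeferenced sample table.
#' @param grid a [grid_spec()].
#' @param params an [idw_params()].
#' @return object of class `nitrate_raster`: list with the `grid` and a
#'   `values` matrix (`nrows` x `ncols`, row 1 = northern edge; `NA` for
#'   nodata).
#' @export
interpolate_grid <- function(samples, grid, params = idw_params()) {
  chk(inherits(grid, "grid_spec"), "'grid' must be a grid_spec")
  samples <- prepare_spatial_samples(samples)
  ctr <- grid_centers(grid)
  tx <- rep(ctr$lon, times = grid$nrows)
  ty <- rep(ctr$lat, each = grid$ncols)
  vals <- idw_core(tx, ty, samples$lon, samples$lat, samples$cf, params)
  values <- matrix(vals, nrow = grid$nrows, ncol = grid$ncols, byrow = TRUE)
  structure(list(grid = grid, values = values), class = "nitrate_raster")
}

#' Guideline exceedance mask
#'
#' Marks cells whose interpolated concentration strictly exceeds a
#' drinking-water guideline (e.g. 50 mg/L nitrate, the WHO limit). Nodata
#' cells stay nodata.
#'
#' @param raster a `nitrate_raster` from [interpolate_grid()].
#' @param guideline concentration limit, mg/L (> 0).
#' @return `nitrate_raster` whose values are logical (`NA` where nodata).
#' @export
exceedance_mask <- function(raster, guideline) {
  chk(inherits(raster, "nitrate_raster"), "'raster' must be a nitrate_raster")
  chk(is.numeric(guideline) && length(guideline) == 1 && guideline > 0,
      "'guideline' must be a single positive number")
  structure(list(grid = raster$grid, values = raster$values > guideline),
            class = "nitrate_raster")
}

#' @export
print.nitrate_raster <- function(x, ...) {
  g <- x$grid
  cat(sprintf("<nitrate_raster> %d x %d cells of %g deg, bbox [%g, %g, %g, %g]\n",
              g$nrows, g$ncols, g$cell_size,
              g$bbox[1], g$bbox[2], g$bbox[3], g$bbox[4]))
  v <- x$values[is.finite(x$values)]
  if (length(v)) {
    cat(sprintf("  values: min %g  mean %g  max %g  (%d nodata)\n",
                min(v), mean(v), max(v), sum(!is.finite(x$values))))
  }
  invisible(x)
}
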