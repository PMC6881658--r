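# ESRI ASCII grid and GeoJSON writers.

#' Write a raster as an ESRI ASCII grid
#'
#' Standard `.asc` layout: NCOLS/NROWS/XLLCORNER/YLLCORNER/CELLSIZE/
#' NODATA_VALUE header followed by rows north to south. Logical rasters
#' (exceedance masks) are written as 1/0.
#'
#' @param raster a `nitrate_raster`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(raster, path) {
  chk(inherits(raster, "nitrate_raster"), "'raster' must be a nitrate_raster")
  g <- raster$grid
  v <- raster$values
  if (is.logical(v)) v <- v * 1
  v[!is.finite(v)] <- g$nodata
  header <- c(
    sprintf("NCOLS %d", g$ncols),
    sprintf("NROWS %d", g$nrows),
    sprintf("XLLCORNER %.10g", g$bbox[1]),
    sprintf("YLLCORNER %.10g", g$bbox[2]),
    sprintf("CELLSIZE %.10g", g$cell_size),
    sprintf("NODATA_VALUE %.10g", g$nodata)
  )
  rows <- apply(v, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                        collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file written by [write_esri_ascii()] or compatible.
#' @return a `nitrate_raster` (nodata cells as `NA`).
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[toupper(parts[1])]] <- as.numeric(parts[2])
  }
  ncols <- as.integer(hdr$NCOLS); nrows <- as.integer(hdr$NROWS)
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:6)]), "\\s+")))
  chk(length(vals) == ncols * nrows, "cell count does not match header")
  values <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  values[values == hdr$NODATA_VALUE] <- NA_real_
  grid <- grid_spec(
    bbox = c(hdr$XLLCORNER, hdr$YLLCORNER,
             hdr$XLLCORNER + ncols * hdr$CELLSIZE,
             hdr$YLLCORNER + nrows * hdr$CELLSIZE),
    cell_size = hdr$CELLSIZE, nodata = hdr$NODATA_VALUE
  )
  structure(list(grid = grid, values = values), class = "nitrate_raster")
}

#' Write well samples as GeoJSON points
#'
#' One Point feature per georeferenced sample, with `id` and `no3_mg_l`
#' properties.
#'
#' @param samples georeferenced sample table.
#' @param path output `.geojson` file.
#' @return `path`, invisibly.
#' @export
write_wells_geojson <- function(samples, path) {
  samples <- validate_samples(samples, require_coords = TRUE)
  features <- lapply(seq_len(nrow(samples)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(samples$lon[i], samples$lat[i])),
      properties = list(id = samples$id[i], no3_mg_l = samples$cf[i])
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
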