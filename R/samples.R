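# Sample tables: validation and the bundled reference survey.

#' Validate a table of well samples
#'
#' A sample table is a data frame with columns `id` (unique labels), `cf`
#' (nitrate concentration in mg/L, non-negative and finite) and, optionally,
#' `lon`/`lat` in decimal degrees (either both present or both absent).
#'
#' @param samples data frame of samples.
#' @param require_coords if `TRUE`, error unless lon/lat are present.
#' @return the validated table, invisibly coerced: `id` as character.
#' @keywords internal
validate_samples <- function(samples, require_coords = FALSE) {
  if (!is.data.frame(samples) || nrow(samples) == 0) {
    stop("'samples' must be a non-empty data frame", call. = FALSE)
  }
  if (!all(c("id", "cf") %in% names(samples))) {
    stop("'samples' must have columns 'id' and 'cf'", call. = FALSE)
  }
  samples$id <- as.character(samples$id)
  dup <- unique(samples$id[duplicated(samples$id)])
  if (length(dup)) {
    stop("duplicate sample ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad <- !is.finite(samples$cf) | samples$cf < 0
  if (any(bad)) {
    stop("negative or non-finite concentration for sample(s): ",
         paste(samples$id[bad], collapse = ", "), call. = FALSE)
  }
  has_lon <- "lon" %in% names(samples)
  has_lat <- "lat" %in% names(samples)
  if (has_lon != has_lat) {
    stop("'lon' and 'lat' must be either both present or both absent",
         call. = FALSE)
  }
  if (require_coords && !has_lon) {
    stop("samples have no 'lon'/'lat' coordinates", call. = FALSE)
  }
  if (has_lon) {
    miss <- xor(is.na(samples$lon), is.na(samples$lat))
    if (any(miss)) {
      stop("samples with only one of lon/lat: ",
           paste(samples$id[miss], collapse = ", "), call. = FALSE)
    }
  }
  invisible(samples)
}

# The 66 nitrate concentrations (mg/L) of the Iranshahr rural groundwater
# survey, in published sample order.
.iranshahr_no3 <- c(
  12.0, 18.5, 24.0, 14.0,  9.0, 12.0, 13.5, 17.5, 15.0, 17.0,
  20.0, 28.0, 14.5, 13.0, 17.6, 14.5, 10.0,  6.5, 16.5, 15.0,
   8.5,  6.5,  9.0, 18.5, 12.0, 13.0, 16.5, 10.0, 13.5, 25.0,
  12.0, 12.0, 13.5, 17.0, 49.0, 17.0, 19.5, 11.5, 15.0, 12.5,
  18.0, 14.5, 13.0, 15.5, 11.5, 14.5, 11.0, 13.0, 15.8, 16.5,
   6.0, 16.0, 15.5, 16.0, 13.0, 13.0, 10.0, 12.5, 23.5, 13.0,
  26.5,  8.5, 20.5, 14.0, 13.0, 12.5
)

#' Iranshahr groundwater nitrate survey
#'
#' Returns the 66 published nitrate measurements from rural drinking-water
#' wells of Iranshahr city (Sistan and Baluchistan province, Iran) as a
#' sample table. Well coordinates were not published, so the table carries
#' none; attach synthetic coordinates with [generate_wells()] if a spatial
#' workflow is needed.
#'
#' @return data frame with columns `id` (`"1"`..`"66"`) and `cf`
#'   (nitrate, mg/L; range 6.0-49.0).
#' @examples
#' wells <- iranshahr_nitrate()
#' range(wells$cf)
#' @export
iranshahr_nitrate <- function() {
  data.frame(id = as.character(seq_along(.iranshahr_no3)),
             cf = .iranshahr_no3, stringsAsFactors = FALSE)
}

#' Published per-sample EDI/HQ reference values for the Iranshahr survey
#'
#' The survey's published per-sample estimated daily intakes and hazard
#' quotients for the four default exposure groups, rounded to 4 decimal
#' places as printed. Used to cross-check [assess()] cell-for-cell.
#'
#' @return data frame with columns `id`, `no3_mg_l`, `edi_<group>` and
#'   `hq_<group>` for infant, children, teenager and adults.
#' @export
iranshahr_hq_reference <- function() {
  path <- system.file("extdata", "iranshahr_hq_reference.csv",
                      package = "nitrateRisk", mustWork = TRUE)
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  ref$id <- as.character(ref$id)
  ref
}
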