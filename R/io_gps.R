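#' Project longitude/latitude to a local metric frame
#'
#' Converts geographic coordinates to planar metres in a local
#' transverse-Mercator-style frame centred on \code{origin}: eastings and
#' northings are computed from the WGS84 prime-vertical and meridional radii
#' of curvature at the origin latitude. Over the spatial extent of a primate
#' home range (tens of hectares) the planar error of this frame is
#' sub-centimetre, so all downstream distances are plain Euclidean.
#'
#' @param lon,lat numeric vectors of degrees.
#' @param origin length-2 numeric \code{c(lon0, lat0)}; defaults to the first
#'   coordinate pair.
#' @return a data.frame with columns \code{x}, \code{y} in metres.
#' @export
local_project <- function(lon, lat, origin = c(lon[1], lat[1])) {
  stopifnot(length(lon) == length(lat), length(origin) == 2L)
  if (any(!is.finite(lon) | !is.finite(lat))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  a <- 6378137
  f <- 1 / 298.257223563
  e2 <- f * (2 - f)
  lat0 <- origin[2] * pi / 180
  s2 <- sin(lat0)^2
  N <- a / sqrt(1 - e2 * s2)            # prime-vertical radius
  M <- a * (1 - e2) / (1 - e2 * s2)^1.5 # meridional radius
  data.frame(x = (lon - origin[1]) * pi / 180 * N * cos(lat0),
             y = (lat - origin[2]) * pi / 180 * M)
}

.gps_frame <- function(timestamp, x, y, has_focal) {
  if (any(!is.finite(x) | !is.finite(y))) {
    stop("GPS fixes with non-finite coordinates", call. = FALSE)
  }
  o <- order(timestamp)
  timestamp <- timestamp[o]
  if (any(diff(as.numeric(timestamp)) <= 0)) {
    stop("non-monotone GPS timestamps", call. = FALSE)
  }
  data.frame(timestamp = timestamp,
             date = as.Date(timestamp, tz = "UTC"),
             minute = as.numeric(timestamp) / 60,
             x = x[o], y = y[o],
             has_focal_behaviour = has_focal[o],
             stringsAsFactors = FALSE)
}

#' Read a GPS tracklog (CSV or GPX 1.1)
#'
#' CSV input carries either projected coordinates (\code{timestamp,x,y,
#' has_focal_behaviour}) or geographic ones (\code{timestamp,lon,lat,
#' has_focal_behaviour}); GPX 1.1 input uses \code{<trkpt lat lon>} elements
#' with \code{<time>} children and an optional \code{<extensions><focal>}
#' flag (absent means \code{true}). Geographic coordinates are converted to
#' metres with [local_project()] on load, so both dialects yield the same fix
#' table.
#'
#' @param path file path (\code{.gpx} files are parsed as GPX, anything else
#'   as CSV).
#' @param origin optional \code{c(lon0, lat0)} projection origin; defaults to
#'   the first fix.
#' @return data.frame of fixes with columns \code{timestamp} (POSIXct, UTC),
#'   \code{date}, \code{minute} (minutes since epoch), \code{x}, \code{y}
#'   (metres), \code{has_focal_behaviour}.
#' @export
read_gps <- function(path, origin = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.gpx$", path, ignore.case = TRUE)) {
    return(.read_gpx(path, origin))
  }
  raw <- read.csv(path, stringsAsFactors = FALSE)
  ts <- as.POSIXct(raw$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(ts)) stop("unparseable GPS timestamp", call. = FALSE)
  .check_columns(raw, "has_focal_behaviour", "GPS file")
  focal <- .parse_logical(as.character(raw$has_focal_behaviour))
  if (all(c("x", "y") %in% names(raw))) {
    xy <- data.frame(x = as.numeric(raw$x), y = as.numeric(raw$y))
  } else if (all(c("lon", "lat") %in% names(raw))) {
    lon <- as.numeric(raw$lon); lat <- as.numeric(raw$lat)
    if (is.null(origin)) origin <- c(lon[1], lat[1])
    xy <- local_project(lon, lat, origin)
  } else {
    stop("GPS file: need columns x,y or lon,lat", call. = FALSE)
  }
  if (anyNA(xy$x) || anyNA(xy$y)) stop("unparseable GPS position",
                                       call. = FALSE)
  .gps_frame(ts, xy$x, xy$y, focal)
}

.read_gpx <- function(path, origin = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trkpt")
  if (!length(pts)) stop("GPX file contains no track points", call. = FALSE)
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  if (anyNA(lat) || anyNA(lon)) stop("unparseable GPS position",
                                     call. = FALSE)
  ts <- as.POSIXct(xml2::xml_text(xml2::xml_find_first(pts, "./time")),
                   format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (anyNA(ts)) stop("unparseable GPS timestamp", call. = FALSE)
  focal_txt <- xml2::xml_text(xml2::xml_find_first(pts, ".//focal"))
  focal <- ifelse(is.na(focal_txt), TRUE, tolower(focal_txt) == "true")
  if (is.null(origin)) origin <- c(lon[1], lat[1])
  xy <- local_project(lon, lat, origin)
  .gps_frame(ts, xy$x, xy$y, focal)
}

#' Write a GPS track as CSV (lon/lat) or GPX 1.1
#'
#' @param track data.frame with \code{timestamp}, \code{lon}, \code{lat} and
#'   \code{has_focal_behaviour} columns.
#' @param path output path; a \code{.gpx} extension selects GPX 1.1.
#' @return `path`, invisibly.
#' @export
write_gps <- function(track, path) {
  .check_columns(track, c("timestamp", "lon", "lat", "has_focal_behaviour"),
                 "GPS track")
  tsz <- format(track$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (grepl("\\.gpx$", path, ignore.case = TRUE)) {
    pts <- sprintf(
      paste0("    <trkpt lat=\"%.8f\" lon=\"%.8f\"><time>%s</time>",
             "<extensions><focal>%s</focal></extensions></trkpt>"),
      track$lat, track$lon, tsz,
      ifelse(track$has_focal_behaviour, "true", "false"))
    writeLines(c(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      "<gpx version=\"1.1\" creator=\"mguard\"",
      "     xmlns=\"http://www.topografix.com/GPX/1/1\">",
      "  <trk><trkseg>", pts, "  </trkseg></trk>", "</gpx>"), path)
  } else {
    out <- data.frame(timestamp = format(track$timestamp,
                                         "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                      lon = sprintf("%.8f", track$lon),
                      lat = sprintf("%.8f", track$lat),
                      has_focal_behaviour =
                        .format_logical(track$has_focal_behaviour))
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
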