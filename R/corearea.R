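## Spatio-temporal assignment of territories to recolonization core areas
## and minimum-convex-polygon construction.

#' Assign territories to recolonization core areas
#'
#' Greedy rule with temporal precedence: territories are processed in
#' founding-year order (ties broken by territory code); each is assigned
#' to the core area containing the nearest already-assigned territory
#' whose founding year does not exceed its own. Distance ties are broken
#' by the smaller founding-year gap, then by area label order.
#' Territories farther than `max_km` from every assigned member are left
#' unassigned.
#'
#' @param territories data.frame with `code`, `lat`, `lon`, `first_year`
#' @param seeds named list/vector mapping area label -> seed territory code
#' @param max_km maximum assignment distance (default Inf)
#' @return data.frame `code`, `area` (NA = unassignable), `dist_km`
#' @export
assign_core_areas <- function(territories, seeds, max_km = Inf) {
  seeds <- unlist(seeds)
  if (anyDuplicated(seeds)) stop("seed territories must be distinct")
  if (!all(seeds %in% territories$code))
    stop("seed territory missing from table: ",
         paste(setdiff(seeds, territories$code), collapse = ", "))
  tt <- territories[order(territories$first_year, territories$code), ,
                    drop = FALSE]
  seed_years <- tt$first_year[match(seeds, tt$code)]
  if (any(tt$first_year < min(seed_years)))
    stop("territory founded before all seeds: ",
         paste(tt$code[tt$first_year < min(seed_years)], collapse = ", "))
  area <- stats::setNames(rep(NA_character_, nrow(tt)), tt$code)
  dist <- stats::setNames(rep(NA_real_, nrow(tt)), tt$code)
  area[seeds] <- names(seeds)
  dist[seeds] <- 0
  for (i in seq_len(nrow(tt))) {
    code <- tt$code[i]
    if (!is.na(area[code])) next
    cand <- tt$code[!is.na(area[tt$code]) & tt$first_year <= tt$first_year[i] &
                    tt$code != code]
    if (!length(cand)) next
    d <- geodesic_distance(tt$lat[i], tt$lon[i],
                           tt$lat[match(cand, tt$code)],
                           tt$lon[match(cand, tt$code)])
    gap <- tt$first_year[i] - tt$first_year[match(cand, tt$code)]
    ord <- order(d, gap, area[cand])
    best <- ord[1]
    if (d[best] <= max_km) {
      area[code] <- area[cand[best]]
      dist[code] <- d[best]
    }
  }
  out <- data.frame(code = tt$code, area = unname(area[tt$code]),
                    dist_km = unname(dist[tt$code]), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Minimum convex polygon of a point set
#'
#' Convex hull in an equirectangular projection about the regional
#' centroid (adequate for extents under ~10 degrees); vertices are
#' returned counter-clockwise in lon/lat. Fewer than 3 distinct
#' non-collinear points yield a degenerate result with a flag.
#'
#' @param lat,lon coordinates in decimal degrees
#' @return list with `polygon` (data.frame lon/lat of hull vertices,
#'   counter-clockwise), `degenerate` (logical), `area_km2` (planar
#'   approximation)
#' @export
minimum_convex_polygon <- function(lat, lon) {
  stopifnot(length(lat) == length(lon))
  R <- 6371.0088
  lat0 <- mean(lat)
  x <- R * cos(lat0 * pi / 180) * lon * pi / 180
  y <- R * lat * pi / 180
  pts <- unique(data.frame(x = x, y = y, lat = lat, lon = lon))
  if (nrow(pts) < 3L)
    return(list(polygon = pts[, c("lon", "lat")], degenerate = TRUE,
                area_km2 = 0))
  h <- grDevices::chull(pts$x, pts$y)     # clockwise
  h <- rev(h)                             # counter-clockwise
  poly <- pts[h, , drop = FALSE]
  xs <- poly$x; ys <- poly$y
  area <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  list(polygon = data.frame(lon = poly$lon, lat = poly$lat),
       degenerate = length(h) < 3L || area == 0,
       area_km2 = area)
}

#' Write core-area polygons as GeoJSON
#'
#' @param polygons named list of results from [minimum_convex_polygon()]
#' @param path output file
#' @export
write_core_geojson <- function(polygons, path) {
  features <- lapply(names(polygons), function(nm) {
    p <- polygons[[nm]]$polygon
    ring <- lapply(c(seq_len(nrow(p)), 1L),
                   function(i) c(p$lon[i], p$lat[i]))
    list(type = "Feature",
         properties = list(area = nm),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
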