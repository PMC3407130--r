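#' Read etymon-classified toponym points
#'
#' @param path delimited file with columns `x_km`, `y_km`,
#'   `etymon_class` (one of Germanic, Slavic, Romance).
#' @return data.frame with numeric `x_km`, `y_km` and character
#'   `etymon_class`.
#' @export
read_pasture_points <- function(path) {
  df <- read_delim_auto(path)
  need <- c("x_km", "y_km", "etymon_class")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("points file lacks column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(x_km = as_num(df$x_km), y_km = as_num(df$y_km),
                    etymon_class = df$etymon_class,
                    stringsAsFactors = FALSE)
  validate_points(out)
  out
}

validate_points <- function(points) {
  if (!all(is.finite(points$x_km)) || !all(is.finite(points$y_km)))
    stop("point coordinates must be finite")
  bad <- setdiff(unique(points$etymon_class),
                 c("Germanic", "Slavic", "Romance"))
  if (length(bad) > 0)
    stop("unknown etymon class(es): ", paste(bad, collapse = ", "))
  invisible(points)
}

#' Circular-neighborhood point density surface
#'
#' For each cell center of a regular grid the density is the number of
#' points within the closed disc of radius `radius_km`, divided by the
#' disc area pi R^2 (points per km^2).  The grid covers the bounding box
#' of the points expanded by the radius; an explicit bounding box can be
#' supplied to put several classes on a common geometry.
#'
#' @param points data.frame with `x_km`, `y_km` (and optionally
#'   `etymon_class`; pre-filter by class for per-class surfaces).
#' @param cell_km grid cell size in km (default 1).
#' @param radius_km neighborhood radius in km (default 10).
#' @param bbox optional numeric vector `c(xmin, xmax, ymin, ymax)` of the
#'   unexpanded bounding box.
#' @return object of class `density_grid`: list with `x` (cell-center
#'   xs), `y`, `density` (matrix, rows = x, cols = y), `cell_km`,
#'   `radius_km`, `n_points`.
#' @export
point_density <- function(points, cell_km = 1, radius_km = 10,
                          bbox = NULL) {
  if (cell_km <= 0) stop("cell size must be positive")
  if (radius_km <= 0) stop("radius must be positive")
  if (is.null(bbox)) {
    if (nrow(points) == 0) bbox <- c(0, 0, 0, 0)
    else bbox <- c(range(points$x_km), range(points$y_km))
  }
  xs <- seq(bbox[1] - radius_km, bbox[2] + radius_km, by = cell_km)
  ys <- seq(bbox[3] - radius_km, bbox[4] + radius_km, by = cell_km)
  dens <- matrix(0, length(xs), length(ys))
  if (nrow(points) > 0) {
    px <- points$x_km; py <- points$y_km
    r2 <- radius_km^2
    for (i in seq_along(xs)) {
      dx2 <- (px - xs[i])^2
      near <- dx2 <= r2
      if (!any(near)) next
      dy <- outer(py[near], ys, "-")
      dens[i, ] <- colSums(dx2[near] + dy^2 <= r2)
    }
    dens <- dens / (pi * r2)
  }
  structure(list(x = xs, y = ys, density = dens, cell_km = cell_km,
                 radius_km = radius_km, n_points = nrow(points)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat("density grid: ", length(x$x), " x ", length(x$y), " cells (",
      x$cell_km, " km), radius ", x$radius_km, " km, ", x$n_points,
      " points, max density ", format(max(x$density), digits = 3),
      " /km^2\n", sep = "")
  invisible(x)
}

# density value at arbitrary locations: nearest cell center
density_at <- function(grid, x, y) {
  ix <- pmin(pmax(round((x - grid$x[1]) / grid$cell_km) + 1, 1),
             length(grid$x))
  iy <- pmin(pmax(round((y - grid$y[1]) / grid$cell_km) + 1, 1),
             length(grid$y))
  grid$density[cbind(ix, iy)]
}

#' Etymon class composition of a point set
#'
#' @param points data.frame with `etymon_class`.
#' @return data.frame with class, count and proportion (sums to 1).
#' @export
etymon_composition <- function(points) {
  if (nrow(points) == 0) stop("need at least one point")
  cls <- factor(points$etymon_class,
                levels = c("Germanic", "Slavic", "Romance"))
  n <- table(cls)
  data.frame(etymon_class = names(n), count = as.integer(n),
             proportion = as.numeric(n) / nrow(points),
             stringsAsFactors = FALSE)
}

#' Density-based assignment of municipalities to regions A/B
#'
#' A municipality is assigned to region A (former Romance settlement)
#' when the Romance-etymon density at its location exceeds the
#' Slavic-etymon density by at least `margin`, to region B in the
#' mirrored case, and is otherwise resolved by the optional fixed
#' fallback table or flagged unresolved.  Germanic-etymon points play no
#' role in the assignment.
#'
#' @param romance,slavic [point_density()] grids on a shared geometry.
#' @param geo a geo table (see [read_geo_and_distances()]) with
#'   municipality coordinates.
#' @param margin minimum density difference in points per km^2
#'   (default 0).
#' @param fallback optional named character vector municipality -> "A"/"B"
#'   used for ties/below-margin municipalities.
#' @return object of class `region_map`: data.frame with `municipality`,
#'   `region` ("A", "B" or NA), `provenance` ("density-derived",
#'   "fixed-table" or "unresolved"), plus densities.
#' @export
classify_regions <- function(romance, slavic, geo, margin = 0,
                             fallback = NULL) {
  if (!identical(romance$x, slavic$x) || !identical(romance$y, slavic$y))
    stop("density grids must share geometry")
  out_x <- geo$x_km < min(romance$x) | geo$x_km > max(romance$x) |
    geo$y_km < min(romance$y) | geo$y_km > max(romance$y)
  if (any(out_x))
    stop("municipality outside grid: ",
         paste(geo$municipality[out_x], collapse = ", "))
  dr <- density_at(romance, geo$x_km, geo$y_km)
  ds <- density_at(slavic, geo$x_km, geo$y_km)
  region <- ifelse(dr - ds >= margin & dr > ds, "A",
                   ifelse(ds - dr >= margin & ds > dr, "B", NA))
  provenance <- ifelse(!is.na(region), "density-derived", "unresolved")
  if (!is.null(fallback)) {
    fix <- is.na(region) & geo$municipality %in% names(fallback)
    region[fix] <- fallback[geo$municipality[fix]]
    provenance[fix] <- "fixed-table"
  }
  structure(data.frame(municipality = geo$municipality, region = region,
                       provenance = provenance, romance_density = dr,
                       slavic_density = ds, stringsAsFactors = FALSE),
            class = c("region_map", "data.frame"))
}
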