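#' Georeferenced single-band grid layer
#'
#' A lightweight in-memory raster: a numeric matrix with an affine
#' north-up transform. Row 1 is the northernmost row; coordinates refer to
#' cell edges (area/pixel-is-area registration, half-open cells), so the
#' grid spans `[xmin, xmin + ncol*dx] x [ymax - nrow*dy, ymax]`.
#' Nodata is held as `NA` in memory; the `nodata` sentinel is only used at
#' file I/O.
#'
#' @param values Numeric matrix (row 1 = north). Each entry finite or `NA`.
#' @param xmin,ymax Coordinates of the outer top-left corner.
#' @param dx,dy Positive cell sizes (x and y). Metres for projected grids,
#'   decimal degrees for geographic grids.
#' @param crs_kind `"projected"` or `"geographic"`.
#' @param nodata Sentinel written to / read from files (default -9999).
#' @param criterion Optional canonical criterion name carried as metadata.
#' @param units Optional units label.
#' @export
grid_layer <- function(values, xmin = 0, ymax = nrow(values) * dy, dx = 1, dy = dx,
                       crs_kind = c("projected", "geographic"),
                       nodata = -9999, criterion = NULL, units = NULL) {
  crs_kind <- match.arg(crs_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_input("grid values must be a numeric matrix")
  }
  if (any(is.nan(values) | is.infinite(values), na.rm = TRUE)) {
    stop_input("grid values must be finite or NA")
  }
  if (!is.finite(dx) || !is.finite(dy) || dx <= 0 || dy <= 0) {
    stop_input("cell sizes dx, dy must be positive")
  }
  values[!is.na(values) & values == nodata] <- NA_real_
  structure(
    list(values = values, xmin = xmin, ymax = ymax, dx = dx, dy = dy,
         crs_kind = crs_kind, nodata = nodata,
         criterion = criterion, units = units),
    class = "grid_layer"
  )
}

#' @export
print.grid_layer <- function(x, ...) {
  cat(sprintf("<grid_layer> %dx%d %s, cell %gx%g, origin (%g, %g)%s\n",
              nrow(x$values), ncol(x$values), x$crs_kind, x$dx, x$dy,
              x$xmin, x$ymax,
              if (!is.null(x$criterion)) paste0(", ", x$criterion) else ""))
  invisible(x)
}

#' @export
dim.grid_layer <- function(x) dim(x$values)

same_transform <- function(a, b, tol = 1e-9) {
  isTRUE(all.equal(c(a$xmin, a$ymax, a$dx, a$dy),
                   c(b$xmin, b$ymax, b$dx, b$dy), tolerance = tol))
}

#' Bundle aligned layers into a stack
#'
#' @param ... Named `grid_layer`s, or a single named list of them. Names
#'   are criterion names.
#' @return A `layer_stack`. Use [check_alignment()] to verify alignment;
#'   operations that need alignment enforce it themselves.
#' @export
layer_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && !inherits(layers[[1]], "grid_layer")) {
    layers <- layers[[1]]
  }
  if (length(layers) == 0) stop_input("layer stack is empty")
  if (is.null(names(layers)) || any(!nzchar(names(layers)))) {
    stop_input("all layers in a stack must be named")
  }
  for (nm in names(layers)) {
    if (!inherits(layers[[nm]], "grid_layer")) {
      stop_input("stack element '%s' is not a grid_layer", nm)
    }
  }
  structure(list(layers = layers), class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("<layer_stack> %d layer(s): %s\n",
              length(x$layers), paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Check that all layers of a stack share grid geometry
#'
#' @param stack A [layer_stack()].
#' @return `list(ok = TRUE)` if aligned, otherwise `list(ok = FALSE,
#'   layer = <name>, property = "shape"|"transform"|"crs_kind")` naming the
#'   first offending layer.
#' @export
check_alignment <- function(stack) {
  if (!inherits(stack, "layer_stack")) stop_input("not a layer_stack")
  layers <- stack$layers
  if (length(layers) == 0) stop_input("layer stack is empty")
  ref <- layers[[1]]
  for (nm in names(layers)[-1]) {
    l <- layers[[nm]]
    if (!identical(dim(l$values), dim(ref$values))) {
      return(list(ok = FALSE, layer = nm, property = "shape"))
    }
    if (!same_transform(l, ref)) {
      return(list(ok = FALSE, layer = nm, property = "transform"))
    }
    if (!identical(l$crs_kind, ref$crs_kind)) {
      return(list(ok = FALSE, layer = nm, property = "crs_kind"))
    }
  }
  list(ok = TRUE)
}

require_aligned <- function(stack) {
  chk <- check_alignment(stack)
  if (!isTRUE(chk$ok)) {
    stop_input("misaligned stack: layer '%s' differs in %s", chk$layer, chk$property)
  }
  invisible(stack)
}

#' Per-cell areas in square kilometres
#'
#' Projected grids have constant cell area `dx*dy` (transform units are
#' metres, converted to km^2). Geographic grids use the exact spherical
#' band formula per row, `R^2 * |dlon_rad| * |sin(lat_top) -
#' sin(lat_bottom)|` with R = 6371.0072 km, which sums exactly to the
#' sphere's surface over a global grid.
#'
#' @param layer A [grid_layer()].
#' @return Numeric matrix of cell areas (km^2), same shape as the layer.
#' @export
cell_areas <- function(layer) {
  if (!inherits(layer, "grid_layer")) stop_input("not a grid_layer")
  nr <- nrow(layer$values); nc <- ncol(layer$values)
  if (layer$crs_kind == "projected") {
    a <- layer$dx * layer$dy / 1e6 # m^2 -> km^2
    return(matrix(a, nr, nc))
  }
  lat_top <- layer$ymax - (seq_len(nr) - 1) * layer$dy
  lat_bot <- lat_top - layer$dy
  lat_top <- pmin(pmax(lat_top, -90), 90)
  lat_bot <- pmin(pmax(lat_bot, -90), 90)
  band <- EARTH_RADIUS_KM^2 * (layer$dx * pi / 180) *
    abs(sin(lat_top * pi / 180) - sin(lat_bot * pi / 180))
  matrix(rep(band, nc), nr, nc)
}

#' Evaluate a crop profile per pixel over a layer stack
#'
#' Each pixel's score is [score_record()] of that pixel's values: the
#' minimum of the per-criterion trapezoidal memberships. Nodata (`NA`) in
#' any used layer propagates to nodata in the output.
#'
#' @param stack Aligned [layer_stack()] covering all non-excluded criteria.
#' @param profile A [crop_profile()], built-in label, or profile path.
#' @param excluded Criterion names to leave out of the combination.
#' @return A `grid_layer` of suitability scores in `[0, 100]`.
#' @export
suitability_map <- function(stack, profile, excluded = character()) {
  profile <- as_crop_profile(profile)
  require_aligned(stack)
  use <- setdiff(names(profile$criteria), excluded)
  if (length(use) == 0) stop_input("all criteria excluded")
  missing <- setdiff(use, names(stack$layers))
  if (length(missing)) {
    stop_input("stack is missing criterion layer(s): %s", paste(missing, collapse = ", "))
  }
  ref <- stack$layers[[use[1]]]
  acc <- NULL
  for (nm in use) {
    m <- membership(stack$layers[[nm]]$values, profile$criteria[[nm]]$set)
    acc <- if (is.null(acc)) m else pmin(acc, m) # pmin propagates NA
  }
  grid_layer(acc, xmin = ref$xmin, ymax = ref$ymax, dx = ref$dx, dy = ref$dy,
             crs_kind = ref$crs_kind, nodata = ref$nodata,
             criterion = "suitability", units = "score 0-100")
}

# ---- ESRI ASCII grid I/O -------------------------------------------------
# Values, nodata and transform live in the .asc header/body; crs_kind,
# criterion, units and (for non-square cells) dy live in a JSON sidecar
# "<path>.json". A missing sidecar means the georeferencing kind is
# unknown and is an error, mirroring a raster file without a CRS.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a grid layer as an ESRI ASCII grid
#'
#' Writes `path` (plain-text `.asc`, top row first) and a `path`.json
#' sidecar with `crs_kind`, `criterion`, `units` and the y cell size.
#' Round-trips values, nodata, transform and crs_kind losslessly.
#'
#' @param layer A [grid_layer()].
#' @param path Output path (conventionally ending in `.asc`).
#' @export
write_map <- function(layer, path) {
  if (!inherits(layer, "grid_layer")) stop_input("not a grid_layer")
  nr <- nrow(layer$values); nc <- ncol(layer$values)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.17g", layer$xmin),
    sprintf("yllcorner %.17g", layer$ymax - nr * layer$dy),
    if (layer$dx == layer$dy) sprintf("cellsize %.17g", layer$dx)
    else c(sprintf("dx %.17g", layer$dx), sprintf("dy %.17g", layer$dy)),
    sprintf("NODATA_value %.17g", layer$nodata)
  )
  v <- layer$values
  v[is.na(v)] <- layer$nodata
  rows <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  jsonlite::write_json(
    list(crs_kind = layer$crs_kind, criterion = layer$criterion,
         units = layer$units, dy = layer$dy),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Read a grid layer written by [write_map()]
#'
#' @param path Path to the `.asc` file; its `.json` sidecar (carrying the
#'   CRS kind) must be present.
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop_input("raster file not found: %s", path)
  if (!file.exists(sidecar_path(path))) {
    stop_input("raster '%s' has no georeferencing sidecar (missing CRS)", path)
  }
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (is.null(meta$crs_kind) || !meta$crs_kind %in% c("projected", "geographic")) {
    stop_input("raster '%s': sidecar lacks a valid crs_kind", path)
  }
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner")
  if (!all(need %in% names(hdr))) stop_input("raster '%s': malformed header", path)
  dx <- hdr$cellsize %||% hdr$dx
  dy <- hdr$cellsize %||% hdr$dy
  if (is.null(dx) || is.null(dy)) stop_input("raster '%s': no cell size", path)
  nodata <- hdr$nodata_value %||% -9999
  body <- lines[i:length(lines)]
  vals <- scan(text = body, quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols) {
    stop_input("raster '%s': expected %d values, found %d",
               path, hdr$nrows * hdr$ncols, length(vals))
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  grid_layer(m, xmin = hdr$xllcorner, ymax = hdr$yllcorner + hdr$nrows * dy,
             dx = dx, dy = dy, crs_kind = meta$crs_kind, nodata = nodata,
             criterion = if (is.null(meta$criterion)) NULL else meta$criterion,
             units = if (is.null(meta$units)) NULL else meta$units)
}

# Nearest-cell (containing-cell) lookup of layer values at coordinates.
# Half-open cells: a point on a shared edge belongs to the cell right/below.
sample_layer <- function(layer, lon, lat) {
  col <- floor((lon - layer$xmin) / layer$dx) + 1
  row <- floor((layer$ymax - lat) / layer$dy) + 1
  out <- rep(NA_real_, length(lon))
  ok <- col >= 1 & col <= ncol(layer$values) & row >= 1 & row <= nrow(layer$values)
  out[ok] <- layer$values[cbind(row[ok], col[ok])]
  out
}
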