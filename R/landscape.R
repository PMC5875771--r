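#' Categorical land-use grids
#'
#' A `land_grid` is a categorical raster on a planar metric grid: an integer
#' matrix of class codes (row 1 = northernmost row, as stored in an ESRI
#' ASCII file), the lower-left corner coordinates, the cell size in metres
#' and a nodata code. After [merge_classes()] the codes index the merged
#' land-use class labels stored in `$classes`.
#'
#' @param cells integer matrix of class codes, row 1 = top (north) row.
#' @param origin_x,origin_y coordinates (m) of the lower-left grid corner.
#' @param cell_size cell edge length in metres (> 0).
#' @param nodata_code integer code marking cells with no data.
#' @param classes optional character vector of merged class labels; when
#'   present, cell values are indices into this vector.
#' @return an object of class `land_grid`.
#' @export
land_grid <- function(cells, origin_x, origin_y, cell_size,
                      nodata_code = -9999L, classes = NULL) {
  if (!is.matrix(cells)) stop("'cells' must be a matrix")
  if (any(!is.finite(cells))) stop("grid cells must be finite")
  if (any(cells != round(cells))) stop("grid cells must be integer class codes")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("'cell_size' must be a single positive number")
  g <- structure(list(
    origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
    cell_size = as.numeric(cell_size),
    n_rows = nrow(cells), n_cols = ncol(cells),
    cells = matrix(as.integer(round(cells)), nrow(cells), ncol(cells)),
    nodata_code = as.integer(nodata_code),
    classes = classes
  ), class = "land_grid")
  g
}

#' @export
print.land_grid <- function(x, ...) {
  cat(sprintf("land_grid: %d x %d cells of %g m (extent %.1f x %.1f km)\n",
              x$n_rows, x$n_cols, x$cell_size,
              x$n_cols * x$cell_size / 1000, x$n_rows * x$cell_size / 1000))
  cat(sprintf("  lower-left corner (%.1f, %.1f), nodata code %d\n",
              x$origin_x, x$origin_y, x$nodata_code))
  if (!is.null(x$classes))
    cat("  merged classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

# cell-centre coordinates; row 1 is the top (north) row
grid_cell_centers <- function(grid) {
  xs <- grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  ys <- grid$origin_y + (grid$n_rows - seq_len(grid$n_rows) + 0.5) * grid$cell_size
  list(x = xs, y = ys)
}

#' Read a categorical raster
#'
#' Reads an ESRI ASCII grid (`ncols`/`nrows`/`xllcorner`/`yllcorner`/
#' `cellsize`/`NODATA_value` header followed by row-major cell values).
#' Coordinates are interpreted as planar metres.
#'
#' @param path path to the raster file.
#' @param format only `"esri_ascii"` is supported.
#' @return a [land_grid()].
#' @export
read_grid <- function(path, format = c("esri_ascii", "geotiff")) {
  format <- match.arg(format)
  if (format == "geotiff")
    stop("GeoTIFF input is not supported: no georeferenced-TIFF reader is ",
         "available; convert the raster to ESRI ASCII (.asc)")
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1]) &&
        !is.na(suppressWarnings(as.numeric(tok[2])))) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("malformed ESRI ASCII header: missing ", paste(miss, collapse = ", "),
         " in ", path)
  if (!"nodata_value" %in% names(hdr))
    stop("malformed ESRI ASCII header: missing NODATA_value declaration in ", path)
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(lines[-seq_len(i)]), "\\s+"))))
  vals <- vals[!is.na(vals)]
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("ESRI ASCII body has ", length(vals), " values, expected ", nr * nc)
  if (any(vals != round(vals)))
    stop("non-integer cell values in ", path,
         " (first at position ", which(vals != round(vals))[1], ")")
  cells <- matrix(as.integer(vals), nrow = nr, ncol = nc, byrow = TRUE)
  land_grid(cells, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
            nodata_code = as.integer(hdr$nodata_value))
}

#' Write a grid as ESRI ASCII
#'
#' @param grid a [land_grid()]; merged class indices are written as plain
#'   integer codes (the label table is not stored in the file).
#' @param path output path.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "land_grid"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.6f", grid$origin_x),
    sprintf("yllcorner %.6f", grid$origin_y),
    sprintf("cellsize %.6f", grid$cell_size),
    sprintf("NODATA_value %d", grid$nodata_code)), con)
  writeLines(apply(grid$cells, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Default land-use class merging table
#'
#' Maps the raw land-use codes of the source classification onto the merged
#' model classes: young and old stands of the same composition are pooled
#' ("Y" = young, "Mo" = mature and old) and built-up codes (built areas,
#' roads, mines) are pooled as "Built". Raw code 25 is agricultural field,
#' carried by a separate land-use layer in the source maps and therefore
#' given its own code here.
#'
#' @return a data frame with columns `raw_code` and `class`.
#' @export
default_class_table <- function() {
  data.frame(
    raw_code = c(1L, 3L, 6L, 4L, 5L, 7L, 8L, 9L, 15L, 10L, 16L, 11L, 17L,
                 12L, 18L, 13L, 19L, 14L, 20L, 21L, 22L, 23L, 24L, 25L),
    class = c("Clear cut", "Y birch", "Y birch", "Y pine", "Y mix", "Y mix",
              "Y mix", "Mo birch", "Mo birch", "Mo pine", "Mo pine",
              "Mo spruce", "Mo spruce", "Mo birch pine", "Mo birch pine",
              "Mo pine spruce", "Mo pine spruce", "Mo birch spruce",
              "Mo birch spruce", "Built", "Built", "Built", "Bog", "Field"),
    stringsAsFactors = FALSE
  )
}

#' Merge raw land-use codes into model classes
#'
#' Replaces raw integer codes with indices into the merged class label set.
#' Applying the operation to an already-merged grid returns it unchanged.
#'
#' @param grid a [land_grid()] of raw codes.
#' @param table a class table as returned by [default_class_table()]
#'   (columns `raw_code`, `class`).
#' @return a merged [land_grid()] with `$classes` set.
#' @export
merge_classes <- function(grid, table = default_class_table()) {
  stopifnot(inherits(grid, "land_grid"))
  if (!is.null(grid$classes)) return(grid)
  if (anyDuplicated(table$raw_code))
    stop("class table maps a raw code to two labels: ",
         paste(unique(table$raw_code[duplicated(table$raw_code)]), collapse = ", "))
  if (any(!nzchar(table$class))) stop("class table contains empty labels")
  cells <- grid$cells
  live <- cells != grid$nodata_code
  unknown <- setdiff(unique(cells[live]), table$raw_code)
  if (length(unknown)) {
    idx <- which(live & matrix(cells %in% unknown, nrow(cells)))[1]
    stop("unknown raw land-use code(s) ", paste(unknown, collapse = ", "),
         " (first at cell index ", idx, ")")
  }
  labels <- unique(table$class)
  code_of <- match(table$class, labels)
  merged <- cells
  merged[live] <- code_of[match(cells[live], table$raw_code)]
  land_grid(merged, grid$origin_x, grid$origin_y, grid$cell_size,
            nodata_code = grid$nodata_code, classes = labels)
}

#' Habitat composition within a circular buffer
#'
#' Areas (hectares) of each land-use class whose cell centre lies within
#' `radius_m` of a point (Euclidean distance on the planar grid). A cell
#' contributes its full area if and only if its centre is inside the buffer;
#' nodata cells are excluded. Classes absent inside the buffer are reported
#' with area 0. Buffers are truncated at the grid edge; a buffer entirely
#' outside the grid yields an all-zero composition with a warning.
#'
#' @param grid a [land_grid()], usually merged.
#' @param x,y point coordinates in metres.
#' @param radius_m buffer radius in metres (> 0).
#' @return a data frame with columns `class` and `area_ha`, with attributes
#'   `radius_m` and `total_area_ha`.
#' @export
buffer_composition <- function(grid, x, y, radius_m) {
  stopifnot(inherits(grid, "land_grid"))
  if (!is.finite(x) || !is.finite(y)) stop("point coordinates must be finite")
  if (!is.numeric(radius_m) || radius_m <= 0) stop("'radius_m' must be > 0")
  universe <- if (!is.null(grid$classes)) grid$classes else
    sort(unique(grid$cells[grid$cells != grid$nodata_code]))
  out <- data.frame(class = as.character(universe),
                    area_ha = numeric(length(universe)),
                    stringsAsFactors = FALSE)
  cc <- grid_cell_centers(grid)
  cols <- which(cc$x >= x - radius_m & cc$x <= x + radius_m)
  rows <- which(cc$y >= y - radius_m & cc$y <= y + radius_m)
  if (!length(cols) || !length(rows)) {
    warning("buffer entirely outside grid at (", x, ", ", y, "), r = ", radius_m)
    attr(out, "radius_m") <- radius_m
    attr(out, "total_area_ha") <- 0
    return(out)
  }
  sub <- grid$cells[rows, cols, drop = FALSE]
  dx <- matrix(cc$x[cols] - x, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  dy <- matrix(cc$y[rows] - y, nrow = length(rows), ncol = length(cols))
  inside <- (dx * dx + dy * dy) <= radius_m^2 & sub != grid$nodata_code
  if (!any(inside)) {
    if (max(cc$x) < x - radius_m || min(cc$x) > x + radius_m ||
        max(cc$y) < y - radius_m || min(cc$y) > y + radius_m)
      warning("buffer entirely outside grid at (", x, ", ", y, "), r = ", radius_m)
    attr(out, "radius_m") <- radius_m
    attr(out, "total_area_ha") <- 0
    return(out)
  }
  cell_ha <- grid$cell_size^2 / 1e4
  tab <- table(sub[inside])
  codes <- as.integer(names(tab))
  key <- if (!is.null(grid$classes)) grid$classes[codes] else as.character(codes)
  out$area_ha[match(key, out$class)] <- as.numeric(tab) * cell_ha
  attr(out, "radius_m") <- radius_m
  attr(out, "total_area_ha") <- sum(out$area_ha)
  out
}

#' Buffer composition for a table of nest boxes
#'
#' Vectorizes [buffer_composition()] over the rows of a nest-box table.
#'
#' @param grid a merged [land_grid()].
#' @param boxes data frame with columns `box_id`, `x`, `y`.
#' @param radius_m buffer radius in metres.
#' @return long-format data frame `box_id`, `radius_m`, `class`, `area_ha`.
#' @export
habitat_composition <- function(grid, boxes, radius_m) {
  stopifnot(all(c("box_id", "x", "y") %in% names(boxes)))
  res <- lapply(seq_len(nrow(boxes)), function(i) {
    comp <- buffer_composition(grid, boxes$x[i], boxes$y[i], radius_m)
    data.frame(box_id = boxes$box_id[i], radius_m = radius_m,
               class = comp$class, area_ha = comp$area_ha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Reshape a long habitat composition to one column per class
#'
#' @param composition output of [habitat_composition()].
#' @return data frame with `box_id` and one area column (ha) per class.
#' @export
habitat_wide <- function(composition) {
  classes <- unique(composition$class)
  wide <- data.frame(box_id = unique(composition$box_id), stringsAsFactors = FALSE)
  for (cl in classes) {
    sub <- composition[composition$class == cl, ]
    wide[[cl]] <- sub$area_ha[match(wide$box_id, sub$box_id)]
  }
  wide
}
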