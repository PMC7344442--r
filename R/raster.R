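#' Canonical land-use legend
#'
#' The eight-class legend used throughout the package. Codes are fixed so
#' that every table, rules matrix and coefficient column refers to the same
#' class order: 1 paddy field, 2 unirrigated field, 3 forest land,
#' 4 grass land, 5 water area, 6 wet land, 7 built-up land, 8 unused land.
#'
#' @return Named character vector; names are the integer codes as strings.
#' @export
land_legend <- function() {
  c("1" = "paddy field", "2" = "unirrigated field", "3" = "forest land",
    "4" = "grass land", "5" = "water area", "6" = "wet land",
    "7" = "built-up land", "8" = "unused land")
}

#' Categorical land-use raster
#'
#' A minimal in-memory container for a class-coded grid: an integer matrix
#' (NA = nodata), the area of one cell in hectares, and a legend mapping
#' codes to class names. No coordinate reference system is attached; the
#' grid is treated as a plain lattice with square cells.
#'
#' @param grid Integer matrix of class codes; NA marks nodata cells.
#' @param cell_area Area of one cell in hectares (> 0).
#' @param legend Named character vector mapping code (as string) to name.
#' @return An object of class `land_raster`.
#' @export
land_raster <- function(grid, cell_area = 1, legend = land_legend()) {
  if (!is.matrix(grid)) stop("`grid` must be a matrix")
  storage.mode(grid) <- "integer"
  if (!is.numeric(cell_area) || length(cell_area) != 1L || cell_area <= 0)
    stop("`cell_area` must be a single positive number (hectares)")
  codes <- sort(unique(as.vector(grid)))
  codes <- codes[!is.na(codes)]
  unknown <- setdiff(as.character(codes), names(legend))
  if (length(unknown))
    stop("grid contains codes absent from the legend: ",
         paste(unknown, collapse = ", "))
  structure(list(grid = grid, cell_area = as.numeric(cell_area),
                 legend = legend),
            class = "land_raster")
}

#' @export
print.land_raster <- function(x, ...) {
  cat("Land-use raster:", nrow(x$grid), "x", ncol(x$grid), "cells,",
      x$cell_area, "ha/cell\n")
  cnt <- class_counts(x)
  shown <- cnt[cnt > 0]
  nm <- x$legend[names(shown)]
  for (i in seq_along(shown))
    cat(sprintf("  %-18s %8d cells (%5.1f%%)\n", nm[i], shown[i],
                100 * shown[i] / sum(cnt)))
  invisible(x)
}

#' @export
dim.land_raster <- function(x) dim(x$grid)

#' Cell counts per legend class
#'
#' @param x A `land_raster`.
#' @return Integer vector named by class code, one entry per legend class
#'   (zero for absent classes); nodata cells are not counted.
#' @export
class_counts <- function(x) {
  stopifnot(inherits(x, "land_raster"))
  codes <- names(x$legend)
  cnt <- table(factor(as.vector(x$grid), levels = codes))
  out <- as.integer(cnt)
  names(out) <- codes
  out
}

#' Class areas in a declared unit
#'
#' @param x A `land_raster`.
#' @param unit `"ha"` or `"km2"`.
#' @return Numeric vector of per-class areas named by code.
#' @export
class_areas <- function(x, unit = c("ha", "km2")) {
  unit <- match.arg(unit)
  a <- class_counts(x) * x$cell_area
  if (unit == "km2") a <- a / 100
  a
}

#' Stack of driving-factor layers
#'
#' @param layers Named list of numeric matrices, all the same dimension.
#' @param kind Character vector (`"continuous"` or `"multi-class"`), one
#'   per layer; recycled if length 1.
#' @return An object of class `factor_stack`.
#' @export
factor_stack <- function(layers, kind = "continuous") {
  if (!length(layers) || is.null(names(layers)) || any(names(layers) == ""))
    stop("`layers` must be a non-empty named list")
  d <- dim(layers[[1]])
  ok <- vapply(layers, function(m) is.matrix(m) && all(dim(m) == d), TRUE)
  if (!all(ok)) stop("all layers must be matrices of identical dimension")
  kind <- rep_len(kind, length(layers))
  if (!all(kind %in% c("continuous", "multi-class")))
    stop("`kind` entries must be 'continuous' or 'multi-class'")
  structure(list(layers = layers, kind = stats::setNames(kind, names(layers))),
            class = "factor_stack")
}

#' @export
print.factor_stack <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat("Factor stack:", length(x$layers), "layers,", d[1], "x", d[2], "cells\n")
  for (nm in names(x$layers)) cat(sprintf("  %-24s %s\n", nm, x$kind[[nm]]))
  invisible(x)
}

#' @export
length.factor_stack <- function(x) length(x$layers)

# ---- plain-text grid I/O (ESRI ASCII grid) ----------------------------------

write_asc_matrix <- function(m, path, nodata = -9999, cellsize = 1,
                             digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)),
               paste("nrows", nrow(m)),
               "xllcorner 0", "yllcorner 0",
               paste("cellsize", cellsize),
               paste("NODATA_value", nodata)), con)
  v <- m
  v[is.na(v)] <- nodata
  txt <- apply(v, 1, function(r) paste(formatC(r, format = "g",
                                               digits = digits),
                                       collapse = " "))
  writeLines(txt, con)
}

read_asc_matrix <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  for (k in c("ncols", "nrows", "nodata_value"))
    if (!k %in% keys) stop("malformed ASCII grid header in ", path)
  v <- scan(path, skip = 6, quiet = TRUE)
  if (length(v) != vals[["ncols"]] * vals[["nrows"]])
    stop("ASCII grid body does not match header dimensions in ", path)
  m <- matrix(v, nrow = vals[["nrows"]], ncol = vals[["ncols"]], byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA
  m
}

#' Write a categorical raster as an ASCII grid with a legend sidecar
#'
#' The grid goes to `<path>` in ESRI ASCII grid format (a plain-text
#' interchange format every GIS reads); the legend and cell area go to
#' `<path>.legend.csv`. Round-trip through [read_raster()] is exact for
#' integer class codes and preserves nodata.
#'
#' @param x A `land_raster`.
#' @param path Output file path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path) {
  stopifnot(inherits(x, "land_raster"))
  write_asc_matrix(x$grid, path, digits = 12)
  utils::write.csv(
    data.frame(code = names(x$legend), name = unname(x$legend),
               cell_area_ha = x$cell_area),
    paste0(path, ".legend.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a categorical raster written by [write_raster()]
#'
#' @param path Path to the `.asc` grid; `<path>.legend.csv` must exist.
#' @return A `land_raster`. Codes not present in the legend are an error.
#' @export
read_raster <- function(path) {
  m <- read_asc_matrix(path)
  if (any(abs(m - round(m)) > 0, na.rm = TRUE))
    stop("non-integer cell values: ", path,
         " does not hold categorical data")
  leg_path <- paste0(path, ".legend.csv")
  if (!file.exists(leg_path)) stop("missing legend sidecar: ", leg_path)
  leg <- utils::read.csv(leg_path, colClasses = c("character", "character",
                                                  "numeric"))
  land_raster(matrix(as.integer(m), nrow(m), ncol(m)),
              cell_area = leg$cell_area_ha[1],
              legend = stats::setNames(leg$name, leg$code))
}

#' Write a factor stack as one ASCII grid per layer
#'
#' Layers are written to `dir/<name>.asc` with an index file
#' `dir/layers.csv` recording name, kind and order.
#'
#' @param x A `factor_stack`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_factors <- function(x, dir) {
  stopifnot(inherits(x, "factor_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  safe <- gsub("[^A-Za-z0-9_.-]", "_", names(x$layers))
  for (i in seq_along(x$layers))
    write_asc_matrix(x$layers[[i]], file.path(dir, paste0(safe[i], ".asc")))
  utils::write.csv(data.frame(name = names(x$layers), file = paste0(safe, ".asc"),
                              kind = unname(x$kind)),
                   file.path(dir, "layers.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a factor stack written by [write_factors()]
#'
#' @param dir Directory containing `layers.csv` and the layer grids.
#' @return A `factor_stack`.
#' @export
read_factors <- function(dir) {
  idx <- utils::read.csv(file.path(dir, "layers.csv"),
                         colClasses = "character")
  layers <- lapply(idx$file, function(f) read_asc_matrix(file.path(dir, f)))
  names(layers) <- idx$name
  factor_stack(layers, kind = idx$kind)
}
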