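#' Define a regular analysis grid
#'
#' A grid of square cells addressed `[row, col]` with a top-left origin,
#' 0-based external addressing in files, 1-based inside R. All rasters in the
#' pipeline (reflectance, AOD, PM2.5, population, risk) share one `grid_spec`.
#'
#' @param n_rows,n_cols Positive integer grid dimensions.
#' @param cell_size_km Cell edge length in kilometres (default 1, the
#'   working resolution of the whole pipeline).
#' @param origin Numeric length-2, world coordinates of the top-left corner
#'   (x, y); only carried through raster headers.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size_km = 1, origin = c(0, 0)) {
  if (length(n_rows) != 1L || n_rows < 1 || n_rows != as.integer(n_rows))
    stop("`n_rows` must be a single positive integer")
  if (length(n_cols) != 1L || n_cols < 1 || n_cols != as.integer(n_cols))
    stop("`n_cols` must be a single positive integer")
  if (cell_size_km <= 0) stop("`cell_size_km` must be > 0")
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size_km = cell_size_km, origin = as.numeric(origin)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %.3g km cell size\n",
              x$n_rows, x$n_cols, x$cell_size_km))
  invisible(x)
}

NODATA <- -9999

#' Write a grid as an ESRI ASCII raster
#'
#' Writes a numeric matrix as an Arc/Info ASCII grid (`.asc`): a plain-text
#' raster format carrying dimensions, the affine origin, cell size and a
#' nodata sentinel (-9999). `NA` cells become nodata.
#'
#' @param grid Numeric matrix (rows are raster rows, top first).
#' @param path Output file path.
#' @param spec Optional [grid_spec()]; defaults to a spec inferred from the
#'   matrix with 1-km cells at origin (0, 0).
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, spec = NULL) {
  if (!is.matrix(grid) || !is.numeric(grid))
    stop("`grid` must be a numeric matrix")
  if (is.null(spec)) spec <- grid_spec(nrow(grid), ncol(grid))
  if (nrow(grid) != spec$n_rows || ncol(grid) != spec$n_cols)
    stop("grid dimensions do not match `spec`")
  cell <- spec$cell_size_km * 1000
  hdr <- c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$origin[1]),
    sprintf("yllcorner %.10g", spec$origin[2] - spec$n_rows * cell),
    sprintf("cellsize %.10g", cell),
    sprintf("NODATA_value %d", NODATA)
  )
  g <- grid
  g[is.na(g)] <- NODATA
  body <- apply(g, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' Inverse of [write_grid()]; nodata cells become `NA`.
#'
#' @param path Path to a `.asc` file.
#' @return A list with `grid` (numeric matrix, `NA` = nodata) and `spec`
#'   (a [grid_spec()]).
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys)) stop("not an ESRI ASCII grid: header incomplete")
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != nr * nc)
    stop(sprintf("expected %d values, found %d", nr * nc, length(body)))
  g <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  g[g == vals[["nodata_value"]]] <- NA_real_
  cell_km <- vals[["cellsize"]] / 1000
  spec <- grid_spec(nr, nc, cell_km,
                    origin = c(vals[["xllcorner"]],
                               vals[["yllcorner"]] + nr * vals[["cellsize"]]))
  list(grid = g, spec = spec)
}

# Evaluate a function under a temporary RNG state; restores the caller's seed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

# Spawn reproducible child seeds from one master seed (kept below 2^31).
derive_seeds <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max - 1L, n))
}
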