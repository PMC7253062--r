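#' Construct a food grid from a matrix of cell values
#'
#' A food grid is the dwelling space of a colony: a `height x width` matrix
#' of non-negative food units (rows are y, columns are x) together with a
#' conservation ledger recording the initial total and the food consumed so
#' far by adults and by larvae.
#'
#' @param cells numeric matrix of non-negative food units.
#' @return An object of class `"food_grid"`.
#' @seealso [make_gaussian_patch()], [read_grid()], [consume_at()]
#' @export
food_grid <- function(cells) {
  if (!is.matrix(cells) || !is.numeric(cells))
    stop("cells must be a numeric matrix")
  if (anyNA(cells)) stop("cells must not contain missing values")
  if (any(cells < 0)) stop("cells must be non-negative")
  structure(list(cells = cells,
                 width = ncol(cells), height = nrow(cells),
                 initial_total = sum(cells),
                 consumed = c(adult = 0, larva = 0)),
            class = "food_grid")
}

#' @export
print.food_grid <- function(x, ...) {
  cat(sprintf("<food_grid> %d x %d cells, %.0f units remaining of %.0f (adults ate %.0f, larvae %.0f)\n",
              x$width, x$height, sum(x$cells), x$initial_total,
              x$consumed[["adult"]], x$consumed[["larva"]]))
  invisible(x)
}

#' Central 2D Gaussian food patch
#'
#' Builds a food grid whose cell values follow an isotropic 2D Gaussian
#' centred at `(width/2, height/2)`, rescaled so the grid sums exactly to
#' `total_food`. The default `sigma` of 5 cells concentrates >= 99% of the
#' food within a 16-cell radius and puts ~6.4 adult meals in the centre
#' cell, so that adult as well as larval feeding can operate on the patch.
#'
#' @param width,height grid dimensions in cells.
#' @param total_food total food units on the patch.
#' @param sigma Gaussian standard deviation in cells.
#' @return A [food_grid()] with its maximum at the centre cell.
#' @export
make_gaussian_patch <- function(width = 300, height = 300,
                                total_food = 1e6, sigma = 5) {
  if (width < 1 || height < 1) stop("grid dimensions must be positive")
  if (total_food <= 0) stop("total_food must be positive")
  if (sigma <= 0) stop("sigma must be positive")
  cx <- width / 2
  cy <- height / 2
  gx <- exp(-((seq_len(width) - cx)^2) / (2 * sigma^2))
  gy <- exp(-((seq_len(height) - cy)^2) / (2 * sigma^2))
  cells <- outer(gy, gx)                   # rows = y, cols = x
  cells <- cells * (total_food / sum(cells))
  food_grid(cells)
}

#' Read / write a food grid as dense CSV
#'
#' The on-disk format is a dense comma-separated table, `height` rows by
#' `width` columns, no header: one food value per cell. Writing then reading
#' reproduces every cell exactly.
#'
#' @param path file path.
#' @return `read_grid()` returns a [food_grid()]; `write_grid()` returns
#'   `path` invisibly.
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("grid file is empty: ", path)
  rows <- strsplit(lines, ",", fixed = TRUE)
  ncols <- length(rows[[1L]])
  vals <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != ncols)
      stop(sprintf("ragged grid: row %d has %d columns, expected %d",
                   i, length(rows[[i]]), ncols))
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop(sprintf("non-numeric cell at row %d, column %d", i, j))
    }
    if (any(v < 0)) {
      j <- which(v < 0)[1L]
      stop(sprintf("negative food value at row %d, column %d", i, j))
    }
    vals[[i]] <- v
  }
  food_grid(do.call(rbind, vals))
}

#' @param grid a [food_grid()].
#' @rdname read_grid
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "food_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  # format() would round; sprintf %.17g preserves doubles exactly
  for (i in seq_len(grid$height))
    writeLines(paste(sprintf("%.17g", grid$cells[i, ]), collapse = ","), con)
  invisible(path)
}

#' All-or-nothing meal at one grid cell
#'
#' A consumer demanding `demand` units at cell `(x, y)` is fed if and only
#' if the cell currently holds at least `demand` units; a fed consumer
#' removes exactly `demand` units, a starved one removes nothing. The
#' grid's consumption ledger is updated under `consumer` ("adult" or
#' "larva") so that adult versus larval food shares can be audited.
#'
#' @param grid a [food_grid()].
#' @param x,y integer cell coordinates (1-based; `x` is the column).
#' @param demand food units demanded (`>= 0`).
#' @param consumer `"adult"` or `"larva"`; which ledger the meal is charged to.
#' @return List with `fed` (logical), `consumed` (units actually removed)
#'   and `grid` (the updated grid).
#' @export
consume_at <- function(grid, x, y, demand, consumer = c("larva", "adult")) {
  stopifnot(inherits(grid, "food_grid"))
  consumer <- match.arg(consumer)
  if (x < 1 || x > grid$width || y < 1 || y > grid$height)
    stop(sprintf("cell (%g, %g) is outside the %d x %d grid",
                 x, y, grid$width, grid$height))
  if (demand < 0) stop("demand must be non-negative")
  fed <- grid$cells[y, x] >= demand
  consumed <- 0
  if (fed) {
    grid$cells[y, x] <- grid$cells[y, x] - demand
    grid$consumed[[consumer]] <- grid$consumed[[consumer]] + demand
    consumed <- demand
  }
  list(fed = fed, consumed = consumed, grid = grid)
}

#' Food remaining on a grid
#' @param grid a [food_grid()].
#' @export
food_remaining <- function(grid) {
  stopifnot(inherits(grid, "food_grid"))
  sum(grid$cells)
}
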