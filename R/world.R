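#' Grid-world directions
#'
#' The four sensor/actuator symbols share one alphabet: `down`, `left`,
#' `up`, `right`, with displacement vectors (0,-1), (-1,0), (0,+1), (+1,0).
#'
#' @return character vector of the four direction names, in canonical order.
#' @export
directions <- function() c("down", "left", "up", "right")

# displacement matrix, rows in canonical direction order
DIR_DISP <- matrix(c(0L, -1L,
                     -1L, 0L,
                     0L, 1L,
                     1L, 0L),
                   ncol = 2, byrow = TRUE,
                   dimnames = list(directions(), c("x", "y")))

#' World setups
#'
#' A setup fixes the pheromone sources, the start radius `d` (initial
#' positions uniform on \{-d..d\}^2) and the horizon `T` (memory read out at
#' time `T`). Two presets mirror the studied scenarios:
#' * `"s+"`: a single source at the origin, `d = 5`;
#' * `"sq"`: four sources at \{-5, 5\}^2, `d = 10`.
#'
#' The infinite grid is represented by the finite box
#' `max(|x|, |y|) <= d + T`, which is closed under `T`-step dynamics from
#' any start cell.
#'
#' @param name `"s+"`, `"sq"`, or `NULL` when `sources` is given explicitly.
#' @param sources integer matrix (n x 2) of source cells; overrides `name`.
#' @param d start radius (nonnegative integer). Defaults to the preset's
#'   value (5 for s+, 10 for sq).
#' @param horizon number of controller applications T (default 15).
#' @param metric distance ordering of the pheromone field: `"euclidean"`
#'   (default, an isotropic plume) or `"manhattan"` (grid metric; changes
#'   the sensor's tie sets at off-axis cells).
#' @return an object of class `world_setup`.
#' @export
world_setup <- function(name = "s+", sources = NULL, d = NULL, horizon = 15,
                        metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  if (is.null(sources)) {
    sources <- switch(name,
      "s+" = matrix(c(0L, 0L), ncol = 2),
      "sq" = as.matrix(expand.grid(x = c(-5L, 5L), y = c(-5L, 5L))),
      stop("unknown setup name: ", name))
    if (is.null(d)) d <- if (identical(name, "sq")) 10L else 5L
  } else {
    sources <- matrix(as.integer(sources), ncol = 2)
    if (nrow(sources) < 1) stop("at least one source is required")
    if (is.null(d)) d <- 5L
    name <- if (is.null(name)) "custom" else name
  }
  d <- as.integer(d); horizon <- as.integer(horizon)
  if (d < 0) stop("d must be >= 0")
  if (horizon < 0) stop("horizon must be >= 0")
  colnames(sources) <- c("x", "y")
  structure(list(name = name, sources = sources, d = d, horizon = horizon,
                 metric = metric),
            class = "world_setup")
}

#' @export
print.world_setup <- function(x, ...) {
  cat(sprintf("world_setup '%s': %d source(s), d=%d, T=%d, box |.|<=%d\n",
              x$name, nrow(x$sources), x$d, x$horizon, x$d + x$horizon))
  invisible(x)
}

box_halfwidth <- function(setup) setup$d + setup$horizon

# cell <-> index maps for a box of halfwidth L (index 1-based,
# idx = (x+L)*(2L+1) + (y+L) + 1)
cell_index <- function(cells, L) {
  (cells[, 1] + L) * (2L * L + 1L) + (cells[, 2] + L) + 1L
}

index_cell <- function(idx, L) {
  w <- 2L * L + 1L
  z <- idx - 1L
  cbind(x = z %/% w - L, y = z %% w - L)
}

box_cells <- function(L) {
  w <- -L:L
  as.matrix(expand.grid(y = w, x = w))[, c("x", "y"), drop = FALSE]
}

# distance to the nearest source, exact in integers (squared Euclidean,
# or Manhattan -- both orderings are computed without floats)
nearest_source_dist2 <- function(setup, cells) {
  manhattan <- identical(setup$metric, "manhattan")
  d2 <- rep(Inf, nrow(cells))
  for (i in seq_len(nrow(setup$sources))) {
    s <- setup$sources[i, ]
    di <- if (manhattan) abs(cells[, 1] - s[1]) + abs(cells[, 2] - s[2])
          else (cells[, 1] - s[1])^2 + (cells[, 2] - s[2])^2
    d2 <- pmin(d2, di)
  }
  d2
}

# Sensor field over the whole box: ncells x 4 matrix of probabilities.
# The sensor points to the adjacent cell with the highest pheromone
# concentration; concentration decreases strictly with Euclidean distance
# to the nearest source, so the argmax is the neighbour minimizing that
# distance. Ties are folded in exactly as a uniform distribution over the
# tied directions.
sensor_field <- function(setup, L = box_halfwidth(setup)) {
  cells <- box_cells(L)
  n <- nrow(cells)
  d2 <- matrix(0, n, 4)
  for (a in 1:4) {
    nb <- cbind(cells[, 1] + DIR_DISP[a, 1], cells[, 2] + DIR_DISP[a, 2])
    d2[, a] <- nearest_source_dist2(setup, nb)
  }
  best <- do.call(pmin, as.data.frame(d2))
  tie <- d2 == best            # exact integer comparison
  tie / rowSums(tie)
}

# per-setup, per-L cache of sensor fields (fields depend only on sources)
.field_cache <- new.env(parent = emptyenv())

cached_sensor_field <- function(setup, L) {
  key <- paste(c(t(setup$sources), setup$metric, L), collapse = "|")
  f <- .field_cache[[key]]
  if (is.null(f)) {
    f <- sensor_field(setup, L)
    .field_cache[[key]] <- f
  }
  f
}

check_in_box <- function(setup, cell, what = "cell") {
  L <- box_halfwidth(setup)
  if (max(abs(cell)) > L)
    stop(sprintf("%s (%d,%d) lies outside the bounding box |.| <= %d",
                 what, cell[1], cell[2], L))
  invisible(TRUE)
}

#' Sensor distribution at a cell
#'
#' Probability over the four directions that the pheromone sensor reports;
#' uniform over the directions whose adjacent cell minimizes the Euclidean
#' distance to the nearest source.
#'
#' @param setup a [world_setup()].
#' @param cell integer vector `c(x, y)` inside the bounding box.
#' @return named numeric vector of length 4 summing to 1.
#' @export
sensor_distribution <- function(setup, cell) {
  check_in_box(setup, cell)
  L <- box_halfwidth(setup)
  f <- cached_sensor_field(setup, L)
  p <- f[cell_index(matrix(as.integer(cell), 1), L), ]
  stats::setNames(as.numeric(p), directions())
}

#' Deterministic world transition
#'
#' Moves a cell one step in the given direction. When a setup is supplied
#' the result must stay inside its bounding box (a move out of the box
#' indicates a horizon/box mismatch).
#'
#' @param cell integer vector `c(x, y)`.
#' @param action one of [directions()].
#' @param setup optional [world_setup()] for the box check.
#' @return the new cell.
#' @export
transition <- function(cell, action, setup = NULL) {
  a <- match(action, directions())
  if (is.na(a)) stop("unknown action: ", action)
  out <- unname(as.integer(cell) + DIR_DISP[a, ])
  if (!is.null(setup)) check_in_box(setup, out, "transition target")
  out
}

#' Uniform prior over initial positions
#'
#' @param setup a [world_setup()].
#' @return data frame with columns `x`, `y`, `prob`: mass `1/(2d+1)^2` on
#'   each cell of \{-d..d\}^2.
#' @export
initial_state_prior <- function(setup) {
  w <- -setup$d:setup$d
  g <- expand.grid(y = w, x = w)[, c("x", "y"), drop = FALSE]
  data.frame(g, prob = 1 / nrow(g))
}

# start cells of R0 as a matrix (canonical order: x slow, y fast)
start_cells <- function(setup) {
  w <- -setup$d:setup$d
  as.matrix(expand.grid(y = w, x = w))[, c("x", "y"), drop = FALSE]
}

#' Serialize / deserialize a world setup to JSON
#' @param setup a [world_setup()].
#' @param path optional file path.
#' @export
world_setup_to_json <- function(setup, path = NULL) {
  obj <- list(name = setup$name,
              sources = unname(apply(setup$sources, 1, as.list)),
              d = setup$d, horizon = setup$horizon,
              metric = setup$metric)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path); invisible(path)
}

#' @rdname world_setup_to_json
#' @param json JSON string or file path.
#' @export
world_setup_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  src <- obj$sources
  if (is.data.frame(src)) src <- as.matrix(src)
  world_setup(name = obj$name, sources = src, d = obj$d,
              horizon = obj$horizon,
              metric = if (is.null(obj$metric)) "euclidean" else obj$metric)
}
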