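#' Deterministic controllers
#'
#' A controller is a total deterministic mapping (memory, sensor) ->
#' (memory', action): the optimization variable of the whole model. It is
#' stored as two `|M| x 4` integer matrices, `mnext` (next memory, in
#' `1..|M|`) and `act` (action index into [directions()]), with columns in
#' canonical direction order.
#'
#' @param memory_size number of memory states, `|M| >= 1`.
#' @param mnext,act `|M| x 4` integer matrices; every entry of `mnext` in
#'   `1..memory_size`, every entry of `act` in `1..4`.
#' @return object of class `controller`.
#' @export
controller <- function(memory_size, mnext, act) {
  memory_size <- as.integer(memory_size)
  if (memory_size < 1) stop("memory_size must be >= 1")
  mnext <- matrix(as.integer(mnext), memory_size, 4)
  act <- matrix(as.integer(act), memory_size, 4)
  if (any(is.na(mnext)) || any(mnext < 1) || any(mnext > memory_size))
    stop("mnext entries must lie in 1..memory_size")
  if (any(is.na(act)) || any(act < 1) || any(act > 4))
    stop("act entries must lie in 1..4")
  structure(list(memory_size = memory_size, mnext = mnext, act = act),
            class = "controller")
}

#' @export
print.controller <- function(x, ...) {
  cat(sprintf("controller: |M| = %d, %d table entries\n",
              x$memory_size, 4 * x$memory_size))
  invisible(x)
}

#' Draw a uniformly random controller
#' @param memory_size number of memory states.
#' @export
random_controller <- function(memory_size) {
  M <- as.integer(memory_size)
  controller(M,
             matrix(sample.int(M, 4 * M, replace = TRUE), M, 4),
             matrix(sample.int(4L, 4 * M, replace = TRUE), M, 4))
}

# controller <-> flat mapping over the space (m,s) -> (m',a), both encoded
# 1..4M with k_domain = m + M*(s-1), value = m' + M*(a-1)
controller_to_mapping <- function(ctrl) {
  as.vector(ctrl$mnext + ctrl$memory_size * (ctrl$act - 1L))
}

mapping_to_controller <- function(mapping, memory_size) {
  M <- as.integer(memory_size)
  v <- as.integer(mapping) - 1L
  controller(M, matrix(v %% M + 1L, M, 4), matrix(v %/% M + 1L, M, 4))
}

# CSR sensor-field encoding + 0-based controller tables for the C++ core
field_csr <- function(setup, L) {
  f <- cached_sensor_field(setup, L)
  nz <- which(t(f) > 0)                    # row-major scan: per cell, dirs
  ncell <- nrow(f)
  counts <- rowSums(f > 0)
  list(off = c(0L, cumsum(as.integer(counts))),
       dir = as.integer((nz - 1L) %% 4L),
       p = as.numeric(t(f))[nz])
}

# p(m_T | r0) for arbitrary start cells; cells: n x 2 integer matrix
propagate_conditional <- function(setup, ctrl, cells,
                                  L = max(box_halfwidth(setup),
                                          max(abs(cells)) + setup$horizon)) {
  cells <- matrix(as.integer(cells), ncol = 2)
  csr <- field_csr(setup, L)
  cond <- propagate_point_cpp(cell_index(cells, L) - 1L, L,
                              ctrl$memory_size, setup$horizon,
                              csr$off, csr$dir, csr$p,
                              as.vector(ctrl$mnext) - 1L,
                              as.vector(ctrl$act) - 1L)
  colnames(cond) <- as.character(seq_len(ctrl$memory_size) - 1L)
  cond
}

cell_labels <- function(cells) paste(cells[, 1], cells[, 2], sep = ",")

#' Exact joint distribution of initial position and final memory
#'
#' Unrolls the perception-action loop as a causal Bayesian network and
#' evaluates it by exact sum-product: memory starts at 0, the start
#' position follows the uniform prior on \{-d..d\}^2, and for each of the
#' `T` steps the sensor distribution is averaged over exactly, the
#' deterministic controller applied, and the world state moved. No
#' sampling is involved anywhere.
#'
#' @param setup a [world_setup()].
#' @param ctrl a [controller()].
#' @return a [dist_table()] over variables `R0` (alphabet "x,y" labels)
#'   and `M` (alphabet "0".."|M|-1"); its marginal over `R0` equals the
#'   prior exactly.
#' @export
propagate <- function(setup, ctrl) {
  cells <- start_cells(setup)
  cond <- propagate_conditional(setup, ctrl, cells)
  prior <- rep(1 / nrow(cells), nrow(cells))
  dist_table(c("R0", "M"),
             list(R0 = cell_labels(cells),
                  M = colnames(cond)),
             array(cond * prior, dim = dim(cond)))
}

#' Agent utility: information captured about the initial position
#'
#' The mutual information `I(R0; M_T)` of a propagated joint, the quantity
#' the controller optimization maximizes. Bounded by
#' `min(log2 |R0|, log2 |M|)`.
#'
#' @param joint a [dist_table()] over `R0` and `M` as returned by
#'   [propagate()].
#' @return utility in bits.
#' @export
loop_utility <- function(joint) mutual_information(joint, "R0", "M")

#' Concepts: a spatial prior plus a conditional symbol table
#'
#' A concept is a pair (R, Y): a spatial random variable R (cells with a
#' prior) and a symbol variable Y given by a conditional table p(y | r).
#' The canonical example is (R0, M_T): what an agent's final memory state
#' says about where it started.
#'
#' @param cells integer matrix (n x 2) of grid cells carrying conditional
#'   rows; the prior's support is the subset with positive prior.
#' @param prior numeric vector of length n, nonnegative, summing to 1.
#' @param cond numeric matrix (n x K): row r is p(y | r), each row summing
#'   to 1 within 1e-9.
#' @param symbols optional symbol labels (default "0".."K-1").
#' @param evaluator optional function(cells_matrix) -> conditional rows,
#'   used to extend the conditional table beyond the stored cells on
#'   demand (e.g. under translated symmetry operations).
#' @return object of class `concept`.
#' @export
concept <- function(cells, prior, cond, symbols = NULL, evaluator = NULL) {
  cells <- matrix(as.integer(cells), ncol = 2)
  prior <- as.numeric(prior)
  cond <- as.matrix(cond)
  if (nrow(cells) != length(prior) || nrow(cells) != nrow(cond))
    stop("cells, prior and cond must agree in length")
  if (any(prior < 0) || abs(sum(prior) - 1) > 1e-9)
    stop("prior must be nonnegative and sum to 1")
  if (any(abs(rowSums(cond) - 1) > 1e-9))
    stop("every conditional row must sum to 1")
  if (is.null(symbols)) symbols <- as.character(seq_len(ncol(cond)) - 1L)
  colnames(cond) <- symbols
  structure(list(cells = cells, prior = prior, cond = cond,
                 symbols = symbols, evaluator = evaluator),
            class = "concept")
}

#' @export
print.concept <- function(x, ...) {
  cat(sprintf("concept: %d cells, %d symbols, I(R;Y) = %.4f bit\n",
              nrow(x$cells), length(x$symbols), concept_information(x)))
  invisible(x)
}

# joint p(r, y) as a dist_table
concept_joint <- function(cpt) {
  dist_table(c("R", "Y"),
             list(R = cell_labels(cpt$cells), Y = cpt$symbols),
             array(cpt$cond * cpt$prior, dim = dim(cpt$cond)))
}

#' Information a concept carries about space: I(R; Y)
#' @param cpt a [concept()].
#' @export
concept_information <- function(cpt) {
  mutual_information(concept_joint(cpt), "R", "Y")
}

# conditional rows at arbitrary cells, extending via the evaluator when a
# cell is not stored
concept_rows <- function(cpt, cells) {
  cells <- matrix(as.integer(cells), ncol = 2)
  key <- cell_labels(cells)
  have <- match(key, cell_labels(cpt$cells))
  out <- matrix(NA_real_, nrow(cells), ncol(cpt$cond))
  out[!is.na(have), ] <- cpt$cond[have[!is.na(have)], ]
  miss <- which(is.na(have))
  if (length(miss) > 0) {
    if (is.null(cpt$evaluator))
      stop("conditional unavailable at cell(s) ",
           paste(key[miss], collapse = " "),
           " and the concept has no evaluator to extend it")
    out[miss, ] <- cpt$evaluator(cells[miss, , drop = FALSE])
  }
  out
}

#' Extract an agent's concept (R0, M_T)
#'
#' Computes p(m_T | r0) by exact propagation from a point prior at each
#' requested cell and attaches the uniform prior over the setup's start
#' region. Cells outside the start region may be included (or computed
#' later on demand); they carry prior 0 and serve to evaluate the concept
#' under translated symmetry operations.
#'
#' @param setup a [world_setup()].
#' @param ctrl a [controller()].
#' @param cells optional integer matrix of cells to tabulate; defaults to
#'   the start region \{-d..d\}^2.
#' @return a [concept()] whose evaluator extends the table by propagation.
#' @export
concept_from_agent <- function(setup, ctrl, cells = NULL) {
  r0 <- start_cells(setup)
  if (is.null(cells)) cells <- r0
  cells <- matrix(as.integer(cells), ncol = 2)
  extra <- cells[is.na(match(cell_labels(cells), cell_labels(r0))), ,
                 drop = FALSE]
  all_cells <- rbind(r0, extra)
  cond <- propagate_conditional(setup, ctrl, all_cells)
  prior <- c(rep(1 / nrow(r0), nrow(r0)), rep(0, nrow(extra)))
  concept(all_cells, prior, cond,
          evaluator = function(cc)
            propagate_conditional(setup, ctrl, cc))
}

#' The sensor map viewed as a concept
#'
#' Interprets the sensor mapping R -> S itself as a concept: p(s | r) over
#' the start region, extensible to any cell of the plane.
#'
#' @param setup a [world_setup()].
#' @param cells optional cells to tabulate (default: the start region).
#' @export
sensor_concept <- function(setup, cells = NULL) {
  r0 <- start_cells(setup)
  if (is.null(cells)) cells <- r0
  cells <- matrix(as.integer(cells), ncol = 2)
  rows_at <- function(cc) {
    L <- max(box_halfwidth(setup), max(abs(cc)) + 1L)
    f <- cached_sensor_field(setup, L)
    unname(f[cell_index(cc, L), , drop = FALSE])
  }
  extra <- cells[is.na(match(cell_labels(cells), cell_labels(r0))), ,
                 drop = FALSE]
  all_cells <- rbind(r0, extra)
  prior <- c(rep(1 / nrow(r0), nrow(r0)), rep(0, nrow(extra)))
  concept(all_cells, prior, rows_at(all_cells), symbols = directions(),
          evaluator = rows_at)
}
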