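#' Space of total deterministic mappings between finite sets
#'
#' The search space for every optimization in the package: all
#' `|codomain|^|domain|` total functions from a finite domain to a finite
#' codomain. A mapping is represented as an integer vector of length
#' `|domain|` with values in `1..|codomain|`.
#'
#' @param domain_size,codomain_size positive integers.
#' @param domain_labels,codomain_labels optional label vectors.
#' @return object of class `mapping_space`.
#' @export
mapping_space <- function(domain_size, codomain_size,
                          domain_labels = NULL, codomain_labels = NULL) {
  domain_size <- as.integer(domain_size)
  codomain_size <- as.integer(codomain_size)
  if (domain_size < 1 || codomain_size < 1)
    stop("domain and codomain must be non-empty")
  structure(list(domain_size = domain_size, codomain_size = codomain_size,
                 domain_labels = domain_labels,
                 codomain_labels = codomain_labels),
            class = "mapping_space")
}

#' @export
print.mapping_space <- function(x, ...) {
  cat(sprintf("mapping_space: %d -> %d (%g mappings)\n", x$domain_size,
              x$codomain_size, x$codomain_size^x$domain_size))
  invisible(x)
}

#' Annealing schedule
#'
#' Geometric cooling: the temperature after step k is
#' `initial_temperature * cooling^k`. When `initial_temperature` is `NULL`
#' it is set per run to the standard deviation of the utility over 100
#' random mappings (self-scaling); when `cooling` is `NULL` it is chosen so
#' the final temperature is `1e-4` times the initial one.
#'
#' @param steps proposals per restart (>= 0).
#' @param restarts independent restarts (>= 1); the best-ever mapping
#'   across restarts is returned.
#' @param initial_temperature positive real, or `NULL` for self-scaling.
#' @param cooling geometric factor in (0, 1), or `NULL` (see above).
#' @param seed integer seed; identical seeds give identical results.
#' @export
anneal_schedule <- function(steps = 20000, restarts = 3,
                            initial_temperature = NULL, cooling = NULL,
                            seed = 1L) {
  if (steps < 0) stop("steps must be >= 0")
  if (restarts < 1) stop("restarts must be >= 1")
  if (!is.null(initial_temperature) && initial_temperature <= 0)
    stop("initial_temperature must be > 0")
  if (!is.null(cooling) && (cooling <= 0 || cooling >= 1))
    stop("cooling must lie in (0, 1)")
  structure(list(steps = as.integer(steps), restarts = as.integer(restarts),
                 initial_temperature = initial_temperature,
                 cooling = cooling, seed = as.integer(seed)),
            class = "anneal_schedule")
}

metropolis_accept <- function(delta, temperature) {
  # delta is the signed improvement; strictly improving moves always pass
  delta > 0 || stats::runif(1) < exp(delta / max(temperature, 1e-300))
}

random_mapping <- function(space) {
  sample.int(space$codomain_size, space$domain_size, replace = TRUE)
}

propose_move <- function(mapping, space) {
  i <- sample.int(space$domain_size, 1)
  if (space$codomain_size == 1) return(mapping)
  old <- mapping[i]
  new <- sample.int(space$codomain_size - 1L, 1)
  mapping[i] <- if (new >= old) new + 1L else new
  mapping
}

#' Simulated annealing over a mapping space
#'
#' Vanilla Metropolis annealing with geometric cooling and restarts: a
#' proposal re-assigns the image of one uniformly chosen domain element;
#' strictly improving proposals are always accepted, worsening ones with
#' probability `exp(delta / temperature)`. The best mapping ever visited
#' across all restarts is returned. All randomness flows from the
#' schedule's seed, so identical seeds give identical output.
#'
#' After the cooling phase each restart's best mapping is refined by
#' zero-temperature sweeps: every domain element in turn is set to its
#' best image, repeated until a full sweep yields no improvement (at most
#' `polish_sweeps` sweeps). This deterministic finish removes the shallow
#' local misses a finite cooling schedule can leave behind.
#'
#' @param space a [mapping_space()].
#' @param utility function(mapping integer vector) -> finite numeric.
#' @param schedule an [anneal_schedule()].
#' @param sense `"maximize"` or `"minimize"`.
#' @param trace_every record the trace every this many steps (0 = only
#'   restart boundaries).
#' @param polish_sweeps maximum zero-temperature refinement sweeps per
#'   restart (0 disables polishing).
#' @return list with `mapping`, `utility` (in the original sense), and
#'   `trace` (data frame: restart, step, temperature, utility, best).
#' @export
anneal <- function(space, utility, schedule = anneal_schedule(),
                   sense = c("maximize", "minimize"), trace_every = 0L,
                   polish_sweeps = 8L) {
  sense <- match.arg(sense)
  sgn <- if (sense == "maximize") 1 else -1
  u_of <- function(m) {
    u <- utility(m)
    if (!is.finite(u)) stop("utility returned a non-finite value")
    sgn * u
  }
  set.seed(schedule$seed)

  t0 <- schedule$initial_temperature
  if (is.null(t0)) {
    us <- vapply(seq_len(100), function(i) u_of(random_mapping(space)),
                 numeric(1))
    t0 <- stats::sd(us)
    if (!is.finite(t0) || t0 <= 0) t0 <- 1
  }
  cool <- schedule$cooling
  if (is.null(cool))
    cool <- if (schedule$steps > 0) (1e-4)^(1 / schedule$steps) else 0.5

  polish <- function(m, u) {
    for (sweep in seq_len(polish_sweeps)) {
      improved <- FALSE
      for (i in seq_len(space$domain_size)) {
        for (v in seq_len(space$codomain_size)) {
          if (v == m[i]) next
          m2 <- m
          m2[i] <- v
          u2 <- u_of(m2)
          if (u2 > u + 1e-12) { m <- m2; u <- u2; improved <- TRUE }
        }
      }
      if (!improved) break
    }
    list(m = m, u = u)
  }

  best_m <- NULL
  best_u <- -Inf
  tr <- list()
  for (r in seq_len(schedule$restarts)) {
    m <- random_mapping(space)
    u <- u_of(m)
    rbest_m <- m
    rbest_u <- u
    if (u > best_u) { best_u <- u; best_m <- m }
    temp <- t0
    for (k in seq_len(schedule$steps)) {
      m2 <- propose_move(m, space)
      u2 <- u_of(m2)
      if (metropolis_accept(u2 - u, temp)) { m <- m2; u <- u2 }
      if (u > rbest_u) { rbest_u <- u; rbest_m <- m }
      if (u > best_u) { best_u <- u; best_m <- m }
      if (trace_every > 0 && k %% trace_every == 0)
        tr[[length(tr) + 1]] <- data.frame(restart = r, step = k,
                                           temperature = temp,
                                           utility = sgn * u,
                                           best = sgn * best_u)
      temp <- temp * cool
    }
    if (polish_sweeps > 0 && schedule$steps > 0) {
      p <- polish(rbest_m, rbest_u)
      if (p$u > best_u) { best_u <- p$u; best_m <- p$m }
    }
    tr[[length(tr) + 1]] <- data.frame(restart = r, step = schedule$steps,
                                       temperature = temp,
                                       utility = sgn * u,
                                       best = sgn * best_u)
  }
  list(mapping = best_m, utility = sgn * best_u,
       trace = do.call(rbind, tr))
}

#' Exhaustive search over a mapping space
#'
#' Enumerates all `|codomain|^|domain|` mappings; the independent oracle
#' against which [anneal()] is validated on small spaces.
#'
#' @inheritParams anneal
#' @return list with `mapping` and `utility` of the optimum.
#' @export
exhaustive_search <- function(space, utility,
                              sense = c("maximize", "minimize")) {
  sense <- match.arg(sense)
  sgn <- if (sense == "maximize") 1 else -1
  n <- space$codomain_size^space$domain_size
  if (n > 2e6) stop("space too large for exhaustive search")
  best_u <- -Inf; best_m <- NULL
  m <- rep(1L, space$domain_size)
  for (i in seq_len(n)) {
    u <- sgn * utility(m)
    if (u > best_u) { best_u <- u; best_m <- m }
    # odometer increment
    j <- 1L
    while (j <= space$domain_size) {
      m[j] <- m[j] + 1L
      if (m[j] <= space$codomain_size) break
      m[j] <- 1L
      j <- j + 1L
    }
  }
  list(mapping = best_m, utility = sgn * best_u)
}

#' Optimize a controller for initial-position capture
#'
#' Anneals over all deterministic controller tables to maximize the exact
#' utility `I(R0; M_T)` from full probability propagation.
#'
#' @param setup a [world_setup()].
#' @param memory_size number of memory states.
#' @param schedule an [anneal_schedule()].
#' @return list with `controller`, `utility` (bits), and `trace`.
#' @export
optimize_agent <- function(setup, memory_size, schedule = anneal_schedule()) {
  M <- as.integer(memory_size)
  cells <- start_cells(setup)
  L <- box_halfwidth(setup)
  csr <- field_csr(setup, L)
  starts0 <- cell_index(cells, L) - 1L
  utility <- function(mapping) {
    v <- as.integer(mapping) - 1L
    cond <- propagate_point_cpp(starts0, L, M, setup$horizon,
                                csr$off, csr$dir, csr$p,
                                v %% M, v %/% M)
    # I(R0;M) = H(M) - H(M|R0); the prior is uniform over the start cells
    hM <- plog2p(colMeans(cond))
    nz <- cond > 0
    hMgR <- -sum(cond[nz] * log2(cond[nz])) / nrow(cond)
    hM - hMgR
  }
  space <- mapping_space(4L * M, 4L * M)
  res <- anneal(space, utility, schedule, "maximize")
  list(controller = mapping_to_controller(res$mapping, M),
       utility = res$utility, trace = res$trace)
}
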