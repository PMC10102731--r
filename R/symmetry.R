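#' Extrinsic symmetry operations on the grid
#'
#' An extrinsic operation acts on the plane as translation o rotation o
#' reflection, in exactly that order:
#' * reflection along the y-axis, `theta = -1`: `(x, y) -> (-x, y)`
#'   (`theta = +1` is the identity);
#' * anticlockwise rotation `phi` in \{0, 90, 180, 270\} degrees, with
#'   `90: (x, y) -> (-y, x)`;
#' * translation by `(x0, y0)`.
#'
#' @param theta reflection flag, `+1` or `-1`.
#' @param phi rotation in degrees: 0, 90, 180 or 270.
#' @param x0,y0 integer translation.
#' @return object of class `extrinsic_op`.
#' @export
extrinsic_op <- function(theta = 1L, phi = 0L, x0 = 0L, y0 = 0L) {
  if (!theta %in% c(1L, -1L)) stop("theta must be +1 or -1")
  if (!phi %in% c(0L, 90L, 180L, 270L)) stop("phi must be 0/90/180/270")
  structure(list(theta = as.integer(theta), phi = as.integer(phi),
                 x0 = as.integer(x0), y0 = as.integer(y0)),
            class = "extrinsic_op")
}

#' @export
print.extrinsic_op <- function(x, ...) {
  cat(sprintf("extrinsic_op: theta=%+d phi=%d translation=(%d,%d)\n",
              x$theta, x$phi, x$x0, x$y0))
  invisible(x)
}

#' Apply an extrinsic operation to cells
#'
#' @param op an [extrinsic_op()].
#' @param cells integer matrix (n x 2) or vector `c(x, y)`.
#' @return transformed cells, same shape as the input.
#' @export
apply_extrinsic <- function(op, cells) {
  vec <- is.null(dim(cells))
  cells <- matrix(as.integer(cells), ncol = 2)
  x <- cells[, 1] * op$theta          # reflection first
  y <- cells[, 2]
  r <- switch(as.character(op$phi),
              "0" = cbind(x, y),
              "90" = cbind(-y, x),
              "180" = cbind(-x, -y),
              "270" = cbind(y, -x))
  out <- cbind(r[, 1] + op$x0, r[, 2] + op$y0)
  if (vec) as.integer(out[1, ]) else out
}

# how the linear part of an op permutes the four direction vectors;
# returns p with p[a] = index of the transformed direction a
direction_permutation <- function(op) {
  v <- apply_extrinsic(extrinsic_op(op$theta, op$phi), DIR_DISP)
  match(cell_labels(v), cell_labels(DIR_DISP))
}

#' Equivariance utility of an extrinsic operation on a concept
#'
#' The transformed concept reads the original conditional at the
#' transformed position: `p(y' | xi(r))`. Its agreement with the original
#' is scored by the mutual information `I(Y; Y^xi)` under the joint
#' `sum_r prior(r) p(y | r) p(y' | xi(r))` (Y and Y^xi are conditionally
#' independent given R). Higher means the operation is better respected;
#' the identity operation is always maximal.
#'
#' @param cpt a [concept()] whose conditional is evaluable at every
#'   transformed support cell (stored or via its evaluator).
#' @param op an [extrinsic_op()].
#' @return utility in bits.
#' @export
extrinsic_utility <- function(cpt, op) {
  sup <- cpt$prior > 0
  cells <- cpt$cells[sup, , drop = FALSE]
  P <- cpt$cond[sup, , drop = FALSE]
  Q <- concept_rows(cpt, apply_extrinsic(op, cells))
  J <- crossprod(P * cpt$prior[sup], Q)      # p(y, y^xi)
  table_mi(J)
}

# I(R; Y^xi): the transformed concept's information about the (untouched)
# prior over R -- the alternative spectrum axis
extrinsic_state_utility <- function(cpt, op) {
  sup <- cpt$prior > 0
  cells <- cpt$cells[sup, , drop = FALSE]
  Q <- concept_rows(cpt, apply_extrinsic(op, cells)) * cpt$prior[sup]
  plog2p(cpt$prior[sup]) + plog2p(colSums(Q)) - plog2p(Q)
}

#' Family of extrinsic operations up to a translation bound
#'
#' All `8 * (2*max_translation + 1)^2` combinations of the 8 dihedral
#' elements with translations `max(|x0|, |y0|) <= max_translation`.
#'
#' @param max_translation nonnegative integer.
#' @return data frame with columns theta, phi, x0, y0.
#' @export
extrinsic_ops_family <- function(max_translation) {
  t <- as.integer(max_translation)
  if (t < 0) stop("max_translation must be >= 0")
  expand.grid(theta = c(1L, -1L), phi = c(0L, 90L, 180L, 270L),
              x0 = -t:t, y0 = -t:t, KEEP.OUT.ATTRS = FALSE)
}

new_spectrum <- function(entries, family, normalization) {
  mx <- max(entries$utility)
  if (mx <= 0) stop("all-zero spectrum: normalization undefined")
  entries$normalized <- entries$utility / mx
  structure(list(entries = entries, max_utility = mx, family = family,
                 normalization = normalization),
            class = "symmetry_spectrum")
}

#' @export
print.symmetry_spectrum <- function(x, ...) {
  cat(sprintf(
    "%s symmetry spectrum: %d operations, max utility %.4f bit, %d best\n",
    x$family, nrow(x$entries), x$max_utility,
    sum(x$entries$normalized >= 1 - 1e-9)))
  invisible(x)
}

#' Extrinsic symmetry spectrum of a concept
#'
#' Evaluates [extrinsic_utility()] for every operation of
#' [extrinsic_ops_family()] and normalizes by the maximum.
#'
#' @param cpt a [concept()].
#' @param max_translation translation bound (5 for the single-source start
#'   region, 10 for the four-source one).
#' @param mode `"concept"` scores `I(Y; Y^xi)` (default); `"state"` scores
#'   `I(R; Y^xi)` (the alternative histogram axis). The choice is recorded
#'   in the spectrum's `normalization` field.
#' @return a `symmetry_spectrum`.
#' @export
extrinsic_spectrum <- function(cpt, max_translation = 5,
                               mode = c("concept", "state")) {
  mode <- match.arg(mode)
  ops <- extrinsic_ops_family(max_translation)
  # pre-extend the conditional table over all transformed cells at once
  sup_cells <- cpt$cells[cpt$prior > 0, , drop = FALSE]
  need <- unique(rbind(
    cpt$cells,
    do.call(rbind, lapply(seq_len(nrow(ops)), function(i)
      apply_extrinsic(do.call(extrinsic_op, as.list(ops[i, ])),
                      sup_cells)))))
  cpt <- concept(need, {
    pr <- numeric(nrow(need))
    pr[match(cell_labels(cpt$cells), cell_labels(need))] <- cpt$prior
    pr
  }, concept_rows(cpt, need), symbols = cpt$symbols,
  evaluator = cpt$evaluator)
  f <- if (mode == "concept") extrinsic_utility else extrinsic_state_utility
  ops$utility <- vapply(seq_len(nrow(ops)), function(i)
    f(cpt, do.call(extrinsic_op, as.list(ops[i, ]))), numeric(1))
  new_spectrum(ops, "extrinsic",
               if (mode == "concept") "I(Y;Y^xi)/max" else "I(R;Y^xi)/max")
}

#' Embodiment permutations
#'
#' A pair of relabelings of the four sensor symbols and the four action
#' symbols. The 576 = 4! x 4! pairs form a group under composition; they
#' are the intrinsic symmetry operations.
#'
#' @param pi_s,pi_a integer permutations of `1:4` (index = canonical
#'   direction order of [directions()]).
#' @return object of class `embodiment_permutation`.
#' @export
embodiment_permutation <- function(pi_s = 1:4, pi_a = 1:4) {
  pi_s <- as.integer(pi_s); pi_a <- as.integer(pi_a)
  if (!identical(sort(pi_s), 1:4) || !identical(sort(pi_a), 1:4))
    stop("pi_s and pi_a must be permutations of 1:4")
  structure(list(pi_s = pi_s, pi_a = pi_a),
            class = "embodiment_permutation")
}

#' All 576 embodiment permutations
#' @return list of [embodiment_permutation()] objects.
#' @export
all_embodiment_permutations <- function() {
  perms <- permutations4()
  out <- vector("list", 576)
  k <- 0
  for (i in seq_len(24)) for (j in seq_len(24)) {
    k <- k + 1
    out[[k]] <- embodiment_permutation(perms[i, ], perms[j, ])
  }
  out
}

permutations4 <- function() {
  p <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  p <- as.matrix(p[apply(p, 1, function(r) length(unique(r)) == 4), ])
  unname(p)
}

#' Compose an embodiment permutation into a controller
#'
#' Re-wires the agent without touching the controller proper: the
#' effective controller is `C'(m, s) = (m', pi_a(a))` with
#' `(m', a) = C(m, pi_s^{-1}(s))`. The identity pair returns the original
#' table; applying a permutation and then its group inverse does too.
#'
#' @param ctrl a [controller()].
#' @param perm an [embodiment_permutation()].
#' @return the effective [controller()].
#' @export
apply_embodiment <- function(ctrl, perm) {
  inv_s <- order(perm$pi_s)
  controller(ctrl$memory_size,
             ctrl$mnext[, inv_s, drop = FALSE],
             matrix(perm$pi_a[ctrl$act[, inv_s]], ctrl$memory_size, 4))
}

#' Group inverse of an embodiment permutation
#' @param perm an [embodiment_permutation()].
#' @export
invert_embodiment <- function(perm) {
  embodiment_permutation(order(perm$pi_s), order(perm$pi_a))
}

#' Intrinsic symmetry utility of an embodiment permutation
#'
#' Scores how well the permuted agent's concept conforms to a common
#' concept: `I(M*; M_T^pi)` under the joint
#' `sum_r prior(r) [common maps r -> m*] p(m^pi | r)`, where
#' `p(m^pi | r)` comes from propagating the permuted controller -- the
#' controller itself is never re-optimized.
#'
#' @param setup a [world_setup()].
#' @param ctrl the agent's [controller()].
#' @param perm an [embodiment_permutation()].
#' @param common a deterministic [concept()] over the same start region
#'   (typically an objective common concept).
#' @return utility in bits.
#' @export
intrinsic_utility <- function(setup, ctrl, perm, common) {
  g <- deterministic_assignment(common, setup)
  cond <- propagate_conditional(setup, apply_embodiment(ctrl, perm),
                                start_cells(setup))
  prior <- 1 / nrow(cond)
  J <- rowsum(cond * prior, g)                 # p(m*, m^pi)
  table_mi(J)
}

# symbol index assigned to each start cell by a deterministic concept
deterministic_assignment <- function(common, setup) {
  rows <- concept_rows(common, start_cells(setup))
  g <- max.col(rows)
  if (any(abs(rows[cbind(seq_along(g), g)] - 1) > 1e-9))
    stop("the common concept must be deterministic in R ",
         "(an objective common concept)")
  g
}

#' Intrinsic symmetry spectrum: all 576 embodiment permutations
#'
#' @inheritParams intrinsic_utility
#' @return a `symmetry_spectrum` whose entries carry the permutations as
#'   columns `s1..s4` (sensor) and `a1..a4` (action).
#' @export
intrinsic_spectrum <- function(setup, ctrl, common) {
  g <- deterministic_assignment(common, setup)
  cells <- start_cells(setup)
  L <- box_halfwidth(setup)
  csr <- field_csr(setup, L)
  starts0 <- cell_index(cells, L) - 1L
  M <- ctrl$memory_size
  prior <- 1 / nrow(cells)
  perms <- all_embodiment_permutations()
  u <- vapply(perms, function(pp) {
    eff <- apply_embodiment(ctrl, pp)
    cond <- propagate_point_cpp(starts0, L, M, setup$horizon,
                                csr$off, csr$dir, csr$p,
                                as.vector(eff$mnext) - 1L,
                                as.vector(eff$act) - 1L)
    table_mi(rowsum(cond * prior, g))
  }, numeric(1))
  entries <- cbind(
    as.data.frame(t(vapply(perms, function(pp) c(pp$pi_s, pp$pi_a),
                           integer(8)))),
    utility = u)
  names(entries)[1:8] <- c(paste0("s", 1:4), paste0("a", 1:4))
  new_spectrum(entries, "intrinsic", "I(M*;M^pi)/max")
}

#' Count good symmetries in a spectrum
#'
#' Operations whose normalized utility reaches at least `threshold`
#' (boundary ties count in).
#'
#' @param spectrum a `symmetry_spectrum`.
#' @param threshold relative cutoff in (0, 1], e.g. 0.85.
#' @export
count_good_symmetries <- function(spectrum, threshold) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  sum(spectrum$entries$normalized >= threshold)
}

#' Operations attaining the spectrum's maximum
#'
#' All entries within relative tolerance `rel_tol` of the maximal utility.
#'
#' @param spectrum a `symmetry_spectrum`.
#' @param rel_tol relative tolerance (default `1e-9`).
#' @return the matching rows of the spectrum's entries.
#' @export
best_symmetries <- function(spectrum, rel_tol = 1e-9) {
  spectrum$entries[spectrum$entries$normalized >= 1 - rel_tol, ,
                   drop = FALSE]
}

#' Fraction of the controller search space covered by embodiment
#' permutations
#'
#' The 4! x 4! = 576 sensor/actuator relabelings versus the
#' `(4|M|)^(4|M|)` deterministic controller tables: re-educating an agent
#' through its embodiment explores a vanishing fraction of the full
#' controller space (about 3.1e-17 for `|M| = 4`).
#'
#' @param memory_size the agent's memory size.
#' @export
intrinsic_search_ratio <- function(memory_size = 4) {
  n <- 4 * as.numeric(memory_size)
  576 / n^n
}

#' Memory-size sweep of good-symmetry counts
#'
#' For each memory size: optimizes `n_agents` agents, merges them into an
#' objective common concept, and counts good extrinsic symmetries (per
#' agent concept, averaged) and good intrinsic symmetries (each agent
#' against the common concept, averaged) at each threshold.
#'
#' @param setup a [world_setup()].
#' @param memory_sizes integer vector of |M| values.
#' @param n_agents agents per memory size (>= 2).
#' @param thresholds relative cutoffs (defaults 0.825, 0.85, 0.875).
#' @param schedule an [anneal_schedule()]; per-agent seeds are derived
#'   from it deterministically.
#' @param y_star_size symbols available to the common concept (default 16).
#' @param alpha bottleneck weight for the common concept.
#' @param max_translation extrinsic translation bound.
#' @return data frame: memory_size, threshold, extrinsic_count,
#'   intrinsic_count.
#' @export
memory_sweep <- function(setup, memory_sizes, n_agents = 8,
                         thresholds = c(0.825, 0.85, 0.875),
                         schedule = anneal_schedule(),
                         y_star_size = 16, alpha = 0.2,
                         max_translation = 5) {
  if (n_agents < 2) stop("n_agents must be >= 2")
  rows <- list()
  for (M in memory_sizes) {
    agents <- lapply(seq_len(n_agents), function(i) {
      sch <- schedule
      sch$seed <- schedule$seed + 1000L * M + i
      optimize_agent(setup, M, sch)
    })
    cpts <- lapply(agents, function(a) concept_from_agent(setup,
                                                          a$controller))
    ens <- concept_ensemble(cpts)
    csch <- schedule
    csch$seed <- schedule$seed + 1000L * M
    common <- objective_common_concept(ens, y_star_size, alpha, csch)
    ext <- vapply(cpts, function(cp) {
      sp <- extrinsic_spectrum(cp, max_translation)
      vapply(thresholds, function(th) count_good_symmetries(sp, th),
             numeric(1))
    }, numeric(length(thresholds)))
    intr <- vapply(agents, function(a) {
      sp <- intrinsic_spectrum(setup, a$controller, common$concept)
      vapply(thresholds, function(th) count_good_symmetries(sp, th),
             numeric(1))
    }, numeric(length(thresholds)))
    ext <- matrix(ext, nrow = length(thresholds))
    intr <- matrix(intr, nrow = length(thresholds))
    rows[[length(rows) + 1]] <- data.frame(
      memory_size = M, threshold = thresholds,
      extrinsic_count = rowMeans(ext), intrinsic_count = rowMeans(intr))
  }
  do.call(rbind, rows)
}

#' Histogram of a symmetry spectrum
#'
#' Raw counts of normalized utilities over a fixed bin grid on [0, 1],
#' with an optional display-only moving-average smoother (off by
#' default).
#'
#' @param spectrum a `symmetry_spectrum`.
#' @param bins number of equal-width bins on [0, 1].
#' @param smooth half-width of the moving-average window in bins
#'   (0 = raw counts).
#' @return data frame with columns `mid` (bin midpoint), `count` and
#'   `display` (smoothed counts; equals `count` when `smooth = 0`).
#' @export
spectrum_histogram <- function(spectrum, bins = 100, smooth = 0) {
  br <- seq(0, 1, length.out = bins + 1)
  idx <- pmin(pmax(findInterval(spectrum$entries$normalized, br,
                                rightmost.closed = TRUE), 1L), bins)
  count <- tabulate(idx, nbins = bins)
  display <- count
  if (smooth > 0) {
    k <- 2 * smooth + 1
    display <- as.numeric(stats::filter(count, rep(1 / k, k),
                                        sides = 2))
    display[is.na(display)] <- count[is.na(display)]
  }
  data.frame(mid = (br[-1] + br[-(bins + 1)]) / 2, count = count,
             display = display)
}
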