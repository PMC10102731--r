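#' Ensembles of input concepts over a shared spatial prior
#'
#' Several agents' concepts (R, Y^(1)), ..., (R, Y^(n)) sharing one spatial
#' prior. The joint model is the causal-network factorization
#' p(r, y1, ..., yn) = prior(r) * prod_i p(y_i | r): the symbol variables
#' are conditionally independent given the position.
#'
#' @param concepts list of [concept()] objects with identical cells and
#'   priors.
#' @return object of class `concept_ensemble`.
#' @export
concept_ensemble <- function(concepts) {
  if (length(concepts) < 1) stop("the ensemble must contain >= 1 concept")
  ref <- concepts[[1]]
  for (cpt in concepts[-1]) {
    if (!identical(cell_labels(cpt$cells), cell_labels(ref$cells)) ||
        max(abs(cpt$prior - ref$prior)) > 1e-12)
      stop("all input concepts must share one support and prior")
  }
  structure(list(concepts = concepts, cells = ref$cells,
                 prior = ref$prior), class = "concept_ensemble")
}

#' @export
print.concept_ensemble <- function(x, ...) {
  cat(sprintf("concept_ensemble: %d concepts over %d cells\n",
              length(x$concepts), nrow(x$cells)))
  invisible(x)
}

#' A merged common concept
#'
#' The result of [objective_common_concept()] or
#' [subjective_common_concept()]: the optimized deterministic mapping, the
#' induced concept (R, Y*), and the achieved score of the respective
#' functional.
#'
#' @name common_concept
NULL

new_common_concept <- function(kind, mapping, cpt, score, alpha = NULL,
                               seed = NULL) {
  structure(list(kind = kind, mapping = mapping, concept = cpt,
                 score = score, alpha = alpha, seed = seed),
            class = "common_concept")
}

#' @export
print.common_concept <- function(x, ...) {
  cat(sprintf("%s common concept: %d symbols (%d populated), score %.4f bit\n",
              x$kind, length(x$concept$symbols),
              populated_symbols(x$concept), x$score))
  invisible(x)
}

# entropy helpers on plain numeric tables (rows already weighted)
table_mi <- function(joint) {
  # mutual information of a 2-d probability table
  plog2p(rowSums(joint)) + plog2p(colSums(joint)) - plog2p(joint)
}

#' Objective common concept: an information bottleneck from R
#'
#' Optimizes a deterministic mapping R -> Y* that maximizes
#' `sum_i [ I(Y*; Y^(i)) - alpha * I(R; Y*) ]`: extract as much information
#' as possible about every input concept while a bottleneck regularizer
#' (weight `alpha` inside the sum, hence effectively `n * alpha`) penalizes
#' keeping more about R than the inputs ground. Because Y* is a function of
#' R, the result has superstition `H(Y* | R) = 0` by construction.
#'
#' @param ensemble a [concept_ensemble()].
#' @param y_star_size number of symbols available to Y*.
#' @param alpha bottleneck weight in `[0, 1]`, default 0.2.
#' @param schedule an [anneal_schedule()].
#' @param alpha_inside if `FALSE`, the regularizer is applied once outside
#'   the sum instead of once per input (sensitivity variant).
#' @return a [common_concept] of kind `"objective"`.
#' @export
objective_common_concept <- function(ensemble, y_star_size, alpha = 0.2,
                                     schedule = anneal_schedule(),
                                     alpha_inside = TRUE) {
  n <- length(ensemble$concepts)
  K <- as.integer(y_star_size)
  if (K < 1) stop("y_star_size must be >= 1")
  prior <- ensemble$prior
  ncell <- length(prior)
  # one block matrix [prior | p(r,y_1) | ... | p(r,y_n)] so each utility
  # evaluation needs a single rowsum over the mapping's groups
  wcond <- lapply(ensemble$concepts, function(cpt) cpt$cond * prior)
  block <- do.call(cbind, c(list(prior), wcond))
  ends <- 1L + cumsum(vapply(wcond, ncol, integer(1)))
  # H(Y_i) terms are mapping-independent
  hy_in <- vapply(wcond, function(W) plog2p(colSums(W)), numeric(1))
  aw <- if (alpha_inside) n * alpha else alpha
  utility <- function(g) {
    J <- rowsum(block, g, reorder = FALSE)
    # I(R; Y*) = H(Y*) since Y* is deterministic in R
    hy <- plog2p(J[, 1])
    s <- 0
    for (i in seq_len(n)) {
      Ji <- J[, (ends[i] - ncol(wcond[[i]]) + 1L):ends[i], drop = FALSE]
      s <- s + hy + hy_in[i] - plog2p(Ji)     # I(Y*; Y_i)
    }
    s - aw * hy
  }
  res <- anneal(mapping_space(ncell, K), utility, schedule, "maximize")
  g <- res$mapping
  cond <- matrix(0, ncell, K)
  cond[cbind(seq_len(ncell), g)] <- 1
  cpt <- concept(ensemble$cells, prior, cond)
  new_common_concept("objective", g, cpt, res$utility, alpha = alpha,
                     seed = schedule$seed)
}

#' Subjective common concept: compressing the symbol tuple
#'
#' Optimizes a deterministic mapping Y^(1) x ... x Y^(n) -> Y* that
#' minimizes the conditional multi-information
#' `I(Y^(1); ...; Y^(n) | Y*)`: Y* absorbs all information the input
#' concepts share, using only the agents' symbols, never R itself. Tuples
#' with joint probability zero cannot affect the objective; they are
#' assigned the first symbol and excluded from proposal moves.
#'
#' @param ensemble a [concept_ensemble()] with at least two concepts.
#' @param y_star_size number of symbols available to Y*.
#' @param schedule an [anneal_schedule()].
#' @return a [common_concept] of kind `"subjective"`; its induced
#'   conditional is `p(y* | r) = sum_tuple [map(tuple) = y*] prod_i
#'   p(y_i | r)`.
#' @export
subjective_common_concept <- function(ensemble, y_star_size,
                                      schedule = anneal_schedule()) {
  n <- length(ensemble$concepts)
  if (n < 2) stop("the subjective common concept needs >= 2 input concepts")
  K <- as.integer(y_star_size)
  prior <- ensemble$prior
  ncell <- length(prior)
  sizes <- vapply(ensemble$concepts, function(cpt) ncol(cpt$cond),
                  integer(1))
  ntup <- prod(sizes)
  # W[r, tuple] = prod_i p(y_i | r); tuple index: first concept fastest
  W <- matrix(1, ncell, 1)
  for (cpt in ensemble$concepts) {
    W <- W[, rep(seq_len(ncol(W)), each = ncol(cpt$cond)), drop = FALSE] *
      cpt$cond[, rep(seq_len(ncol(cpt$cond)), times = ncol(W)),
               drop = FALSE]
  }
  # after the loop, the tuple index varies the LAST concept fastest
  q <- as.numeric(prior %*% W)               # p(tuple)
  live <- which(q > STRUCTURAL_ZERO)
  # component index of each live tuple per concept
  comp <- matrix(0L, length(live), n)
  z <- live - 1L
  for (i in rev(seq_len(n))) {
    comp[, i] <- z %% sizes[i] + 1L
    z <- z %/% sizes[i]
  }
  qlive <- q[live]
  # H(tuple | Y*) = H(tuple) - H(Y*) because Y* is a function of the tuple
  utility <- function(g) {
    s <- 0
    hy <- plog2p(as.numeric(rowsum(qlive, g)))
    for (i in seq_len(n)) {
      Ji <- rowsum(qlive, g + K * (comp[, i] - 1L))  # p(y*, y_i)
      s <- s + plog2p(Ji) - hy                       # H(Y_i | Y*)
    }
    s - (plog2p(qlive) - hy)                         # - H(tuple | Y*)
  }
  res <- anneal(mapping_space(length(live), K), utility, schedule,
                "minimize")
  g_live <- res$mapping
  g <- rep(1L, ntup)
  g[live] <- g_live
  # induced conditional p(y* | r); zero-probability tuples keep their
  # reserved symbol so rows still sum to exactly 1
  cond <- matrix(0, ncell, K)
  agg <- rowsum(t(W), g)
  cond[, as.integer(rownames(agg))] <- t(agg)
  cpt <- concept(ensemble$cells, prior, cond)
  new_common_concept("subjective", g, cpt, res$utility,
                     seed = schedule$seed)
}

#' Superstition of a concept: H(Y | R)
#'
#' Representational entropy not grounded in the world state -- information
#' in the symbols that does not reflect the position at all. Zero exactly
#' for deterministic concepts.
#'
#' @param cpt a [concept()].
#' @return bits.
#' @export
superstition <- function(cpt) {
  nz <- cpt$cond > 0
  rowh <- -rowSums(ifelse(nz, cpt$cond * log2(pmax(cpt$cond, 1e-300)), 0))
  sum(cpt$prior * rowh)
}

#' Information distance between two concepts over a shared prior
#'
#' `D(Y_a, Y_b) = H(Y_a | Y_b) + H(Y_b | Y_a)` computed on the joint
#' `p(r) p(y_a | r) p(y_b | r)` (the symbol variables are conditionally
#' independent given the position, per the generative structure). Zero
#' exactly when the two concepts are symbol-permutation equivalent.
#'
#' @param a,b [concept()] objects sharing support and prior.
#' @return bits.
#' @export
concept_distance <- function(a, b) {
  if (!identical(cell_labels(a$cells), cell_labels(b$cells)) ||
      max(abs(a$prior - b$prior)) > 1e-12)
    stop("concepts must share one support and prior")
  J <- crossprod(a$cond * a$prior, b$cond)     # p(y_a, y_b)
  hab <- plog2p(J)
  hab - plog2p(colSums(J)) + hab - plog2p(rowSums(J))
}

#' Number of populated symbols of a concept
#'
#' Symbols whose marginal probability exceeds `threshold` under the
#' concept's prior.
#'
#' @param cpt a [concept()].
#' @param threshold marginal-probability cutoff (default `1e-9`).
#' @export
populated_symbols <- function(cpt, threshold = 1e-9) {
  sum(as.numeric(cpt$prior %*% cpt$cond) > threshold)
}
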