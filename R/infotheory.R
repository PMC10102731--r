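#' Finite joint probability tables
#'
#' A `dist_table` is the universal currency of all information measures in
#' this package: a joint probability distribution over a set of named
#' discrete variables, each with a finite alphabet. Probabilities are stored
#' exactly as a dense array (one cell per joint outcome), so every
#' downstream quantity -- entropies, mutual information, multi-information,
#' information distances -- is computed exactly, never estimated from
#' samples.
#'
#' @param variables character vector of variable names (ordered).
#' @param alphabets named list of character vectors, one per variable, in
#'   the same order as `variables`; the finite value sets.
#' @param probabilities numeric array (or vector) of joint probabilities.
#'   If a vector, it is interpreted in row-major order: the *last* variable
#'   varies fastest. Must be nonnegative and sum to 1 within `1e-9`.
#' @return an object of class `dist_table`.
#' @examples
#' d <- dist_table(c("X", "Y"),
#'                 list(X = c("0", "1"), Y = c("0", "1")),
#'                 c(0.5, 0, 0, 0.5))
#' mutual_information(d, "X", "Y")  # 1 bit
#' @export
dist_table <- function(variables, alphabets, probabilities) {
  stopifnot(is.character(variables), length(variables) >= 1)
  if (!identical(sort(names(alphabets)), sort(variables)))
    stop("alphabets must be a named list covering exactly the variables")
  alphabets <- alphabets[variables]
  sizes <- vapply(alphabets, length, integer(1))
  if (any(sizes < 1)) stop("every alphabet must be non-empty")
  n <- prod(sizes)
  p <- as.numeric(probabilities)
  if (length(p) != n)
    stop(sprintf("expected %d probabilities, got %d", n, length(p)))
  if (!is.array(probabilities)) {
    # row-major input: last variable fastest -> fill a reversed-dim array
    # column-major, then permute back
    a <- array(p, dim = unname(rev(sizes)))
    p <- aperm(a, rev(seq_along(sizes)))
  } else {
    p <- array(p, dim = unname(sizes))
  }
  if (any(p < -1e-12)) stop("probabilities must be nonnegative")
  p[p < 0] <- 0
  if (abs(sum(p) - 1) > 1e-9)
    stop(sprintf("probabilities must sum to 1 (got %.12f)", sum(p)))
  dimnames(p) <- unname(alphabets)
  structure(list(variables = variables, alphabets = alphabets, p = p),
            class = "dist_table")
}

#' @export
print.dist_table <- function(x, ...) {
  sizes <- vapply(x$alphabets, length, integer(1))
  cat("dist_table over", paste(sprintf("%s(%d)", x$variables, sizes),
                               collapse = " x "), "\n")
  invisible(x)
}

var_indices <- function(dist, vars) {
  idx <- match(vars, dist$variables)
  if (anyNA(idx))
    stop("unknown variable(s): ", paste(vars[is.na(idx)], collapse = ", "))
  idx
}

check_disjoint <- function(...) {
  sets <- list(...)
  all <- unlist(sets)
  if (anyDuplicated(all))
    stop("variable subsets must be disjoint (shared: ",
         paste(unique(all[duplicated(all)]), collapse = ", "), ")")
  invisible(TRUE)
}

#' Marginalize a joint table onto a subset of its variables
#'
#' @param dist a [dist_table()].
#' @param vars character vector of variables to keep.
#' @return a `dist_table` over `vars`.
#' @export
marginal <- function(dist, vars) {
  idx <- var_indices(dist, vars)
  if (length(idx) == length(dist$variables)) return(dist)
  m <- apply(dist$p, idx, sum)
  m <- array(m, dim = vapply(dist$alphabets[idx], length, integer(1)))
  dist_table(dist$variables[idx], dist$alphabets[idx], m)
}

plog2p <- function(p) {
  # 0 * log 0 := 0
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Shannon entropy of a variable subset (bits)
#'
#' \eqn{H(X) = -\sum_x p(x)\log_2 p(x)}; zero-probability outcomes
#' contribute nothing.
#'
#' @param dist a [dist_table()].
#' @param over variables to take the entropy of; defaults to all.
#' @return entropy in bits.
#' @export
entropy <- function(dist, over = dist$variables) {
  if (length(over) == 0) stop("`over` must be a non-empty variable subset")
  idx <- var_indices(dist, over)
  if (length(idx) == length(dist$variables)) return(plog2p(dist$p))
  plog2p(apply(dist$p, idx, sum))
}

#' Conditional entropy H(X | Y) in bits
#'
#' Computed as `H(X, Y) - H(Y)`.
#'
#' @param dist a [dist_table()].
#' @param of,given disjoint variable subsets.
#' @export
conditional_entropy <- function(dist, of, given) {
  check_disjoint(of, given)
  if (length(given) == 0) return(entropy(dist, of))
  entropy(dist, c(of, given)) - entropy(dist, given)
}

#' Mutual information I(A; B) in bits
#'
#' Computed as `H(A) + H(B) - H(A, B)`.
#'
#' @param dist a [dist_table()].
#' @param a,b disjoint variable subsets.
#' @export
mutual_information <- function(dist, a, b) {
  check_disjoint(a, b)
  entropy(dist, a) + entropy(dist, b) - entropy(dist, c(a, b))
}

#' Multi-information (total correlation), optionally conditional
#'
#' \eqn{I(X_1; \ldots; X_n) = [\sum_i H(X_i)] - H(X_1, \ldots, X_n)}, and
#' the conditional form replaces every entropy by its conditional version
#' given `given`. With two groups this reduces exactly to (conditional)
#' mutual information.
#'
#' @param dist a [dist_table()].
#' @param groups list of at least two pairwise-disjoint variable subsets.
#' @param given optional conditioning subset, disjoint from all groups.
#' @export
multi_information <- function(dist, groups, given = character(0)) {
  if (!is.list(groups) || length(groups) < 2)
    stop("multi-information needs at least 2 variable subsets")
  do.call(check_disjoint, c(groups, list(given)))
  sum(vapply(groups, function(g) conditional_entropy(dist, g, given),
             numeric(1))) -
    conditional_entropy(dist, unlist(groups), given)
}

#' Information distance D(A, B) = H(A|B) + H(B|A) in bits
#'
#' A pseudo-metric on random variables: symmetric, satisfies the triangle
#' inequality, and vanishes exactly when the two variables are permutation
#' equivalent on their supports.
#'
#' @param dist a [dist_table()].
#' @param a,b disjoint variable subsets.
#' @export
information_distance <- function(dist, a, b) {
  check_disjoint(a, b)
  conditional_entropy(dist, a, b) + conditional_entropy(dist, b, a)
}

# row-major (last variable fastest) flattening used by the JSON form
flatten_rowmajor <- function(p) as.vector(aperm(p, rev(seq_along(dim(p)))))

#' Serialize / deserialize a dist_table to the package's JSON dialect
#'
#' The JSON object carries `variables` (names), `alphabets` (string lists)
#' and `probabilities` (flat row-major list, last variable fastest).
#'
#' @param dist a [dist_table()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
dist_table_to_json <- function(dist, path = NULL) {
  obj <- list(variables = dist$variables,
              alphabets = lapply(dist$alphabets, as.character),
              probabilities = flatten_rowmajor(dist$p))
  js <- jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname dist_table_to_json
#' @param json a JSON string or file path produced by [dist_table_to_json()].
#' @export
dist_table_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  dist_table(obj$variables, as.list(obj$alphabets), obj$probabilities)
}

# structural-zero threshold: probabilities below this are treated as exact
# zeros when supports matter (guards against float dust)
STRUCTURAL_ZERO <- 1e-12
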