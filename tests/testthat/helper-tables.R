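# fixtures built in code: random joint tables and tiny worlds

random_joint <- function(sizes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vars <- paste0("X", seq_along(sizes))
  alph <- lapply(sizes, function(k) as.character(seq_len(k) - 1L))
  names(alph) <- vars
  p <- stats::rexp(prod(sizes))
  dist_table(vars, alph, array(p / sum(p), dim = sizes))
}

fair_coin_copies <- function(n) {
  # n perfect copies of one fair coin
  vars <- paste0("X", seq_len(n))
  alph <- stats::setNames(rep(list(c("0", "1")), n), vars)
  p <- array(0, dim = rep(2, n))
  p[matrix(1, 1, n)] <- 0.5
  p[matrix(2, 1, n)] <- 0.5
  dist_table(vars, alph, p)
}

independent_coins <- function(n) {
  vars <- paste0("X", seq_len(n))
  alph <- stats::setNames(rep(list(c("0", "1")), n), vars)
  dist_table(vars, alph, array(1 / 2^n, dim = rep(2, n)))
}

# deterministic toy concept on a 3x3 world: symbol = sign bucket of x
toy_concept_3x3 <- function(nsym = 3) {
  cells <- as.matrix(expand.grid(y = -1:1, x = -1:1))[, c("x", "y")]
  g <- cells[, 1] + 2L      # 1..3 by x coordinate
  cond <- matrix(0, 9, nsym)
  cond[cbind(1:9, pmin(g, nsym))] <- 1
  concept(cells, rep(1 / 9, 9), cond)
}

# slow, independent reference propagation: exhaustive sum-product in R
propagate_reference <- function(setup, ctrl, start) {
  states <- list(list(cell = start, m = 1L, p = 1))
  for (t in seq_len(setup$horizon)) {
    nxt <- list()
    for (st in states) {
      sd <- sensor_distribution(setup, st$cell)
      for (s in which(sd > 0)) {
        m2 <- ctrl$mnext[st$m, s]
        a <- ctrl$act[st$m, s]
        cell2 <- st$cell + c(c(0, -1, 0, 1)[a], c(-1, 0, 1, 0)[a])
        key <- paste(cell2[1], cell2[2], m2)
        found <- FALSE
        for (j in seq_along(nxt)) {
          if (identical(nxt[[j]]$key, key)) {
            nxt[[j]]$p <- nxt[[j]]$p + st$p * sd[s]
            found <- TRUE
            break
          }
        }
        if (!found)
          nxt[[length(nxt) + 1]] <- list(cell = cell2, m = m2,
                                         p = st$p * sd[s], key = key)
      }
    }
    states <- nxt
  }
  out <- numeric(ctrl$memory_size)
  for (st in states) out[st$m] <- out[st$m] + st$p
  out
}

# Monte-Carlo rollout oracle for p(m_T | r0)
rollout_mc <- function(setup, ctrl, start, n = 1e4) {
  disp <- matrix(c(0, -1, -1, 0, 0, 1, 1, 0), 4, 2, byrow = TRUE)
  counts <- numeric(ctrl$memory_size)
  for (i in seq_len(n)) {
    cell <- start
    m <- 1L
    for (t in seq_len(setup$horizon)) {
      sd <- sensor_distribution(setup, cell)
      s <- sample.int(4, 1, prob = sd)
      a <- ctrl$act[m, s]
      m <- ctrl$mnext[m, s]
      cell <- cell + disp[a, ]
    }
    counts[m] <- counts[m] + 1
  }
  counts / n
}
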