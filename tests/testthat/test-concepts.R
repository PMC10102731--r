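test_that("objective merge of one deterministic concept recovers it", {
  cpt <- toy_concept_3x3(3)
  ens <- concept_ensemble(list(cpt))

  # exhaustive oracle over all 3^9 mappings of the toy cells
  prior <- ens$prior
  W <- cpt$cond * prior
  u <- function(g) {
    J <- rowsum(W, g)
    conceptsym:::table_mi(J)  # alpha = 0
  }
  ex <- exhaustive_search(mapping_space(9, 3), u)
  hy1 <- entropy(dist_table("Y", list(Y = cpt$symbols),
                            as.numeric(prior %*% cpt$cond)))
  expect_equal(ex$utility, hy1, tolerance = 1e-12)

  cc <- objective_common_concept(ens, 3, alpha = 0,
                                 anneal_schedule(steps = 1500,
                                                 restarts = 3, seed = 2))
  expect_equal(cc$score, hy1, tolerance = 1e-9)
  expect_equal(concept_distance(cc$concept, cpt), 0, tolerance = 1e-9)
  # objective merges are deterministic in R: superstition 0 exactly
  expect_identical(superstition(cc$concept), 0)
})

test_that("objective score is invariant under symbol relabelings", {
  cpt <- toy_concept_3x3(3)
  set.seed(31)
  # a noisy second input: mixture of the first with uniform rows
  cond2 <- 0.8 * cpt$cond + 0.2 / 3
  cpt2 <- concept(cpt$cells, cpt$prior, cond2)
  ens <- concept_ensemble(list(cpt, cpt2))
  sch <- anneal_schedule(steps = 800, restarts = 2, seed = 7)
  cc <- objective_common_concept(ens, 3, 0.2, sch)

  # permuting the Y* labels of the mapping leaves the functional unchanged
  n <- length(ens$concepts); aw <- n * 0.2
  score_of <- function(g) {
    s <- 0
    for (cin in ens$concepts) {
      J <- rowsum(cin$cond * ens$prior, g)
      s <- s + conceptsym:::table_mi(J)
    }
    py <- as.numeric(rowsum(ens$prior, g))
    s - aw * (-sum(py[py > 0] * log2(py[py > 0])))
  }
  for (r in 1:3) {
    perm <- sample(3)
    expect_equal(score_of(perm[cc$mapping]), cc$score, tolerance = 1e-12)
  }
})

test_that("a finer partition without information gain is never preferred", {
  # two cells, one input that cannot distinguish them: splitting Y* over
  # the cells adds I(R;Y*) cost but no I(Y*;Y1) gain
  cells <- rbind(c(0L, 0L), c(1L, 0L))
  flat <- concept(cells, c(0.5, 0.5), matrix(0.5, 2, 2))
  ens <- concept_ensemble(list(flat))
  cc <- objective_common_concept(ens, 2, alpha = 0.2,
                                 anneal_schedule(steps = 300,
                                                 restarts = 3, seed = 4))
  expect_equal(populated_symbols(cc$concept), 1)
})

test_that("subjective merge of identical deterministic inputs is exact", {
  cpt <- toy_concept_3x3(3)
  ens <- concept_ensemble(list(cpt, cpt, cpt))
  cc <- subjective_common_concept(ens, 3,
                                  anneal_schedule(steps = 1000,
                                                  restarts = 3, seed = 9))
  expect_equal(cc$score, 0, tolerance = 1e-9)
  expect_equal(superstition(cc$concept), 0, tolerance = 1e-9)
  # the merged concept is permutation-equivalent to the shared input
  expect_equal(concept_distance(cc$concept, cpt), 0, tolerance = 1e-9)

  expect_error(subjective_common_concept(concept_ensemble(list(cpt)), 3),
               ">= 2")
})

test_that("a constant subjective mapping scores the full
           multi-information", {
  cpt <- toy_concept_3x3(3)
  set.seed(13)
  cond2 <- 0.7 * cpt$cond + 0.3 / 3
  cpt2 <- concept(cpt$cells, cpt$prior, cond2)
  ens <- concept_ensemble(list(cpt, cpt2))

  # conditioning on a constant changes nothing: the subjective objective
  # of the all-to-one mapping equals the unconditional multi-information
  p <- array(0, dim = c(9, 3, 3))
  for (r in 1:9) p[r, , ] <- ens$prior[r] *
      outer(cpt$cond[r, ], cpt2$cond[r, ])
  d <- dist_table(c("R", "Y1", "Y2"),
                  list(R = as.character(1:9), Y1 = cpt$symbols,
                       Y2 = cpt2$symbols), p)
  mi <- multi_information(d, list("Y1", "Y2"))

  cc <- subjective_common_concept(ens, 1,
                                  anneal_schedule(steps = 0, restarts = 1,
                                                  seed = 1,
                                                  initial_temperature = 1))
  expect_equal(cc$score, mi, tolerance = 1e-9)
})

test_that("superstition measures the conditional symbol entropy", {
  det <- toy_concept_3x3(3)
  expect_identical(superstition(det), 0)

  cells <- det$cells
  fuzzy <- concept(cells, rep(1 / 9, 9),
                   matrix(c(0.5, 0.5), 9, 2, byrow = TRUE))
  expect_equal(superstition(fuzzy), 1.0, tolerance = 1e-12)
})

test_that("concept distance vanishes exactly on symbol permutations", {
  cpt <- toy_concept_3x3(3)
  expect_equal(concept_distance(cpt, cpt), 0, tolerance = 1e-12)
  permuted <- concept(cpt$cells, cpt$prior, cpt$cond[, c(2, 3, 1)])
  expect_equal(concept_distance(cpt, permuted), 0, tolerance = 1e-9)

  other <- concept(cpt$cells, cpt$prior,
                   matrix(1 / 3, 9, 3))
  expect_gt(concept_distance(cpt, other), 0)

  moved <- concept(cpt$cells + 5L, cpt$prior, cpt$cond)
  expect_error(concept_distance(cpt, moved), "share")
})

test_that("ensembles require one shared support and prior", {
  cpt <- toy_concept_3x3(3)
  shifted <- concept(cpt$cells + 1L, cpt$prior, cpt$cond)
  expect_error(concept_ensemble(list(cpt, shifted)), "share")
  expect_error(concept_ensemble(list()), ">= 1")
})

test_that("concepts and common concepts round-trip through JSON", {
  cpt <- toy_concept_3x3(3)
  cpt2 <- concept_from_json(concept_to_json(cpt))
  expect_equal(cpt2$cells, cpt$cells)
  expect_equal(cpt2$prior, cpt$prior)
  expect_equal(unname(cpt2$cond), unname(cpt$cond))

  ens <- concept_ensemble(list(cpt, cpt, cpt))
  cc <- subjective_common_concept(ens, 3,
                                  anneal_schedule(steps = 200,
                                                  restarts = 1, seed = 2))
  cc2 <- common_concept_from_json(common_concept_to_json(cc))
  expect_identical(cc2$kind, cc$kind)
  expect_equal(cc2$mapping, cc$mapping)
  expect_equal(cc2$score, cc$score)
  expect_equal(unname(cc2$concept$cond), unname(cc$concept$cond))
})
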