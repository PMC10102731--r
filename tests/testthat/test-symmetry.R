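test_that("extrinsic operations compose reflection, rotation,
           translation in order", {
  expect_equal(apply_extrinsic(extrinsic_op(phi = 90), c(1, 0)), c(0, 1))
  expect_equal(apply_extrinsic(extrinsic_op(theta = -1), c(2, 3)),
               c(-2, 3))
  # reflect, then rotate 90, then translate (1,1):
  # (1,0) -> (-1,0) -> (0,-1) -> (1,0)
  expect_equal(apply_extrinsic(extrinsic_op(theta = -1, phi = 90,
                                            x0 = 1, y0 = 1), c(1, 0)),
               c(1, 0))
  # matrix form preserves shape
  cells <- rbind(c(0, 0), c(2, -1))
  out <- apply_extrinsic(extrinsic_op(phi = 180), cells)
  expect_equal(out, rbind(c(0, 0), c(-2, 1)))
})

test_that("the identity operation is maximal and self-match equals H(Y)
           for deterministic concepts", {
  det <- toy_concept_3x3(3)
  hy <- entropy(dist_table("Y", list(Y = det$symbols),
                           as.numeric(det$prior %*% det$cond)))
  expect_equal(extrinsic_utility(det, extrinsic_op()), hy,
               tolerance = 1e-12)

  # identity dominates every operation, also on random stochastic
  # concepts (evaluable everywhere via a periodic evaluator)
  set.seed(17)
  for (rep in 1:3) {
    base <- matrix(stats::rexp(9 * 3), 9, 3)
    base <- base / rowSums(base)
    cells <- as.matrix(expand.grid(y = -1:1, x = -1:1))[, c("x", "y")]
    ev <- function(cc) base[(cc[, 1] %% 3) * 3 + (cc[, 2] %% 3) + 1, ,
                            drop = FALSE]
    cpt <- concept(cells, rep(1 / 9, 9), ev(cells), evaluator = ev)
    u_id <- extrinsic_utility(cpt, extrinsic_op())
    ops <- extrinsic_ops_family(2)
    for (i in seq_len(nrow(ops))) {
      u <- extrinsic_utility(cpt, do.call(extrinsic_op,
                                          as.list(ops[i, ])))
      expect_lte(u, u_id + 1e-9)
    }
  }
})

test_that("the s+ sensor concept scores all 8 dihedral operations
           equally and maximally", {
  s <- world_setup("s+")
  sp <- extrinsic_spectrum(sensor_concept(s), 5)
  expect_equal(nrow(sp$entries), 968)

  dihedral <- sp$entries$x0 == 0 & sp$entries$y0 == 0
  expect_equal(sum(dihedral), 8)
  expect_lte(diff(range(sp$entries$utility[dihedral])), 1e-9)
  expect_equal(sp$entries$normalized[dihedral], rep(1, 8),
               tolerance = 1e-9)
  # a pure translation scores strictly below the dihedral maximum
  t3 <- sp$entries$x0 == 3 & sp$entries$y0 == 0 &
    sp$entries$theta == 1 & sp$entries$phi == 0
  expect_lt(sp$entries$utility[t3], sp$max_utility - 1e-6)

  sp0 <- extrinsic_spectrum(sensor_concept(s), 0)
  expect_equal(nrow(sp0$entries), 8)
})

test_that("good-symmetry counting respects thresholds and boundaries", {
  s <- world_setup("s+")
  sp <- extrinsic_spectrum(sensor_concept(s), 5)
  expect_equal(count_good_symmetries(sp, 1.0), 8)
  # just above the second peak the count is still exactly the 8 perfect
  # operations
  second <- max(sp$entries$normalized[sp$entries$normalized < 1 - 1e-9])
  expect_equal(count_good_symmetries(sp, second + 1e-9), 8)
  expect_equal(count_good_symmetries(sp, second),
               8 + sum(abs(sp$entries$normalized - second) <= 1e-15))
  expect_equal(count_good_symmetries(sp, 1e-12), nrow(sp$entries))
  expect_error(count_good_symmetries(sp, 0), "threshold")
})

test_that("embodiment permutations form a group acting on controllers", {
  set.seed(23)
  ctrl <- random_controller(4)
  idp <- embodiment_permutation()
  expect_equal(apply_embodiment(ctrl, idp)$mnext, ctrl$mnext)
  expect_equal(apply_embodiment(ctrl, idp)$act, ctrl$act)

  for (rep in 1:5) {
    pp <- embodiment_permutation(sample(4), sample(4))
    eff <- apply_embodiment(ctrl, pp)
    back <- apply_embodiment(eff, invert_embodiment(pp))
    expect_equal(back$mnext, ctrl$mnext)
    expect_equal(back$act, ctrl$act)
  }
  expect_error(embodiment_permutation(c(1, 1, 2, 3), 1:4), "permutation")
  expect_equal(length(all_embodiment_permutations()), 576)
})

test_that("intrinsic utility under the identity equals the plain
           common-concept agreement", {
  s <- world_setup("s+", d = 3, horizon = 8)
  set.seed(29)
  ctrl <- random_controller(4)
  cpt <- concept_from_agent(s, ctrl)
  ens <- concept_ensemble(list(cpt))
  common <- objective_common_concept(ens, 4, 0.2,
                                     anneal_schedule(steps = 500,
                                                     restarts = 2,
                                                     seed = 3))
  # I(M*; M_T) through the shared start-cell joint
  g <- conceptsym:::deterministic_assignment(common$concept, s)
  J <- rowsum(cpt$cond * cpt$prior, g)
  expect_equal(intrinsic_utility(s, ctrl, embodiment_permutation(),
                                 common$concept),
               conceptsym:::table_mi(J), tolerance = 1e-12)

  # permutation pairs producing identical effective controllers yield
  # identical utilities (stabilizer cosets)
  p1 <- embodiment_permutation(c(2, 1, 3, 4), 1:4)
  eff <- apply_embodiment(ctrl, p1)
  expect_equal(intrinsic_utility(s, ctrl, p1, common$concept),
               intrinsic_utility(s, eff, embodiment_permutation(),
                                 common$concept),
               tolerance = 1e-12)

  sp <- intrinsic_spectrum(s, ctrl, common$concept)
  expect_equal(nrow(sp$entries), 576)
  idrow <- which(apply(sp$entries[, 1:8], 1, function(r)
    all(r == c(1:4, 1:4))))
  expect_equal(sp$entries$utility[idrow],
               intrinsic_utility(s, ctrl, embodiment_permutation(),
                                 common$concept),
               tolerance = 1e-12)

  # non-deterministic "common" concepts are rejected
  expect_error(intrinsic_utility(s, ctrl, p1, cpt), "deterministic")
})

test_that("the intrinsic/controller search-space ratio is astronomically
           small", {
  expect_equal(intrinsic_search_ratio(4), 576 / 16^16, tolerance = 1e-15)
  expect_lt(intrinsic_search_ratio(8), intrinsic_search_ratio(4))
})
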