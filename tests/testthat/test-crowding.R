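test_that("nearest_member finds the structurally closest conformation", {
  set.seed(1)
  members <- lapply(1:5, function(i) random_conformation(8))
  pop <- de_population(members, rep(0, 5))
  # identical to member 3 -> index 3 with distance 0
  expect_equal(nearest_member(members[[3]], pop), 3)
  # population of 1
  pop1 <- de_population(members[1], 0)
  expect_equal(nearest_member(members[[3]], pop1), 1)
  expect_error(nearest_member(members[[1]], de_population(list(), numeric(0))))
  # brute-force all-pairs oracle on fresh probes
  for (probe_seed in 1:5) {
    probe <- random_conformation(8, 100 + probe_seed)
    d <- sapply(members, function(m) ca_rmsd(probe, m))
    expect_equal(nearest_member(probe, pop), which.min(d))
  }
})

test_that("crowding replacement is local and strictly-better", {
  w <- score_weights(1, 1, 1, 1, 1)
  set.seed(2)
  members <- lapply(1:4, function(i) random_conformation(8, 200 + i))
  ssc <- strrep("L", 8)
  fit <- sapply(members, function(m)
    stage_score(energy_terms(m, ssc), w))
  pop <- de_population(members, fit)
  # a trial close to member 2, better than it but worse than the global
  # best, must replace member 2 and leave the best member in place
  near2 <- members[[2]]
  near2$dihedrals[4, "phi"] <- wrap_angle(near2$dihedrals[4, "phi"] + 2)
  j_expect <- nearest_member(near2, pop)
  expect_equal(j_expect, 2)
  res <- crowding_replace(near2, pop, w, ssc,
                          trial_fitness = fit[2] - 0.5)
  expect_equal(res$replaced, 2)
  expect_equal(res$population$fitness[2], fit[2] - 0.5)
  for (i in c(1, 3, 4))   # competition is local: everyone else untouched
    expect_identical(res$population$members[[i]]$dihedrals,
                     members[[i]]$dihedrals)
  expect_equal(res$population$fitness[c(1, 3, 4)], fit[c(1, 3, 4)])
  # worse than its nearest member: population unchanged (ties keep incumbent)
  res2 <- crowding_replace(near2, pop, w, ssc, trial_fitness = fit[2] + 1)
  expect_true(is.na(res2$replaced))
  expect_equal(res2$population$fitness, fit)
  res3 <- crowding_replace(near2, pop, w, ssc, trial_fitness = fit[2])
  expect_true(is.na(res3$replaced))
})

test_that("a replay on a two-basin population preserves both basins", {
  # two structural families (helix-like and strand-like); trials from each
  # family only ever displace members of their own family
  sq <- random_sequence(8)
  mk <- function(phi, psi, jit)
    conformation(sq, cbind(rep(180, 8), rep(phi, 8) + jit, rep(psi, 8)))
  set.seed(3)
  helixish <- lapply(c(0, 2), function(j) mk(-57, -47, j))
  strandish <- lapply(c(0, 2), function(j) mk(-120, 120, j))
  members <- c(helixish, strandish)
  fit <- c(10, 11, 10, 11)
  pop <- de_population(members, fit)
  w <- score_weights(1, 1, 1, 1, 1)
  trials <- list(mk(-57, -47, 4), mk(-120, 120, 4), mk(-57, -47, -2),
                 mk(-120, 120, -2))
  tfit <- c(9, 8, 7, 6)
  replaced <- integer(0)
  for (i in seq_along(trials)) {
    res <- crowding_replace(trials[[i]], pop, w, trial_fitness = tfit[i])
    pop <- res$population
    replaced <- c(replaced, res$replaced)
  }
  # scripted exhaustive expectation: helix trials hit members 1..2,
  # strand trials hit members 3..4
  expect_true(all(replaced[c(1, 3)] %in% 1:2))
  expect_true(all(replaced[c(2, 4)] %in% 3:4))
  # both basins still represented
  d_to_helix <- sapply(pop$members, function(m) ca_rmsd(m, helixish[[1]]))
  d_to_strand <- sapply(pop$members, function(m) ca_rmsd(m, strandish[[1]]))
  expect_true(any(d_to_helix < d_to_strand))
  expect_true(any(d_to_strand < d_to_helix))
})

test_that("with population size 1 crowding equals greedy selection", {
  tp <- make_toy_problem(10, seed = 6)
  sched <- toy_schedule(c(15L, 15L, 15L, 30L))
  cfg <- de_config(population_size = 1, generations_per_stage = 3,
                   increase_cycles = 1, seed = 9)
  hb <- hybridde(tp$target, tp$libraries, cfg, sched$evolutionary,
                 tp$ss_target)
  cd <- crowdingde(tp$target, tp$libraries, cfg, sched$evolutionary,
                   tp$ss_target)
  expect_identical(hb$population$members[[1]]$dihedrals,
                   cd$population$members[[1]]$dihedrals)
  expect_equal(hb$population$fitness, cd$population$fitness)
  expect_equal(hb$history$best, cd$history$best)
})

test_that("crowdingde keeps population size and never loses the best", {
  tp <- make_toy_problem(10, seed = 8)
  sched <- toy_schedule(c(15L, 15L, 15L, 30L))
  cfg <- de_config(population_size = 5, generations_per_stage = 3,
                   increase_cycles = 1, seed = 2)
  cd <- crowdingde(tp$target, tp$libraries, cfg, sched$evolutionary,
                   tp$ss_target)
  expect_length(cd$population$members, 5)
  h <- cd$history
  for (s in 1:3)
    expect_true(all(diff(h$best[h$stage == s]) <= 1e-9))
  # the diversity trace is recorded and finite
  expect_true(all(is.finite(h$diversity)))
})

test_that("niche summary counts basins and alternative stubs refuse", {
  sq <- random_sequence(8)
  mk <- function(phi, psi) conformation(sq, cbind(rep(180, 8), rep(phi, 8),
                                                  rep(psi, 8)))
  pop <- de_population(list(mk(-57, -47), mk(-58, -46), mk(-120, 120)),
                       c(1, 2, 3))
  ns <- niche_summary(pop, threshold = 2)
  expect_equal(ns$n_niches, 2)
  expect_true(isSymmetric(ns$distance))
  expect_true(all(diag(ns$distance) == 0))
  expect_error(sharing_select(), "not implemented")
  expect_error(speciation_select(), "not implemented")
})
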