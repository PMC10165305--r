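make_pop <- function(n, L, seed = 1) {
  set.seed(seed)
  members <- lapply(seq_len(n), function(i) random_conformation(L))
  de_population(members, fitness = rep(NA_real_, n))
}

test_that("de_trial edge cases follow the rand/1/bin contract", {
  pop <- make_pop(4, 6, 1)
  # CR = 1: every gene comes from the mutant; with F = 0 the mutant is the
  # base vector, so the trial's genes all belong to one population member
  set.seed(2)
  tr <- de_trial(1, pop, F = 0, CR = 1)
  genes <- function(cf) as.vector(cf$dihedrals[, c("phi", "psi")])
  match_member <- sapply(1:4, function(i)
    all(abs(wrap_angle(genes(tr) - genes(pop$members[[i]]))) < 1e-9))
  expect_true(any(match_member[2:4]))
  expect_false(match_member[1])

  # F = 0, CR = 0: trial equals target except the single forced gene,
  # which equals the base member's gene (exhaustive over many draws)
  for (rep in 1:20) {
    tr0 <- de_trial(2, pop, F = 0, CR = 0)
    d <- which(abs(wrap_angle(genes(tr0) - genes(pop$members[[2]]))) > 1e-9)
    expect_lte(length(d), 1)  # at most one gene differs (it may coincide)
    if (length(d) == 1) {
      from_others <- sapply(c(1, 3, 4), function(i)
        abs(wrap_angle(genes(tr0)[d] - genes(pop$members[[i]])[d])) < 1e-9)
      expect_true(any(from_others))
    }
  }
  expect_error(de_trial(1, make_pop(3, 6, 3), 0.5, 0.5))
})

test_that("numerically identical difference donors give mutant = base", {
  # target 1 leaves only copies of b as donors: the difference vector is
  # exactly zero, so for any F the mutant equals the base member b and,
  # with CR = 1, the trial equals b
  L <- 5
  a <- random_conformation(L, 10)
  b <- random_conformation(L, 11)
  pop <- de_population(list(a, b, b, b), rep(NA_real_, 4))
  gb <- as.vector(b$dihedrals[, c("phi", "psi")])
  set.seed(12)
  for (i in 1:10) {
    tr <- de_trial(1, pop, F = stats::runif(1, 0, 10), CR = 1)
    g <- as.vector(tr$dihedrals[, c("phi", "psi")])
    expect_true(all(abs(wrap_angle(g - gb)) < 1e-9))
  }
})

test_that("mutation uses shortest-arc angular arithmetic across the seam", {
  # x_r1 = 170, x_r2 = -170, x_r3 = 170: d = 20 through the seam,
  # mutant = wrap(170 + F * 20) = 170.5 at F = 0.025
  L <- 1
  mk <- function(phi) conformation(aa_sequence("A"),
                                   cbind(180, phi, 0))
  pop <- de_population(list(mk(0), mk(170), mk(-170), mk(170)),
                       rep(NA_real_, 4))
  # target = 1; sample until (r1, r2, r3) = (2, 3, 4)
  set.seed(33)
  found <- FALSE
  for (i in 1:500) {
    seed_i <- 1000 + i
    set.seed(seed_i)
    r <- sample(2:4, 3)
    if (identical(r, c(2L, 3L, 4L))) {
      set.seed(seed_i)
      tr <- de_trial(1, pop, F = 0.025, CR = 1)
      expect_equal(unname(tr$dihedrals[1, "phi"]), 170.5, tolerance = 1e-9)
      found <- TRUE
      break
    }
  }
  expect_true(found)
  # brute-force cross-check of the shortest arc value
  cand <- (-170 - 170) + c(-720, -360, 0, 360, 720)
  d <- cand[which.min(abs(cand))]
  expect_equal(wrap_angle(170 + 0.025 * d), 170.5)
})

test_that("local_refine honours its budget and best-seen contract", {
  tp <- make_toy_problem(10, seed = 7)
  stage <- protocol_stage("s", score_weights(1, 1, 1, 1, 1), 3, 0)
  ext <- extended_conformation(tp$target)
  ssc <- cgfold:::ss_codes(tp$ss_target, 10)
  e0 <- cgfold:::conf_energy(ext, ssc, stage$weights)
  r0 <- local_refine(ext, tp$libraries[["3"]], stage, 0,
                     ss_target = tp$ss_target, e_start = e0)
  expect_equal(r0$conformation$dihedrals, ext$dihedrals)
  expect_equal(r0$energy, e0)
  cnt <- new_eval_counter()
  set.seed(3)
  r <- local_refine(ext, tp$libraries[["3"]], stage, 40,
                    ss_target = tp$ss_target, counter = cnt, e_start = e0)
  expect_equal(cnt$n, 40L)
  expect_lte(r$energy, e0)
  e_check <- cgfold:::conf_energy(r$conformation, ssc, stage$weights)
  expect_equal(e_check, r$energy, tolerance = 1e-9)
})

test_that("hybridde maintains population size and monotone best fitness", {
  tp <- make_toy_problem(10, seed = 5)
  sched <- toy_schedule(c(20L, 20L, 20L, 40L))
  cfg <- de_config(population_size = 5, generations_per_stage = 4,
                   increase_cycles = 0.5, seed = 3)
  hb <- hybridde(tp$target, tp$libraries, cfg, sched$evolutionary,
                 tp$ss_target)
  expect_length(hb$population$members, 5)
  h <- hb$history
  expect_equal(nrow(h), 3 * 4)
  expect_true(all(is.finite(h$best)), all(is.finite(h$mean)))
  for (s in 1:3) {
    hs <- h[h$stage == s, ]
    expect_true(all(diff(hs$best) <= 1e-9))
  }
  # generations_per_stage = 0: population equals the stage-1 seeding
  cfg0 <- de_config(population_size = 5, generations_per_stage = 0,
                    increase_cycles = 0.5, seed = 3)
  hb0 <- hybridde(tp$target, tp$libraries, cfg0, sched$evolutionary,
                  tp$ss_target)
  for (i in 1:5)
    expect_identical(hb0$population$members[[i]]$dihedrals,
                     hb0$initial_population[[i]]$dihedrals)
  expect_equal(nrow(hb0$history), 0)
})

test_that("de_config validates its invariants", {
  expect_error(de_config(population_size = 2))
  expect_error(de_config(population_size = 3))
  expect_error(de_config(CR = 1.5))
  expect_error(de_config(CR = -0.1))
  expect_error(de_config(F = -1))
  expect_error(de_config(increase_cycles = 0))
  expect_equal(de_config(population_size = 1)$population_size, 1L)
  expect_equal(de_config()$strategy, "rand/1/bin")
})
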