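test_that("steric term follows the quadratic clash formula", {
  # two residues far apart along the chain forced to clash: a long chain
  # bent is hard to control, so check against the independent reference
  # on random conformations instead, plus the closed-form support rule
  cf <- random_conformation(10, 1)
  s <- build_backbone(cf)
  t_pkg <- energy_terms(s, strrep("L", 10))
  ref <- ref_build_backbone(cf$dihedrals[, "omega"], cf$dihedrals[, "phi"],
                            cf$dihedrals[, "psi"],
                            cgfold:::cen_radii(cf$sequence))
  t_ref <- ref_energy_terms(ref, cf$dihedrals[, "phi"],
                            cf$dihedrals[, "psi"], strrep("L", 10))
  expect_equal(unname(t_pkg), unname(t_ref), tolerance = 1e-8)
})

test_that("a clash pair contributes (r_clash - d)^2 and support is exact", {
  # direct evaluation of the compiled kernel on synthetic coordinates:
  # 2 residues, CA atoms 2.0 A apart, everything else far away
  far <- function(base) matrix(base + c(0, 500, 0), 1, 3)
  coords <- rbind(
    far(c(0, 0, 0)), c(0, 0, 0), far(c(1, 0, 0)), far(c(2, 0, 0)),
    far(c(3, 0, 0)),
    far(c(100, 0, 0)), c(2, 0, 0), far(c(101, 0, 0)), far(c(102, 0, 0)),
    far(c(103, 0, 0)))
  # residue separation 1 only -> excluded; need separation >= 2: use 3 residues
  coords <- rbind(coords[1:5, ], matrix(rep(c(50, -500, 0), 5), 5, 3,
                                        byrow = TRUE), coords[6:10, ])
  t <- cgfold:::cpp_energy_terms(coords, rep(180, 3), rep(180, 3),
                                 rep(2L, 3))
  # the only pair within 4 A with separation >= 2 is CA1..CA3 at d = 2
  expect_equal(t[1], (4 - 2)^2)
  # move it out of range -> steric support vanishes
  coords[12, ] <- c(50, 0, 0)
  t2 <- cgfold:::cpp_energy_terms(coords, rep(180, 3), rep(180, 3),
                                  rep(2L, 3))
  expect_equal(t2[1], 0)
})

test_that("stage_score is a dot product and linear in the weights", {
  t <- c(steric = 4, vdw_attract = -2, rg = 10, hbond = -1, ss_pair = 3)
  expect_equal(stage_score(t, score_weights(steric = 1)), 4)
  expect_equal(stage_score(t, score_weights(1, 1, 1, 1, 1)), 14)
  expect_error(stage_score(t[-1], score_weights(1, 1, 1, 1, 1)))
  expect_error(score_weights())                      # all-zero rejected
  expect_error(score_weights(steric = -1, rg = 1))   # negative rejected
  set.seed(9)
  for (i in 1:20) {
    w1 <- score_weights(runif(1), runif(1), runif(1), runif(1), runif(1))
    w2 <- score_weights(runif(1), runif(1), runif(1), runif(1), runif(1))
    w12 <- score_weights(w1[1] + w2[1], w1[2] + w2[2], w1[3] + w2[3],
                         w1[4] + w2[4], w1[5] + w2[5])
    tv <- stats::rnorm(5); names(tv) <- names(t)
    expect_equal(stage_score(tv, w12),
                 stage_score(tv, w1) + stage_score(tv, w2),
                 tolerance = 1e-10)
  }
})

test_that("energy terms are invariant under rigid motion of the chain", {
  cf <- random_conformation(9, 5)
  s <- build_backbone(cf)
  t0 <- energy_terms(s, strrep("L", 9))
  set.seed(6)
  for (i in 1:5) {
    s2 <- s
    s2$coords <- s$coords %*% random_rotation() +
      matrix(stats::rnorm(3, sd = 20), nrow(s$coords), 3, byrow = TRUE)
    expect_equal(energy_terms(s2, strrep("L", 9)), t0, tolerance = 1e-8)
  }
})

test_that("an ideal helix scores no worse than the extended chain", {
  set.seed(10)
  w <- score_weights(1, 1, 1, 1, 1)
  for (L in sample(8:20, 5)) {
    sq <- random_sequence(L)
    ss <- strrep("H", L)
    helix <- conformation(sq, cbind(rep(180, L), rep(-57, L), rep(-47, L)))
    ext <- extended_conformation(sq)
    e_h <- stage_score(energy_terms(helix, ss), w)
    e_e <- stage_score(energy_terms(ext, ss), w)
    expect_lte(e_h, e_e)
    # and the helix is more compact
    expect_lt(energy_terms(helix, ss)["rg"], energy_terms(ext, ss)["rg"])
  }
})

test_that("default schedules have the documented staged shape", {
  s <- default_schedules()
  expect_length(s$abinitio, 4)
  expect_length(s$evolutionary, 3)
  # final stage enables all five terms
  expect_true(all(unclass(s$abinitio[[4]]$weights) > 0))
  expect_true(all(unclass(s$evolutionary[[3]]$weights) > 0))
  # stage 1 is steric-only; the evolutionary schedule equals stages 2-4
  w1 <- unclass(s$abinitio[[1]]$weights)
  expect_equal(unname(w1), c(1, 0, 0, 0, 0))
  for (i in 1:3)
    expect_equal(s$evolutionary[[i]]$weights, s$abinitio[[i + 1]]$weights)
  # fragment lengths follow the 9,9,9,3 convention
  expect_equal(vapply(s$abinitio, `[[`, integer(1), "k"), c(9L, 9L, 9L, 3L))
  # a schedule whose last stage disables terms is rejected
  expect_error(stage_schedule(s$abinitio[[1]]))
})

test_that("schedules survive a YAML round trip", {
  s <- default_schedules(base_cycles = c(10L, 20L, 30L, 40L))$abinitio
  f <- tempfile(fileext = ".yaml")
  schedule_to_yaml(s, f)
  s2 <- schedule_from_yaml(f)
  expect_equal(length(s2), length(s))
  for (i in seq_along(s)) {
    expect_equal(s2[[i]]$weights, s[[i]]$weights)
    expect_equal(s2[[i]]$cycles, s[[i]]$cycles)
    expect_equal(s2[[i]]$k, s[[i]]$k)
  }
})
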