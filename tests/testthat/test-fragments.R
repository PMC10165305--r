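test_that("library construction enumerates and ranks windows correctly", {
  # a source of length 10 yields L - k + 1 = 8 candidate 3-mers per window
  src <- random_conformation(10, 1)
  lib <- build_library(list(src), src$sequence, 3, n_per_position = 100)
  expect_length(lib$positions, 8)
  expect_true(all(lengths(lib$positions) == 8))

  # identical source: every window's top fragment is the aligned k-mer
  for (pos in seq_along(lib$positions)) {
    top <- lib$positions[[pos]][[1]]
    expect_equal(top$source_seq,
                 paste(unclass(src$sequence)[pos:(pos + 2)], collapse = ""))
    expect_equal(unname(top$dihedrals),
                 unname(src$dihedrals[pos:(pos + 2), ]))
  }
  expect_error(build_library(list(), src$sequence, 3))
  expect_error(build_library(list(src), aa_sequence("AC"), 3))
})

test_that("similarity ranking prefers more identities, brute-force checked", {
  # two single-window sources competing for target window 'ACD'
  target <- aa_sequence("ACD")
  d1 <- cbind(rep(180, 3), rep(-57, 3), rep(-47, 3))
  d2 <- cbind(rep(180, 3), rep(-120, 3), rep(120, 3))
  exact <- conformation(aa_sequence("ACD", id = "exact"), d1)
  close <- conformation(aa_sequence("ACE", id = "close"), d2)
  lib <- build_library(list(close, exact), target, 3, 2)
  expect_equal(lib$positions[[1]][[1]]$source_seq, "ACD") # 3 identities first
  expect_equal(lib$positions[[1]][[2]]$source_seq, "ACE")

  # brute-force check on a longer random case
  set.seed(21)
  tgt <- random_sequence(9)
  srcs <- lapply(1:3, function(i) random_conformation(9, 30 + i))
  lib2 <- build_library(srcs, tgt, 3, n_per_position = 5)
  for (pos in c(1, 4, 7)) {
    w <- unclass(tgt)[pos:(pos + 2)]
    scores <- unlist(lapply(srcs, function(s) {
      sapply(1:7, function(off)
        sum(unclass(s$sequence)[off:(off + 2)] == w))
    }))
    best5 <- sort(scores, decreasing = TRUE)[1:5]
    got <- sapply(lib2$positions[[pos]], function(f)
      sum(strsplit(f$source_seq, "")[[1]] == w))
    expect_equal(got, best5)
  }
})

test_that("fragment insertion is local, pure and self-inverse", {
  cf <- random_conformation(10, 2)
  lib <- build_library(list(cf), cf$sequence, 3, 1)
  # reinsertion of the fragment extracted at pos leaves the genome unchanged
  for (pos in c(1, 5, 8)) {
    out <- insert_fragment(cf, lib$positions[[pos]][[1]], pos)
    expect_equal(out$dihedrals, cf$dihedrals)
  }
  # insertion at pos 1 leaves residues 4..10 untouched, input unmodified
  other <- random_conformation(10, 3)
  frag <- fragment(other$dihedrals[1:3, ], "XYZ"[1], "o")
  before <- cf$dihedrals
  out <- insert_fragment(cf, frag, 1)
  expect_equal(out$dihedrals[4:10, ], before[4:10, ])
  expect_equal(out$dihedrals[1:3, ], frag$dihedrals)
  expect_equal(cf$dihedrals, before)
  expect_error(insert_fragment(cf, frag, 9))
  expect_error(insert_fragment(cf, frag, 0))
})

test_that("insertions at disjoint windows commute", {
  set.seed(22)
  cf <- random_conformation(12, 4)
  fa <- fragment(matrix(stats::runif(9, -180, 180), 3), "AAA", "a")
  fb <- fragment(matrix(stats::runif(9, -180, 180), 3), "BBB", "b")
  for (i in 1:10) {
    p1 <- sample(1:4, 1); p2 <- sample(7:10, 1)
    ab <- insert_fragment(insert_fragment(cf, fa, p1), fb, p2)
    ba <- insert_fragment(insert_fragment(cf, fb, p2), fa, p1)
    expect_equal(ab$dihedrals, ba$dihedrals)
  }
})

test_that("proposal positions are uniform and seed-reproducible", {
  cf <- random_conformation(11, 5)
  lib <- build_library(list(cf), cf$sequence, 3, 2)
  npos <- length(lib$positions)
  set.seed(99)
  pos <- replicate(10000, random_fragment_move(cf, lib)$pos)
  tab <- tabulate(pos, npos)
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.01)
  # degenerate support: L == k with one fragment -> only one proposal
  short <- random_conformation(3, 6)
  slib <- build_library(list(short), short$sequence, 3, 1)
  mv <- random_fragment_move(short, slib)
  expect_equal(mv$pos, 1)
  # seeded reproducibility
  set.seed(7); a <- replicate(20, random_fragment_move(cf, lib)$pos)
  set.seed(7); b <- replicate(20, random_fragment_move(cf, lib)$pos)
  expect_identical(a, b)
})

test_that("fragment libraries survive a TSV round trip", {
  cf <- random_conformation(10, 8)
  lib <- build_library(list(cf), cf$sequence, 3, 3)
  f <- tempfile(fileext = ".tsv")
  write_fragments(lib, f)
  lib2 <- read_fragments(f)
  expect_equal(lib2$k, lib$k)
  expect_length(lib2$positions, length(lib$positions))
  for (pos in seq_along(lib$positions))
    for (r in seq_along(lib$positions[[pos]]))
      expect_equal(lib2$positions[[pos]][[r]]$dihedrals,
                   lib$positions[[pos]][[r]]$dihedrals,
                   tolerance = 1e-4)
})

test_that("greedy top-1 paving reconstructs the source conformation", {
  cf <- random_conformation(14, 9)
  for (k in c(3, 9)) {
    lib <- build_library(list(cf), cf$sequence, k, 1)
    paved <- pave_top_fragments(extended_conformation(cf$sequence), lib)
    expect_equal(paved$dihedrals, cf$dihedrals)
    expect_lt(ca_rmsd(paved, cf), 1e-9)
  }
})
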