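load_model <- function(ts) {
  f <- tempfile(fileext = ".pdb")
  writeLines(ts$pdb, f)
  on.exit(unlink(f))
  read_structure(f)
}

test_that("C-alpha distances are Euclidean, symmetric and non-negative", {
  # plant a 3-4-5 triangle directly
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA B   1       3.000   4.000   0.000  1.00  0.00           C",
    "END"), f)
  m <- read_structure(f)
  cm <- chain_map(list(S1 = "A", S2 = "B"))
  expect_equal(ca_distance(m, cm, "S1", 1, "S2", 1), 5.0)
  expect_equal(ca_distance(m, cm, "S2", 1, "S1", 1), 5.0)
  expect_equal(ca_distance(m, cm, "S1", 1, "S1", 1), 0.0)
})

test_that("multi-copy subunits take the minimum over chain-pair combinations", {
  # four chains: S1 -> {A, B}, S2 -> {C, D}; residue 1 of each at
  # hand-placed positions giving candidate distances {12, 7.5, 31, 18.2}
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA B   1      12.000   0.000   7.500  1.00  0.00           C",
    "ATOM      3  CA  ALA C   1      12.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  ALA D   1      19.550   0.000  24.060  1.00  0.00           C",
    "END"), f)
  m <- read_structure(f)
  cm <- chain_map(list(S1 = c("A", "B"), S2 = c("C", "D")))
  # brute-force oracle over all cross-copy pairs from the parsed atoms
  cand <- c()
  for (p in c("A", "B")) for (q in c("C", "D")) {
    u <- unlist(m$atoms[m$atoms$chain == p, c("x", "y", "z")])
    v <- unlist(m$atoms[m$atoms$chain == q, c("x", "y", "z")])
    cand <- c(cand, sqrt(sum((u - v)^2)))
  }
  expect_equal(sort(cand), c(7.5, 12.0, 18.2, 31.0), tolerance = 1e-3)
  expect_equal(ca_distance(m, cm, "S1", 1, "S2", 1), min(cand))
})

test_that("the packaged crosslink table classifies to the published counts", {
  tab <- table1_fixture()
  a <- assess_crosslinks(tab, distances = tab$distance)
  s <- assessment_stats(a)
  expect_equal(s$n, 33L)
  expect_equal(s$n_below_reference, 25L)   # below the 23 A empirical bound
  expect_equal(s$n_unresolved, 5L)
  expect_equal(s$n_violated, 3L)           # above the 30 A cutoff
  expect_equal(s$n_satisfied + s$n_violated + s$n_unresolved, 33L)
  # the unresolved rows are exactly the flagged ones
  expect_equal(a$status == "unresolved", tab$flag != "")
})

test_that("planted crosslinks classify by distance against the cutoff", {
  ts <- gen_toy_structure(
    data.frame(chain = c("A", "B"), n_residues = c(30, 30)),
    planted_crosslinks = data.frame(chain1 = "A", res1 = 10, chain2 = "B",
                                    res2 = 15, distance = 10),
    seed = 7)
  m <- load_model(ts)
  cm <- chain_map(list(S1 = "A", S2 = "B"))
  r <- xl_rows("S1", 10L, "S2", 15L)
  a <- assess_crosslinks(r, model = m, cmap = cm)
  expect_equal(a$status, "satisfied")
  expect_equal(a$distance, 10, tolerance = 1e-3)

  # a crosslink into a deleted range is unresolved
  ts2 <- gen_toy_structure(
    data.frame(chain = c("A", "B"), n_residues = c(30, 30)),
    deleted_ranges = data.frame(chain = "B", from = 14, to = 16),
    seed = 7)
  a2 <- assess_crosslinks(r, model = load_model(ts2), cmap = cm)
  expect_equal(a2$status, "unresolved")
  expect_true(is.na(a2$distance))
})

test_that("distance-supplied and compute modes produce identical statuses", {
  ts <- gen_toy_structure(
    data.frame(chain = c("A", "B"), n_residues = c(60, 60)),
    planted_crosslinks = data.frame(chain1 = "A", res1 = 10, chain2 = "B",
                                    res2 = 20, distance = 28),
    seed = 9)
  m <- load_model(ts)
  cm <- chain_map(list(S1 = "A", S2 = "B"))
  r <- xl_rows(rep("S1", 4), c(10L, 10L, 30L, 5L),
               rep("S2", 4), c(20L, 50L, 40L, 12L))
  computed <- assess_crosslinks(r, model = m, cmap = cm)
  supplied <- assess_crosslinks(r, distances = computed$distance)
  expect_identical(supplied$status, computed$status)
})

test_that("satisfied sets are monotone in the cutoff", {
  tab <- table1_fixture()
  sat <- function(t) {
    a <- assess_crosslinks(tab, distances = tab$distance,
                           config = validation_config(satisfied_max = t,
                                                      reference_observed_max = min(23, t)))
    which(a$status == "satisfied")
  }
  thresholds <- c(10, 23, 30, 60, 400)
  for (i in seq_len(length(thresholds) - 1)) {
    expect_true(all(sat(thresholds[i]) %in% sat(thresholds[i + 1])))
  }
  # boundary: a distance exactly at the cutoff counts as satisfied
  r <- xl_rows("A", 10L, "B", 20L)
  a <- assess_crosslinks(r, distances = 30)
  expect_equal(a$status, "satisfied")
})

test_that("proximity estimates anchor at the nearest modeled flank", {
  # chain B residues 14-20 deleted; crosslink from a resolved A residue to
  # the missing B residue 16; flanks are 13 and 21
  ts <- gen_toy_structure(
    data.frame(chain = c("A", "B"), n_residues = c(40, 40)),
    deleted_ranges = data.frame(chain = "B", from = 14, to = 20),
    planted_crosslinks = data.frame(chain1 = "A", res1 = 10, chain2 = "B",
                                    res2 = 13, distance = 15),
    seed = 13)
  m <- load_model(ts)
  cm <- chain_map(list(S1 = "A", S2 = "B"))
  r <- xl_rows("S1", 10L, "S2", 16L)
  a <- assess_crosslinks(r, model = m, cmap = cm)
  expect_equal(a$status, "unresolved")
  est <- unresolved_proximity(m, cm, a[1, ])
  # exhaustive oracle over the two flanks
  p10 <- get_ca(m, cm, "S1", 10)
  cand <- c(`13` = sqrt(sum((p10 - get_ca(m, cm, "S2", 13))^2)),
            `21` = sqrt(sum((p10 - get_ca(m, cm, "S2", 21))^2)))
  expect_equal(est$distance, min(cand))
  expect_match(est$anchor_note, names(which.min(cand)))
  expect_true(est$plausible)
})

test_that("a terminus gap uses the single available flank", {
  ts <- gen_toy_structure(
    data.frame(chain = c("A", "B"), n_residues = c(20, 20)),
    deleted_ranges = data.frame(chain = "B", from = 1, to = 5),
    planted_crosslinks = data.frame(chain1 = "A", res1 = 10, chain2 = "B",
                                    res2 = 6, distance = 12),
    seed = 14)
  m <- load_model(ts)
  cm <- chain_map(list(S1 = "A", S2 = "B"))
  r <- xl_rows("S1", 10L, "S2", 3L)
  a <- assess_crosslinks(r, model = m, cmap = cm)
  est <- unresolved_proximity(m, cm, a[1, ])
  expect_match(est$anchor_note, "residue 6")
  expect_match(est$anchor_note, "upper flank")
})

test_that("far-away flanks are flagged not plausible", {
  # stretch the chains far apart: B placed 500 A away by default layout
  ts <- gen_toy_structure(
    data.frame(chain = c("A", "B"), n_residues = c(20, 20)),
    deleted_ranges = data.frame(chain = "B", from = 8, to = 12),
    seed = 15)
  m <- load_model(ts)
  cm <- chain_map(list(S1 = "A", S2 = "B"))
  r <- xl_rows("S1", 10L, "S2", 10L)
  a <- assess_crosslinks(r, model = m, cmap = cm)
  est <- unresolved_proximity(m, cm, a[1, ])
  expect_gt(est$distance, 50)
  expect_false(est$plausible)
})

test_that("both sides unmodeled yields an unavailable estimate, not an error", {
  ts <- gen_toy_structure(
    data.frame(chain = c("A", "B"), n_residues = c(20, 20)),
    deleted_ranges = data.frame(chain = c("A", "B"), from = c(5, 5),
                                to = c(10, 10)),
    seed = 16)
  m <- load_model(ts)
  cm <- chain_map(list(S1 = "A", S2 = "B"))
  r <- xl_rows("S1", 7L, "S2", 7L)
  a <- assess_crosslinks(r, model = m, cmap = cm)
  est <- unresolved_proximity(m, cm, a[1, ])
  expect_true(is.na(est$distance))
  expect_match(est$anchor_note, "both sides")
})

test_that("subunit-pair summaries partition the assessments", {
  tab <- table1_fixture()
  a <- assess_crosslinks(tab, distances = tab$distance)
  pairs <- summarize_pairs(a)
  expect_equal(sum(pairs$n), 33L)
  expect_equal(pairs$n, pairs$n_satisfied + pairs$n_violated +
                 pairs$n_unresolved)
  h14 <- pairs[pairs$subunit1 == "HAUS1" & pairs$subunit2 == "HAUS4", ]
  expect_equal(h14$n, 2L)
  expect_equal(nrow(summarize_pairs(a[0, ])), 0L)
})

test_that("config invariants are enforced", {
  expect_error(validation_config(satisfied_max = 20,
                                 reference_observed_max = 23), NULL)
  expect_error(validation_config(theoretical_range = c(30, 26)), NULL)
})
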