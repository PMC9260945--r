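test_that("the published reactivity table is recovered from its energies", {
  fe <- read_frontier_energies(ip_extdata("frontier_energies.tsv"))
  gr <- global_indices(fe)
  expect_equal(gr$compound_id, reactivity_expected$id)
  tol <- 1e-4 + 1e-9  # one unit in the fourth decimal
  expect_true(all(abs(gr$gap - reactivity_expected$gap) <= tol))
  expect_true(all(abs(gr$hardness - reactivity_expected$hardness) <= tol))
  expect_true(all(abs(gr$chemical_potential - reactivity_expected$mu) <= tol))
  expect_true(all(abs(gr$electrophilicity - reactivity_expected$omega) <= tol))
  # Koopmans bookkeeping columns
  expect_equal(gr$ionization_potential, -gr$e_homo)
  expect_equal(gr$electron_affinity, -gr$e_lumo)
  expect_equal(gr$electronegativity, -gr$chemical_potential)
})

test_that("symmetric energies give zero potential and omega", {
  g <- global_indices(c(-2.5, 2.5))
  expect_equal(g$chemical_potential, 0)
  expect_equal(g$electronegativity, 0)
  expect_equal(g$electrophilicity, 0)
  expect_equal(g$hardness, 2.5)
})

test_that("degenerate or invalid gaps are rejected", {
  expect_error(global_indices(c(-5, -5)), "degenerate")
  expect_error(global_indices(c(-1, -2)), "degenerate")
  fe <- data.frame(compound_id = c("a", "b"),
                   e_homo_ev = c(-5, -4), e_lumo_ev = c(-1, -4.5))
  expect_error(global_indices(fe), "b")
})

test_that("omega * 2 eta recovers mu squared before rounding", {
  set.seed(42)
  n <- 1000
  homo <- runif(n, -9, -3)
  lumo <- homo + runif(n, 0.1, 6)
  g <- global_indices(data.frame(compound_id = as.character(seq_len(n)),
                                 e_homo_ev = homo, e_lumo_ev = lumo),
                      digits = NULL)
  expect_true(all(abs(g$electrophilicity * 2 * g$hardness -
                        g$chemical_potential^2) < 1e-9))
  # monotonicity: omega increases in |mu| at fixed eta, decreases in eta
  eta <- 2
  mus <- seq(0.5, 5, by = 0.5)
  omega <- mus^2 / (2 * eta)
  expect_true(all(diff(omega) > 0))
  etas <- seq(0.5, 5, by = 0.5)
  omega2 <- 3^2 / (2 * etas)
  expect_true(all(diff(omega2) < 0))
})

test_that("ranking is a deterministic permutation, invariant to row order", {
  fe <- read_frontier_energies(ip_extdata("frontier_energies.tsv"))
  gr <- global_indices(fe)
  r <- rank_library(gr, "gap")
  expect_setequal(r$order, gr$compound_id)
  expect_equal(r$argmin, "4o")
  expect_equal(unname(r$values[1]), 3.3198)
  expect_equal(softest_compound(gr), "4o")
  expect_equal(strongest_electrophile(gr), "4f")
  set.seed(1)
  perm <- gr[sample(nrow(gr)), ]
  expect_equal(rank_library(perm, "gap")$order, r$order)
  expect_equal(rank_library(gr[3, ], "hardness")$order, gr$compound_id[3])
  expect_error(rank_library(gr[0, ], "gap"), "empty")
  expect_error(rank_library(gr, "charisma"), "arg")
})

test_that("unicode minus glyphs in energy tables are normalized", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("compound_id\te_homo_ev\te_lumo_ev",
               "x\t−5.3878\t–1.4150"), tmp)
  fe <- read_frontier_energies(tmp)
  expect_equal(fe$e_homo_ev, -5.3878)
  expect_equal(global_indices(fe)$gap, 3.9728)
})
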