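test_that("Fukui indices follow the charge-difference form exactly", {
  # three-atom set checked by hand arithmetic; every column sums to 1
  cs <- charge_set(atom_label = c("a1", "a2", "a3"),
                   element = c("C", "C", "O"),
                   q_nminus1 = c(0.5, 0.3, 0.2),
                   q_n = c(0.1, -0.1, 0.0),
                   q_nplus1 = c(-0.4, -0.3, -0.3))
  ft <- fukui_indices(cs)
  expect_equal(ft$f_minus, c(0.4, 0.4, 0.2))
  expect_equal(ft$f_plus, c(0.5, 0.2, 0.3))
  expect_equal(ft$f_zero, c(0.45, 0.3, 0.25))
  expect_equal(attr(ft, "provenance"), "computed")

  # diatomic with the added electron localized wholly on atom 1
  cs2 <- charge_set(c("x", "y"), c("N", "C"),
                    q_nminus1 = c(1, 0), q_n = c(0, 0),
                    q_nplus1 = c(-1, 0))
  expect_equal(fukui_indices(cs2)$f_plus, c(1, 0))
})

test_that("charge sets violating the one-electron bookkeeping are rejected", {
  expect_error(
    charge_set(c("a", "b"), c("C", "C"), c(0, 0), c(0, 0), c(0, 0)),
    "N-1 and N"
  )
  expect_error(
    charge_set(c("a", "b"), c("C", "C"), c(0.5, 0.5), c(0, 0), c(0.2, 0)),
    "N and N\\+1"
  )
  expect_error(
    charge_set(c("a", "b"), c("C", "C"), c(1, 0), c(0, 0), c(-1, 0, 0)),
    "length"
  )
  expect_error(
    charge_set(c("a", "a"), c("C", "C"), c(1, 0), c(0, 0), c(-1, 0)),
    "duplicate"
  )
})

test_that("computed tables conserve one electron and average exactly", {
  cfg <- generator_config(seed = 11)
  sets <- generate_charge_sets(cfg, n_atoms = 9, n_sets = 50)
  for (cs in sets) {
    ft <- fukui_indices(cs)
    expect_lt(abs(sum(ft$f_plus) - 1), 1e-6)
    expect_lt(abs(sum(ft$f_minus) - 1), 1e-6)
    expect_lt(abs(sum(ft$f_zero) - 1), 1e-6)
    expect_equal(ft$f_zero, (ft$f_plus + ft$f_minus) / 2)
  }
})

test_that("permuting atom order permutes outputs identically", {
  cfg <- generator_config(seed = 3)
  cs <- generate_charge_sets(cfg, n_atoms = 7)[[1]]
  perm <- sample(7)
  cs2 <- charge_set(cs$atoms$atom_label[perm], cs$atoms$element[perm],
                    cs$q_nminus1[perm], cs$q_n[perm], cs$q_nplus1[perm])
  ft <- fukui_indices(cs); ft2 <- fukui_indices(cs2)
  expect_equal(ft2$f_plus, ft$f_plus[perm])
  expect_equal(top_sites(ft, "plus", 1)$atom_label,
               top_sites(ft2, "plus", 1)$atom_label)
})

test_that("published site table imports verbatim and calls the right sites", {
  ft <- import_fukui_table(ip_extdata("fukui_4o.tsv"))
  expect_equal(nrow(ft), 29L)
  expect_equal(attr(ft, "provenance"), "imported")
  top_plus <- top_sites(ft, "plus", 2)
  expect_equal(top_plus$atom_label, c("O25", "C5"))
  expect_equal(top_plus$value, c(1.4858, 0.5879))
  top_minus <- top_sites(ft, "minus", 1)
  expect_equal(top_minus$atom_label, "C21")
  expect_equal(top_minus$value, 0.7955)
  expect_equal(top_sites(ft, "zero", 1)$atom_label, "C6")
})

test_that("partial imports expose only the columns they carry", {
  rows <- data.frame(atom_label = c("C1", "C2"), f_plus = c(0.4, 0.6))
  ft <- import_fukui_table(rows)
  expect_equal(top_sites(ft, "plus", 1)$atom_label, "C2")
  expect_error(top_sites(ft, "minus", 1), "absent")
  expect_error(import_fukui_table(rows[0, ]), "empty")
  expect_error(
    import_fukui_table(data.frame(atom_label = c("C1", "C1"),
                                  f_plus = c(1, 2))),
    "duplicate"
  )
  expect_error(
    import_fukui_table(data.frame(atom_label = "C1", q = 1)),
    "at least one"
  )
})

test_that("top_sites respects k and rejects bad k", {
  ft <- import_fukui_table(ip_extdata("fukui_4o.tsv"))
  expect_equal(nrow(top_sites(ft, "plus", 0)), 0L)
  expect_equal(nrow(top_sites(ft, "plus", 100)), 29L)
  expect_error(top_sites(ft, "plus", -1), "k must be")
})
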