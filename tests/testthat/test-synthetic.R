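test_that("generation is bit-identical under one seed", {
  cfg <- generator_config(seed = 5)
  expect_identical(generate_library(cfg), generate_library(cfg))
  expect_identical(generate_docking_tables(cfg),
                   generate_docking_tables(cfg))
  expect_identical(generate_admet_tables(cfg), generate_admet_tables(cfg))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_screen(cfg, d1); simulate_screen(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # and a different seed changes the draw
  expect_false(identical(generate_library(cfg)$energies,
                         generate_library(generator_config(seed = 6))$energies))
})

test_that("nitro compounds occupy the low end of the gap range", {
  for (seed in 1:5) {
    lib <- generate_library(generator_config(seed = seed))
    gr <- global_indices(lib$energies, digits = NULL)
    ewg <- lib$compounds$is_ewg
    expect_true(max(gr$gap[ewg]) < min(gr$gap[!ewg]))
    expect_equal(softest_compound(gr), lib$softest_id)
    expect_true(all(gr$gap >= 3.3 - 1e-6 & gr$gap <= 4.1 + 1e-6))
  }
  one <- generate_library(generator_config(seed = 1, n_compounds = 1,
                                           fraction_ewg = 1))
  expect_equal(one$softest_id, one$compounds$id)
})

test_that("generated structures and tables pass input validation cleanly", {
  cfg <- generator_config(seed = 8)
  dir <- withr::local_tempdir()
  simulate_screen(cfg, dir)
  expect_no_warning({
    lib <- read_compounds(file.path(dir, "compounds.tsv"))
    fe <- read_frontier_energies(file.path(dir, "frontier_energies.tsv"))
    cs <- read_charge_set(file.path(dir, "charges.tsv"))
    sc <- read_dock_scores(file.path(dir, "dock_scores.csv"))
    ct <- read_hbond_contacts(file.path(dir, "hbond_contacts.csv"))
    adm <- read_admet(file.path(dir, "admet.csv"))
    tk <- read_topkat(file.path(dir, "topkat.csv"))
  })
  # every generated SMILES parses to descriptors without error
  prof <- physchem_profile(lib, require_logp = FALSE)
  expect_equal(nrow(prof), cfg$n_compounds)
  expect_true(all(prof$tpsa >= 54.60))  # scaffold floor
})

test_that("planted docking extrema are strict and recovered", {
  for (seed in c(2, 13)) {
    cfg <- generator_config(seed = seed)
    dk <- generate_docking_tables(cfg)
    for (tg in cfg$targets) {
      expect_equal(best_ligand(dk$scores, tg)$ligand_id,
                   unname(dk$best_ligand_per_target[[tg]]))
      cmp <- compare_to_reference(dk$scores, tg, "moldock")
      expect_true(cmp$comparison$better[
        cmp$comparison$ligand_id == dk$best_ligand_per_target[[tg]]])
    }
  }
})

test_that("zero spread makes non-planted ligands tie and sort by id", {
  cfg <- generator_config(seed = 4, docking_sd = 0)
  dk <- generate_docking_tables(cfg)
  r <- rank_ligands(dk$scores, cfg$targets[1], "moldock")
  planted <- unname(dk$best_ligand_per_target[[cfg$targets[1]]])
  expect_equal(r$ligand_id[1], planted)
  rest <- r$ligand_id[-1]
  expect_equal(rest, sort(rest))
})

test_that("admet generator respects band and level domains", {
  cfg <- generator_config(seed = 10)
  ad <- generate_admet_tables(cfg)
  expect_true(all(ad$admet$bbb_level %in% 0:4))
  expect_true(all(ad$admet$absorption_level %in% 0:3))
  expect_true(all(ad$admet$log_solubility >= -6 &
                    ad$admet$log_solubility <= 0))
  # planted band counts are recovered by re-banding the probabilities
  for (ep in rownames(ad$band_counts)) {
    bands <- topkat_band(ad$topkat[[ep]])
    expect_equal(as.integer(table(factor(bands,
                                         colnames(ad$band_counts)))),
                 unname(ad$band_counts[ep, ]))
  }
})

test_that("invalid generator configs are rejected", {
  expect_error(generator_config(n_compounds = 0), "n_compounds")
  expect_error(generator_config(fraction_ewg = 1.5), "fraction_ewg")
  expect_error(generator_config(gap_range = c(2, 1)), "gap_range")
  cfg <- generator_config(seed = 1)
  expect_error(generate_charge_sets(cfg, n_atoms = 1), "n_atoms")
  cfg0 <- generator_config(seed = 1, targets = character(0))
  expect_error(generate_docking_tables(cfg0), "no targets")
})
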