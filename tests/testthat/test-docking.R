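fdps <- read_dock_scores(ip_extdata("dock_fdps.csv"))
pde3b <- read_dock_scores(ip_extdata("dock_pde3b.csv"))

test_that("ligand ranking finds the published best binders", {
  b <- best_ligand(fdps, "FDPS", "moldock")
  expect_equal(b$ligand_id, "4k")
  expect_equal(b$value, -145.600)
  b2 <- best_ligand(pde3b, "PDE3B", "moldock")
  expect_equal(b2$ligand_id, "4g")
  expect_equal(b2$value, -130.663)
  # best under moldock equals a direct argmin scan (oracle)
  lib_rows <- fdps[!fdps$is_reference, ]
  expect_equal(b$ligand_id, lib_rows$ligand_id[which.min(lib_rows$moldock)])
  # ranking is a permutation of the library and invariant to row order
  r <- rank_ligands(fdps, "FDPS", "moldock")
  expect_setequal(r$ligand_id, library_ids)
  set.seed(9)
  shuffled <- fdps[sample(nrow(fdps)), ]
  expect_equal(rank_ligands(shuffled, "FDPS", "moldock")$ligand_id,
               r$ligand_id)
  expect_error(rank_ligands(fdps, "FDPS", "vibes"), "unknown ranking key")
  expect_error(rank_ligands(fdps, "XXX", "moldock"), "no docking records")
})

test_that("reference comparison uses strict more-negative-is-better", {
  cmp <- compare_to_reference(fdps, "FDPS", "moldock")
  expect_equal(cmp$reference, "minodronic acid")
  expect_equal(cmp$reference_value, -111.023)
  expect_equal(cmp$n_better, 15L)
  # on the H-bond column the reference drug is not beaten
  hb <- compare_to_reference(fdps, "FDPS", "hbond")
  expect_equal(hb$n_better, 0L)
  # zero or multiple references are structural errors
  expect_error(compare_to_reference(fdps[!fdps$is_reference, ], "FDPS"),
               "reference")
  doubled <- rbind(fdps, fdps[fdps$is_reference, ][1, ])
  doubled$ligand_id[nrow(doubled)] <- "second ref"
  expect_error(compare_to_reference(doubled, "FDPS"), "reference")
  expect_error(compare_to_reference(fdps[fdps$is_reference, ], "FDPS"),
               "no library ligands")
})

test_that("equal scores do not count as better", {
  df <- data.frame(ligand_id = c("a", "ref"), target_id = "T",
                   moldock = c(-10, -10), rerank = -1,
                   interaction_energy = -1, steric = -1, hbond = -1,
                   is_reference = c(FALSE, TRUE))
  expect_equal(compare_to_reference(df, "T", "moldock")$n_better, 0L)
})

test_that("hydrogen-bond reports aggregate contacts per residue", {
  contacts <- read_hbond_contacts(ip_extdata("contacts_fdps.csv"))
  r <- hbond_report(contacts, "4k", "FDPS")
  expect_equal(r$n_contacts, 8L)
  expect_equal(sort(names(hbond_report(contacts, "4b", "FDPS")$residues)),
               c("Arg 60", "Asn 59", "Tyr 58"))
  # sum over the printed contacts tracks the published H-bond score for 4k
  expect_equal(r$total_energy, -12.8601, tolerance = 1e-4)
  expect_equal(r$strongest$bond_energy_kj_mol, -2.49869)
  none <- hbond_report(contacts, "4k", "PDE3B")
  expect_equal(none$n_contacts, 0L)
  expect_null(none$strongest)
  # fixture sanity: printed bond energies lie in [-2.5, 0], lengths > 0
  expect_true(all(contacts$bond_energy_kj_mol >= -2.5 &
                    contacts$bond_energy_kj_mol <= 0))
  expect_true(all(contacts$bond_length_A > 0))
})

test_that("selectivity summary spans targets and validates ligand sets", {
  sel <- selectivity_matrix(rbind(fdps, pde3b))
  expect_equal(sel$best_per_target$FDPS$ligand_id, "4k")
  expect_equal(sel$best_per_target$PDE3B$ligand_id, "4g")
  expect_equal(dim(sel$rank_matrix), c(15L, 2L))
  expect_true(all(apply(sel$rank_matrix, 2, sort) == 1:15))
  expect_equal(unname(sel$best_target_per_ligand[["4g"]]), "PDE3B")
  # a single target degenerates to a plain ranking
  one <- selectivity_matrix(fdps)
  expect_equal(unname(one$rank_matrix[, "FDPS"]),
               rank_ligands(fdps, "FDPS")$rank[
                 match(rownames(one$rank_matrix),
                       rank_ligands(fdps, "FDPS")$ligand_id)])
  ragged <- rbind(fdps, pde3b[pde3b$ligand_id != "4c", ])
  expect_error(selectivity_matrix(ragged), "4c")
})

test_that("score parsing validates schema and aliases column names", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound name,MolDock score,rerank score (kJ/mol),interaction energy (kJ/mol),steric,HBond,is_reference",
               "lig1,−100.5,-90,-110,-95,-3.2,FALSE",
               "ref,-80,-70,-90,-85,-9.9,TRUE"), tmp)
  sc <- read_dock_scores(tmp, target_id = "T")
  expect_equal(sc$moldock, c(-100.5, -80))
  expect_equal(best_ligand(sc, "T")$ligand_id, "lig1")
  writeLines(c("ligand_id,moldock,rerank,interaction_energy,steric,hbond,is_reference",
               "a,-1,-1,-1,-1,-1,FALSE",
               "a,-2,-2,-2,-2,-2,FALSE"), tmp)
  expect_error(read_dock_scores(tmp, target_id = "T"), "duplicate")
})
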