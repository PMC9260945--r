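# Shared fixtures: published reference values and cached computations.

library_ids <- sprintf("4%s", letters[1:15])

# Published physicochemical reference rows for the 15 library compounds:
# MW (g/mol), acceptor count, donor count, TPSA (A^2), imported logP,
# Lipinski violation count.
physchem_expected <- data.frame(
  id = library_ids,
  mw = c(332.40, 366.84, 348.40, 362.42, 411.29, 377.39, 377.39, 346.42,
         425.32, 362.42, 391.42, 362.42, 380.87, 376.45, 391.42),
  n_hba = c(3, 3, 4, 4, 3, 5, 5, 3, 3, 4, 5, 4, 3, 4, 5),
  n_hbd = c(1, 1, 2, 1, 1, 1, 1, 1, 1, 2, 1, 2, 1, 1, 1),
  tpsa = c(54.60, 54.60, 74.83, 63.83, 54.60, 100.42, 100.42, 54.60,
           54.60, 74.83, 100.42, 74.83, 54.60, 63.83, 100.42),
  logp = c(3.56, 4.12, 3.18, 3.59, 4.19, 2.85, 2.84, 3.89, 4.54, 3.49,
           3.20, 3.45, 4.45, 3.91, 3.21),
  nlv = 0L
)

# Published global reactivity columns (eV) recomputable from the two
# frontier energies: gap, hardness, chemical potential, electrophilicity.
reactivity_expected <- data.frame(
  id = library_ids,
  gap = c(3.9728, 4.0273, 3.8912, 3.8096, 4.0001, 3.4014, 3.4286, 3.9184,
          3.9185, 3.8096, 3.3470, 3.9185, 3.9185, 3.8095, 3.3198),
  hardness = c(1.9864, 2.0137, 1.9456, 1.9048, 2.0001, 1.7007, 1.7143,
               1.9592, 1.9593, 1.9048, 1.6735, 1.9593, 1.9593, 1.9048,
               1.6599),
  mu = c(-3.4014, -3.5375, -3.3334, -3.5103, -3.5239, -4.1225, -4.0001,
         -3.3198, -3.4559, -3.2654, -3.9320, -3.2110, -3.4559, -3.2382,
         -4.0273),
  omega = c(2.9122, 3.1072, 2.8556, 3.2345, 3.1043, 4.9965, 4.6669,
            2.8126, 3.0478, 2.7989, 4.6192, 2.6312, 3.0478, 2.7525,
            4.8856)
)

# Structure perception is the slow step; compute the library profile once.
cached_profile <- local({
  prof <- NULL
  function() {
    if (is.null(prof)) prof <<- physchem_profile(ip_library())
    prof
  }
})
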