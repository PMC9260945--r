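# Seeded synthetic inputs with planted ground truths for every pipeline
# stage.
#
# The generator emulates the statistical shape of the real screening
# inputs -- a substituted scaffold library whose electron-withdrawing
# (nitro) members sit at the narrow end of the frontier-orbital gap range,
# one-electron-consistent charge sets, per-target docking tables with one
# reference drug, and banded ADMET/TOPKAT tables -- while planting strict
# extrema (never statistical tendencies) so that recovery tests are
# deterministic. Each generate_* function reseeds from the config, so
# identical configs give bit-identical outputs.

.r1_set <- c("H", "4-CH3")
.r2_set <- c("H", "4-Cl", "2-OH", "4-OH", "4-OMe", "4-Br", "4-NO2",
             "3-NO2")

.aryl_smiles <- c(
  "H" = "c2ccccc2",
  "4-Cl" = "c2ccc(Cl)cc2",
  "2-OH" = "c2ccccc2O",
  "4-OH" = "c2ccc(O)cc2",
  "4-OMe" = "c2ccc(OC)cc2",
  "4-Br" = "c2ccc(Br)cc2",
  "4-NO2" = "c2ccc([N+](=O)[O-])cc2",
  "3-NO2" = "c2cccc([N+](=O)[O-])c2"
)

# SMILES for one scaffold instance of the library grammar.
scaffold_smiles <- function(r1, r2) {
  pyr <- if (r1 == "4-CH3") "nc2ccc(C)cn12" else "nc2ccccn12"
  paste0("OC1=C(C(=O)CC(C)(C)C1)c1c(-", .aryl_smiles[[r2]], ")", pyr)
}

#' Configuration for the synthetic-data generator
#'
#' @param seed Integer seed; all generators derive their streams from it.
#' @param n_compounds Library size (default 15).
#' @param fraction_ewg Fraction of nitro-substituted (electron-withdrawing)
#'   compounds (default 4/15, the library's own proportion).
#' @param gap_range HOMO-LUMO gap range in eV (default `c(3.3, 4.1)`,
#'   the span observed across the library).
#' @param docking_mean,docking_sd Normal parameters for docking score
#'   columns (default -120 and 10, the scale of the real score tables).
#' @param targets Target ids (default the four screening targets).
#' @param planted Optional list overriding the planted ground truths:
#'   `softest_id`, `best_ligand_per_target` (named character),
#'   `fukui_hotspot_atom` (index).
#' @return List of class `ip_generator_config`.
#' @export
generator_config <- function(seed = 1L, n_compounds = 15L,
                             fraction_ewg = 4 / 15,
                             gap_range = c(3.3, 4.1),
                             docking_mean = -120, docking_sd = 10,
                             targets = c("FDPS", "PDE3B", "CXCR4",
                                         "GABAa"),
                             planted = list()) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (n_compounds < 1L) stop("n_compounds must be >= 1")
  if (fraction_ewg < 0 || fraction_ewg > 1) {
    stop("fraction_ewg must be in [0, 1]")
  }
  stopifnot(length(gap_range) == 2L, gap_range[1] > 0,
            gap_range[2] > gap_range[1])
  if (docking_sd < 0) stop("docking_sd must be >= 0")
  cfg <- list(seed = as.integer(seed), n_compounds = as.integer(n_compounds),
              fraction_ewg = fraction_ewg, gap_range = gap_range,
              docking_mean = docking_mean, docking_sd = docking_sd,
              targets = targets, planted = planted)
  class(cfg) <- "ip_generator_config"
  cfg
}

#' Generate a synthetic compound library with frontier energies
#'
#' Builds `n_compounds` scaffold SMILES from the substituent grammar, with
#' `round(fraction_ewg * n)` nitro-substituted members. Gaps are drawn
#' uniformly in `gap_range`; the nitro compounds occupy the smallest gaps
#' (electron-withdrawing groups narrow the gap) and the planted softest
#' compound receives the strict minimum. HOMO energies are drawn uniformly
#' in [-6, -5] eV and LUMO = HOMO + gap.
#'
#' @param cfg An [generator_config()].
#' @return List: `compounds` (id, r1, r2, smiles, is_ewg), `energies`
#'   (compound_id, e_homo_ev, e_lumo_ev), `softest_id`.
#' @export
generate_library <- function(cfg) {
  stopifnot(inherits(cfg, "ip_generator_config"))
  set.seed(cfg$seed + 101L)
  n <- cfg$n_compounds
  ids <- sprintf("c%02d", seq_len(n))
  n_ewg <- round(cfg$fraction_ewg * n)
  nitro_r2 <- rep(c("3-NO2", "4-NO2"), length.out = n_ewg)
  plain_r2 <- rep(setdiff(.r2_set, c("3-NO2", "4-NO2")),
                  length.out = n - n_ewg)
  r2 <- c(nitro_r2, plain_r2)
  r1 <- rep(.r1_set, length.out = n)
  is_ewg <- seq_len(n) <= n_ewg
  smiles <- mapply(scaffold_smiles, r1, r2, USE.NAMES = FALSE)

  gaps <- sort(stats::runif(n, cfg$gap_range[1], cfg$gap_range[2]))
  if (n > 1L && gaps[1] >= gaps[2]) {
    gaps[1] <- gaps[2] - 1e-6  # enforce a strict minimum
  }
  softest <- cfg$planted$softest_id %||% ids[1L]
  if (!softest %in% ids) stop("planted softest_id not in library")
  # smallest gaps go to the nitro block; the planted softest gets gaps[1]
  ord <- c(setdiff(which(is_ewg), match(softest, ids)),
           which(!is_ewg))
  gap_by_compound <- numeric(n)
  gap_by_compound[match(softest, ids)] <- gaps[1L]
  if (!is_ewg[match(softest, ids)] && n_ewg > 0L) {
    stop("planted softest_id must be a nitro compound")
  }
  gap_by_compound[ord] <- gaps[-1L][seq_along(ord)]
  e_homo <- stats::runif(n, -6, -5)
  list(
    compounds = data.frame(id = ids, r1 = r1, r2 = r2, smiles = smiles,
                           is_ewg = is_ewg, stringsAsFactors = FALSE),
    energies = data.frame(compound_id = ids, e_homo_ev = e_homo,
                          e_lumo_ev = e_homo + gap_by_compound,
                          stringsAsFactors = FALSE),
    softest_id = softest
  )
}

#' Generate charge sets with exact one-electron conservation
#'
#' For each set, per-atom shares of the two one-electron transitions are
#' drawn Dirichlet-style (normalized unit-rate gamma deviates), so each
#' Fukui index column sums to exactly 1 by construction. The planted
#' hotspot atom's nucleophilic-attack share is boosted above 0.5, making
#' it the strict `f_plus` maximum.
#'
#' @param cfg An [generator_config()].
#' @param n_atoms Number of atoms per set (>= 2).
#' @param n_sets Number of charge sets to generate.
#' @return List of [charge_set()] objects; each carries the planted
#'   hotspot index as attribute `"hotspot"`.
#' @export
generate_charge_sets <- function(cfg, n_atoms, n_sets = 1L) {
  stopifnot(inherits(cfg, "ip_generator_config"))
  if (n_atoms < 2L) stop("n_atoms must be >= 2")
  set.seed(cfg$seed + 202L)
  hotspot <- cfg$planted$fukui_hotspot_atom %||% 1L
  if (hotspot < 1L || hotspot > n_atoms) stop("hotspot atom out of range")
  elements <- c("C", "N", "O")
  lapply(seq_len(n_sets), function(i) {
    dirichlet <- function(m) {
      g <- stats::rgamma(m, shape = 1)
      g / sum(g)
    }
    share_plus <- dirichlet(n_atoms)
    boost <- 0.5 + 0.4 * stats::runif(1)
    share_plus <- share_plus / sum(share_plus) * (1 - boost)
    share_plus[hotspot] <- share_plus[hotspot] + boost
    share_plus <- share_plus / sum(share_plus)  # exact renormalization
    share_minus <- dirichlet(n_atoms)
    q_n <- stats::rnorm(n_atoms, 0, 0.2)
    cs <- charge_set(
      atom_label = paste0("A", seq_len(n_atoms)),
      element = sample(elements, n_atoms, replace = TRUE),
      q_nminus1 = q_n + share_minus,
      q_n = q_n,
      q_nplus1 = q_n - share_plus,
      compound_id = sprintf("synthetic_%03d", i),
      scheme = "synthetic"
    )
    attr(cs, "hotspot") <- hotspot
    cs
  })
}

#' Generate docking score and contact tables with a planted best ligand
#'
#' Per target, every metric column is drawn Normal(`docking_mean`,
#' `docking_sd`) truncated to negative values; the planted best ligand is
#' then forced to the strict minimum of every column, and one reference
#' ligand is placed at the library median. Contacts are drawn with bond
#' energies in [-2.5, 0] kJ/mol and lengths in [2.0, 3.6] Angstrom.
#'
#' @param cfg An [generator_config()].
#' @return List: `scores` (all targets stacked, schema of
#'   [read_dock_scores()]), `contacts`, `best_ligand_per_target` (named
#'   character vector of planted ids).
#' @export
generate_docking_tables <- function(cfg) {
  stopifnot(inherits(cfg, "ip_generator_config"))
  if (!length(cfg$targets)) stop("no targets configured")
  set.seed(cfg$seed + 303L)
  n <- cfg$n_compounds
  ids <- sprintf("c%02d", seq_len(n))
  planted <- cfg$planted$best_ligand_per_target %||%
    stats::setNames(ids[((seq_along(cfg$targets) - 1L) %% n) + 1L],
                    cfg$targets)
  if (!all(cfg$targets %in% names(planted))) {
    stop("planted best ligands must cover every target")
  }
  rneg <- function(m) {
    x <- stats::rnorm(m, cfg$docking_mean, cfg$docking_sd)
    pmin(x, -1e-3)  # truncate at zero from below
  }
  res_pool <- c("Tyr", "Asn", "Arg", "Thr", "Glu", "Ser", "His", "Leu")
  scores_l <- list(); contacts_l <- list()
  for (tg in cfg$targets) {
    sc <- data.frame(ligand_id = ids, target_id = tg,
                     moldock = rneg(n), rerank = rneg(n),
                     interaction_energy = rneg(n), steric = rneg(n),
                     hbond = stats::runif(n, -15, 0),
                     is_reference = FALSE, stringsAsFactors = FALSE)
    bi <- match(planted[[tg]], ids)
    for (m in c("moldock", "rerank", "interaction_energy", "steric")) {
      sc[[m]][bi] <- min(sc[[m]]) - stats::runif(1, 1, 5)
    }
    ref <- data.frame(ligand_id = paste0("ref_", tg), target_id = tg,
                      moldock = stats::median(sc$moldock),
                      rerank = stats::median(sc$rerank),
                      interaction_energy = stats::median(sc$interaction_energy),
                      steric = stats::median(sc$steric),
                      hbond = stats::runif(1, -20, -10),
                      is_reference = TRUE, stringsAsFactors = FALSE)
    scores_l[[tg]] <- rbind(sc, ref)
    nc <- sample(1:8, n, replace = TRUE)
    contacts_l[[tg]] <- data.frame(
      ligand_id = rep(ids, nc),
      target_id = tg,
      residue = paste0(sample(res_pool, sum(nc), replace = TRUE), " ",
                       sample(40:300, sum(nc), replace = TRUE), " (N)"),
      ligand_atom = paste0("O (", sample(10:30, sum(nc), replace = TRUE),
                           ")"),
      bond_energy_kj_mol = stats::runif(sum(nc), -2.5, 0),
      bond_length_A = stats::runif(sum(nc), 2.0, 3.6),
      stringsAsFactors = FALSE
    )
  }
  list(scores = do.call(rbind, c(scores_l, list(make.row.names = FALSE))),
       contacts = do.call(rbind, c(contacts_l,
                                   list(make.row.names = FALSE))),
       best_ligand_per_target = planted)
}

#' Generate ADMET and TOPKAT tables with known band counts
#'
#' Levels are sampled within their enumerated ranges, log-solubility within
#' [-6, 0], and each TOPKAT probability is drawn by first choosing a band
#' (nontoxic / intermediate / toxic with weights 0.7 / 0.15 / 0.15) and
#' then a value inside it, so the true band counts are known.
#'
#' @param cfg An [generator_config()].
#' @return List: `admet` (schema of [read_admet()]), `topkat` (schema of
#'   [read_topkat()], bare numerics), `band_counts` (endpoint x band
#'   matrix of planted counts).
#' @export
generate_admet_tables <- function(cfg) {
  stopifnot(inherits(cfg, "ip_generator_config"))
  set.seed(cfg$seed + 404L)
  n <- cfg$n_compounds
  ids <- sprintf("c%02d", seq_len(n))
  admet <- data.frame(
    compound_id = ids,
    bbb_level = sample(0:4, n, replace = TRUE),
    absorption_level = sample(0:3, n, replace = TRUE,
                              prob = c(0.7, 0.15, 0.1, 0.05)),
    hepatotoxicity = stats::rbinom(n, 1, 0.1),
    cyp2d6 = stats::rbinom(n, 1, 0.2),
    ppb = sample(c("true", "false"), n, replace = TRUE,
                 prob = c(0.85, 0.15)),
    log_solubility = stats::runif(n, -6, 0),
    alogp98 = stats::rnorm(n, 4, 0.8),
    psa_2d = stats::runif(n, 35, 160),
    stringsAsFactors = FALSE
  )
  endpoints <- c("rat_male_ntp", "mouse_male_ntp", "ames_mutagenicity",
                 "skin_irritation", "aerobic_biodegradability")
  bands <- c("nontoxic", "intermediate", "toxic")
  topkat <- data.frame(compound_id = ids, stringsAsFactors = FALSE)
  band_counts <- matrix(0L, nrow = length(endpoints), ncol = 3L,
                        dimnames = list(endpoints, bands))
  for (ep in endpoints) {
    b <- sample(bands, n, replace = TRUE, prob = c(0.7, 0.15, 0.15))
    lo <- c(nontoxic = 0, intermediate = 0.30, toxic = 0.70)[b]
    hi <- c(nontoxic = 0.2999, intermediate = 0.6999, toxic = 1)[b]
    topkat[[ep]] <- stats::runif(n, lo, hi)
    band_counts[ep, ] <- as.integer(table(factor(b, levels = bands)))
  }
  list(admet = admet, topkat = topkat, band_counts = band_counts)
}

#' Write a full synthetic fixture directory
#'
#' Runs all generators and writes the TSV/CSV files in the schemas the
#' other modules read, plus a `manifest.json` recording every planted
#' ground truth (softest compound, best ligand per target, Fukui hotspot,
#' TOPKAT band counts).
#'
#' @param cfg An [generator_config()].
#' @param dir Output directory (created if needed).
#' @param n_atoms Atoms per synthetic charge set.
#' @return Path of the manifest file, invisibly.
#' @export
simulate_screen <- function(cfg, dir, n_atoms = 12L) {
  stopifnot(inherits(cfg, "ip_generator_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lib <- generate_library(cfg)
  cs <- generate_charge_sets(cfg, n_atoms)[[1]]
  dock <- generate_docking_tables(cfg)
  adm <- generate_admet_tables(cfg)

  wt <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  lib$compounds$logp <- round(stats::runif(nrow(lib$compounds), 1, 5), 2)
  wt(lib$compounds, "compounds.tsv")
  wt(lib$energies, "frontier_energies.tsv")
  wt(data.frame(atom_label = cs$atoms$atom_label,
                element = cs$atoms$element,
                q_nminus1 = cs$q_nminus1, q_n = cs$q_n,
                q_nplus1 = cs$q_nplus1), "charges.tsv")
  utils::write.csv(dock$scores, file.path(dir, "dock_scores.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(dock$contacts, file.path(dir, "hbond_contacts.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(adm$admet, file.path(dir, "admet.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(adm$topkat, file.path(dir, "topkat.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(
    seed = cfg$seed,
    n_compounds = cfg$n_compounds,
    softest_id = lib$softest_id,
    fukui_hotspot_atom = attr(cs, "hotspot"),
    best_ligand_per_target = as.list(dock$best_ligand_per_target),
    topkat_band_counts = apply(adm$band_counts, 1L, as.list)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
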