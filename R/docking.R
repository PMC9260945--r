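# Docking-score ranking, reference comparison, hydrogen-bond contact
# reports and cross-target selectivity summaries.
#
# Docking scores are consumed as data (MolDock, rerank, protein-ligand
# interaction, steric and H-bond columns from a virtual docker); this
# module never rescores. Throughout, more negative means better.

.dock_metrics <- c("moldock", "rerank", "interaction_energy", "steric",
                   "hbond")

# Column-name aliases accepted at parse time (lowercased, punctuation
# stripped) -> canonical name.
.dock_aliases <- c(
  "moldock" = "moldock", "moldockscore" = "moldock",
  "rerank" = "rerank", "rerankscore" = "rerank", "rerankscorekjmol" = "rerank",
  "interactionenergy" = "interaction_energy",
  "interaction" = "interaction_energy",
  "proteinligandinteraction" = "interaction_energy",
  "interactionenergykjmol" = "interaction_energy",
  "steric" = "steric", "stericscore" = "steric",
  "hbond" = "hbond", "hbondscore" = "hbond", "hbondkjmol" = "hbond",
  "ligandid" = "ligand_id", "compound" = "ligand_id",
  "compoundname" = "ligand_id",
  "targetid" = "target_id", "target" = "target_id",
  "isreference" = "is_reference", "reference" = "is_reference"
)

canonical_dock_names <- function(nms) {
  key <- gsub("[^a-z0-9]", "", tolower(nms))
  hit <- .dock_aliases[key]
  ifelse(is.na(hit), nms, hit)
}

#' Read a docking score table
#'
#' CSV with columns `ligand_id`, `moldock`, `rerank`,
#' `interaction_energy`, `steric`, `hbond`, `is_reference` and (optionally,
#' or supplied via `target_id`) `target_id`. Common column aliases
#' ("MolDock score", "HBond", ...) and Unicode minus glyphs are accepted.
#'
#' @param path Path to a CSV score table.
#' @param target_id Target id to attach if the file has no such column.
#' @return Data frame with one row per (ligand, target).
#' @export
read_dock_scores <- function(path, target_id = NULL) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        check.names = FALSE)
  names(df) <- canonical_dock_names(names(df))
  if (!"target_id" %in% names(df)) {
    if (is.null(target_id)) stop("no target_id column and none supplied")
    df$target_id <- target_id
  }
  need <- c("ligand_id", .dock_metrics, "is_reference")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (m in .dock_metrics) df[[m]] <- parse_numeric(df[[m]])
  df$is_reference <- as.logical(df$is_reference)
  key <- paste(df$ligand_id, df$target_id)
  if (anyDuplicated(key)) {
    stop("duplicate (ligand, target) record(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  df
}

dock_subset <- function(scores, target_id) {
  stopifnot(is.data.frame(scores))
  sub <- scores[scores$target_id == target_id, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no docking records for target ", target_id)
  sub
}

#' Rank ligands for one target
#'
#' Sorts the non-reference ligands ascending on the chosen metric (most
#' negative first, i.e. best first), ties broken by ligand id.
#'
#' @param scores Docking score data frame (see [read_dock_scores()]).
#' @param target_id Target to rank.
#' @param key One of `"moldock"`, `"rerank"`, `"interaction_energy"`,
#'   `"steric"`, `"hbond"`.
#' @return Data frame with `rank`, `ligand_id`, `value`.
#' @export
rank_ligands <- function(scores, target_id, key = "moldock") {
  if (!key %in% .dock_metrics) {
    stop("unknown ranking key '", key, "'; use one of: ",
         paste(.dock_metrics, collapse = ", "))
  }
  sub <- dock_subset(scores, target_id)
  sub <- sub[!sub$is_reference, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no non-reference ligands for target ", target_id)
  ord <- order(sub[[key]], sub$ligand_id)
  data.frame(rank = seq_len(nrow(sub)),
             ligand_id = sub$ligand_id[ord],
             value = sub[[key]][ord],
             stringsAsFactors = FALSE)
}

#' Best (most negative) library ligand for a target
#'
#' @inheritParams rank_ligands
#' @return One-row data frame: `ligand_id`, `value`.
#' @export
best_ligand <- function(scores, target_id, key = "moldock") {
  r <- rank_ligands(scores, target_id, key)
  r[1L, c("ligand_id", "value")]
}

#' Compare library ligands against the target's reference drug
#'
#' A ligand is "better" iff its metric is strictly more negative than the
#' reference drug's value; equality counts as not better.
#'
#' @inheritParams rank_ligands
#' @param metric Metric to compare on (same choices as `key` in
#'   [rank_ligands()]).
#' @return List: `reference` (id), `reference_value`, `comparison` (data
#'   frame with `ligand_id`, `value`, `better`), `n_better`.
#' @export
compare_to_reference <- function(scores, target_id, metric = "moldock") {
  if (!metric %in% .dock_metrics) stop("unknown metric '", metric, "'")
  sub <- dock_subset(scores, target_id)
  ref <- sub[sub$is_reference, , drop = FALSE]
  if (nrow(ref) != 1L) {
    stop("target ", target_id, " has ", nrow(ref),
         " reference records; exactly one is required")
  }
  lig <- sub[!sub$is_reference, , drop = FALSE]
  if (nrow(lig) == 0L) stop("no library ligands for target ", target_id)
  cmp <- data.frame(ligand_id = lig$ligand_id,
                    value = lig[[metric]],
                    better = lig[[metric]] < ref[[metric]],
                    stringsAsFactors = FALSE)
  cmp <- cmp[order(cmp$ligand_id), , drop = FALSE]
  rownames(cmp) <- NULL
  list(target_id = target_id, metric = metric,
       reference = ref$ligand_id, reference_value = ref[[metric]],
       comparison = cmp, n_better = sum(cmp$better))
}

#' Read a hydrogen-bond contact table
#'
#' CSV with columns `ligand_id`, `target_id`, `residue` (e.g.
#' `"Ser 205 (O)"`), `ligand_atom`, `bond_energy_kj_mol`,
#' `bond_length_A`. Bond energies above zero or lengths outside a
#' physically plausible range raise a validation warning (not an error).
#'
#' @param path Path to the CSV.
#' @return Data frame of contacts with parsed `residue_name`,
#'   `residue_number`.
#' @export
read_hbond_contacts <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        check.names = FALSE)
  need <- c("ligand_id", "target_id", "residue", "ligand_atom",
            "bond_energy_kj_mol", "bond_length_A")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df$bond_energy_kj_mol <- parse_numeric(df$bond_energy_kj_mol)
  df$bond_length_A <- parse_numeric(df$bond_length_A)
  if (any(df$bond_energy_kj_mol > 0) || any(df$bond_length_A <= 0)) {
    warning("contacts with positive bond energy or non-positive length")
  }
  if (any(df$bond_energy_kj_mol < -2.5)) {
    warning("contact bond energies below -2.5 kJ/mol (outside the usual ",
            "docker cap)")
  }
  # residue identity = (name, number); the atom in parentheses is ignored
  # for per-residue aggregation
  m <- regmatches(df$residue,
                  regexec("^\\s*([A-Za-z]+)\\s*([0-9]+)", df$residue))
  df$residue_name <- vapply(m, function(x) if (length(x) >= 2) x[2] else NA_character_, "")
  df$residue_number <- vapply(m, function(x) if (length(x) >= 3) as.integer(x[3]) else NA_integer_, 1L)
  if (anyNA(df$residue_name)) stop("unparseable residue field(s)")
  df
}

#' Hydrogen-bond contact report for one (ligand, target) pair
#'
#' @param contacts Contact data frame from [read_hbond_contacts()].
#' @param ligand_id,target_id Pair to report on (an empty pair is allowed
#'   and yields zero counts).
#' @return List: `n_contacts`, `residues` (per-residue contact counts),
#'   `strongest` (contact row with the most negative energy, or `NULL`),
#'   `total_energy` (sum of bond energies; reported alongside, and not to
#'   be equated with, a docker's H-bond score column).
#' @export
hbond_report <- function(contacts, ligand_id, target_id) {
  sub <- contacts[contacts$ligand_id == ligand_id &
                    contacts$target_id == target_id, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(list(ligand_id = ligand_id, target_id = target_id,
                n_contacts = 0L, residues = integer(0), strongest = NULL,
                total_energy = 0))
  }
  res_key <- paste(sub$residue_name, sub$residue_number)
  res_counts <- table(res_key)
  counts <- stats::setNames(as.integer(res_counts), names(res_counts))
  i <- which.min(sub$bond_energy_kj_mol)
  list(ligand_id = ligand_id, target_id = target_id,
       n_contacts = nrow(sub),
       residues = counts,
       strongest = sub[i, c("residue", "ligand_atom", "bond_energy_kj_mol",
                            "bond_length_A")],
       total_energy = sum(sub$bond_energy_kj_mol))
}

#' Cross-target selectivity summary
#'
#' For a score table covering several targets (each with exactly one
#' reference drug and a common library ligand set): the per-target MolDock
#' rank of every ligand, the best library ligand per target with its full
#' metric row, per-ligand reference comparisons, and each ligand's best
#' target (smallest rank; ties keep target order).
#'
#' @param scores Docking score data frame covering all targets.
#' @return List of class `ip_selectivity`: `targets`, `ligands`,
#'   `rank_matrix` (ligand x target), `best_per_target`,
#'   `best_target_per_ligand`, `reference_comparison`.
#' @export
selectivity_matrix <- function(scores) {
  stopifnot(is.data.frame(scores))
  targets <- unique(scores$target_id)
  if (!length(targets)) stop("no targets in score table")
  lig_sets <- lapply(targets, function(tg) {
    sort(scores$ligand_id[scores$target_id == tg & !scores$is_reference])
  })
  all_ligs <- sort(unique(unlist(lig_sets)))
  for (i in seq_along(targets)) {
    missing <- setdiff(all_ligs, lig_sets[[i]])
    if (length(missing)) {
      stop("ragged ligand sets: target ", targets[i], " is missing ",
           paste(missing, collapse = ", "))
    }
  }
  rank_matrix <- matrix(NA_integer_, nrow = length(all_ligs),
                        ncol = length(targets),
                        dimnames = list(all_ligs, targets))
  best_per_target <- vector("list", length(targets))
  names(best_per_target) <- targets
  ref_cmp <- vector("list", length(targets))
  names(ref_cmp) <- targets
  for (tg in targets) {
    r <- rank_ligands(scores, tg, "moldock")
    rank_matrix[r$ligand_id, tg] <- r$rank
    sub <- dock_subset(scores, tg)
    best_row <- sub[!sub$is_reference & sub$ligand_id == r$ligand_id[1L], ,
                    drop = FALSE]
    best_per_target[[tg]] <- best_row[, c("ligand_id", .dock_metrics)]
    ref_cmp[[tg]] <- compare_to_reference(scores, tg, "moldock")
  }
  best_target <- apply(rank_matrix, 1L, function(rr) targets[which.min(rr)])
  out <- list(targets = targets, ligands = all_ligs,
              rank_matrix = rank_matrix,
              best_per_target = best_per_target,
              best_target_per_ligand = best_target,
              reference_comparison = ref_cmp)
  class(out) <- "ip_selectivity"
  out
}

#' @export
print.ip_selectivity <- function(x, ...) {
  cat("selectivity summary over", length(x$targets), "target(s) and",
      length(x$ligands), "ligands\n")
  for (tg in x$targets) {
    b <- x$best_per_target[[tg]]
    cat(sprintf("  %s: best %s (MolDock %.3f), %d/%d beat %s\n",
                tg, b$ligand_id, b$moldock,
                x$reference_comparison[[tg]]$n_better, length(x$ligands),
                x$reference_comparison[[tg]]$reference))
  }
  invisible(x)
}

#' Write the selectivity rank matrix as TSV
#'
#' @param sel An `ip_selectivity` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rank_matrix <- function(sel, path) {
  df <- data.frame(ligand_id = rownames(sel$rank_matrix),
                   sel$rank_matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
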