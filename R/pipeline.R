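# End-to-end orchestration: run enabled stages from a flat config and emit
# a consolidated screening report (JSON + markdown).

#' Pipeline run configuration
#'
#' One flat document of input paths and options. Referenced files are
#' checked for existence for every enabled stage before any computation
#' starts, so a bad path fails fast.
#'
#' @param compounds Path to a compound TSV (id, smiles, logp; see
#'   [read_compounds()]). Needed by stage `"descriptors"`.
#' @param frontier_energies Path to a frontier-energy TSV. Stage
#'   `"reactivity"`.
#' @param charges Path to a per-atom charge TSV ([read_charge_set()]), or
#'   `NULL`. Stage `"fukui"` (computed route).
#' @param fukui_table Path to a published Fukui-index TSV, or `NULL`.
#'   Stage `"fukui"` (import route; used when `charges` is `NULL`).
#' @param dock_scores Character vector of docking score CSV paths (each
#'   with a `target_id` column or one target per file). Stage `"docking"`.
#' @param hbond_contacts Path to a contact CSV, or `NULL`.
#' @param admet Path to an ADMET CSV. Stage `"admet"`.
#' @param topkat Path to a TOPKAT CSV, or `NULL`.
#' @param stages Stages to run, subset of `c("descriptors", "reactivity",
#'   "fukui", "docking", "admet")`.
#' @param digits Report rounding for reactivity indices (default 4).
#' @param raw If `TRUE`, keep full-precision values (no report rounding).
#' @return List of class `ip_run_config`.
#' @export
run_config <- function(compounds = NULL, frontier_energies = NULL,
                       charges = NULL, fukui_table = NULL,
                       dock_scores = NULL, hbond_contacts = NULL,
                       admet = NULL, topkat = NULL,
                       stages = c("descriptors", "reactivity", "fukui",
                                  "docking", "admet"),
                       digits = 4, raw = FALSE) {
  all_stages <- c("descriptors", "reactivity", "fukui", "docking", "admet")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg <- list(compounds = compounds, frontier_energies = frontier_energies,
              charges = charges, fukui_table = fukui_table,
              dock_scores = dock_scores, hbond_contacts = hbond_contacts,
              admet = admet, topkat = topkat, stages = stages,
              digits = digits, raw = raw)
  needed <- list(
    descriptors = "compounds",
    reactivity = "frontier_energies",
    fukui = if (is.null(charges) && is.null(fukui_table)) "charges"
            else if (!is.null(charges)) "charges" else "fukui_table",
    docking = "dock_scores",
    admet = "admet"
  )
  for (st in stages) {
    for (field in needed[[st]]) {
      paths <- cfg[[field]]
      if (is.null(paths)) {
        stop("stage '", st, "' is enabled but config field '", field,
             "' is not set")
      }
      missing <- paths[!file.exists(paths)]
      if (length(missing)) {
        stop("stage '", st, "' input file(s) not found: ",
             paste(missing, collapse = ", "))
      }
    }
  }
  for (field in c("hbond_contacts", "topkat")) {
    if (!is.null(cfg[[field]]) && !file.exists(cfg[[field]])) {
      stop("config file not found: ", cfg[[field]])
    }
  }
  class(cfg) <- "ip_run_config"
  cfg
}

#' Run the screening pipeline
#'
#' Executes the enabled stages in dependency order and assembles a
#' consolidated report: per-compound physicochemical profiles with
#' Lipinski verdicts, global reactivity indices with softest-compound and
#' strongest-electrophile calls, Fukui site calls, per-target docking
#' ranks with reference comparisons, and ADMET/TOPKAT verdicts. Re-running
#' on identical inputs yields an identical report.
#'
#' @param cfg An [run_config()].
#' @return List of class `ip_screening_report`; sections are exactly the
#'   enabled stages, plus `summary`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "ip_run_config"))
  digits <- if (isTRUE(cfg$raw)) NULL else cfg$digits
  report <- list(sections = character(0))
  summary <- list()

  if ("descriptors" %in% cfg$stages) {
    lib <- read_compounds(cfg$compounds)
    prof <- physchem_profile(lib)
    report$descriptors <- as.data.frame(prof)
    summary$n_compounds <- nrow(prof)
    summary$n_lipinski_failures <- sum(!prof$lipinski_pass)
    report$sections <- c(report$sections, "descriptors")
  }
  if ("reactivity" %in% cfg$stages) {
    fe <- read_frontier_energies(cfg$frontier_energies)
    gr <- global_indices(fe, digits = digits)
    report$reactivity <- as.data.frame(gr)
    summary$softest_compound <- softest_compound(gr)
    summary$strongest_electrophile <- strongest_electrophile(gr)
    report$sections <- c(report$sections, "reactivity")
  }
  if ("fukui" %in% cfg$stages) {
    ft <- if (!is.null(cfg$charges)) {
      fukui_indices(read_charge_set(cfg$charges))
    } else {
      import_fukui_table(cfg$fukui_table)
    }
    kinds <- c("plus", "minus", "zero")
    kinds <- kinds[paste0("f_", kinds) %in% names(ft)]
    report$fukui <- list(
      provenance = attr(ft, "provenance"),
      n_atoms = nrow(ft),
      top_sites = stats::setNames(
        lapply(kinds, function(kk) top_sites(ft, kk, k = 3L)), kinds)
    )
    if ("plus" %in% kinds) {
      summary$top_nucleophilic_attack_site <-
        report$fukui$top_sites$plus$atom_label[1L]
    }
    report$sections <- c(report$sections, "fukui")
  }
  if ("docking" %in% cfg$stages) {
    scores <- do.call(rbind, lapply(cfg$dock_scores, read_dock_scores))
    sel <- selectivity_matrix(scores)
    dock <- list(
      targets = sel$targets,
      rank_matrix = data.frame(ligand_id = rownames(sel$rank_matrix),
                               sel$rank_matrix, check.names = FALSE),
      best_per_target = sel$best_per_target,
      best_target_per_ligand = as.list(sel$best_target_per_ligand),
      n_better_than_reference = lapply(sel$reference_comparison,
                                       function(x) x$n_better)
    )
    if (!is.null(cfg$hbond_contacts)) {
      contacts <- read_hbond_contacts(cfg$hbond_contacts)
      dock$hbond <- lapply(sel$targets, function(tg) {
        b <- sel$best_per_target[[tg]]$ligand_id
        r <- hbond_report(contacts, b, tg)
        list(ligand_id = b, n_contacts = r$n_contacts,
             total_energy = r$total_energy)
      })
      names(dock$hbond) <- sel$targets
    }
    report$docking <- dock
    summary$best_ligand_per_target <-
      lapply(sel$best_per_target, function(b) b$ligand_id)
    report$sections <- c(report$sections, "docking")
  }
  if ("admet" %in% cfg$stages) {
    admet <- read_admet(cfg$admet)
    tox <- if (!is.null(cfg$topkat)) read_topkat(cfg$topkat) else NULL
    lip <- if (!is.null(report$descriptors)) report$descriptors else NULL
    # report on the ids every supplied table covers (ADMET tables may
    # carry standard drugs beyond the profiled library)
    ids <- if (!is.null(lip)) lip$id
           else if (!is.null(tox)) intersect(admet$compound_id,
                                             tox$compound_id)
           else admet$compound_id
    dl <- druglikeness_report(admet, tox, lip, ids = ids)
    report$admet <- list(per_compound = dl$per_compound,
                         summary = dl$summary)
    summary$n_bbb_undefined <-
      unname(dl$summary$n_per_bbb_level[["level_4"]])
    summary$cyp2d6_inhibitors <- dl$summary$cyp2d6_inhibitors
    report$sections <- c(report$sections, "admet")
  }
  report$summary <- summary
  class(report) <- "ip_screening_report"
  report
}

#' @export
print.ip_screening_report <- function(x, ...) {
  cat("screening report; sections:",
      paste(x$sections, collapse = ", "), "\n")
  s <- x$summary
  if (!is.null(s$softest_compound)) {
    cat("  softest compound:", s$softest_compound,
        " strongest electrophile:", s$strongest_electrophile, "\n")
  }
  if (!is.null(s$best_ligand_per_target)) {
    cat("  best ligand per target:",
        paste(names(s$best_ligand_per_target),
              unlist(s$best_ligand_per_target), sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a screening report
#'
#' Writes `report.json` (stable section order, fixed rounding -- identical
#' inputs give byte-identical output) and a human-readable `report.md`.
#'
#' @param report An `ip_screening_report`.
#' @param dir Output directory (created if needed).
#' @return The JSON path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ip_screening_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  md <- c("# Screening report", "")
  s <- report$summary
  if (!is.null(s$n_compounds)) {
    md <- c(md, paste0("- compounds profiled: ", s$n_compounds,
                       " (Lipinski failures: ", s$n_lipinski_failures, ")"))
  }
  if (!is.null(s$softest_compound)) {
    md <- c(md, paste0("- softest compound (smallest gap): ",
                       s$softest_compound),
            paste0("- strongest electrophile: ", s$strongest_electrophile))
  }
  if (!is.null(s$top_nucleophilic_attack_site)) {
    md <- c(md, paste0("- top nucleophilic-attack site: ",
                       s$top_nucleophilic_attack_site))
  }
  if (!is.null(s$best_ligand_per_target)) {
    md <- c(md, paste0("- best ligand per target: ",
                       paste(names(s$best_ligand_per_target),
                             unlist(s$best_ligand_per_target),
                             sep = " = ", collapse = ", ")))
  }
  if (!is.null(s$n_bbb_undefined)) {
    md <- c(md, paste0("- compounds at undefined BBB level: ",
                       s$n_bbb_undefined),
            paste0("- CYP2D6 inhibitors: ",
                   paste(s$cyp2d6_inhibitors, collapse = ", ")))
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(json_path)
}
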