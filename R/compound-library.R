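# Compound library: structure-derived physicochemical descriptors and
# Lipinski rule-of-five verdicts.
#
# The library members share one scaffold -- a 3-hydroxy-5,5-dimethyl-
# cyclohex-2-enone (dimedone-derived) ring attached at C3 of a
# 2-arylimidazo[1,2-a]pyridine -- and differ in a methyl on the pyridine
# ring (R1) and a substituent on the 2-aryl ring (R2).

#' Read a compound table
#'
#' Reads a TSV with at least `id` and one of `smiles` or `formula`;
#' optional columns (`logp`, `r1`, `r2`, `name`) are carried through.
#' Lines starting with `#` are treated as comments.
#'
#' @param path Path to a tab-separated compound table.
#' @return A data frame with one row per compound.
#' @export
read_compounds <- function(path) {
  df <- read_delim_table(path)
  if (!"id" %in% names(df)) stop("compound table needs an 'id' column")
  if (!any(c("smiles", "formula") %in% names(df))) {
    stop("compound table needs a 'smiles' or 'formula' column")
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate compound id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  if ("logp" %in% names(df)) df$logp <- parse_numeric(df$logp)
  df
}

#' The packaged 15-member imidazo[1,2-a]pyridine library
#'
#' Compound identities (id, substituents, SMILES) for the fifteen library
#' members `4a`-`4o`, with the externally predicted octanol-water logP
#' carried as data (logP is never computed by this package).
#'
#' @return Data frame with columns `id`, `r1`, `r2`, `smiles`, `logp`, `name`.
#' @export
#' @examples
#' head(ip_library())
ip_library <- function() {
  read_compounds(ip_extdata("compounds.tsv"))
}

#' Lipinski rule-of-five verdict
#'
#' Counts violations of the four classic criteria -- MW < 500 g/mol,
#' logP <= 5, hydrogen-bond donors <= 5, acceptors <= 10 -- and passes a
#' compound with at most one violation. Thresholds are applied as printed:
#' strict `<` for molecular weight, `<=` elsewhere, so a value exactly at a
#' `<=` boundary does not violate. TPSA is reported alongside descriptors
#' but is not a violation criterion (see the methods vignette).
#'
#' @param mw Molecular weight (g/mol).
#' @param logp Octanol-water partition coefficient (imported, not computed).
#' @param n_hbd Hydrogen-bond donor count.
#' @param n_hba Hydrogen-bond acceptor count.
#' @return Data frame with `n_violations` (0-4) and logical `pass`.
#' @export
#' @examples
#' lipinski_verdict(332.40, 3.56, 1, 3)
lipinski_verdict <- function(mw, logp, n_hbd, n_hba) {
  if (any(is.na(logp))) stop("logp is required for a Lipinski verdict")
  stopifnot(length(mw) == length(logp), length(mw) == length(n_hbd),
            length(mw) == length(n_hba))
  n <- (mw >= 500) + (logp > 5) + (n_hbd > 5) + (n_hba > 10)
  data.frame(n_violations = as.integer(n), pass = n <= 1L)
}

#' Physicochemical profile of a compound table
#'
#' Computes MW, donor/acceptor counts and TPSA from each compound's
#' structure and attaches the Lipinski verdict. logP is passed through
#' from the input (`NA` logP yields `NA` verdicts only if
#' `require_logp = FALSE`; by default missing logP is an error).
#'
#' @param compounds Data frame with `id` and `smiles` columns (see
#'   [read_compounds()]), plus optionally `logp`.
#' @param require_logp Error on missing logP (default `TRUE`).
#' @return Data frame with columns `id`, `mw`, `n_hba`, `n_hbd`, `tpsa`,
#'   `logp`, `n_lipinski_violations`, `lipinski_pass`.
#' @export
physchem_profile <- function(compounds, require_logp = TRUE) {
  stopifnot(is.data.frame(compounds), "id" %in% names(compounds),
            "smiles" %in% names(compounds))
  logp <- if ("logp" %in% names(compounds)) compounds$logp else
    rep(NA_real_, nrow(compounds))
  if (require_logp && any(is.na(logp))) {
    stop("missing logp for: ",
         paste(compounds$id[is.na(logp)], collapse = ", "))
  }
  sts <- lapply(compounds$smiles, parse_structure)
  mw <- vapply(sts, function(s) molecular_weight(structure_formula(s)),
               numeric(1))
  prof <- data.frame(
    id = compounds$id,
    mw = round_half_up(mw, 2),
    n_hba = vapply(sts, count_hba, numeric(1)),
    n_hbd = vapply(sts, count_hbd, numeric(1)),
    tpsa = vapply(sts, tpsa, numeric(1)),
    logp = logp,
    stringsAsFactors = FALSE
  )
  if (all(!is.na(logp))) {
    v <- lipinski_verdict(prof$mw, prof$logp, prof$n_hbd, prof$n_hba)
    prof$n_lipinski_violations <- v$n_violations
    prof$lipinski_pass <- v$pass
  } else {
    prof$n_lipinski_violations <- NA_integer_
    prof$lipinski_pass <- NA
  }
  class(prof) <- c("ip_physchem", "data.frame")
  prof
}

#' Write a physicochemical profile as TSV
#'
#' @param profile Result of [physchem_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_physchem <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
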