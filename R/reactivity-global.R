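# Global conceptual-DFT reactivity descriptors from frontier orbital
# energies.
#
# Under the Koopmans/Parr approximation the ionization potential and
# electron affinity are the negated HOMO and LUMO energies; from these the
# gap, chemical hardness eta = (I - A)/2, electronic chemical potential
# mu = -(I + A)/2, electronegativity chi = -mu and electrophilicity index
# omega = mu^2 / (2 eta) follow. More reactive (softer) molecules have a
# smaller gap; stronger electrophiles a larger omega.

#' Read a frontier-orbital energy table
#'
#' TSV with columns `compound_id`, `e_homo_ev`, `e_lumo_ev`. Unicode minus
#' glyphs (as often found in published tables) are normalized.
#'
#' @param path Path to a tab-separated energy table.
#' @return Data frame with numeric `e_homo_ev`, `e_lumo_ev`.
#' @export
read_frontier_energies <- function(path) {
  df <- read_delim_table(path)
  need <- c("compound_id", "e_homo_ev", "e_lumo_ev")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df$e_homo_ev <- parse_numeric(df$e_homo_ev)
  df$e_lumo_ev <- parse_numeric(df$e_lumo_ev)
  df
}

#' Global reactivity indices from frontier orbital energies
#'
#' Computes, per compound: ionization potential `I = -E_HOMO`, electron
#' affinity `A = -E_LUMO`, gap `dE = E_LUMO - E_HOMO`, chemical hardness
#' `eta = dE / 2`, chemical potential `mu = (E_HOMO + E_LUMO) / 2`,
#' electronegativity `chi = -mu`, electrophilicity `omega = mu^2 / (2 eta)`
#' and (as a convenience not part of the published table set) softness
#' `S = 1 / (2 eta)`. All energies in eV.
#'
#' @param fe Data frame with `compound_id`, `e_homo_ev`, `e_lumo_ev`, or a
#'   two-element numeric vector `c(e_homo, e_lumo)` for a single compound.
#' @param digits Decimal places for report rounding (half-up, default 4);
#'   `NULL` keeps full precision.
#' @return Data frame of class `ip_reactivity` with one row per compound.
#' @export
#' @examples
#' global_indices(c(-5.3878, -1.4150))
global_indices <- function(fe, digits = 4) {
  if (is.numeric(fe) && length(fe) == 2L) {
    fe <- data.frame(compound_id = "compound", e_homo_ev = fe[1],
                     e_lumo_ev = fe[2])
  }
  stopifnot(is.data.frame(fe),
            all(c("compound_id", "e_homo_ev", "e_lumo_ev") %in% names(fe)))
  homo <- fe$e_homo_ev; lumo <- fe$e_lumo_ev
  if (any(!is.finite(homo)) || any(!is.finite(lumo))) {
    stop("non-finite orbital energies")
  }
  bad <- lumo <= homo
  if (any(bad)) {
    stop("degenerate gap (E_LUMO <= E_HOMO) for: ",
         paste(fe$compound_id[bad], collapse = ", "),
         "; hardness and electrophilicity are undefined")
  }
  gap <- lumo - homo
  eta <- gap / 2
  mu <- (homo + lumo) / 2
  out <- data.frame(
    compound_id = fe$compound_id,
    e_homo = homo,
    e_lumo = lumo,
    ionization_potential = -homo,
    electron_affinity = -lumo,
    gap = gap,
    hardness = eta,
    chemical_potential = mu,
    electronegativity = -mu,
    electrophilicity = mu^2 / (2 * eta),
    softness = 1 / (2 * eta),
    stringsAsFactors = FALSE
  )
  if (!is.null(digits)) {
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], round_half_up, digits = digits)
  }
  class(out) <- c("ip_reactivity", "data.frame")
  out
}

#' Rank the library on a global reactivity key
#'
#' Orders compounds ascending on `gap`, `hardness` or `electrophilicity`
#' (ties broken lexicographically by compound id) and exposes the extremes:
#' the argmin of the gap/hardness is the softest, most reactive compound;
#' the argmax of electrophilicity the strongest electrophile.
#'
#' @param records An `ip_reactivity` data frame from [global_indices()].
#' @param key One of `"gap"`, `"hardness"`, `"electrophilicity"`.
#' @return List of class `ip_ranking`: `key`, `order` (ids ascending on the
#'   key), `values` (named, sorted), `argmin`, `argmax`.
#' @export
rank_library <- function(records, key = c("gap", "hardness",
                                          "electrophilicity")) {
  key <- match.arg(key)
  stopifnot(is.data.frame(records), key %in% names(records))
  if (nrow(records) == 0L) stop("empty reactivity table")
  v <- records[[key]]
  ord <- order(v, records$compound_id)
  out <- list(key = key,
              order = records$compound_id[ord],
              values = stats::setNames(v[ord], records$compound_id[ord]),
              argmin = records$compound_id[ord[1L]],
              argmax = records$compound_id[ord[length(ord)]])
  class(out) <- "ip_ranking"
  out
}

#' @export
print.ip_ranking <- function(x, ...) {
  cat("ranking on", x$key, "(ascending):\n ",
      paste(x$order, collapse = " < "), "\n")
  cat("  argmin:", x$argmin, " argmax:", x$argmax, "\n")
  invisible(x)
}

#' Softest (smallest-gap) compound
#'
#' @param records An `ip_reactivity` data frame.
#' @return Compound id with the smallest HOMO-LUMO gap.
#' @export
softest_compound <- function(records) rank_library(records, "gap")$argmin

#' Strongest electrophile (largest electrophilicity index)
#'
#' @param records An `ip_reactivity` data frame.
#' @return Compound id with the largest electrophilicity index.
#' @export
strongest_electrophile <- function(records) {
  rank_library(records, "electrophilicity")$argmax
}
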