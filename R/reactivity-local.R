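# Condensed Fukui functions from per-atom charges at three electron
# counts, and atomic site calls.
#
# In the charge-difference (finite difference) form, with q_k(N) the
# charge on atom k of the N-electron molecule:
#   f+ = q(N) - q(N+1)   susceptibility to nucleophilic attack
#   f- = q(N-1) - q(N)   susceptibility to electrophilic attack
#   f0 = (q(N-1) - q(N+1)) / 2   radical attack, the mean of f+ and f-
# Positive values mark the susceptible sites; each column sums to 1
# because the three states differ by exactly one electron.

#' Construct a validated charge set
#'
#' Bundles per-atom charges of the cationic (N-1), neutral (N) and anionic
#' (N+1) states of one compound and enforces the bookkeeping invariants:
#' equal lengths and state totals differing by exactly one electron
#' (within `tol`).
#'
#' @param atom_label Character vector of atom labels (e.g. `"C1"`).
#' @param element Element symbols, same length.
#' @param q_nminus1,q_n,q_nplus1 Numeric charge vectors (e) for the N-1,
#'   N and N+1 electron states.
#' @param compound_id Compound identifier.
#' @param scheme Population-analysis label (e.g. `"NBO"`).
#' @param tol Tolerance on the one-electron totals (e), default `1e-3`.
#' @return Object of class `ip_charge_set`.
#' @export
charge_set <- function(atom_label, element, q_nminus1, q_n, q_nplus1,
                       compound_id = "compound", scheme = "NBO",
                       tol = 1e-3) {
  n <- length(atom_label)
  if (n < 1L) stop("empty charge set")
  if (length(element) != n || length(q_nminus1) != n || length(q_n) != n ||
      length(q_nplus1) != n) {
    stop("charge vectors and atom labels differ in length")
  }
  if (anyDuplicated(atom_label)) {
    stop("duplicate atom label(s): ",
         paste(unique(atom_label[duplicated(atom_label)]), collapse = ", "))
  }
  q_nminus1 <- parse_numeric(q_nminus1)
  q_n <- parse_numeric(q_n)
  q_nplus1 <- parse_numeric(q_nplus1)
  d_cat <- sum(q_nminus1) - sum(q_n)
  d_an <- sum(q_n) - sum(q_nplus1)
  if (abs(d_cat - 1) > tol) {
    stop("states N-1 and N do not differ by one electron: total charge ",
         "difference ", format(d_cat), " (tolerance ", tol, ")")
  }
  if (abs(d_an - 1) > tol) {
    stop("states N and N+1 do not differ by one electron: total charge ",
         "difference ", format(d_an), " (tolerance ", tol, ")")
  }
  structure(list(compound_id = compound_id, scheme = scheme,
                 atoms = data.frame(atom_label = atom_label,
                                    element = element,
                                    stringsAsFactors = FALSE),
                 q_nminus1 = q_nminus1, q_n = q_n, q_nplus1 = q_nplus1),
            class = "ip_charge_set")
}

#' Read a per-atom charge table
#'
#' TSV with columns `atom_label`, `element`, `q_nminus1`, `q_n`,
#' `q_nplus1` for one compound.
#'
#' @param path Path to the table.
#' @inheritParams charge_set
#' @return An `ip_charge_set`.
#' @export
read_charge_set <- function(path, compound_id = "compound",
                            scheme = "NBO", tol = 1e-3) {
  df <- read_delim_table(path)
  need <- c("atom_label", "element", "q_nminus1", "q_n", "q_nplus1")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  charge_set(df$atom_label, df$element, df$q_nminus1, df$q_n, df$q_nplus1,
             compound_id = compound_id, scheme = scheme, tol = tol)
}

#' Condensed Fukui indices from a charge set
#'
#' Computes `f_plus`, `f_minus` and `f_zero` per atom by the
#' charge-difference form. The result carries provenance `"computed"`;
#' each index column sums to 1 (up to the charge set's tolerance) and
#' `f_zero` is exactly the atomwise mean of `f_plus` and `f_minus`.
#'
#' @param cs An [charge_set()] object.
#' @return Data frame of class `ip_fukui` with columns `atom_label`,
#'   `element`, `f_plus`, `f_minus`, `f_zero`.
#' @export
fukui_indices <- function(cs) {
  stopifnot(inherits(cs, "ip_charge_set"))
  out <- data.frame(
    atom_label = cs$atoms$atom_label,
    element = cs$atoms$element,
    f_plus = cs$q_n - cs$q_nplus1,
    f_minus = cs$q_nminus1 - cs$q_n,
    f_zero = (cs$q_nminus1 - cs$q_nplus1) / 2,
    stringsAsFactors = FALSE
  )
  attr(out, "provenance") <- "computed"
  attr(out, "compound_id") <- cs$compound_id
  class(out) <- c("ip_fukui", "data.frame")
  out
}

#' Import a published Fukui table
#'
#' Loads an externally computed table of condensed Fukui indices (atom
#' labels plus any subset of `f_plus`, `f_minus`, `f_zero`). No
#' conservation or consistency check is enforced on imported values --
#' published tables are taken verbatim -- so the result carries provenance
#' `"imported"`. Index columns that are absent stay absent (`NULL`).
#'
#' @param rows Data frame with `atom_label` and at least one index column,
#'   or a path to such a TSV.
#' @return Data frame of class `ip_fukui` with provenance `"imported"`.
#' @export
import_fukui_table <- function(rows) {
  if (is.character(rows) && length(rows) == 1L) rows <- read_delim_table(rows)
  stopifnot(is.data.frame(rows))
  if (nrow(rows) == 0L) stop("empty Fukui table")
  if (!"atom_label" %in% names(rows)) stop("missing 'atom_label' column")
  idx_cols <- intersect(c("f_plus", "f_minus", "f_zero"), names(rows))
  if (!length(idx_cols)) {
    stop("need at least one of f_plus, f_minus, f_zero")
  }
  if (anyDuplicated(rows$atom_label)) {
    stop("duplicate atom label(s): ",
         paste(unique(rows$atom_label[duplicated(rows$atom_label)]),
               collapse = ", "))
  }
  keep <- c("atom_label", intersect("element", names(rows)), idx_cols)
  out <- rows[keep]
  for (cc in idx_cols) out[[cc]] <- parse_numeric(out[[cc]])
  attr(out, "provenance") <- "imported"
  class(out) <- c("ip_fukui", "data.frame")
  out
}

#' Most reactive atomic sites
#'
#' Ranks atoms by descending value of the requested index (the highest
#' positive values mark the most probable attack sites: `plus` for
#' nucleophilic, `minus` for electrophilic, `zero` for radical attack) and
#' returns the top `k` with values reported at 4-decimal half-up rounding.
#' Ties keep the input atom order.
#'
#' @param ft An `ip_fukui` table.
#' @param index_kind One of `"plus"`, `"minus"`, `"zero"`.
#' @param k Number of sites to return (`k = 0` gives an empty frame).
#' @return Data frame with columns `atom_label`, `value`.
#' @export
top_sites <- function(ft, index_kind = c("plus", "minus", "zero"), k = 1) {
  index_kind <- match.arg(index_kind)
  stopifnot(inherits(ft, "ip_fukui"))
  if (length(k) != 1L || is.na(k) || k < 0) stop("k must be >= 0")
  col <- paste0("f_", index_kind)
  if (!col %in% names(ft) || all(is.na(ft[[col]]))) {
    stop("index ", col, " is absent from this table")
  }
  v <- ft[[col]]
  ord <- order(-v, seq_along(v))
  take <- utils::head(ord, k)
  data.frame(atom_label = ft$atom_label[take],
             value = round_half_up(v[take], 4),
             stringsAsFactors = FALSE)
}

#' Write a Fukui table as TSV
#'
#' @param ft An `ip_fukui` table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fukui <- function(ft, path) {
  utils::write.table(as.data.frame(ft), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
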