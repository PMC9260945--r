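# ADMET level semantics and TOPKAT probability banding.
#
# No predictive modeling happens here: the package applies the published
# level/band semantics to descriptor tables that external predictors
# produced. Band endpoints are half-open, low-inclusive, so every value in
# a band's stated domain maps to exactly one label.

.bbb_labels <- c("very high", "high", "medium", "low", "undefined")  # 0..4
.absorption_labels <- c("good", "moderate", "low", "very low")       # 0..3

#' Decode ADMET level codes to labels
#'
#' Maps the integer level semantics of an ADMET descriptor table to
#' human-readable labels: BBB level 0-4 = very high / high / medium / low /
#' undefined; absorption level 0-3 = good / moderate / low / very low;
#' hepatotoxicity 0/1 = nontoxic / toxic; CYP2D6 0/1 = noninhibitor /
#' inhibitor; PPB true/false = binding / nonbinding.
#'
#' @param rec Data frame with columns `bbb_level`, `absorption_level`,
#'   `hepatotoxicity`, `cyp2d6`, `ppb` (any subset; present columns are
#'   decoded). Out-of-range codes raise an error.
#' @return Data frame of decoded label columns (plus `compound_id` when
#'   present in the input).
#' @export
#' @examples
#' decode_levels(data.frame(bbb_level = 4, absorption_level = 0))
decode_levels <- function(rec) {
  stopifnot(is.data.frame(rec))
  out <- rec[intersect("compound_id", names(rec))]
  decode <- function(x, labels, what) {
    x <- as.integer(x)
    bad <- !is.na(x) & (x < 0L | x >= length(labels))
    if (any(bad)) {
      stop("out-of-range ", what, " level(s): ",
           paste(unique(x[bad]), collapse = ", "),
           " (valid: 0-", length(labels) - 1L, ")")
    }
    labels[x + 1L]
  }
  if ("bbb_level" %in% names(rec)) {
    out$bbb <- decode(rec$bbb_level, .bbb_labels, "BBB")
  }
  if ("absorption_level" %in% names(rec)) {
    out$absorption <- decode(rec$absorption_level, .absorption_labels,
                             "absorption")
  }
  if ("hepatotoxicity" %in% names(rec)) {
    out$hepatotoxicity <- decode(rec$hepatotoxicity,
                                 c("nontoxic", "toxic"), "hepatotoxicity")
  }
  if ("cyp2d6" %in% names(rec)) {
    out$cyp2d6 <- decode(rec$cyp2d6, c("noninhibitor", "inhibitor"),
                         "CYP2D6")
  }
  if ("ppb" %in% names(rec)) {
    ppb <- tolower(as.character(rec$ppb))
    if (!all(ppb %in% c("true", "false", "binding", "nonbinding"))) {
      stop("unparseable PPB value(s)")
    }
    out$ppb <- ifelse(ppb %in% c("true", "binding"), "binding", "nonbinding")
  }
  out
}

#' Band a log-solubility level value
#'
#' Half-open, low-inclusive bands on the log-solubility scale:
#' `[-6, -4)` low, `[-4, -2)` good, `[-2, 0]` optimal; anything outside
#' `[-6, 0]` is `out_of_band` (never silently clamped).
#'
#' @param value Numeric vector of log-solubility level values.
#' @return Character vector of band labels.
#' @export
#' @examples
#' solubility_band(c(-5.186, -1.462, -6.455))
solubility_band <- function(value) {
  stopifnot(is.numeric(value))
  ifelse(value >= -6 & value < -4, "low",
         ifelse(value >= -4 & value < -2, "good",
                ifelse(value >= -2 & value <= 0, "optimal", "out_of_band")))
}

#' Flag AlogP98 values exceeding 5
#'
#' Neutral threshold flag: `TRUE` iff the atom-based logP98 value is
#' strictly greater than 5 (a value of exactly 5.0 is not flagged). No
#' pharmacological interpretation is attached.
#'
#' @param value Numeric vector of AlogP98 values.
#' @return Logical vector.
#' @export
alogp98_flag <- function(value) {
  stopifnot(is.numeric(value))
  value > 5
}

#' Band a toxicity probability
#'
#' Probabilities in `[0, 0.30)` are nontoxic, `[0.30, 0.70)` intermediate,
#' `[0.70, 1]` toxic. Values outside `[0, 1]` are an error.
#'
#' @param p Numeric vector of probabilities.
#' @return Character vector of band labels.
#' @export
#' @examples
#' topkat_band(c(0, 0.5, 0.992))
topkat_band <- function(p) {
  stopifnot(is.numeric(p))
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stop("probability outside [0, 1]: ",
         paste(format(p[bad]), collapse = ", "))
  }
  ifelse(p < 0.30, "nontoxic", ifelse(p < 0.70, "intermediate", "toxic"))
}

#' Read an ADMET descriptor table
#'
#' CSV with columns `compound_id`, `bbb_level`, `absorption_level`,
#' `hepatotoxicity`, `cyp2d6`, `ppb`, `log_solubility`, `alogp98`,
#' `psa_2d`.
#'
#' @param path Path to the CSV.
#' @return Data frame, one row per compound.
#' @export
read_admet <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        check.names = FALSE)
  need <- c("compound_id", "bbb_level", "absorption_level",
            "hepatotoxicity", "cyp2d6", "ppb", "log_solubility",
            "alogp98", "psa_2d")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (cc in c("log_solubility", "alogp98", "psa_2d")) {
    df[[cc]] <- parse_numeric(df[[cc]])
  }
  decode_levels(df)  # validates level ranges as a side effect
  if (any(df$psa_2d < 0)) stop("negative psa_2d")
  df
}

# Parse one "label (p)" cell, e.g. "non-carcinogen (0.000)"; bare numerics
# are accepted too.
parse_prob_cell <- function(x) {
  x <- trimws(normalize_minus(as.character(x)))
  num <- suppressWarnings(as.numeric(x))
  m <- regexec("^(.*)\\(\\s*([0-9.]+)\\s*\\)\\s*$", x)
  hit <- regmatches(x, m)
  out <- vapply(seq_along(x), function(i) {
    if (!is.na(num[i])) return(num[i])
    if (length(hit[[i]]) == 3L) return(as.numeric(hit[[i]][3]))
    stop("unparseable probability cell: '", x[i], "'")
  }, numeric(1))
  out
}

#' Read a TOPKAT toxicity-probability table
#'
#' CSV whose probability cells may be bare numerics or `"label (p)"`
#' strings as printed by toxicity-prediction software (e.g.
#' `"non-carcinogen (0.000)"`). All columns except `compound_id` are
#' treated as probability endpoints; band labels per [topkat_band()] are
#' attached as `band_<endpoint>` columns.
#'
#' @param path Path to the CSV.
#' @return Data frame with numeric probability columns and band columns.
#' @export
read_topkat <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!"compound_id" %in% names(df)) stop("missing 'compound_id' column")
  endpoints <- setdiff(names(df), "compound_id")
  if (!length(endpoints)) stop("no probability columns")
  for (ep in endpoints) {
    df[[ep]] <- parse_prob_cell(df[[ep]])
    df[[paste0("band_", ep)]] <- topkat_band(df[[ep]])
  }
  attr(df, "endpoints") <- endpoints
  df
}

#' Consolidated drug-likeness report
#'
#' Joins decoded ADMET levels, solubility and AlogP98 bands, TOPKAT band
#' labels and Lipinski verdicts into a per-compound table plus library-level
#' summary counts.
#'
#' @param admet ADMET data frame (see [read_admet()]).
#' @param tox TOPKAT data frame (see [read_topkat()]); may be `NULL`.
#' @param lipinski Data frame with `id` and `n_lipinski_violations`
#'   (e.g. from [physchem_profile()]); may be `NULL`.
#' @param ids Compound ids to report on; defaults to the ADMET table's ids.
#' @return List of class `ip_druglikeness`: `per_compound` data frame and
#'   `summary` list (`n_per_bbb_level`, `n_alogp98_flagged`,
#'   `n_any_toxic`, `cyp2d6_inhibitors`).
#' @export
druglikeness_report <- function(admet, tox = NULL, lipinski = NULL,
                                ids = NULL) {
  stopifnot(is.data.frame(admet))
  if (nrow(admet) == 0L) stop("empty ADMET table")
  ids <- ids %||% admet$compound_id
  orphan <- setdiff(ids, admet$compound_id)
  if (length(orphan)) {
    stop("ids missing from the ADMET table: ",
         paste(orphan, collapse = ", "))
  }
  adm <- admet[match(ids, admet$compound_id), , drop = FALSE]
  per <- decode_levels(adm)
  per$solubility_band <- solubility_band(adm$log_solubility)
  per$alogp98 <- adm$alogp98
  per$alogp98_gt5 <- alogp98_flag(adm$alogp98)
  any_toxic <- rep(NA, length(ids))
  if (!is.null(tox)) {
    orphan <- setdiff(ids, tox$compound_id)
    if (length(orphan)) {
      stop("ids missing from the toxicity table: ",
           paste(orphan, collapse = ", "))
    }
    tx <- tox[match(ids, tox$compound_id), , drop = FALSE]
    endpoints <- attr(tox, "endpoints") %||%
      setdiff(names(tox)[!startsWith(names(tox), "band_")], "compound_id")
    band_cols <- paste0("band_", endpoints)
    per[band_cols] <- tx[band_cols]
    any_toxic <- apply(tx[band_cols] == "toxic", 1L, any)
  }
  per$any_toxic <- any_toxic
  if (!is.null(lipinski)) {
    orphan <- setdiff(ids, lipinski$id)
    if (length(orphan)) {
      stop("ids missing from the Lipinski table: ",
           paste(orphan, collapse = ", "))
    }
    per$n_lipinski_violations <-
      lipinski$n_lipinski_violations[match(ids, lipinski$id)]
  }
  n_bbb <- table(factor(adm$bbb_level, levels = 0:4))
  out <- list(
    per_compound = per,
    summary = list(
      n_compounds = length(ids),
      n_per_bbb_level = stats::setNames(as.integer(n_bbb),
                                        paste0("level_", 0:4)),
      n_alogp98_flagged = sum(per$alogp98_gt5),
      n_any_toxic = if (all(is.na(any_toxic))) NA_integer_
                    else sum(any_toxic, na.rm = TRUE),
      cyp2d6_inhibitors = ids[adm$cyp2d6 == 1L]
    )
  )
  class(out) <- "ip_druglikeness"
  out
}

#' @export
print.ip_druglikeness <- function(x, ...) {
  s <- x$summary
  cat("drug-likeness report for", s$n_compounds, "compounds\n")
  cat("  BBB levels 0-4:", paste(s$n_per_bbb_level, collapse = "/"), "\n")
  cat("  AlogP98 > 5:", s$n_alogp98_flagged,
      " CYP2D6 inhibitors:", paste(s$cyp2d6_inhibitors, collapse = ", "),
      "\n")
  if (!is.na(s$n_any_toxic)) {
    cat("  compounds with any toxic endpoint:", s$n_any_toxic, "\n")
  }
  invisible(x)
}
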