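# Structure perception for the supported scaffold grammar.
#
# SMILES parsing and kekulization are delegated to ChemmineR/ChemmineOB
# (OpenBabel). On top of the resulting atom/bond block this file perceives
# the handful of features the descriptor layer needs: implicit hydrogen
# counts, ring membership (igraph bridge detection: a bond is a ring bond
# iff it is not a graph bridge), nitro groups, and the polar-fragment
# classes of the Ertl TPSA table that cover the library's chemistry.

#' Parse a SMILES string into an annotated molecular graph
#'
#' Builds an `ip_structure`: a list with an `atoms` data frame (element,
#' implicit hydrogen count, heavy-atom degree, ring-bond count, nitro
#' membership) and a `bonds` data frame (atom indices, bond order, ring
#' flag). The molecule must be a single connected component.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `ip_structure`.
#' @export
#' @examples
#' \donttest{
#' st <- parse_structure("c1ccccc1O")  # phenol
#' count_hbd(st)
#' }
parse_structure <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) stop("unparseable SMILES '", smiles, "': ",
                             conditionMessage(e))
  )
  ab <- ChemmineR::atomblock(sdf[[1]])
  if (nrow(ab) == 1L && identical(rownames(ab), "0")) {
    # bond-less (single heavy atom) molecules read back as a dummy block;
    # re-convert with explicit hydrogens so the graph is non-degenerate
    sdfstr <- ChemmineOB::convertFormat(
      "SMI", "SDF", source = paste0(smiles, " mol\n"),
      options = data.frame(names = "h", args = "")
    )
    sdf <- suppressWarnings(
      ChemmineR::read.SDFset(unlist(strsplit(sdfstr, "\n", fixed = TRUE)))
    )
    ab <- ChemmineR::atomblock(sdf[[1]])
    if (nrow(ab) == 1L && identical(rownames(ab), "0")) {
      stop("unparseable SMILES '", smiles, "'")
    }
  }
  bb <- ChemmineR::bondblock(sdf[[1]])
  element <- sub("_.*$", "", rownames(ab))
  n <- length(element)
  if (n == 0L) stop("unparseable SMILES '", smiles, "': no atoms")

  # bond-less molecules come back as a dummy zero row with two columns
  if (is.null(dim(bb)) || nrow(bb) == 0L || ncol(bb) < 3L ||
      all(bb[, 1:2] == 0)) {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0),
                        order = integer(0), ring = logical(0))
  } else {
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
    g <- igraph::graph_from_edgelist(cbind(bonds$a1, bonds$a2),
                                     directed = FALSE)
    if (igraph::vcount(g) < n) {
      g <- igraph::add_vertices(g, n - igraph::vcount(g))
    }
    if (igraph::components(g)$no > 1L) {
      stop("SMILES '", smiles, "' is not a single connected molecule")
    }
    bridge_ids <- igraph::bridges(g)
    bonds$ring <- !seq_len(nrow(bonds)) %in% as.integer(bridge_ids)
  }
  if (n > 1L && nrow(bonds) == 0L) {
    stop("SMILES '", smiles, "' is not a single connected molecule")
  }

  deg <- valsum <- ringdeg <- ringdbl <- integer(n)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds$a1[i]; b <- bonds$a2[i]; o <- bonds$order[i]
    deg[c(a, b)] <- deg[c(a, b)] + 1L
    valsum[c(a, b)] <- valsum[c(a, b)] + o
    if (bonds$ring[i]) {
      ringdeg[c(a, b)] <- ringdeg[c(a, b)] + 1L
      if (o == 2L) ringdbl[c(a, b)] <- ringdbl[c(a, b)] + 1L
    }
  }

  # Nitro perception: an N bonded to exactly two terminal oxygens (each O
  # with a single heavy neighbour). Works for both the charge-separated and
  # the pentavalent kekulized forms OpenBabel may emit.
  nitro_n <- rep(FALSE, n); nitro_o <- rep(FALSE, n)
  for (k in which(element == "N")) {
    nb <- c(bonds$a2[bonds$a1 == k], bonds$a1[bonds$a2 == k])
    term_o <- nb[element[nb] == "O" & deg[nb] == 1L]
    if (length(term_o) == 2L) {
      nitro_n[k] <- TRUE
      nitro_o[term_o] <- TRUE
    } else if (length(term_o) > 2L) {
      stop("unsupported polar fragment: N with ", length(term_o),
           " terminal oxygens")
    }
  }

  default_valence <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L,
                       F = 1L, Cl = 1L, Br = 1L, I = 1L, H = 1L, B = 3L)
  nH <- integer(n)
  for (k in seq_len(n)) {
    v <- default_valence[element[k]]
    nH[k] <- if (is.na(v)) 0L else max(0L, v - valsum[k])
  }
  nH[nitro_n | nitro_o] <- 0L  # charged nitro atoms carry no hydrogen
  # explicit hydrogens written in the SMILES count toward their neighbour
  for (k in which(element == "H")) {
    nb <- c(bonds$a2[bonds$a1 == k], bonds$a1[bonds$a2 == k])
    if (length(nb)) nH[nb[1]] <- nH[nb[1]] + 1L
  }

  atoms <- data.frame(
    idx = seq_len(n), element = element, n_h = nH, degree = deg,
    ring_bonds = ringdeg, ring_double = ringdbl,
    nitro_n = nitro_n, nitro_o = nitro_o,
    stringsAsFactors = FALSE
  )
  structure(list(smiles = smiles, atoms = atoms, bonds = bonds),
            class = "ip_structure")
}

#' @export
print.ip_structure <- function(x, ...) {
  heavy <- x$atoms[x$atoms$element != "H", ]
  cat("ip_structure:", x$smiles, "\n")
  cat(" ", nrow(heavy), "heavy atoms,", nrow(x$bonds), "bonds,",
      sum(x$bonds$ring), "ring bonds\n")
  invisible(x)
}

as_structure <- function(x) {
  if (inherits(x, "ip_structure")) x else parse_structure(x)
}

#' Molecular formula of a parsed structure
#'
#' Element counts including implicit hydrogens, suitable for
#' [molecular_weight()].
#'
#' @param structure An `ip_structure` or SMILES string.
#' @return Named integer vector of element counts in Hill order.
#' @export
structure_formula <- function(structure) {
  st <- as_structure(structure)
  at <- st$atoms
  counts <- table(at$element)
  out <- as.integer(counts); names(out) <- names(counts)
  h <- sum(at$n_h) + sum(out["H"], na.rm = TRUE)
  out <- out[names(out) != "H"]
  if (h > 0) out <- c(out, H = as.integer(h))
  hill <- c(intersect(c("C", "H"), names(out)),
            sort(setdiff(names(out), c("C", "H"))))
  out[hill]
}

#' Count hydrogen-bond donors
#'
#' Number of O-H and N-H hydrogens over all oxygen and nitrogen atoms
#' (a group with two hydrogens contributes two).
#'
#' @inheritParams structure_formula
#' @return Integer donor count.
#' @export
count_hbd <- function(structure) {
  st <- as_structure(structure)
  at <- st$atoms
  sum(at$n_h[at$element %in% c("N", "O")])
}

#' Count hydrogen-bond acceptors
#'
#' Pharmacophore-style acceptor count: every nitrogen and oxygen accepts,
#' except the bridgehead aromatic nitrogen (three ring bonds, as in fused
#' bicyclic azines) and the nitro nitrogen; nitro oxygens each count.
#'
#' @inheritParams structure_formula
#' @return Integer acceptor count.
#' @export
count_hba <- function(structure) {
  st <- as_structure(structure)
  at <- st$atoms
  acc <- (at$element == "O") |
    (at$element == "N" & !at$nitro_n & at$ring_bonds < 3L)
  sum(acc)
}

# Fragment contributions (Angstrom^2) for the polar groups occurring in the
# supported scaffold grammar. Values are the standard topological polar
# surface area fragment contributions.
.tpsa_fragments <- c(
  hydroxyl = 20.23,          # [O;H1] bonded to one heavy atom
  carbonyl_o = 17.07,        # O double-bonded, terminal
  aromatic_n_2bond = 12.89,  # pyridine-type ring N, two ring bonds
  aromatic_n_3bond = 4.41,   # bridgehead ring N, three ring bonds
  aryl_ether_o = 9.23,       # O with two single bonds, >=1 aromatic C
  nitro = 45.82              # whole -NO2 group
)

#' Topological polar surface area by fragment summation
#'
#' Sums tabulated fragment contributions over the molecule's polar atoms.
#' The supported fragment grammar covers the library's chemistry: hydroxyl
#' (20.23), terminal carbonyl oxygen (17.07), two-ring-bond aromatic
#' nitrogen (12.89), three-ring-bond bridgehead aromatic nitrogen (4.41),
#' aryl ether oxygen (9.23) and the nitro group (45.82); carbon and
#' halogens contribute zero. A polar atom that matches none of these
#' fragments raises an error naming the fragment rather than silently
#' contributing zero.
#'
#' @inheritParams structure_formula
#' @param digits Decimal places for report rounding (half-up); `NULL` for
#'   full precision.
#' @return TPSA in Angstrom^2.
#' @export
#' @examples
#' \donttest{
#' tpsa("c1ccccc1")  # benzene: 0
#' }
tpsa <- function(structure, digits = 2) {
  st <- as_structure(structure)
  at <- st$atoms
  bonds <- st$bonds
  neighbours <- function(k) c(bonds$a2[bonds$a1 == k], bonds$a1[bonds$a2 == k])
  aromatic_like <- function(k) at$ring_double[k] > 0L | at$ring_bonds[k] >= 3L

  total <- 0
  total <- total + .tpsa_fragments[["nitro"]] * sum(at$nitro_n)
  for (k in which(at$element == "O" & !at$nitro_o)) {
    dbl <- any(bonds$order[bonds$a1 == k | bonds$a2 == k] == 2L)
    if (at$n_h[k] >= 1L && at$degree[k] == 1L) {
      total <- total + .tpsa_fragments[["hydroxyl"]]
    } else if (dbl && at$degree[k] == 1L) {
      total <- total + .tpsa_fragments[["carbonyl_o"]]
    } else if (at$degree[k] == 2L && at$n_h[k] == 0L && !dbl &&
               any(vapply(neighbours(k), aromatic_like, logical(1)))) {
      total <- total + .tpsa_fragments[["aryl_ether_o"]]
    } else {
      stop("polar fragment outside the contribution table: O atom ", k,
           " (", at$n_h[k], " H, degree ", at$degree[k], ")")
    }
  }
  for (k in which(at$element == "N" & !at$nitro_n)) {
    in_ring <- at$ring_bonds[k] >= 2L
    if (in_ring && at$n_h[k] == 0L && at$ring_bonds[k] == 2L &&
        at$ring_double[k] > 0L) {
      total <- total + .tpsa_fragments[["aromatic_n_2bond"]]
    } else if (in_ring && at$n_h[k] == 0L && at$ring_bonds[k] == 3L) {
      total <- total + .tpsa_fragments[["aromatic_n_3bond"]]
    } else {
      stop("polar fragment outside the contribution table: N atom ", k,
           " (", at$n_h[k], " H, ", at$ring_bonds[k], " ring bonds)")
    }
  }
  for (sym in setdiff(unique(at$element),
                      c("C", "H", "O", "N", "F", "Cl", "Br", "I"))) {
    stop("polar fragment outside the contribution table: element ", sym)
  }
  if (!is.null(digits)) total <- round_half_up(total, digits)
  total
}
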