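## Molecular graph layer: SMILES -> annotated heavy-atom graph.
## Parsing is delegated to OpenBabel through ChemmineR/ChemmineOB; everything
## downstream (fingerprints, scaffolds, filters) works on the parsed graph.

# V2000 charge codes: 0 = neutral, 1..3 = +3..+1, 4 = radical, 5..7 = -1..-3
.charge_from_code <- function(code) {
  out <- integer(length(code))
  out[code == 1] <- 3L
  out[code == 2] <- 2L
  out[code == 3] <- 1L
  out[code == 5] <- -1L
  out[code == 6] <- -2L
  out[code == 7] <- -3L
  out
}

# default valences used to infer implicit hydrogen counts (neutral organics)
.default_valence <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Se = 2, Br = 1, I = 1
)

# elements considered non-metals; anything else counts as a metal for the
# compound filters
.nonmetals <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl",
                "Se", "Br", "I")

# monoisotopic-free average atomic masses for molecular-weight computation
.atomic_mass <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.086, P = 30.974, S = 32.065, Cl = 35.453, Se = 78.96,
  Br = 79.904, I = 126.904, Na = 22.99, K = 39.098, Li = 6.941,
  Mg = 24.305, Ca = 40.078, Fe = 55.845, Zn = 65.38, Cu = 63.546,
  Mn = 54.938, Co = 58.933, Ni = 58.693, Pt = 195.084, Hg = 200.59,
  As = 74.922, Al = 26.982
)

#' Parse a SMILES string into an annotated molecular graph
#'
#' Converts a SMILES string into the package's internal heavy-atom graph
#' representation carrying, per atom: element, formal charge, heavy-atom
#' degree, implicit hydrogen count, pi-electron count, ring membership and a
#' simple aromaticity flag. Bonds carry their (kekulized) order. Parsing is
#' performed by OpenBabel via \pkg{ChemmineOB}; results are cached per SMILES
#' within the session.
#'
#' @param smiles character scalar, a SMILES string.
#' @return An object of class `fpmol`, or `NULL` when the SMILES cannot be
#'   parsed (a warning is emitted).
#' @examples
#' m <- parse_smiles("Cc1ccccc1")
#' m$natoms
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  cached <- .mol_cache[[smiles]]
  if (!is.null(cached)) return(if (identical(cached, "FAIL")) NULL else cached)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) == 0L) {
    .mol_cache[[smiles]] <- "FAIL"
    warning(sprintf("unparsable SMILES: '%s'", smiles), call. = FALSE)
    return(NULL)
  }
  mol <- .mol_from_sdf(sdf[[1]], smiles)
  .mol_cache[[smiles]] <- mol
  mol
}

.mol_cache <- new.env(parent = emptyenv())

#' @keywords internal
.mol_from_sdf <- function(sdf, smiles) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  charges <- if (ncol(ab) >= 5) .charge_from_code(as.integer(ab[, 5])) else integer(n)
  if (is.null(dim(bb)) || nrow(bb) == 0L) {
    bonds <- matrix(integer(0), ncol = 3,
                    dimnames = list(NULL, c("i", "j", "order")))
  } else {
    bonds <- cbind(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
  }
  # drop explicit hydrogens (OpenBabel usually emits none for plain SMILES)
  heavy <- which(elements != "H")
  if (length(heavy) < n) {
    map <- integer(n); map[heavy] <- seq_along(heavy)
    keep <- bonds[, "i"] %in% heavy & bonds[, "j"] %in% heavy
    h_on <- tabulate(c(bonds[!keep, "i"], bonds[!keep, "j"]), nbins = n)
    bonds <- bonds[keep, , drop = FALSE]
    bonds[, "i"] <- map[bonds[, "i"]]; bonds[, "j"] <- map[bonds[, "j"]]
    elements <- elements[heavy]; charges <- charges[heavy]
    explicit_h <- h_on[heavy]
    n <- length(heavy)
  } else {
    explicit_h <- integer(n)
  }
  degree <- tabulate(c(bonds[, "i"], bonds[, "j"]), nbins = n)
  ordsum <- numeric(n)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      o <- bonds[r, "order"]
      ordsum[bonds[r, "i"]] <- ordsum[bonds[r, "i"]] + o
      ordsum[bonds[r, "j"]] <- ordsum[bonds[r, "j"]] + o
    }
  }
  val <- .default_valence[elements]
  val[is.na(val)] <- 0
  # charge-adjusted valence: N+ has 4, O- has 1, etc.
  adj <- ifelse(elements %in% c("N", "P"), val + charges,
                ifelse(elements %in% c("O", "S"), val + charges, val))
  nH <- pmax(0, adj - ordsum - explicit_h)
  nH <- as.integer(round(nH))
  # pi electrons per atom from kekulized bond orders
  pi_e <- integer(n)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      extra <- bonds[r, "order"] - 1L
      if (extra > 0L) {
        pi_e[bonds[r, "i"]] <- pi_e[bonds[r, "i"]] + extra
        pi_e[bonds[r, "j"]] <- pi_e[bonds[r, "j"]] + extra
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(bonds)) {
    g <- igraph::add_edges(g, as.vector(t(bonds[, c("i", "j")])))
  }
  ring_edge <- rep(FALSE, nrow(bonds))
  in_ring <- rep(FALSE, n)
  if (nrow(bonds)) {
    br <- igraph::bridges(g)
    ring_edge <- !(seq_len(nrow(bonds)) %in% as.integer(br))
    if (any(ring_edge)) {
      re <- bonds[ring_edge, , drop = FALSE]
      in_ring[unique(c(re[, "i"], re[, "j"]))] <- TRUE
    }
  }
  aromatic <- .perceive_aromatic(elements, pi_e, in_ring, bonds, ring_edge, n)
  structure(list(
    smiles = smiles, natoms = n, elements = elements, charges = charges,
    bonds = bonds, degree = degree, nH = nH, pi = pi_e,
    in_ring = in_ring, ring_edge = ring_edge, aromatic = aromatic,
    graph = g
  ), class = "fpmol")
}

# Pragmatic aromaticity perception on kekulized input: a ring system (a
# connected component of ring bonds) is flagged aromatic when every atom in it
# either carries a pi electron or is a heteroatom (N, O, S, Se) able to donate
# a lone pair. Marks benzene/pyridine/pyrrole-type systems; leaves saturated
# and partially unsaturated carbocycles alone.
#' @keywords internal
.perceive_aromatic <- function(elements, pi_e, in_ring, bonds, ring_edge, n) {
  aromatic <- rep(FALSE, n)
  if (!any(ring_edge)) return(aromatic)
  rg <- igraph::make_empty_graph(n = n, directed = FALSE)
  re <- bonds[ring_edge, , drop = FALSE]
  rg <- igraph::add_edges(rg, as.vector(t(re[, c("i", "j")])))
  comp <- igraph::components(rg)
  for (k in seq_len(comp$no)) {
    atoms <- which(comp$membership == k & in_ring)
    if (length(atoms) < 3L) next
    ok <- all(pi_e[atoms] > 0L | elements[atoms] %in% c("N", "O", "S", "Se"))
    if (ok) aromatic[atoms] <- TRUE
  }
  aromatic
}

#' Molecular weight of a parsed molecule
#'
#' Average molecular weight including implicit hydrogens, from a standard
#' atomic-mass table.
#'
#' @param mol an `fpmol` from [parse_smiles()].
#' @return numeric scalar, g/mol.
#' @export
mol_weight <- function(mol) {
  stopifnot(inherits(mol, "fpmol"))
  m <- .atomic_mass[mol$elements]
  m[is.na(m)] <- 0
  sum(m) + sum(mol$nH) * .atomic_mass[["H"]]
}

#' Does a molecule contain a metal atom?
#'
#' A metal is any element outside the documented non-metal set
#' (H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I).
#'
#' @param mol an `fpmol`.
#' @return logical scalar.
#' @export
contains_metal <- function(mol) {
  stopifnot(inherits(mol, "fpmol"))
  any(!(mol$elements %in% .nonmetals))
}

#' @export
print.fpmol <- function(x, ...) {
  cat(sprintf("<fpmol> %s: %d heavy atoms, %d bonds\n",
              x$smiles, x$natoms, nrow(x$bonds)))
  invisible(x)
}
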