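## Fingerprint registry: named, pluggable 2D fingerprints.
##
## Circular (ECFP/ECFC/FCFP/FCFC), atom-pair (AP), topological-torsion (TT)
## and path (RDK5) fingerprints are computed here on the parsed molecular
## graph; MACCS keys delegate to OpenBabel through ChemmineOB. Bit strings are
## folded to a fixed length (default 1024 bits, long variants 16384); count
## vectors are kept sparse over 31-bit feature identifiers.

.HASH_MOD <- 2147483647  # 2^31 - 1; keeps double arithmetic exact

# deterministic FNV-style hash (xor then multiply) of a non-negative integer
# vector into [0, 2^31); the xor step makes distinct prefixes reorder the
# whole key space instead of merely shifting it
.hash_ints <- function(v) {
  h <- 98764321
  for (x in v) {
    h <- bitwXor(as.integer(h), as.integer(x %% .HASH_MOD))
    h <- (h * 1000003) %% .HASH_MOD
  }
  h
}

.atomic_number <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, Se = 34, Br = 35, I = 53
)

#' Construct a fingerprint vector
#'
#' Sparse container for both bit strings (`kind = "bitstring"`, 0-based
#' indices below `length`, all counts 1) and count vectors
#' (`kind = "countvector"`, unbounded feature identifiers, positive counts).
#'
#' @param idx integer vector of feature indices (0-based).
#' @param counts integer vector of positive counts, parallel to `idx`.
#' @param kind `"bitstring"` or `"countvector"`.
#' @param length bit-string length (ignored for count vectors).
#' @return An object of class `fpvec`.
#' @export
fpvec <- function(idx, counts = rep(1L, length(idx)),
                  kind = c("bitstring", "countvector"), length = NA_integer_) {
  kind <- match.arg(kind)
  stopifnot(base::length(idx) == base::length(counts), all(counts >= 1))
  o <- order(idx)
  idx <- as.integer(idx[o]); counts <- as.integer(counts[o])
  if (kind == "bitstring") {
    stopifnot(!is.na(length), all(idx < length), all(idx >= 0))
    counts <- rep(1L, base::length(idx))
  }
  structure(list(kind = kind, length = as.integer(length),
                 idx = idx, counts = counts), class = "fpvec")
}

#' @export
print.fpvec <- function(x, ...) {
  cat(sprintf("<fpvec %s> %d features, total count %d%s\n", x$kind,
              length(x$idx), sum(x$counts),
              if (x$kind == "bitstring") sprintf(", length %d", x$length) else ""))
  invisible(x)
}

#' Number of on-bits / total feature count of a fingerprint
#' @param fp an `fpvec`.
#' @return integer, number of distinct features set.
#' @export
n_bits_on <- function(fp) {
  stopifnot(inherits(fp, "fpvec"))
  length(fp$idx)
}

# accumulate raw feature ids into an fpvec, folding when a bitstring
.features_to_fpvec <- function(ids, kind, length = NA_integer_) {
  if (base::length(ids) == 0L)
    return(fpvec(integer(0), integer(0), kind, length))
  if (kind == "bitstring") {
    idx <- unique(as.integer(ids %% length))
    fpvec(idx, kind = "bitstring", length = length)
  } else {
    tab <- table(ids)
    fpvec(as.integer(names(tab)), as.integer(tab), kind = "countvector")
  }
}

## ---- atom invariants ------------------------------------------------------

# extended-connectivity invariant: element, heavy degree, H count, charge,
# ring membership (the classic EC atom type minus isotope)
.ec_invariants <- function(mol) {
  z <- .atomic_number[mol$elements]; z[is.na(z)] <- 0
  vapply(seq_len(mol$natoms), function(a) {
    .hash_ints(c(1L, z[a], mol$degree[a], mol$nH[a],
                 mol$charges[a] + 8L, as.integer(mol$in_ring[a])))
  }, numeric(1))
}

# element-only invariant: makes diameter-0 count vectors a pure atom count,
# identical for molecules with the same heavy-atom-type multiset
.element_invariants <- function(mol) {
  z <- .atomic_number[mol$elements]; z[is.na(z)] <- 99
  as.numeric(z)
}

# pharmacophoric feature invariant for FCFP/FCFC: donor, acceptor, aromatic,
# halogen, basic N, acidic O (simple documented rules)
.fc_invariants <- function(mol) {
  el <- mol$elements
  carbonyl_c <- rep(FALSE, mol$natoms)
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      b <- mol$bonds[r, ]
      if (b["order"] == 2L) {
        if (el[b["i"]] == "C" && el[b["j"]] == "O") carbonyl_c[b["i"]] <- TRUE
        if (el[b["j"]] == "C" && el[b["i"]] == "O") carbonyl_c[b["j"]] <- TRUE
      }
    }
  }
  adj <- .adjacency_list(mol)
  vapply(seq_len(mol$natoms), function(a) {
    donor <- el[a] %in% c("N", "O") && mol$nH[a] > 0L
    acceptor <- el[a] %in% c("N", "O") && mol$charges[a] <= 0L
    arom <- mol$aromatic[a]
    halogen <- el[a] %in% c("F", "Cl", "Br", "I")
    nbr_carbonyl <- any(carbonyl_c[adj[[a]]$nbr])
    basic <- el[a] == "N" && !arom && !nbr_carbonyl
    acidic <- el[a] == "O" && mol$nH[a] > 0L && nbr_carbonyl
    .hash_ints(c(2L, as.integer(c(donor, acceptor, arom, halogen, basic, acidic))))
  }, numeric(1))
}

.adjacency_list <- function(mol) {
  adj <- rep(list(list(nbr = integer(0), order = integer(0))), mol$natoms)
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[r, "i"]; j <- mol$bonds[r, "j"]; o <- mol$bonds[r, "order"]
      adj[[i]]$nbr <- c(adj[[i]]$nbr, j); adj[[i]]$order <- c(adj[[i]]$order, o)
      adj[[j]]$nbr <- c(adj[[j]]$nbr, i); adj[[j]]$order <- c(adj[[j]]$order, o)
    }
  }
  adj
}

## ---- circular (Morgan-style) fingerprints ---------------------------------

# iterative neighbourhood hashing; returns all feature ids emitted over
# radii 0..radius (one per atom per radius)
.morgan_features <- function(mol, radius, init) {
  ids <- init
  feats <- ids
  if (radius == 0L || mol$natoms == 0L) return(feats)
  adj <- .adjacency_list(mol)
  for (r in seq_len(radius)) {
    new_ids <- vapply(seq_len(mol$natoms), function(a) {
      nb <- adj[[a]]
      if (length(nb$nbr) == 0L) return(.hash_ints(c(r, ids[a])))
      pairs <- cbind(nb$order, ids[nb$nbr])
      o <- order(pairs[, 1], pairs[, 2])
      .hash_ints(c(r, ids[a], as.vector(t(pairs[o, , drop = FALSE]))))
    }, numeric(1))
    feats <- c(feats, new_ids)
    ids <- new_ids
  }
  feats
}

## ---- atom pairs and topological torsions ----------------------------------

# AP/TT atom type: element, number of heavy-atom neighbours, pi electrons
.ap_atom_types <- function(mol) {
  z <- .atomic_number[mol$elements]; z[is.na(z)] <- 99
  z * 100 + mol$degree * 10 + pmin(mol$pi, 9L)
}

.atom_pair_features <- function(mol) {
  n <- mol$natoms
  if (n < 2L) return(numeric(0))
  t <- .ap_atom_types(mol)
  d <- igraph::distances(mol$graph)
  feats <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      dij <- d[i, j]
      if (!is.finite(dij)) next
      lo <- min(t[i], t[j]); hi <- max(t[i], t[j])
      feats <- c(feats, .hash_ints(c(3L, lo, hi, dij)))
    }
  }
  feats
}

.torsion_features <- function(mol) {
  t <- .ap_atom_types(mol)
  adj <- .adjacency_list(mol)
  feats <- numeric(0)
  if (nrow(mol$bonds) == 0L) return(feats)
  for (r in seq_len(nrow(mol$bonds))) {
    j <- mol$bonds[r, "i"]; k <- mol$bonds[r, "j"]
    for (i in adj[[j]]$nbr) {
      if (i == k) next
      for (l in adj[[k]]$nbr) {
        if (l == j || l == i) next
        # each torsion appears once per central bond; canonicalize direction
        fwd <- c(t[i], t[j], t[k], t[l]); rev <- base::rev(fwd)
        seq4 <- if (paste(fwd, collapse = ",") <= paste(rev, collapse = ","))
          fwd else rev
        feats <- c(feats, .hash_ints(c(4L, seq4)))
      }
    }
  }
  feats
}

## ---- path (Daylight-style) fingerprint ------------------------------------

# enumerate all simple linear paths of 1..maxlen bonds; each path hashed over
# alternating atom codes (element + aromaticity) and bond codes (order, with
# aromatic ring bonds as a distinct code)
.path_features <- function(mol, maxlen = 5L) {
  n <- mol$natoms
  if (nrow(mol$bonds) == 0L) return(numeric(0))
  z <- .atomic_number[mol$elements]; z[is.na(z)] <- 99
  acode <- z * 2 + as.integer(mol$aromatic)
  adj <- .adjacency_list(mol)
  bcode_of <- function(a, b, o) {
    if (mol$aromatic[a] && mol$aromatic[b] && o > 0L) 4L else o
  }
  feats <- numeric(0)
  # DFS over simple paths from each start atom; dedupe reversed paths by
  # keeping the lexicographically smaller code sequence
  walk <- function(path, codes) {
    last <- path[length(path)]
    nb <- adj[[last]]
    for (q in seq_along(nb$nbr)) {
      nxt <- nb$nbr[q]
      if (nxt %in% path) next
      cs <- c(codes, bcode_of(last, nxt, nb$order[q]), acode[nxt])
      rs <- base::rev(cs)
      key <- if (paste(cs, collapse = ",") <= paste(rs, collapse = ",")) cs else rs
      feats <<- c(feats, .hash_ints(c(5L, length(path), key)))
      if (length(path) < maxlen) walk(c(path, nxt), cs)
    }
  }
  for (a in seq_len(n)) walk(a, acode[a])
  # every path was emitted from both of its ends with the same canonical key;
  # halve multiplicity by dropping duplicates per occurrence pair
  feats <- sort(feats)
  feats[seq(1L, length(feats), by = 2L)]
}

## ---- MACCS via OpenBabel --------------------------------------------------

.maccs_features <- function(smiles) {
  obmol <- tryCatch(
    ChemmineOB::forEachMol("SMILES", smiles, identity),
    error = function(e) NULL
  )
  if (is.null(obmol)) stop("MACCS backend could not parse SMILES: ", smiles)
  m <- ChemmineOB::fingerprint_OB(if (is.list(obmol)) obmol else list(obmol),
                                  "MACCS")
  row <- if (is.matrix(m)) m[1, ] else as.numeric(m)
  bits <- which(row != 0) - 1L   # 0-based key indices
  bits[bits < 166L]
}

## ---- registry -------------------------------------------------------------

.fp_registry <- new.env(parent = emptyenv())

#' Register a fingerprint descriptor
#'
#' The registry is string-keyed and user-extensible: additional fingerprints
#' can be added by name and are then usable everywhere a built-in is.
#'
#' @param name canonical fingerprint token.
#' @param kind `"bitstring"` or `"countvector"`.
#' @param length bit-string length (NA for count vectors).
#' @param fn function taking an `fpmol` and the SMILES string, returning a
#'   numeric vector of raw feature identifiers.
#' @return The descriptor, invisibly.
#' @export
register_fingerprint <- function(name, kind, length, fn) {
  stopifnot(is.character(name), length(name) == 1L)
  desc <- structure(list(name = name, kind = kind,
                         length = as.integer(length), fn = fn),
                    class = "fp_descriptor")
  assign(name, desc, envir = .fp_registry)
  invisible(desc)
}

#' @export
print.fp_descriptor <- function(x, ...) {
  cat(sprintf("<fingerprint %s> %s%s\n", x$name, x$kind,
              if (!is.na(x$length)) sprintf(" (%d bits)", x$length) else ""))
  invisible(x)
}

.register_builtins <- function() {
  circ <- function(radius, invfn) function(mol, smiles)
    .morgan_features(mol, radius, invfn(mol))
  unavailable <- function(name) function(mol, smiles)
    stop(sprintf(paste0("fingerprint '%s' has no available backend in this ",
                        "installation"), name), call. = FALSE)
  register_fingerprint("ECFC0",  "countvector", NA, circ(0L, .element_invariants))
  register_fingerprint("ECFC4",  "countvector", NA, circ(2L, .ec_invariants))
  register_fingerprint("FCFC4",  "countvector", NA, circ(2L, .fc_invariants))
  register_fingerprint("ECFP4",  "bitstring", 1024L, circ(2L, .ec_invariants))
  register_fingerprint("lECFP4", "bitstring", 16384L, circ(2L, .ec_invariants))
  register_fingerprint("ECFP6",  "bitstring", 1024L, circ(3L, .ec_invariants))
  register_fingerprint("lECFP6", "bitstring", 16384L, circ(3L, .ec_invariants))
  register_fingerprint("FCFP4",  "bitstring", 1024L, circ(2L, .fc_invariants))
  register_fingerprint("AP", "countvector", NA,
                       function(mol, smiles) .atom_pair_features(mol))
  register_fingerprint("TT", "countvector", NA,
                       function(mol, smiles) .torsion_features(mol))
  register_fingerprint("RDK5", "bitstring", 1024L,
                       function(mol, smiles) .path_features(mol, 5L))
  register_fingerprint("MACCS", "bitstring", 166L,
                       function(mol, smiles) .maccs_features(smiles))
  register_fingerprint("Avalon",  "bitstring", 1024L, unavailable("Avalon"))
  register_fingerprint("lAvalon", "bitstring", 16384L, unavailable("lAvalon"))
}

#' List registered fingerprint names
#' @return character vector of canonical names.
#' @export
fingerprint_names <- function() sort(ls(.fp_registry))

#' Look up a fingerprint descriptor by name
#' @param name canonical fingerprint token.
#' @return `fp_descriptor`.
#' @export
fingerprint_descriptor <- function(name) {
  if (!exists(name, envir = .fp_registry, inherits = FALSE)) {
    stop(sprintf("unknown fingerprint '%s'; available: %s", name,
                 paste(fingerprint_names(), collapse = ", ")), call. = FALSE)
  }
  get(name, envir = .fp_registry, inherits = FALSE)
}

.fpvec_cache <- new.env(parent = emptyenv())

#' Compute a fingerprint for one molecule
#'
#' @param smiles SMILES string (or an `fpmol`).
#' @param descriptor an `fp_descriptor` or a canonical name.
#' @return An `fpvec` of the descriptor's kind and length.
#' @export
compute_fingerprint <- function(smiles, descriptor) {
  if (is.character(descriptor)) descriptor <- fingerprint_descriptor(descriptor)
  if (inherits(smiles, "fpmol")) {
    mol <- smiles; smi <- mol$smiles
  } else {
    smi <- smiles
    mol <- parse_smiles(smi)
    if (is.null(mol)) stop("cannot compute fingerprint: unparsable SMILES '",
                           smi, "'", call. = FALSE)
  }
  key <- paste0(descriptor$name, "\r", smi)
  cached <- .fpvec_cache[[key]]
  if (!is.null(cached)) return(cached)
  ids <- descriptor$fn(mol, smi)
  out <- if (descriptor$name == "MACCS") {
    fpvec(as.integer(ids), kind = "bitstring", length = 166L)
  } else {
    .features_to_fpvec(ids, descriptor$kind, descriptor$length)
  }
  .fpvec_cache[[key]] <- out
  out
}

#' Compute fingerprints for many molecules
#' @param smiles character vector of SMILES.
#' @inheritParams compute_fingerprint
#' @return list of `fpvec` (entries are `NULL` for unparsable SMILES).
#' @export
compute_fingerprints <- function(smiles, descriptor) {
  if (is.character(descriptor)) descriptor <- fingerprint_descriptor(descriptor)
  lapply(smiles, function(s) {
    tryCatch(compute_fingerprint(s, descriptor), error = function(e) NULL)
  })
}

#' Read a fingerprint-names configuration file
#'
#' Plain text, one canonical fingerprint name per line; `#` comments and
#' blank lines ignored. Order is preserved and drives column order downstream.
#'
#' @param path file path.
#' @return list of `fp_descriptor`.
#' @export
load_fingerprint_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("fingerprint config '", path,
                                "' names no fingerprints", call. = FALSE)
  if (anyDuplicated(lines)) stop("duplicate fingerprint name(s) in config: ",
                                 paste(unique(lines[duplicated(lines)]),
                                       collapse = ", "), call. = FALSE)
  lapply(lines, fingerprint_descriptor)
}

#' Count bit collisions introduced by folding
#'
#' Compares the short (folded) and long variant of a bit-string fingerprint on
#' a set of molecules and reports how many on-bits were merged by folding.
#'
#' @param smiles character vector of SMILES.
#' @param short,long fingerprint names, e.g. `"ECFP4"` and `"lECFP4"`.
#' @return integer vector: per molecule, on-bits(long) - on-bits(short).
#' @export
folding_collisions <- function(smiles, short = "ECFP4", long = "lECFP4") {
  s <- compute_fingerprints(smiles, short)
  l <- compute_fingerprints(smiles, long)
  mapply(function(a, b) {
    if (is.null(a) || is.null(b)) NA_integer_ else n_bits_on(b) - n_bits_on(a)
  }, s, l)
}
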