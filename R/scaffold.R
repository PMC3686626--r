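## Bemis-Murcko scaffold (molecular framework) extraction and the scaffold
## enrichment factor, which probes scaffold hopping.

#' Bemis-Murcko scaffold key of a molecule
#'
#' The molecular framework: ring systems plus the linkers connecting them,
#' obtained by iteratively pruning terminal side-chain atoms (the 2-core of
#' the heavy-atom graph). The framework is canonicalized with a
#' graph-canonical labelling (element and formal charge as vertex colors,
#' bond orders on edges), so the key is invariant to SMILES atom ordering.
#' Acyclic molecules have no framework and share the sentinel key
#' `"ACYCLIC"`.
#'
#' @param smiles SMILES string or `fpmol`.
#' @return character scaffold key.
#' @export
bemis_murcko <- function(smiles) {
  mol <- if (inherits(smiles, "fpmol")) smiles else parse_smiles(smiles)
  if (is.null(mol)) stop("cannot extract scaffold: unparsable SMILES",
                         call. = FALSE)
  if (!any(mol$in_ring)) return("ACYCLIC")
  # iterative pruning of degree-1 atoms = the 2-core of the heavy-atom graph
  core <- which(igraph::coreness(mol$graph) >= 2)
  if (length(core) == 0L) return("ACYCLIC")
  in_core <- logical(mol$natoms); in_core[core] <- TRUE
  pos <- integer(mol$natoms); pos[core] <- seq_along(core)
  keep <- in_core[mol$bonds[, "i"]] & in_core[mol$bonds[, "j"]]
  bonds <- mol$bonds[keep, , drop = FALSE]
  # bond code: aromatic ring bonds share code 4 so the kekulization phase
  # chosen by the parser cannot leak into the key
  arom_bond <- mol$aromatic[bonds[, "i"]] & mol$aromatic[bonds[, "j"]] &
    mol$ring_edge[keep]
  code <- ifelse(arom_bond, 4L, bonds[, "order"])
  # edge-subdivision trick: bonds become colored vertices so that bond codes
  # take part in graph canonization (plain BLISS has no edge colors)
  n_a <- length(core); n_b <- nrow(bonds)
  color_key <- paste(mol$elements[core], mol$charges[core], sep = "/")
  colors <- c(as.integer(factor(color_key,
                                levels = sort(unique(color_key)))),
              100L + code)
  g <- igraph::make_empty_graph(n = n_a + n_b, directed = FALSE)
  if (n_b) {
    ev <- n_a + seq_len(n_b)
    g <- igraph::add_edges(g, as.vector(rbind(
      c(pos[bonds[, "i"]], pos[bonds[, "j"]]), c(ev, ev))))
  }
  perm <- igraph::canonical_permutation(g, colors = colors)$labeling
  v_can <- order(perm)  # canonical position -> original vertex
  labels <- c(color_key, paste0("b", code))[v_can]
  ends <- igraph::as_edgelist(g, names = FALSE)
  e_can <- cbind(pmin(perm[ends[, 1]], perm[ends[, 2]]),
                 pmax(perm[ends[, 1]], perm[ends[, 2]]))
  e_can <- e_can[order(e_can[, 1], e_can[, 2]), , drop = FALSE]
  paste0(paste(labels, collapse = ","), "|",
         paste(e_can[, 1], e_can[, 2], sep = "-", collapse = ";"))
}

#' Scaffold assignment for a set of molecules
#'
#' @param internal_id character vector of compound IDs.
#' @param smiles parallel character vector of SMILES.
#' @return named character vector: internal_id -> scaffold key (`NA` for
#'   unparsable molecules).
#' @export
assign_scaffolds <- function(internal_id, smiles) {
  stopifnot(length(internal_id) == length(smiles))
  keys <- vapply(smiles, function(s) {
    tryCatch(bemis_murcko(s), error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
  stats::setNames(keys, internal_id)
}

#' Scaffold summary of an active list
#'
#' @param smiles character vector of active SMILES.
#' @return list with `n_scaffolds` (distinct Bemis-Murcko scaffolds) and
#'   `ratio` (scaffolds / actives).
#' @export
dataset_scaffold_summary <- function(smiles) {
  keys <- assign_scaffolds(seq_along(smiles), smiles)
  keys <- keys[!is.na(keys)]
  n <- length(unique(keys))
  list(n_scaffolds = n, ratio = n / length(smiles))
}

#' Scaffold enrichment factor
#'
#' Analogue of the enrichment factor over distinct active scaffolds: the
#' number of distinct active scaffolds retrieved among the top `chi` fraction
#' of the ranked list, divided by the random expectation `chi * S` where `S`
#' is the number of distinct scaffolds among the test-set actives of that
#' repetition.
#'
#' @param result a `ranked_screen_result`.
#' @param assignment named scaffold vector from [assign_scaffolds()]; must
#'   cover every test active.
#' @param chi fraction of the ranked list considered (e.g. 0.05).
#' @return numeric scaffold enrichment factor.
#' @export
scaffold_enrichment_factor <- function(result, assignment, chi) {
  stopifnot(inherits(result, "ranked_screen_result"),
            chi > 0, chi < 1)
  act_ids <- result$internal_id[result$is_active]
  keys <- assignment[act_ids]
  if (anyNA(keys))
    stop("scaffold assignment missing for test active(s): ",
         paste(act_ids[is.na(keys)][1:min(3, sum(is.na(keys)))],
               collapse = ", "), call. = FALSE)
  S_total <- length(unique(keys))
  if (S_total == 0L) stop("no scaffolds among test actives", call. = FALSE)
  N <- length(result$internal_id)
  top <- result$internal_id[seq_len(floor(chi * N))]
  top_act <- intersect(top, act_ids)
  S_top <- length(unique(assignment[top_act]))
  S_top / (chi * S_total)
}
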