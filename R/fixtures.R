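## Synthetic compound-set generator: benchmark-shaped targets with
## controllable difficulty, emulating the curation styles of the public
## collections (MUV-like: few, maximally diverse actives among many decoys;
## DUD-like: analog series with property-matched decoys; ChEMBL-like:
## diverse actives with two atom-count-matched decoys each).
##
## Actives are assembled by string-level substitution on a curated internal
## library of drug-like scaffold templates and substituents; no external
## structure source is needed and generation is deterministic per seed.

# scaffold templates for actives; "{R}" is the substitution site
.active_templates <- c(
  "c1ccc({R})cc1",                    # benzene
  "c1cc({R})ccn1",                    # pyridine
  "c1ccc2[nH]c({R})cc2c1",            # indole
  "c1ccc2nc({R})ccc2c1",              # quinoline
  "c1ccc2sc({R})nc2c1",               # benzothiazole
  "c1ccc2oc({R})nc2c1",               # benzoxazole
  "c1ccc2[nH]c({R})nc2c1",            # benzimidazole
  "c1ccc(-c2ccc({R})cc2)cc1",         # biphenyl
  "C1CCN(c2ccc({R})cc2)CC1",          # phenylpiperidine
  "C1COCCN1c1ccc({R})cc1",            # phenylmorpholine
  "O=C(c1ccc({R})cc1)N1CCNCC1",       # benzoylpiperazine
  "c1cnc({R})nc1",                    # pyrimidine
  "c1ccc(-c2ccc({R})o2)cc1",          # phenylfuran
  "c1csc({R})c1",                     # thiophene
  "c1cc({R})n[nH]1",                  # pyrazole
  "c1cnc({R})[nH]1",                  # imidazole
  "c1ccc2cc({R})ccc2c1",              # naphthalene
  "C1CCC(c2ccc({R})cc2)CC1",          # cyclohexylbenzene
  "O=C1CCCN1c1ccc({R})cc1",           # phenylpyrrolidinone
  "C1Cc2ccc({R})cc2C1"                # indane
)

# scaffold templates used only for decoys (disjoint frameworks)
.decoy_templates <- c(
  "C1CCC({R})CC1",                    # cyclohexane
  "C1CCC({R})C1",                     # cyclopentane
  "C1CCN({R})CC1",                    # piperidine
  "C1CCOC({R})C1",                    # tetrahydropyran
  "c1cc({R})nnc1",                    # pyridazine
  "c1oc({R})nc1",                     # oxazole
  "c1sc({R})nc1",                     # thiazole
  "c1cc({R})oc1",                     # furan
  "C1CCCC({R})CC1",                   # cycloheptane
  "C1OCC({R})O1"                      # 1,3-dioxolane
)

# acyclic substituents: prune away under Bemis-Murcko, so they vary analogs
# within a series without changing the framework
.chain_substituents <- c(
  "C", "CC", "CCC", "C(C)C", "CCCC", "O", "OC", "OCC", "N", "NC",
  "N(C)C", "F", "Cl", "Br", "C#N", "C(=O)O", "C(=O)OC", "C(=O)N",
  "C(=O)NC", "C(F)(F)F", "S(C)(=O)=O", "CO", "CCO", "CN", "CCN",
  "C(C)=O", "SC", "CC#N", "OC(C)C", "CCC(C)C"
)

# ring-bearing substituents: occupy the template's {R} site and extend the
# framework, multiplying the number of distinct scaffolds available
.ring_substituents <- c(
  "c4ccccc4", "c4ccco4", "c4cccs4", "c4ccncc4", "C4CC4", "C4CCC4",
  "N4CCOCC4", "c4cn[nH]c4"
)

#' Recipe for a synthetic benchmark target
#'
#' @param style `"MUV-like"`, `"DUD-like"` or `"ChEMBL-like"`.
#' @param n_actives number of actives. Defaults per style mirror the public
#'   collections: 30 (MUV-like, DUD-like) or 100 (ChEMBL-like).
#' @param n_decoys number of decoys. Defaults: 15000 (MUV-like), 1080
#'   (DUD-like), `2 * n_actives` (ChEMBL-like).
#' @param n_series number of active analog series; controls the
#'   scaffolds/actives ratio. Defaults: `n_actives` (MUV-like, one series
#'   per active), 5 (DUD-like), `n_actives` (ChEMBL-like).
#' @param difficulty in \code{[0, 1]}: fraction of decoys that share a
#'   scaffold template with some active (structural overlap of decoys with
#'   actives). Default 0.
#' @param seed integer seed; output is reproducible per seed.
#' @return object of class `fixture_recipe`.
#' @export
fixture_recipe <- function(style = c("MUV-like", "DUD-like", "ChEMBL-like"),
                           n_actives = NULL, n_decoys = NULL,
                           n_series = NULL, difficulty = 0, seed = 1L) {
  style <- match.arg(style)
  if (is.null(n_actives))
    n_actives <- switch(style, "MUV-like" = 30L, "DUD-like" = 30L,
                        "ChEMBL-like" = 100L)
  if (is.null(n_decoys))
    n_decoys <- switch(style, "MUV-like" = 15000L, "DUD-like" = 1080L,
                       "ChEMBL-like" = 2L * n_actives)
  if (is.null(n_series))
    n_series <- switch(style, "MUV-like" = n_actives, "DUD-like" = 5L,
                       "ChEMBL-like" = n_actives)
  stopifnot(n_series <= n_actives, difficulty >= 0, difficulty <= 1,
            n_actives >= 2, n_decoys >= 1)
  structure(list(style = style, n_actives = as.integer(n_actives),
                 n_decoys = as.integer(n_decoys),
                 n_series = as.integer(n_series),
                 difficulty = difficulty, seed = as.integer(seed)),
            class = "fixture_recipe")
}

#' @export
print.fixture_recipe <- function(x, ...) {
  cat(sprintf("<fixture_recipe %s> %d actives (%d series), %d decoys, %s\n",
              x$style, x$n_actives, x$n_series, x$n_decoys,
              sprintf("difficulty %.2f, seed %d", x$difficulty, x$seed)))
  invisible(x)
}

# substitute the {R} site of a template
.fill_template <- function(template, sub) {
  sub("{R}", sub, template, fixed = TRUE)
}

# all framework variants of a template set: bare (chain sub) plus each
# ring substituent
.framework_pool <- function(templates) {
  out <- expand.grid(template = templates,
                     ring_sub = c(NA_character_, .ring_substituents),
                     stringsAsFactors = FALSE)
  out
}

# one molecule of a series: the series fixes (template, ring_sub); the
# analog index picks the chain decoration (prefix on the first template atom)
.series_molecule <- function(template, ring_sub, variant) {
  ns <- length(.chain_substituents)
  pre <- .chain_substituents[(variant - 1L) %% ns + 1L]
  extra <- (variant - 1L) %/% ns
  if (extra > 0L) pre <- paste0(.chain_substituents[(extra - 1L) %% ns + 1L],
                                pre)
  core_sub <- if (is.na(ring_sub)) "C" else ring_sub
  paste0(pre, .fill_template(template, core_sub))
}

#' Generate a synthetic benchmark target
#'
#' Builds a complete `target_dataset` (actives, decoys, internal IDs)
#' according to the recipe's collection style. Molecule SMILES are assembled
#' from the internal template/substituent library:
#' \itemize{
#'   \item Actives are grouped into `n_series` analog series; each series is
#'     a distinct scaffold framework and its analogs differ in acyclic
#'     decorations.
#'   \item MUV-like: actives are MaxMin diversity-picked from a candidate
#'     pool, one per series, and embedded among decoys built from a disjoint
#'     template set.
#'   \item DUD-like: decoys are matched to the heavy-atom counts of the
#'     actives (property matching).
#'   \item ChEMBL-like: exactly two decoys per active are selected from the
#'     decoy pool by the ECFC0 Dice > 0.5 atom-count rule.
#' }
#' The `difficulty` knob is the fraction of decoys drawn from active scaffold
#' templates rather than decoy-only templates.
#'
#' @param recipe a `fixture_recipe`.
#' @param target_id identifier for the generated target (default derived
#'   from the style and seed).
#' @param dataset_name collection token used in internal IDs (default
#'   `"SYN"`).
#' @return a `target_dataset` (without training lists; see
#'   [generate_training_lists()]).
#' @export
generate_target <- function(recipe, target_id = NULL, dataset_name = "SYN") {
  stopifnot(inherits(recipe, "fixture_recipe"))
  if (is.null(target_id))
    target_id <- sprintf("%s%02d", sub("-like$", "", recipe$style),
                         recipe$seed %% 100L)
  with_seed(recipe$seed, {
    ## ---- actives ----
    fw <- .framework_pool(.active_templates)
    fw <- fw[sample.int(nrow(fw)), , drop = FALSE]
    # some (template, ring substituent) combinations coincide as frameworks
    # (e.g. benzene + phenyl = biphenyl); select series with distinct
    # Bemis-Murcko keys so n_series really is the scaffold count
    sel <- integer(0); seen <- character(0)
    for (i in seq_len(nrow(fw))) {
      if (length(sel) == recipe$n_series) break
      rep_smi <- .fill_template(fw$template[i],
                                if (is.na(fw$ring_sub[i])) "C"
                                else fw$ring_sub[i])
      key <- bemis_murcko(rep_smi)
      if (!(key %in% seen)) { sel <- c(sel, i); seen <- c(seen, key) }
    }
    if (length(sel) < recipe$n_series)
      stop(sprintf("n_series = %d exceeds the %d distinct frameworks available",
                   recipe$n_series, length(seen)), call. = FALSE)
    series <- fw[sel, , drop = FALSE]
    per_series <- diff(round(seq(0, recipe$n_actives,
                                 length.out = recipe$n_series + 1L)))
    if (identical(recipe$style, "MUV-like")) {
      # several candidates per series, then MaxMin-pick one per series worth
      cand <- unlist(lapply(seq_len(recipe$n_series), function(s) {
        vapply(1:3, function(v)
          .series_molecule(series$template[s], series$ring_sub[s],
                           sample.int(60, 1)), character(1))
      }))
      cand <- unique(cand)
      actives_smiles <- pick_diverse(cand, recipe$n_actives,
                                     descriptor = "ECFP4", measure = "Dice",
                                     seed = recipe$seed + 1L)
    } else {
      actives_smiles <- unlist(lapply(seq_len(recipe$n_series), function(s) {
        variants <- sample.int(60, per_series[s])
        vapply(variants, function(v)
          .series_molecule(series$template[s], series$ring_sub[s], v),
          character(1))
      }))
    }
    actives_smiles <- unique(actives_smiles)
    # top up if deduplication lost molecules
    guard <- 0L
    while (length(actives_smiles) < recipe$n_actives && guard < 1000L) {
      s <- sample.int(recipe$n_series, 1)
      actives_smiles <- unique(c(actives_smiles,
        .series_molecule(series$template[s], series$ring_sub[s],
                         sample.int(500, 1))))
      guard <- guard + 1L
    }
    actives_smiles <- actives_smiles[seq_len(recipe$n_actives)]

    ## ---- decoy pool ----
    n_hard <- round(recipe$difficulty * recipe$n_decoys)
    n_easy <- recipe$n_decoys - n_hard
    easy_fw <- .framework_pool(.decoy_templates)
    hard_fw <- series   # decoys sharing active scaffold templates
    gen_pool <- function(fwtab, n) {
      if (n == 0L) return(character(0))
      out <- character(0); guard <- 0L
      while (length(out) < n && guard < 50L) {
        need <- n - length(out)
        rows <- sample.int(nrow(fwtab), need, replace = TRUE)
        new <- vapply(seq_len(need), function(q)
          .series_molecule(fwtab$template[rows[q]], fwtab$ring_sub[rows[q]],
                           sample.int(900, 1)), character(1))
        out <- unique(c(out, new))
        guard <- guard + 1L
      }
      out[seq_len(min(n, length(out)))]
    }
    if (identical(recipe$style, "ChEMBL-like")) {
      pool <- unique(c(gen_pool(easy_fw, max(4L * recipe$n_decoys, n_easy)),
                       gen_pool(hard_fw, 4L * n_hard)))
      pool <- setdiff(pool, actives_smiles)
      decoys_smiles <- select_decoys_by_atom_count(
        actives_smiles, pool,
        per_active = max(1L, recipe$n_decoys %/% recipe$n_actives),
        threshold = 0.5, seed = recipe$seed + 2L)
    } else if (identical(recipe$style, "DUD-like")) {
      pool <- setdiff(unique(c(gen_pool(easy_fw, 4L * n_easy),
                               gen_pool(hard_fw, 4L * n_hard))),
                      actives_smiles)
      decoys_smiles <- .match_heavy_atoms(actives_smiles, pool,
                                          recipe$n_decoys)
    } else {
      decoys_smiles <- setdiff(unique(c(gen_pool(easy_fw, n_easy),
                                        gen_pool(hard_fw, n_hard))),
                               actives_smiles)
      if (length(decoys_smiles) < recipe$n_decoys)
        stop("could not generate enough distinct decoys; reduce n_decoys",
             call. = FALSE)
      decoys_smiles <- decoys_smiles[seq_len(recipe$n_decoys)]
    }

    actives <- data.frame(
      external_id = sprintf("SYNA%05d", seq_along(actives_smiles)),
      internal_id = make_internal_id(dataset_name, target_id, "active",
                                     seq_along(actives_smiles) - 1L),
      smiles = actives_smiles, role = "active",
      index = seq_along(actives_smiles) - 1L, smiles_ok = TRUE,
      stringsAsFactors = FALSE)
    decoys <- data.frame(
      external_id = sprintf("SYND%05d", seq_along(decoys_smiles)),
      internal_id = make_internal_id(dataset_name, target_id, "decoy",
                                     seq_along(decoys_smiles) - 1L),
      smiles = decoys_smiles, role = "decoy",
      index = seq_along(decoys_smiles) - 1L, smiles_ok = TRUE,
      stringsAsFactors = FALSE)
    class(actives) <- class(decoys) <- c("compound_list", "data.frame")
    target_dataset(target_id, actives, decoys)
  })
}

# pick decoys whose heavy-atom counts match the actives (round-robin over
# actives, nearest heavy-atom count first)
.match_heavy_atoms <- function(actives_smiles, pool, n_decoys) {
  hv <- function(smis) vapply(smis, function(s) {
    m <- parse_smiles(s); if (is.null(m)) NA_integer_ else m$natoms
  }, integer(1), USE.NAMES = FALSE)
  ha <- hv(actives_smiles); hp <- hv(pool)
  ok <- !is.na(hp); pool <- pool[ok]; hp <- hp[ok]
  if (length(pool) < n_decoys)
    stop("decoy pool too small for heavy-atom matching", call. = FALSE)
  taken <- logical(length(pool))
  out <- character(0)
  i <- 0L
  while (length(out) < n_decoys) {
    a <- ha[(i %% length(ha)) + 1L]
    cand <- which(!taken)
    pick <- cand[which.min(abs(hp[cand] - a))]
    taken[pick] <- TRUE
    out <- c(out, pool[pick])
    i <- i + 1L
  }
  out
}

#' MaxMin diversity picking
#'
#' Greedy MaxMin selection: starting from a seeded random pick, iteratively
#' add the candidate whose minimum distance (1 - similarity) to the already
#' picked set is largest.
#'
#' @param candidates character vector of SMILES.
#' @param k number of compounds to pick.
#' @param descriptor fingerprint name or descriptor used for the distance
#'   (default `"ECFP4"`).
#' @param measure similarity measure (default `"Dice"`).
#' @param seed integer seed for the first pick.
#' @return character vector of `k` picked SMILES.
#' @export
pick_diverse <- function(candidates, k, descriptor = "ECFP4",
                         measure = "Dice", seed = 1L) {
  n <- length(candidates)
  if (k > n) stop(sprintf("cannot pick %d from %d candidates", k, n),
                  call. = FALSE)
  if (k == n) return(candidates)
  fps <- compute_fingerprints(candidates, descriptor)
  ok <- !vapply(fps, is.null, logical(1))
  if (sum(ok) < k) stop("too few parsable candidates", call. = FALSE)
  cand_idx <- which(ok)
  first <- with_seed(seed, sample(cand_idx, 1))
  picked <- first
  # min distance of every candidate to the picked set, updated incrementally
  mind <- rep(Inf, n)
  repeat {
    last <- picked[length(picked)]
    for (i in cand_idx) {
      if (i %in% picked) next
      d <- 1 - similarity(fps[[last]], fps[[i]], measure)
      if (d < mind[i]) mind[i] <- d
    }
    if (length(picked) == k) break
    rest <- setdiff(cand_idx, picked)
    picked <- c(picked, rest[which.max(mind[rest])])
  }
  candidates[picked]
}

#' Select decoys by the atom-count similarity rule
#'
#' For each active, decoys are sampled without replacement from the pool
#' members whose ECFC0 (atom-count fingerprint) Dice similarity to that
#' active exceeds `threshold`. Each pool molecule is used at most once.
#'
#' @param actives character vector of active SMILES.
#' @param pool character vector of candidate decoy SMILES.
#' @param per_active decoys per active (default 2).
#' @param threshold Dice similarity threshold (default 0.5, exclusive).
#' @param seed integer seed.
#' @return character vector of `per_active * length(actives)` decoy SMILES.
#' @export
select_decoys_by_atom_count <- function(actives, pool, per_active = 2L,
                                        threshold = 0.5, seed = 1L) {
  fpa <- compute_fingerprints(actives, "ECFC0")
  fpp <- compute_fingerprints(pool, "ECFC0")
  ok <- !vapply(fpp, is.null, logical(1))
  with_seed(seed, {
    taken <- logical(length(pool))
    out <- character(0)
    for (a in seq_along(actives)) {
      if (is.null(fpa[[a]]))
        stop("unparsable active SMILES: ", actives[a], call. = FALSE)
      sims <- vapply(seq_along(pool), function(p) {
        if (!ok[p] || taken[p]) return(-1)
        similarity(fpa[[a]], fpp[[p]], "Dice")
      }, numeric(1))
      elig <- which(sims > threshold)
      if (length(elig) < per_active)
        stop(sprintf(paste0("fewer than %d eligible decoys (ECFC0 Dice > ",
                            "%g) for active '%s'"),
                     per_active, threshold, actives[a]), call. = FALSE)
      pick <- if (length(elig) == per_active) elig else
        sample(elig, per_active)
      taken[pick] <- TRUE
      out <- c(out, pool[pick])
    }
    out
  })
}

#' Filter compounds by molecular weight and metal content
#'
#' Curation rule applied when assembling benchmark sets: molecules with a
#' molecular weight above `mw_max` (default 700 g/mol) or containing a metal
#' atom are removed. Unparsable records are kept (they are flagged, not
#' curated).
#'
#' @param records a `compound_list` data.frame.
#' @param mw_max molecular-weight cutoff in g/mol.
#' @param exclude_metals drop molecules with atoms outside the documented
#'   non-metal set.
#' @return the filtered `compound_list` (indices are *not* renumbered; the
#'   filter precedes list writing in the curation flow).
#' @export
filter_compounds <- function(records, mw_max = 700, exclude_metals = TRUE) {
  keep <- vapply(seq_len(nrow(records)), function(i) {
    m <- suppressWarnings(parse_smiles(records$smiles[i]))
    if (is.null(m)) return(TRUE)   # flagged elsewhere, not curated here
    if (mol_weight(m) > mw_max) return(FALSE)
    if (exclude_metals && contains_metal(m)) return(FALSE)
    TRUE
  }, logical(1))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
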