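# synthetic compound-set generation and the curation operators

test_that("generated targets are valid, deterministic and style-shaped", {
  rec <- fixture_recipe("DUD-like", n_actives = 10, n_decoys = 40,
                        n_series = 3, difficulty = 0, seed = 17)
  ds <- generate_target(rec)
  expect_s3_class(ds, "target_dataset")
  expect_equal(nrow(ds$actives), 10L)
  expect_equal(nrow(ds$decoys), 40L)
  # every SMILES parses
  for (s in c(ds$actives$smiles, ds$decoys$smiles))
    expect_false(is.null(parse_smiles(s)))
  # internal IDs follow the scheme with 0-based file-order numbering
  p <- parse_internal_id(ds$actives$internal_id)
  expect_equal(p$number, ds$actives$index)
  expect_true(all(p$role == "active"))
  # determinism: same recipe, byte-identical lists
  ds2 <- generate_target(rec)
  expect_identical(ds$actives$smiles, ds2$actives$smiles)
  expect_identical(ds$decoys$smiles, ds2$decoys$smiles)
  # a different seed gives different molecules
  ds3 <- generate_target(fixture_recipe("DUD-like", n_actives = 10,
                                        n_decoys = 40, n_series = 3,
                                        seed = 18))
  expect_false(identical(ds$actives$smiles, ds3$actives$smiles))
})

test_that("one series per active yields a scaffolds/actives ratio of 1", {
  rec <- fixture_recipe("DUD-like", n_actives = 30, n_decoys = 10,
                        n_series = 30, seed = 5)
  ds <- generate_target(rec)
  s <- dataset_scaffold_summary(ds$actives$smiles)
  expect_equal(s$n_scaffolds, 30L)
  expect_equal(s$ratio, 1.0)
  # few series -> few scaffolds
  rec2 <- fixture_recipe("DUD-like", n_actives = 12, n_decoys = 10,
                         n_series = 2, seed = 5)
  s2 <- dataset_scaffold_summary(generate_target(rec2)$actives$smiles)
  expect_lte(s2$n_scaffolds, 2L)
})

test_that("ChEMBL-like fixtures carry two atom-count-matched decoys per active", {
  rec <- fixture_recipe("ChEMBL-like", n_actives = 15, n_series = 15,
                        seed = 23)
  expect_equal(rec$n_decoys, 30L)
  ds <- generate_target(rec)
  expect_equal(nrow(ds$decoys), 30L)
  # re-check the selection rule: every decoy passes ECFC0 Dice > 0.5
  # against at least one active
  fa <- compute_fingerprints(ds$actives$smiles, "ECFC0")
  for (dsmi in ds$decoys$smiles) {
    fd <- compute_fingerprint(dsmi, "ECFC0")
    best <- max(vapply(fa, similarity, numeric(1), y = fd))
    expect_gt(best, 0.5)
  }
})

test_that("MaxMin diversity picking prefers spread-out candidates", {
  # 3 identical + 1 distinct: the distinct molecule must be picked
  cand <- c("CCO", "CCO", "CCO", "c1ccc2ccccc2c1")
  picked <- pick_diverse(cand, 2, seed = 3)
  expect_true("c1ccc2ccccc2c1" %in% picked)
  # k = all returns everything
  expect_equal(pick_diverse(cand, 4), cand)
  expect_error(pick_diverse(cand, 5), "cannot pick")
  # picked sets dominate random subsets in minimum pairwise distance
  rec <- fixture_recipe("DUD-like", n_actives = 20, n_decoys = 5,
                        n_series = 10, seed = 2)
  pool <- generate_target(rec)$actives$smiles
  min_pair_dist <- function(smis) {
    fps <- compute_fingerprints(smis, "ECFP4")
    combs <- utils::combn(length(fps), 2)
    min(apply(combs, 2, function(ij)
      1 - similarity(fps[[ij[1]]], fps[[ij[2]]], "Dice")))
  }
  d_picked <- min_pair_dist(pick_diverse(pool, 5, seed = 4))
  d_random <- with_seed(8, replicate(20, min_pair_dist(sample(pool, 5))))
  expect_gte(d_picked, max(d_random))
})

test_that("decoy selection by atom-count similarity enforces its threshold", {
  actives <- c("CCO", "CCCO")
  pool <- c("CCO", "OCC", "CC(C)O", "CCCCO", "C(O)CC", "CCN")
  dec <- select_decoys_by_atom_count(actives, pool, per_active = 2,
                                     threshold = 0.5, seed = 1)
  expect_length(dec, 4L)
  expect_equal(anyDuplicated(dec), 0L)   # pool sampled without replacement
  # disjoint element composition: nothing is eligible
  expect_error(select_decoys_by_atom_count("CCO", c("[SiH4]", "BrBr"),
                                           per_active = 1),
               "fewer than 1 eligible")
})

test_that("compound filtering removes heavy and metal-containing molecules", {
  smis <- c("c1ccccc1",                        # benzene, retained
            "CC(=O)Oc1ccccc1C(=O)O",           # aspirin, retained
            paste(rep("C", 60), collapse = ""),# MW >> 700, removed
            "CC[Pb](CC)(CC)CC",                # metal, removed
            "c1ccncc1",                        # retained
            "CCCCCCCC",                        # retained
            paste(rep("O", 1) , "C(F)(F)F", sep = ""), # retained
            paste0("C1CCCCC1", ""),            # retained
            "[Si](C)(C)(C)C",                  # silicon is a non-metal here
            "CC[Sn](CC)(CC)CC")                # metal, removed
  rec <- data.frame(external_id = sprintf("E%d", seq_along(smis)),
                    internal_id = make_internal_id("SYN", "T", "active",
                                                   seq_along(smis) - 1),
                    smiles = smis, role = "active",
                    index = seq_along(smis) - 1, smiles_ok = TRUE,
                    stringsAsFactors = FALSE)
  out <- filter_compounds(rec)
  expect_equal(nrow(out), 7L)
  expect_false(any(grepl("Pb|Sn", out$smiles)))
  expect_true("c1ccccc1" %in% out$smiles)
  # molecular-weight check against a hand value: benzene = 78.1 g/mol
  expect_equal(mol_weight(parse_smiles("c1ccccc1")), 78.11, tolerance = 1e-3)
})

test_that("recipes validate their invariants", {
  expect_error(fixture_recipe("DUD-like", n_actives = 5, n_series = 10))
  expect_error(fixture_recipe("DUD-like", difficulty = 2))
  r <- fixture_recipe("MUV-like")
  expect_equal(r$n_actives, 30L)
  expect_equal(r$n_decoys, 15000L)
  expect_equal(r$n_series, 30L)
})
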