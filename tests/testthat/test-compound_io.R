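# compound lists, internal IDs and training lists

test_that("compound lists round-trip with sequential 0-based indices", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("# header comment",
               "CHEMBL12345 ChEMBL_28_A_0 c1ccccc1",
               "CHEMBL99    ChEMBL_28_A_1 CCO",
               "CHEMBL7     ChEMBL_28_A_2 Cc1ccccc1"), path)
  rec <- read_compound_list(path, "active")
  expect_s3_class(rec, "compound_list")
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$external_id[1], "CHEMBL12345")
  expect_equal(rec$internal_id[1], "ChEMBL_28_A_0")
  expect_equal(rec$index, 0:2)
  expect_true(all(rec$role == "active"))
  expect_true(all(rec$smiles_ok))

  out <- withr::local_tempfile(fileext = ".smi")
  write_compound_list(rec, out)
  again <- read_compound_list(out, "active")
  expect_equal(again, rec)

  # gzip transparency
  gz <- withr::local_tempfile(fileext = ".smi.gz")
  write_compound_list(rec, gz)
  expect_equal(read_compound_list(gz, "active"), rec)
})

test_that("empty and malformed compound files are handled explicitly", {
  empty <- withr::local_tempfile(fileext = ".smi")
  writeLines(character(0), empty)
  expect_equal(nrow(read_compound_list(empty, "decoy")), 0L)

  bad <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("ID1 SYN_T_A_0 CCO", "just_two_fields x"), bad)
  expect_error(read_compound_list(bad, "active"), "line 2")
})

test_that("unparsable SMILES are flagged and retained, not dropped", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("A SYN_T_A_0 CCO", "B SYN_T_A_1 C1CC", "C SYN_T_A_2 CCN"),
             path)
  expect_warning(rec <- read_compound_list(path, "active"), "failed to parse")
  expect_equal(nrow(rec), 3L)        # record kept
  expect_equal(rec$smiles_ok, c(TRUE, FALSE, TRUE))
})

test_that("internal IDs encode dataset, target, role and 0-based number", {
  ids <- make_internal_id("ChEMBL", "28", "active", 0:2)
  expect_equal(ids[1], "ChEMBL_28_A_0")
  parsed <- parse_internal_id(ids)
  expect_equal(parsed$dataset, rep("ChEMBL", 3))
  expect_equal(parsed$role, rep("active", 3))
  expect_equal(parsed$number, 0:2)
  expect_equal(parse_internal_id("MUV_466_D_15000")$role, "decoy")
  expect_error(parse_internal_id("no-scheme-here"), "malformed")
})

test_that("training lists sample the configured sizes and partition the set", {
  ds <- make_tiny_dataset(n_act = 8, n_dec = 20, repetitions = 6,
                          n_queries = 3)
  tr <- generate_training_lists(ds, n_queries = 3, decoy_fraction = 0.2,
                                repetitions = 6, seed = 9)
  expect_length(tr, 6L)
  for (tl in tr) {
    expect_equal(nrow(tl$query_actives), 3L)
    expect_equal(nrow(tl$training_decoys), round(0.2 * 20))
    # partition: queries within actives, training decoys within decoys,
    # no overlap between the two ID sets
    expect_true(all(tl$query_actives$internal_id %in%
                      ds$actives$internal_id))
    expect_true(all(tl$training_decoys$internal_id %in%
                      ds$decoys$internal_id))
    expect_length(intersect(tl$query_actives$internal_id,
                            tl$training_decoys$internal_id), 0L)
  }
  # determinism and seed sensitivity
  expect_identical(tr, generate_training_lists(ds, 3, 0.2, 6, seed = 9))
  expect_false(identical(tr, generate_training_lists(ds, 3, 0.2, 6,
                                                     seed = 10)))
})

test_that("training-list generation rejects invalid configurations", {
  ds <- make_tiny_dataset(n_act = 5, n_dec = 10)
  expect_error(generate_training_lists(ds, n_queries = 5), "smaller than")
  expect_error(generate_training_lists(ds, n_queries = 2,
                                       decoy_fraction = 0), "between 0 and 1")
  # boundary: n_queries = actives - 1 leaves exactly one test active
  tr <- generate_training_lists(ds, n_queries = 4, decoy_fraction = 0.2,
                                repetitions = 1, seed = 3)
  expect_equal(nrow(tr[[1]]$query_actives), 4L)
})

test_that("training lists round-trip through JSON-lines and are validated", {
  ds <- make_tiny_dataset(repetitions = 5)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_training_lists(ds$training, path)
  back <- read_training_lists(path, ds)
  expect_equal(back, ds$training)

  # out-of-range index -> validation error
  broken <- ds$training
  broken[[1]]$training_decoys$index[1] <- 10000L
  path2 <- withr::local_tempfile(fileext = ".jsonl")
  write_training_lists(broken, path2)
  expect_error(read_training_lists(path2, ds), "decoy index")
  # without a dataset the file is read as-is (degenerate lists accepted)
  expect_length(read_training_lists(path2), 5L)
})
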