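# shared in-code fixtures: no files are stored, everything is built here

# a small set of drug-like molecules used across fingerprint/similarity tests
fixture_smiles <- c(
  "CCO", "Cc1ccccc1", "c1ccccc1", "Cc1ccc(O)cc1", "Cc1ccc(N)cc1",
  "CCOC(=O)c1ccccc1", "c1ccc2[nH]ccc2c1", "O=C(N)c1cccnc1",
  "Clc1ccc(CN2CCOCC2)cc1", "CC(C)Cc1ccc(C(C)C(=O)O)cc1"
)

# deterministic hand-built target: n_act actives as two analog series plus
# unrelated decoys; structurally trivial but valid
make_tiny_dataset <- function(n_act = 8, n_dec = 24, target_id = "T1",
                              repetitions = 4, n_queries = 3, seed = 42) {
  subs <- c("C", "CC", "CCC", "O", "OC", "N", "F", "Cl", "CO", "CN",
            "CCO", "C(C)C")
  act <- c(sprintf("%sc1ccc(C)cc1", subs), sprintf("%sc1ccc2[nH]ccc2c1", subs))
  dec <- c(sprintf("%sC1CCCCC1", subs), sprintf("%sC1CCNCC1", subs),
           sprintf("%sc1ccncc1", subs), sprintf("%sC1CCOCC1", subs))
  act <- unique(act)[seq_len(n_act)]
  dec <- unique(dec)[seq_len(n_dec)]
  mk <- function(smis, role) {
    df <- data.frame(
      external_id = sprintf("EXT%s%03d", toupper(substr(role, 1, 1)),
                            seq_along(smis)),
      internal_id = make_internal_id("SYN", target_id, role,
                                     seq_along(smis) - 1L),
      smiles = smis, role = role, index = seq_along(smis) - 1L,
      smiles_ok = TRUE, stringsAsFactors = FALSE)
    class(df) <- c("compound_list", "data.frame")
    df
  }
  ds <- target_dataset(target_id, mk(act, "active"), mk(dec, "decoy"))
  ds$training <- generate_training_lists(ds, n_queries = n_queries,
                                         decoy_fraction = 0.25,
                                         repetitions = repetitions,
                                         seed = seed)
  ds
}

# brute-force pair-counting AUC oracle (Mann-Whitney), independent of auc()
auc_oracle <- function(labels) {
  act <- which(labels); inact <- which(!labels)
  correct <- 0; total <- 0
  for (a in act) for (i in inact) {
    total <- total + 1
    if (a < i) correct <- correct + 1
  }
  correct / total
}

# random sparse bit-string fingerprint
random_fpvec <- function(len = 64, density = 0.3) {
  idx <- which(stats::runif(len) < density) - 1L
  if (length(idx) == 0L) idx <- sample.int(len, 1) - 1L
  fpvec(idx, kind = "bitstring", length = len)
}

# build a ranked_screen_result directly from a label vector (best first)
result_from_labels <- function(labels, target = "T", fp = "FP", rep = 0) {
  n <- length(labels)
  ranked_screen_result(target, fp, rep,
                       similarity = seq(1, 0, length.out = n),
                       internal_id = sprintf("%s_%s_%s_%d", "SYN", target,
                                             ifelse(labels, "A", "D"),
                                             seq_len(n) - 1L),
                       is_active = labels)
}
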