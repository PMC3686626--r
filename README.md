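# fpbench

An open benchmarking platform for ligand-based virtual screening (VS) with
2D molecular fingerprints.

Retrospective VS benchmarks rank a library of known actives and presumed
inactives (decoys) by their fingerprint similarity to a small set of query
actives, and ask how well each fingerprint concentrates the actives at the
top of the list. `fpbench` provides the complete three-stage experiment —
**scoring**, **validation**, **analysis** — for R users who want to compare
fingerprints, similarity measures or evaluation metrics under controlled,
fully reproducible conditions, without depending on any external compound
download: a synthetic-fixture generator emulates the curation styles of the
common public benchmark collections.

## What it computes

**Scoring.** For each of R repetitions (default 50), a target's test set
(all actives except the queries, all decoys except a training fraction) is
ranked by MAX group fusion: each test molecule scores its highest similarity
to any of the query actives. Fourteen fingerprints are registered (MACCS,
AP, TT, RDK5, Avalon/lAvalon, ECFP4/6, lECFP4/6, FCFP4, ECFC4, FCFC4,
ECFC0), and eight similarity measures (Dice — the default — Tanimoto,
Cosine, Russel, Kulczynski, McConnaughey, Manhattan, Rogot–Goldberg). The
registry is user-extensible with `register_fingerprint()`.

**Validation.** Ranked lists are summarized by standard early-recognition
metrics. With *n* actives among *N* test molecules and *r_i* the rank of
the *i*-th active:

- ROC area `AUC` — fraction of (active, inactive) pairs ordered correctly;
  0.5 is random.
- Enrichment factor `EF(χ) = Σ_i [r_i ≤ χN] / (χ n)`, bounded by
  `min(1/χ, N/n)`.
- Robust initial enhancement
  `RIE(α) = Σ_i exp(−α r_i/N) / ⟨·⟩_random`, with the analytic random
  average `(n/N)(1−e^{−α})/(e^{α/N}−1)`.
- `BEDROC(α) = (RIE − RIE_min)/(RIE_max − RIE_min)`, the min–max rescaling
  of RIE onto [0, 1] using the closed-form bounds.

**Analysis.** Within each repetition the fingerprints are ranked (average
ranks on ties); per-target mean ranks feed a tie-corrected global Friedman
test across targets, followed by post-hoc pairwise Friedman comparisons:
the 50 repetition ranks are bootstrap-resampled 100 times, each replicate's
pairwise p-values are multiplicity-adjusted by a resampling maxT scheme,
and each fingerprint pair is categorized from its 100 adjusted p-values
("-" all below α = 0.05, "X" all above, "o" mixed). Linear-regression
summaries (`slope`, `intercept`, `r`, `r²`, `RMSE`) correlate methods or
fingerprints across targets, and Bemis–Murcko scaffold analysis adds the
scaffold enrichment factor, the scaffold-hopping analogue of EF.

## Worked example

```r
library(fpbench)

recipe <- fixture_recipe("DUD-like", n_actives = 12, n_decoys = 60,
                         n_series = 3, seed = 7)
ds <- generate_target(recipe)
ds$training <- generate_training_lists(ds, n_queries = 5,
                                       repetitions = 10, seed = 1)
results <- c(score_target(ds, "ECFP4", "Dice", seed = 1),
             score_target(ds, "ECFC0", "Dice", seed = 1))
values <- evaluate(results, list(metric_spec("AUC"),
                                 metric_spec("BEDROC", 20),
                                 metric_spec("EF", 0.05)))
average_performance(values)
#>  target     method fingerprint mean_value
#>   DUD07        AUC       ECFC0  0.6863095
#>   DUD07        AUC       ECFP4  0.9077381
#>   DUD07 BEDROC(20)       ECFC0  0.2083150
#>   DUD07 BEDROC(20)       ECFP4  0.9441226
#>   DUD07   EF(0.05)       ECFC0  0.5714286
#>   DUD07   EF(0.05)       ECFP4  5.7142857
```

The synthetic target holds three analog series of actives among unrelated
decoys. ECFP4, a circular fingerprint that sees full atom environments,
ranks the test actives far better (AUC 0.91, BEDROC(20) 0.94) than the
baseline atom-count fingerprint ECFC0 (AUC 0.69, BEDROC(20) 0.21); an
EF(5%) of 5.7 means ECFP4 retrieves 5.7 times more actives in the top 5%
of the list than a random ranking would. Scaffold composition of the
actives:

```r
dataset_scaffold_summary(ds$actives$smiles)
#> scaffolds: 3  (BMS/actives = 0.25)
```

Multi-target runs work through file interfaces (`run_fixtures()`,
`run_score()`, `run_validate()`, `run_analyze()`), or from a shell via the
thin CLI wrapper:

```sh
Rscript inst/cli/fpbench.R fixtures -o work/fix --targets 4 --repetitions 10
Rscript inst/cli/fpbench.R score    -i work/fix -o work/scores -f fps.txt -s Dice
Rscript inst/cli/fpbench.R validate -i work/scores -o work/values.csv -m methods.txt
Rscript inst/cli/fpbench.R analyze  -i work/values.csv -o work/analysis
```

## File formats

- **Compound list** (`*.smi`): whitespace-separated text, `#` comments,
  optionally gzipped; per line `external_id internal_id SMILES`. Internal
  IDs follow `<dataset>_<target>_<A|D>_<number>` with 0-based, file-order
  numbering, e.g.

  ```
  CHEMBL12345 ChEMBL_28_A_0 c1ccccc1
  ```

- **Training list** (`*_training.jsonl`): one JSON object per repetition
  with `repetition`, `query_actives`, `training_decoys` (internal ID +
  list index each).
- **Scored list** (`*_scores.jsonl`): one JSON object per
  (fingerprint, repetition) with parallel `similarity`, `internal_id`,
  `is_active` arrays; externally produced files in this schema are accepted
  by the validation stage.
- **Configs**: fingerprint names one per line; evaluation methods as
  `NAME [parameter]` lines (`AUC`, `EF 0.05`, `BEDROC 20`).

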