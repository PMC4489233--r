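M15 <- strrep("M", 15)

test_that("segment overlap boundary sits exactly at five residues", {
  ref <- paste0(strrep("i", 5), M15, strrep("o", 20))     # helix 6..20
  pred5 <- paste0(strrep("i", 15), M15, strrep("o", 10))  # helix 16..30
  pred4 <- paste0(strrep("i", 16), M15, strrep("o", 9))   # helix 17..31
  expect_true(topology_correct(ref, pred5))
  expect_false(topology_correct(ref, pred4))
  # the threshold is configurable and monotone
  expect_false(topology_correct(ref, pred5, min_overlap = 6))
  expect_true(topology_correct(ref, pred4, min_overlap = 4))
  expect_error(topology_correct(ref, paste0(ref, "o")), "does not match")
})

test_that("termini orientation and SP presence are enforced", {
  ref <- paste0(strrep("i", 5), M15, strrep("o", 5))
  inverted <- paste0(strrep("o", 5), M15, strrep("i", 5))
  expect_false(topology_correct(ref, inverted))
  expect_true(topology_correct(ref, inverted, require_termini = FALSE))

  # SP prefix is skipped when reading the N-terminal side
  ref_sp <- paste0(strrep("S", 10), strrep("o", 5), M15, strrep("i", 5))
  pred_sp <- paste0(strrep("S", 14), "o", M15, strrep("i", 5))
  expect_true(topology_correct(ref_sp, pred_sp))
  # missing SP fails even with matching helix
  no_sp <- paste0(strrep("o", 15), M15, strrep("i", 5))
  expect_false(topology_correct(ref_sp, no_sp))

  # globular references are judged on absences only, not loop side
  expect_true(topology_correct(strrep("i", 30), strrep("o", 30)))
  expect_false(topology_correct(strrep("i", 30),
                                paste0(strrep("i", 8), M15, strrep("o", 7))))
})

test_that("reflexivity: every valid topology is correct against itself", {
  truth <- simulate_proteins(150, sim_config(), seed = 13)
  for (t in truth$topology) expect_true(topology_correct(t, t))
})

test_that("raising min_overlap only flips correct to incorrect", {
  cfg <- sim_config()
  truth <- simulate_proteins(100, cfg, seed = 19)
  preds <- perturb_predictions(truth, cfg, n_methods = 1, seed = 20)
  for (k in seq_len(nrow(truth))) {
    verdicts <- vapply(1:8, function(mo) {
      topology_correct(truth$topology[k], preds$topology[k], min_overlap = mo)
    }, logical(1))
    expect_true(all(diff(as.integer(verdicts)) <= 0))
  }
})

test_that("error taxonomy matches its definitions on constructed pairs", {
  # SP region predicted as membrane helix (and vice versa)
  ref_sp <- paste0(strrep("S", 10), strrep("o", 30))
  pred_m <- paste0("i", M15, strrep("o", 24))
  expect_equal(as.character(judge_topology(ref_sp, pred_m)$error_kind),
               "TM_SP_CONFUSION")
  ref_m <- paste0(strrep("i", 5), M15, strrep("o", 20))
  pred_s <- paste0(strrep("S", 20), strrep("o", 20))
  expect_equal(as.character(judge_topology(ref_m, pred_s)$error_kind),
               "TM_SP_CONFUSION")
  # SP disagreement far from any helix is SP/non-TM, not cross-prediction
  ref_deep <- paste0(strrep("i", 100), M15, strrep("o", 20))
  pred_deep_sp <- paste0(strrep("S", 20), strrep("o", 80), M15, strrep("i", 20))
  expect_equal(as.character(judge_topology(ref_deep, pred_deep_sp)$error_kind),
               "SP_NONTM_CONFUSION")
  # extra helix with matching class: wrong topology
  ref2 <- paste0(strrep("i", 5), M15, strrep("o", 25))
  pred3 <- paste0(strrep("i", 5), M15, strrep("o", 5), M15, strrep("i", 5))
  j <- judge_topology(ref2, pred3)
  expect_equal(as.character(j$error_kind), "WRONG_TOPOLOGY")
  expect_equal(as.character(j$ref_class), as.character(j$pred_class))
  # globular agreement
  expect_equal(as.character(judge_topology(strrep("i", 30),
                                           strrep("i", 30))$error_kind),
               "CORRECT")
  # SP+TM read as globular counts as SP/non-TM (footnote definition)
  ref_sptm <- paste0(strrep("S", 10), strrep("o", 5), M15, strrep("i", 5))
  expect_equal(as.character(judge_topology(ref_sptm,
                                           strrep("o", 35))$error_kind),
               "SP_NONTM_CONFUSION")
  # membrane protein read as globular
  expect_equal(as.character(judge_topology(ref_m,
                                           strrep("i", 40))$error_kind),
               "TM_NONTM_CONFUSION")
})

test_that("error kinds are mutually exclusive and exhaustive", {
  cfg <- sim_config()
  truth <- simulate_proteins(200, cfg, seed = 23)
  preds <- perturb_predictions(truth, cfg, n_methods = 2, seed = 24)
  joined <- dplyr::left_join(preds, truth[, c("protein_id", "topology")],
                             by = "protein_id", suffix = c("_pred", "_ref"))
  out <- evaluate_topologies(data.frame(protein_id = joined$protein_id,
                                        ref = joined$topology_ref,
                                        pred = joined$topology_pred))
  expect_false(anyNA(out$error_kind))
  expect_equal(out$correct, out$error_kind == "CORRECT")
})

test_that("benchmark aggregation is an exact tally", {
  truth <- simulate_proteins(120, sim_config(), seed = 29)
  cfg <- sim_config()
  preds <- perturb_predictions(truth, cfg, n_methods = 1, seed = 30)
  dat <- data.frame(protein_id = truth$protein_id, ref = truth$topology,
                    pred = preds$topology)
  bm <- topology_benchmark(dat)
  expect_equal(sum(bm$by_class$n), 120L)
  expect_equal(sum(bm$confusion$n), 120L)
  # confusion rows sum to the class counts exactly
  rowsum <- tapply(bm$confusion$n, bm$confusion$ref_class, sum)
  expect_equal(as.integer(rowsum[as.character(bm$by_class$ref_class)]),
               bm$by_class$n)
  # row percentages sum to 100 within rounding
  pctsum <- tapply(bm$confusion$pct, bm$confusion$ref_class, sum)
  expect_true(all(is.na(pctsum) | abs(pctsum - 100) < 1e-9))
  # identical predictions give an all-diagonal matrix
  bm_id <- topology_benchmark(data.frame(protein_id = truth$protein_id,
                                         ref = truth$topology,
                                         pred = truth$topology))
  expect_true(all(bm_id$outcomes$correct))
  off <- bm_id$confusion[as.character(bm_id$confusion$ref_class) !=
                           as.character(bm_id$confusion$pred_class), ]
  expect_true(all(off$n == 0L))
  expect_equal(glance(bm_id)$pct_correct, 100)
  expect_error(topology_benchmark(dat[0, ]), "empty")
})

test_that("tidiers and plots expose the benchmark", {
  truth <- simulate_proteins(40, sim_config(), seed = 31)
  bm <- topology_benchmark(data.frame(protein_id = truth$protein_id,
                                      ref = truth$topology,
                                      pred = truth$topology))
  expect_named(tidy(bm), c("ref_class", "n", "n_correct", "pct_correct"))
  expect_equal(glance(bm)$n_proteins, 40L)
  expect_s3_class(autoplot(bm), "ggplot")
})
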