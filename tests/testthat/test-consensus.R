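test_that("profile columns are exact voting fractions", {
  preds <- c(a = "MMi", b = "MMi", c = "MMo", d = "iMo", e = "iMi")
  prof <- topo_profile(preds)
  expect_equal(prof$n_methods, 5L)
  expect_equal(unname(prof$fractions[1L, ]), c(0, 3, 2, 0) / 5)
  expect_equal(unname(prof$fractions[2L, ]), c(0, 5, 0, 0) / 5)
  expect_equal(unname(prof$fractions[3L, ]), c(0, 0, 3, 2) / 5)
  expect_true(all(abs(rowSums(prof$fractions) - 1) < 1e-12))

  one <- topo_profile(rep("iMo", 4))
  expect_true(all(one$fractions %in% c(0, 1)))

  expect_error(topo_profile(c(x = "iiiiiiiiii", y = "iiiiiiiiiii")),
               "'y' has length 11, expected 10")
  expect_error(topo_profile(character()), "at least one prediction")

  td <- tidy(prof)
  expect_equal(nrow(td), 3L * 4L)
  expect_equal(sum(td$fraction), 3)
})

test_that("path scoring matches closed forms and direct summation", {
  t <- paste0("iii", strrep("M", 15), "ooo")
  prof <- topo_profile(rep(t, 3))
  # one-hot matching path: score -> 0 as epsilon -> 0
  expect_equal(score_topology(prof, t, 1e-9), 0, tolerance = 1e-7)
  expect_equal(score_topology(prof, t, 0), 0)
  # uniform profile: constant log(0.25 + smoothing) for any path
  unif <- topo_profile(c("iiii", "oooo", "MMMM", "SSSS"))
  eps <- 1e-6
  expect_equal(score_topology(unif, "iMoS", eps),
               log((0.25 + eps) / (1 + 4 * eps)))
  expect_equal(score_topology(unif, "iiii", eps),
               score_topology(unif, "SoMi", eps))
  # arbitrary fixture equals the independent per-column oracle
  set.seed(42)
  for (rep in 1:20) {
    prof <- random_profile(sample(3:12, 1), sample(3:7, 1))
    topo <- paste(sample(topo_labels, prof$length, replace = TRUE), collapse = "")
    expect_equal(score_topology(prof, topo, eps),
                 oracle_score(prof$fractions, topo, eps), tolerance = 1e-12)
  }
  expect_error(score_topology(prof, "ii"), "does not match profile length")
})

test_that("decoder reproduces unanimous predictions and majority votes", {
  truth <- simulate_proteins(30, sim_config(), seed = 5)
  for (t in truth$topology) {
    res <- decode_consensus(topo_profile(rep(t, 5)))
    expect_identical(res$topology, t)
    expect_true(all(res$agreement == 1))
    # reported score is the score of the reported path
    expect_equal(res$log_score,
                 score_topology(topo_profile(rep(t, 5)), res$topology, 1e-6),
                 tolerance = 1e-12)
  }
  # 2-vs-1 all-i against all-o: no mixed path is grammar-valid without a
  # membrane crossing, so majority wins everywhere
  res <- decode_consensus(topo_profile(c(strrep("i", 20), strrep("i", 20),
                                         strrep("o", 20))))
  expect_identical(res$topology, strrep("i", 20))
  expect_equal(res$agreement, rep(2 / 3, 20))
})

test_that("decoded consensus is always grammar-valid and deterministic", {
  set.seed(99)
  g <- relaxed_grammar()
  for (rep in 1:50) {
    prof <- random_profile(sample(4:10, 1), sample(3:7, 1))
    res <- decode_consensus(prof, g)
    expect_true(is_valid_topology(res$topology, g))
    res2 <- decode_consensus(prof, g)
    expect_identical(res$topology, res2$topology)
    expect_identical(res$log_score, res2$log_score)
  }
})

test_that("DP score matches exhaustive enumeration on small profiles", {
  set.seed(123)
  g <- relaxed_grammar()
  eps <- 1e-6
  for (rep in 1:40) {
    prof <- random_profile(sample(4:10, 1), sample(3:7, 1))
    res <- decode_consensus(prof, g, eps)
    best <- oracle_best(prof, g, eps)
    expect_equal(res$log_score, best$score, tolerance = 1e-12)
    expect_true(res$topology %in% best$argmax)
  }
})

test_that("DP result dominates random grammar-valid alternatives", {
  set.seed(77)
  g <- relaxed_grammar()
  prof <- random_profile(9, 5)
  res <- decode_consensus(prof, g)
  cand <- enumerate_valid_topologies(9L, g)
  alt <- sample(cand, min(1000L, length(cand)))
  for (a in alt) {
    expect_lte(score_topology(prof, a, 1e-6), res$log_score + 1e-12)
  }
})

test_that("smoothing is inert when the profile has no zeros", {
  # zero-free profiles with an unambiguous optimum: seven methods vote for a
  # valid topology, one method each votes for the three remaining labels at
  # every column, giving fractions 0.7/0.1/0.1/0.1
  g <- relaxed_grammar()
  truth <- simulate_proteins(
    10, sim_config(helix_len_range = c(3L, 6L), loop_len_range = c(1L, 5L),
                   sp_len_range = c(2L, 6L), globular_len_range = c(4L, 12L),
                   grammar = g),
    seed = 7)
  for (t in truth$topology) {
    labsets <- vapply(split_t <- strsplit(t, "")[[1]], function(l) {
      setdiff(topo_labels, l)
    }, character(3))
    dissent <- apply(labsets, 1, paste, collapse = "")
    prof <- topo_profile(c(rep(t, 7), dissent))
    expect_true(all(prof$fractions > 0))
    expect_identical(decode_consensus(prof, g, 1e-6)$topology, t)
    expect_identical(decode_consensus(prof, g, 0)$topology, t)
  }
})

test_that("unanimous columns are kept when an on-label path is feasible", {
  # all methods agree except on a stretch where one dissents; the consensus
  # must follow the unanimous labels
  t <- paste0(strrep("i", 10), strrep("M", 15), strrep("o", 10))
  dissent <- paste0(strrep("i", 10), strrep("M", 15), strrep("i", 10))
  res <- decode_consensus(topo_profile(c(t, t, t, t, dissent)))
  expect_identical(res$topology, t)
})

test_that("consensus_topology wraps per-protein decoding tidily", {
  truth <- simulate_proteins(10, sim_config(), seed = 3)
  preds <- perturb_predictions(truth, quiet_sim_config(), seed = 4)
  out <- consensus_topology(preds)
  expect_equal(out$protein_id, truth$protein_id)
  expect_identical(out$topology, truth$topology)   # noise-free methods
  expect_true(all(out$n_methods == 5L))
  expect_true(all(out$mean_agreement == 1))
  expect_error(consensus_topology(preds[0, ]), "empty prediction table")
})

test_that("decoder honours allow_globular_paths and rejects internal SPs", {
  prof <- topo_profile(rep(strrep("i", 40), 3))
  g <- grammar_config(allow_globular_paths = FALSE)
  res <- decode_consensus(prof, g)
  expect_true(grepl("M", res$topology))
  expect_true(is_valid_topology(res$topology, g))
  expect_error(
    decode_consensus(prof, grammar_config(sp_must_start_at_nterm = FALSE)),
    "N-terminal signal peptides")
})
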