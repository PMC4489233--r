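test_that("scale constructor and reader validate their input", {
  sc <- toy_scale(0.5)
  expect_s3_class(sc, "dg_scale")
  expect_equal(unname(sc$values[["L"]]), 0.5)

  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vals <- rlang::set_names(rep(0.5, 20), aa)
  expect_error(dg_scale(vals[-20]), "scale missing residue Y")
  expect_error(dg_scale(vals[setdiff(aa, c("W", "Y"))], ), "W, Y")
  expect_error(dg_scale(vals, window = 20), "window must be odd")
  expect_error(dg_scale(vals, positional_weights = rep(1, 5)),
               "length `window`")

  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", paste(aa, 0.5, sep = "\t")), tmp)
  expect_equal(unname(read_dg_scale(tmp)$values), rep(0.5, 20))
  writeLines(paste(aa[-5], 0.5, sep = "\t"), tmp)
  expect_error(read_dg_scale(tmp), "scale missing residue F")
  writeLines(c(paste(aa, 0.5, sep = "\t"), "A\tnotanumber")[-1], tmp)
  expect_error(read_dg_scale(tmp), "non-numeric value")

  shipped <- default_dg_scale()
  expect_equal(shipped$window, 21L)
  expect_lt(shipped$values[["L"]], 0)   # hydrophobic residues favour insertion
  expect_gt(shipped$values[["D"]], 0)
})

test_that("window geometry and closed-form values are exact", {
  sc <- toy_scale(0.5, window = 21)
  tr <- dg_track(strrep("A", 41), sc)
  expect_equal(tr$position, 11:31)
  expect_true(all(tr$dg == 21 * 0.5))

  tr1 <- dg_track(strrep("A", 21), sc)
  expect_equal(tr1$position, 11L)   # single centre for L == W

  expect_equal(nrow(dg_track(strrep("A", 20), sc)), 0L)
  for (L in c(1L, 5L, 21L, 22L, 100L)) {
    expect_equal(nrow(dg_track(strrep("A", L), sc)), max(0L, L - 21L + 1L))
  }
})

test_that("track equals brute-force window summation", {
  set.seed(31)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:20) {
    sc <- random_scale()
    seqc <- paste(sample(aa, 60, replace = TRUE), collapse = "")
    got <- dg_track(seqc, sc)
    want <- oracle_dg(seqc, sc)
    expect_equal(got$position, want$position)
    expect_equal(got$dg, want$dg, tolerance = 1e-9)
  }
  # positional weights change the sum as the oracle says they should
  w <- seq(0.1, 2.1, length.out = 21)
  scw <- dg_scale(rlang::set_names(stats::runif(20), aa),
                  positional_weights = w)
  seqc <- paste(sample(aa, 50, replace = TRUE), collapse = "")
  expect_equal(dg_track(seqc, scw)$dg, oracle_dg(seqc, scw)$dg,
               tolerance = 1e-9)
})

test_that("track is linear in the scale and shift-invariant", {
  set.seed(17)
  sc <- random_scale()
  seqc <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60,
                       replace = TRUE), collapse = "")
  base <- dg_track(seqc, sc)
  sc3 <- dg_scale(sc$values * 3)
  expect_equal(dg_track(seqc, sc3)$dg, 3 * base$dg, tolerance = 1e-9)
  shifted <- dg_track(paste0(strrep("P", 7), seqc), sc)
  overlap <- dplyr::inner_join(
    dplyr::mutate(base, position = position + 7L), shifted,
    by = "position")
  expect_gt(nrow(overlap), 0L)
  expect_equal(overlap$dg.x, overlap$dg.y, tolerance = 1e-9)
})

test_that("unknown residues follow the configured policy", {
  sc <- toy_scale(1)
  expect_warning(tr <- dg_track(paste0(strrep("A", 30), "X",
                                       strrep("A", 10)), sc),
                 "unknown residue")
  expect_equal(nrow(tr), 21L)
  expect_true(all(tr$dg == 21))   # mean of a constant scale is the constant
  sc_err <- toy_scale(1, unknown = "error")
  expect_error(dg_track("AXAAAAAAAAAAAAAAAAAAAAAA", sc_err),
               "unknown residue")
})

test_that("dg_tracks maps over a protein table", {
  truth <- simulate_proteins(5, sim_config(), seed = 8)
  out <- dg_tracks(truth, toy_scale(0.1))
  expect_equal(sort(unique(out$protein_id)), sort(truth$protein_id))
  expect_equal(nrow(out), sum(pmax(0L, truth$length - 20L)))
})

test_that("membrane helices dip below loops in simulated tracks", {
  cfg <- sim_config()
  truth <- simulate_proteins(200, cfg, seed = 21)
  tm <- truth[truth$class %in% c("TM", "SP+TM"), ]
  sc <- default_dg_scale()
  helix_dg <- c(); loop_dg <- c()
  for (k in seq_len(nrow(tm))) {
    tr <- dg_track(tm$sequence[k], sc)
    labs <- strsplit(tm$topology[k], "")[[1]][tr$position]
    helix_dg <- c(helix_dg, tr$dg[labs == "M"])
    loop_dg <- c(loop_dg, tr$dg[labs %in% c("i", "o")])
  }
  expect_lt(mean(helix_dg), mean(loop_dg) - 5)  # clear separation, kcal/mol
  expect_gt(mean(loop_dg), 0)
})
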