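# Residue sampling weights used by the generator. Membrane runs are drawn
# hydrophobic-heavy so that insertion free-energy tracks dip inside true
# helices; loops lean polar; signal peptides get a milder hydrophobic tilt
# (their h-region resembles a short TM helix, which is the whole
# cross-prediction problem).
aa_weights <- list(
  M = c(A = 2, C = 1, D = 0.05, E = 0.05, F = 4, G = 1, H = 0.1, I = 5,
        K = 0.05, L = 6, M = 2, N = 0.1, P = 0.3, Q = 0.1, R = 0.05,
        S = 0.7, T = 0.7, V = 4, W = 1, Y = 1),
  loop = c(A = 1.5, C = 0.5, D = 2, E = 2.5, F = 0.7, G = 2.5, H = 1,
           I = 0.8, K = 2.5, L = 1.2, M = 0.5, N = 2, P = 2, Q = 2,
           R = 2.5, S = 2.5, T = 2, V = 0.9, W = 0.3, Y = 0.8),
  S = c(A = 3, C = 1, D = 0.2, E = 0.2, F = 2.5, G = 1.5, H = 0.3,
        I = 2.5, K = 0.5, L = 5, M = 1.5, N = 0.4, P = 1, Q = 0.5,
        R = 0.5, S = 1.5, T = 1, V = 2.5, W = 1, Y = 0.7)
)

#' Configuration of the synthetic topology generator
#'
#' Defines the study conditions under which the package tests itself:
#' ground-truth topologies drawn from a class mix, with structural ranges,
#' plus a per-method noise model that mimics the error modes of real
#' predictors (boundary imprecision, missed and invented helices, SP/TM
#' cross-prediction, missed signal peptides, inverted orientation).
#'
#' The default class mix follows the composition of a representative
#' benchmark of solved topologies (roughly 4.6% TM, 11% SP+TM, 32% SP-only,
#' 52% globular), i.e. mostly non-membrane proteins, as in a proteome-wide
#' scan.
#'
#' @param n_proteins Default ensemble size.
#' @param class_mix Named fractions over [topo_classes] (normalised
#'   internally).
#' @param helices_range Min/max membrane helices per TM protein.
#' @param helix_len_range Min/max helix length (residues); the minimum must
#'   respect the grammar's `min_helix_len`.
#' @param loop_len_range Min/max inter-helix loop length.
#' @param sp_len_range Min/max signal-peptide length.
#' @param globular_len_range Length range for proteins without membrane
#'   segments (the mature part of SP-only proteins uses it too).
#' @param n_methods Number of simulated predictor methods.
#' @param boundary_shift_max Maximum +/- shift (residues) applied to each
#'   segment boundary per method.
#' @param helix_drop_prob Probability that a method misses each true helix.
#' @param helix_add_prob Probability, per loop run, that a method invents a
#'   helix inside it.
#' @param sp_tm_swap_prob Probability of the SP/TM cross-prediction: an SP
#'   relabelled as an N-terminal helix, or an N-terminal helix (starting
#'   within signal-peptide territory) absorbed into a predicted SP.
#' @param sp_drop_prob Probability that a method misses the signal peptide
#'   entirely.
#' @param invert_prob Probability of predicting the inverted orientation
#'   (i/o swapped); only applied to proteins without a signal peptide, whose
#'   orientation the grammar pins down.
#' @param grammar The [grammar_config()] every generated and perturbed
#'   topology must satisfy.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 500L,
                       class_mix = c("TM" = 313, "SP+TM" = 752,
                                     "SP-only" = 2194, "Globular" = 3597),
                       helices_range = c(1L, 7L),
                       helix_len_range = c(15L, 30L),
                       loop_len_range = c(5L, 60L),
                       sp_len_range = c(10L, 40L),
                       globular_len_range = c(50L, 300L),
                       n_methods = 5L,
                       boundary_shift_max = 3L,
                       helix_drop_prob = 0.05,
                       helix_add_prob = 0.02,
                       sp_tm_swap_prob = 0.05,
                       sp_drop_prob = 0.02,
                       invert_prob = 0.02,
                       grammar = grammar_config()) {
  stopifnot(inherits(grammar, "topo_grammar"))
  if (is.null(names(class_mix)) || !setequal(names(class_mix), topo_classes)) {
    stop("class_mix must be named with all four topology classes", call. = FALSE)
  }
  class_mix <- class_mix[topo_classes] / sum(class_mix)
  ranges <- list(helices_range = helices_range,
                 helix_len_range = helix_len_range,
                 loop_len_range = loop_len_range, sp_len_range = sp_len_range,
                 globular_len_range = globular_len_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < 1L) {
      stop(sprintf("invalid %s", nm), call. = FALSE)
    }
  }
  if (helix_len_range[1L] < grammar$min_helix_len ||
      helix_len_range[2L] > grammar$max_helix_len) {
    stop("helix_len_range must lie within the grammar's helix bounds", call. = FALSE)
  }
  if (sp_len_range[1L] < grammar$min_sp_len ||
      sp_len_range[2L] > grammar$max_sp_len) {
    stop("sp_len_range must lie within the grammar's signal-peptide bounds", call. = FALSE)
  }
  probs <- c(helix_drop_prob = helix_drop_prob, helix_add_prob = helix_add_prob,
             sp_tm_swap_prob = sp_tm_swap_prob, sp_drop_prob = sp_drop_prob,
             invert_prob = invert_prob)
  if (any(probs < 0 | probs > 1)) stop("noise probabilities must be in [0, 1]", call. = FALSE)
  if (boundary_shift_max < 0L) stop("boundary_shift_max must be >= 0", call. = FALSE)
  if (n_methods < 1L) stop("n_methods must be >= 1", call. = FALSE)
  structure(
    c(list(n_proteins = as.integer(n_proteins)), ranges,
      list(class_mix = class_mix, n_methods = as.integer(n_methods),
           boundary_shift_max = as.integer(boundary_shift_max)),
      as.list(probs), list(grammar = grammar)),
    class = "sim_config"
  )
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

rint <- function(range) {
  if (range[1L] == range[2L]) as.integer(range[1L])
  else sample.int(range[2L] - range[1L] + 1L, 1L) + as.integer(range[1L]) - 1L
}

opposite_side <- function(side) if (side == "i") "o" else "i"

# Canonical structural representation of a grammar-valid topology:
# optional signal-peptide length, the side of the first loop, loop lengths
# (one more than the helix count) and helix lengths.  Sides are implied by
# alternation, which is exactly what the grammar dictates, so the structure
# round-trips losslessly with the label string.
topo_structure <- function(topology) {
  segs <- topo_segments(topology)
  sp <- if (segs$label[1L] == "S") segs$length[1L] else 0L
  body <- if (sp > 0L) segs[-1L, , drop = FALSE] else segs
  list(sp = sp,
       first_side = body$label[1L],
       loops = body$length[body$label != "M"],
       helices = body$length[body$label == "M"])
}

structure_to_topology <- function(s, grammar) {
  side <- if (s$sp > 0L) grammar$post_sp_side else s$first_side
  parts <- if (s$sp > 0L) strrep("S", s$sp) else character()
  h <- length(s$helices)
  for (k in seq_len(h + 1L)) {
    parts <- c(parts, strrep(side, s$loops[k]))
    if (k <= h) {
      parts <- c(parts, strrep("M", s$helices[k]))
      side <- opposite_side(side)
    }
  }
  paste(parts, collapse = "")
}

drop_helix <- function(s, k) {
  s$loops <- c(s$loops[seq_len(k - 1L)],
               s$loops[k] + s$helices[k] + s$loops[k + 1L],
               if (k + 1L < length(s$loops)) s$loops[(k + 2L):length(s$loops)])
  s$helices <- s$helices[-k]
  s
}

# Make a perturbed structure grammar-valid again: clamp the signal-peptide
# length, grow under-length helices into their flanking loops (dropping a
# helix when the loops cannot spare the residues), and split over-length
# helices back into the loops. Total length is always conserved.
repair_structure <- function(s, grammar) {
  if (s$sp > 0L) {
    if (s$sp > grammar$max_sp_len) {
      s$loops[1L] <- s$loops[1L] + s$sp - grammar$max_sp_len
      s$sp <- as.integer(grammar$max_sp_len)
    }
    if (s$sp < grammar$min_sp_len) {
      need <- grammar$min_sp_len - s$sp
      if (s$loops[1L] - need >= 1L) {
        s$sp <- s$sp + need
        s$loops[1L] <- s$loops[1L] - need
      } else {
        s$loops[1L] <- s$loops[1L] + s$sp
        s$sp <- 0L
      }
    }
  }
  repeat {
    short <- which(s$helices < grammar$min_helix_len)
    if (length(short) == 0L) break
    k <- short[1L]
    need <- grammar$min_helix_len - s$helices[k]
    avail_l <- s$loops[k] - 1L
    avail_r <- s$loops[k + 1L] - 1L
    if (avail_l + avail_r >= need) {
      take_l <- min(avail_l, need)
      take_r <- need - take_l
      s$loops[k] <- s$loops[k] - take_l
      s$loops[k + 1L] <- s$loops[k + 1L] - take_r
      s$helices[k] <- s$helices[k] + need
    } else {
      s <- drop_helix(s, k)
    }
  }
  if (is.finite(grammar$max_helix_len)) {
    long <- which(s$helices > grammar$max_helix_len)
    for (k in long) {
      excess <- s$helices[k] - as.integer(grammar$max_helix_len)
      give_l <- excess %/% 2L
      s$loops[k] <- s$loops[k] + give_l
      s$loops[k + 1L] <- s$loops[k + 1L] + (excess - give_l)
      s$helices[k] <- as.integer(grammar$max_helix_len)
    }
  }
  s
}

generate_structure <- function(class, config) {
  g <- config$grammar
  s <- switch(
    as.character(class),
    "Globular" = list(sp = 0L, first_side = sample(c("i", "o"), 1L),
                      loops = rint(config$globular_len_range), helices = integer()),
    "SP-only" = list(sp = rint(config$sp_len_range), first_side = g$post_sp_side,
                     loops = rint(config$globular_len_range), helices = integer()),
    {
      h <- rint(config$helices_range)
      list(
        sp = if (class == "SP+TM") rint(config$sp_len_range) else 0L,
        first_side = if (class == "SP+TM") g$post_sp_side else sample(c("i", "o"), 1L),
        loops = vapply(seq_len(h + 1L), function(k) rint(config$loop_len_range), integer(1)),
        helices = vapply(seq_len(h), function(k) rint(config$helix_len_range), integer(1))
      )
    }
  )
  s
}

sample_sequence <- function(topology) {
  labs <- split_labels(topology)
  kind <- ifelse(labs == "M", "M", ifelse(labs == "S", "S", "loop"))
  aa <- character(length(labs))
  for (k in c("M", "S", "loop")) {
    idx <- which(kind == k)
    if (length(idx) > 0L) {
      aa[idx] <- sample(aa_standard, length(idx), replace = TRUE,
                        prob = aa_weights[[k]][aa_standard])
    }
  }
  paste(aa, collapse = "")
}

#' Generate ground-truth proteins with known topologies
#'
#' Draws `n` proteins from the configured class mix, builds a grammar-valid
#' topology for each (signal peptide, alternating loops, membrane helices
#' within the configured length ranges) and samples an amino-acid sequence
#' whose composition tracks the topology (hydrophobic membrane runs, polar
#' loops), so that downstream free-energy tracks behave like real ones.
#'
#' @param n Number of proteins; defaults to `config$n_proteins`.
#' @param config A [sim_config()].
#' @param seed Optional integer; when given, output is fully reproducible
#'   and the caller's RNG state is untouched.
#' @return A tibble with columns `protein_id`, `class`, `topology`,
#'   `sequence` and `length`. Every topology passes [validate_topology()]
#'   under `config$grammar`.
#' @export
simulate_proteins <- function(n = config$n_proteins, config = sim_config(),
                              seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  with_seed(seed, {
    classes <- sample(topo_classes, n, replace = TRUE, prob = config$class_mix)
    topo <- vapply(classes, function(cl) {
      structure_to_topology(generate_structure(cl, config), config$grammar)
    }, character(1), USE.NAMES = FALSE)
    seqs <- vapply(topo, sample_sequence, character(1), USE.NAMES = FALSE)
    tibble::tibble(
      protein_id = sprintf("P%04d", seq_len(n)),
      class = factor(classes, levels = topo_classes),
      topology = topo,
      sequence = seqs,
      length = nchar(topo)
    )
  })
}

#' Apply predictor-style noise to a true topology
#'
#' Simulates one fallible prediction method. Noise operations are applied in
#' a fixed order -- SP/TM cross-prediction swap, signal-peptide drop, helix
#' drops, helix additions, boundary shifts, orientation inversion -- on the
#' structural representation of the topology, and a repair step then
#' restores grammar validity (helices below the minimum length are grown
#' into their loops or dropped; the signal-peptide length is clamped), so
#' the output is always grammar-valid and of unchanged length. With all
#' noise probabilities and the shift at zero the output equals the input.
#'
#' @param topology A grammar-valid topology string.
#' @param config A [sim_config()]; uses the current RNG state (seed at the
#'   ensemble level, e.g. via [perturb_predictions()]).
#' @return A perturbed, grammar-valid topology string of the same length.
#' @export
perturb_topology <- function(topology, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$grammar
  s <- topo_structure(topology)

  # SP <-> N-terminal helix cross-prediction
  if (stats::runif(1) < config$sp_tm_swap_prob) {
    if (s$sp > 0L) {
      # the signal peptide is read as a membrane helix: keep one residue as
      # the new N-terminal loop, borrow from the next loop if the helix
      # would be under-length (repair drops it otherwise)
      hl <- s$sp - 1L
      borrow <- min(max(g$min_helix_len - hl, 0L), max(s$loops[1L] - 1L, 0L))
      s <- list(sp = 0L, first_side = opposite_side(g$post_sp_side),
                loops = c(1L, s$loops[1L] - borrow, s$loops[-1L]),
                helices = c(hl + borrow, s$helices))
    } else if (length(s$helices) > 0L &&
               s$loops[1L] + 1L <= g$max_sp_len) {
      # the N-terminal helix is read as a signal peptide: the leading loop
      # and first helix become the S run
      s <- list(sp = s$loops[1L] + s$helices[1L], first_side = g$post_sp_side,
                loops = s$loops[-1L], helices = s$helices[-1L])
    }
  }

  # missed signal peptide
  if (s$sp > 0L && stats::runif(1) < config$sp_drop_prob) {
    s$loops[1L] <- s$loops[1L] + s$sp
    s$sp <- 0L
  }

  # missed helices
  for (k in rev(seq_along(s$helices))) {
    if (stats::runif(1) < config$helix_drop_prob) s <- drop_helix(s, k)
  }

  # invented helices inside loops
  k <- 1L
  while (k <= length(s$loops)) {
    if (s$loops[k] >= g$min_helix_len + 2L &&
        stats::runif(1) < config$helix_add_prob) {
      hl <- min(rint(config$helix_len_range), s$loops[k] - 2L)
      left <- rint(c(1L, s$loops[k] - hl - 1L))
      right <- s$loops[k] - hl - left
      s$loops <- c(s$loops[seq_len(k - 1L)], left, right,
                   if (k < length(s$loops)) s$loops[(k + 1L):length(s$loops)])
      s$helices <- append(s$helices, hl, after = k - 1L)
      k <- k + 1L  # skip the freshly created right part
    }
    k <- k + 1L
  }

  # boundary imprecision: shift every internal run boundary
  if (config$boundary_shift_max > 0L) {
    lens <- c(if (s$sp > 0L) s$sp,
              as.vector(rbind(s$loops, c(s$helices, NA)))[
                seq_len(2L * length(s$helices) + 1L)])
    L <- sum(lens)
    if (length(lens) > 1L) {
      b <- cumsum(lens)[-length(lens)]
      b <- b + sample(seq.int(-config$boundary_shift_max,
                              config$boundary_shift_max),
                      length(b), replace = TRUE)
      for (j in seq_along(b)) {  # keep every run at least 1 residue long
        lo <- if (j == 1L) 1L else b[j - 1L] + 1L
        b[j] <- min(max(b[j], lo), L - (length(b) - j) - 1L)
      }
      lens <- diff(c(0L, b, L))
      off <- 0L
      if (s$sp > 0L) { s$sp <- lens[1L]; off <- 1L }
      nh <- length(s$helices)
      s$loops <- lens[off + 2L * seq_len(nh + 1L) - 1L]
      s$helices <- if (nh > 0L) lens[off + 2L * seq_len(nh)] else integer()
    }
  }

  # inverted orientation (grammar pins the orientation of SP proteins)
  if (s$sp == 0L && stats::runif(1) < config$invert_prob) {
    s$first_side <- opposite_side(s$first_side)
  }

  structure_to_topology(repair_structure(s, g), g)
}

#' Simulate noisy per-method predictions for an ensemble
#'
#' Runs [perturb_topology()] independently for each protein and each of
#' `n_methods` simulated methods, in a fixed order so a seed makes the whole
#' prediction table reproducible.
#'
#' @param truth A data frame with `protein_id` and `topology` columns, e.g.
#'   from [simulate_proteins()].
#' @param config A [sim_config()].
#' @param n_methods Number of methods; defaults to `config$n_methods`.
#' @param seed Optional integer seed.
#' @return A long prediction tibble (`protein_id`, `method`, `topology`)
#'   suitable for [consensus_topology()] or [write_topology_table()].
#' @export
perturb_predictions <- function(truth, config = sim_config(),
                                n_methods = config$n_methods, seed = NULL) {
  stopifnot(is.data.frame(truth),
            all(c("protein_id", "topology") %in% names(truth)))
  with_seed(seed, {
    grid <- tidyr::expand_grid(
      protein_id = truth$protein_id,
      method = sprintf("method%d", seq_len(n_methods))
    )
    topo <- character(nrow(grid))
    idx <- 1L
    for (p in seq_len(nrow(truth))) {
      for (m in seq_len(n_methods)) {
        topo[idx] <- perturb_topology(truth$topology[p], config)
        idx <- idx + 1L
      }
    }
    dplyr::mutate(grid, topology = topo)
  })
}
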