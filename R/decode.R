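# Grammar state machine for the consensus decoder.
#
# Length bounds carry all the structure (every transition that exists has
# probability 1), so minimum lengths are encoded by chaining sub-states:
# a membrane helix is a chain M_1..M_K entered from a loop state, and only
# its exit states may hand over to the opposite-side loop.  Loop states come
# in pre-/post-membrane copies (i0/o0 vs i1/o1) so that paths without any
# membrane segment can be excluded when the grammar demands one.  State
# indices are fixed (loops < membrane chains < signal-peptide chain); on DP
# score ties the lowest-index predecessor wins, which prefers fewer membrane
# segments and makes the decoder byte-deterministic.
build_decoder_states <- function(grammar) {
  if (!grammar$sp_must_start_at_nterm) {
    stop("the decoder only supports N-terminal signal peptides (sp_must_start_at_nterm = TRUE)",
         call. = FALSE)
  }
  helix_inf <- !is.finite(grammar$max_helix_len)
  sp_inf <- !is.finite(grammar$max_sp_len)
  Km <- if (helix_inf) grammar$min_helix_len else as.integer(grammar$max_helix_len)
  Ks <- if (sp_inf) grammar$min_sp_len else as.integer(grammar$max_sp_len)

  i0 <- 1L; i1 <- 2L; o0 <- 3L; o1 <- 4L
  m_io <- 4L + seq_len(Km)                 # helix crossing i -> o
  m_oi <- 4L + Km + seq_len(Km)            # helix crossing o -> i
  s_ch <- 4L + 2L * Km + seq_len(Ks)
  n_states <- 4L + 2L * Km + Ks

  state_label <- c("i", "i", "o", "o",
                   rep("M", 2L * Km), rep("S", Ks))

  m_io_exit <- if (helix_inf) m_io[Km] else m_io[grammar$min_helix_len:Km]
  m_oi_exit <- if (helix_inf) m_oi[Km] else m_oi[grammar$min_helix_len:Km]
  s_exit <- if (sp_inf) s_ch[Ks] else s_ch[grammar$min_sp_len:Ks]

  preds <- vector("list", n_states)
  preds[[i0]] <- i0
  preds[[o0]] <- o0
  preds[[i1]] <- c(i1, m_oi_exit)
  preds[[o1]] <- c(o1, m_io_exit)
  if (grammar$post_sp_side == "o") {
    preds[[o0]] <- c(o0, s_exit)
  } else {
    preds[[i0]] <- c(i0, s_exit)
  }
  preds[[m_io[1L]]] <- c(i0, i1)
  preds[[m_oi[1L]]] <- c(o0, o1)
  if (Km > 1L) {
    for (k in 2L:Km) {
      preds[[m_io[k]]] <- m_io[k - 1L]
      preds[[m_oi[k]]] <- m_oi[k - 1L]
    }
  }
  if (helix_inf) {
    preds[[m_io[Km]]] <- sort(c(preds[[m_io[Km]]], m_io[Km]))
    preds[[m_oi[Km]]] <- sort(c(preds[[m_oi[Km]]], m_oi[Km]))
  }
  if (Ks > 1L) for (k in 2L:Ks) preds[[s_ch[k]]] <- s_ch[k - 1L]
  if (sp_inf) preds[[s_ch[Ks]]] <- sort(c(preds[[s_ch[Ks]]], s_ch[Ks]))

  simple <- which(lengths(preds) == 1L)
  merge <- which(lengths(preds) > 1L)
  list(
    n_states = n_states,
    state_label = state_label,
    label_index = match(state_label, topo_labels),
    start_states = c(i0, o0, s_ch[1L]),
    end_states = if (grammar$allow_globular_paths) c(i0, i1, o0, o1) else c(i1, o1),
    simple_to = simple,
    simple_from = vapply(preds[simple], identity, integer(1)),
    merge_states = merge,
    merge_preds = lapply(preds[merge], sort)
  )
}

#' Decode the consensus topology from a voting profile
#'
#' Finds the grammar-valid topology string with the highest geometric-mean
#' profile score by dynamic programming over the topology state machine --
#' a Viterbi pass in which each state emits its own label with score equal
#' to the (smoothed) profile fraction for that label, all permitted
#' transitions score 1, and length bounds are encoded as chained sub-states.
#' No training is involved: the profile and the grammar fully determine the
#' result. On score ties the path through the lowest-indexed state wins
#' (loops before helices before signal peptide), so the output is
#' deterministic and prefers fewer membrane segments.
#'
#' @param profile A [topo_profile()].
#' @param grammar A [grammar_config()].
#' @param epsilon Pseudocount used to smooth the profile (see
#'   [score_topology()]); must be positive for the optimality guarantee,
#'   since unsmoothed conflicting one-hot columns can make every valid path
#'   score zero.
#' @return An object of class `topo_consensus` with elements `topology`
#'   (grammar-valid consensus string), `log_score` (mean log smoothed
#'   fraction along the path, the quantity maximised), `agreement`
#'   (per-residue fraction of input methods matching the consensus label,
#'   a reliability track), `class`, `n_methods`, `grammar`, `epsilon`.
#' @examples
#' prof <- topo_profile(rep(strrep("iiiiiMMMMMMMMMMMMMMMooooo", 1), 3))
#' decode_consensus(prof)$topology
#' @export
decode_consensus <- function(profile, grammar = grammar_config(), epsilon = 1e-6) {
  stopifnot(inherits(profile, "topo_profile"))
  st <- build_decoder_states(grammar)
  L <- profile$length
  p <- smooth_profile(profile$fractions, epsilon)
  emis <- log(p)[, st$label_index, drop = FALSE]   # L x n_states

  n <- st$n_states
  dp <- matrix(-Inf, nrow = L, ncol = n)
  bp <- matrix(0L, nrow = L, ncol = n)
  dp[1L, st$start_states] <- emis[1L, st$start_states]

  if (L > 1L) {
    for (t in 2L:L) {
      prev <- dp[t - 1L, ]
      cur <- rep(-Inf, n)
      cur[st$simple_to] <- prev[st$simple_from]
      bp[t, st$simple_to] <- st$simple_from
      for (k in seq_along(st$merge_states)) {
        pk <- st$merge_preds[[k]]
        vals <- prev[pk]
        w <- which.max(vals)
        j <- st$merge_states[k]
        cur[j] <- vals[w]
        bp[t, j] <- pk[w]
      }
      dp[t, ] <- cur + emis[t, ]
    }
  }

  final <- dp[L, st$end_states]
  if (all(final == -Inf)) {
    stop("no grammar-valid path exists for this sequence length", call. = FALSE)
  }
  state <- st$end_states[which.max(final)]
  path <- integer(L)
  path[L] <- state
  if (L > 1L) {
    for (t in L:2L) path[t - 1L] <- bp[t, path[t]]
  }
  labs <- st$state_label[path]
  topology <- paste(labs, collapse = "")

  structure(
    list(
      topology = topology,
      log_score = max(final) / L,
      agreement = unname(profile$fractions[cbind(seq_len(L), match(labs, topo_labels))]),
      class = classify_topology(topology),
      n_methods = profile$n_methods,
      grammar = grammar,
      epsilon = epsilon
    ),
    class = "topo_consensus"
  )
}

#' @export
print.topo_consensus <- function(x, ...) {
  cat(sprintf("Consensus topology (%d residues, %d methods, class %s)\n",
              nchar(x$topology), x$n_methods, as.character(x$class)))
  cat(sprintf("  log geometric-mean score: %.6f\n", x$log_score))
  cat(sprintf("  mean agreement: %.3f\n", mean(x$agreement)))
  cat(strwrap(x$topology, width = 60), sep = "\n")
  invisible(x)
}

#' @describeIn decode_consensus Per-residue tibble (`position`, `label`,
#'   `agreement`) for a decoded consensus.
#' @param x A `topo_consensus` object.
#' @param ... Unused.
#' @method tidy topo_consensus
#' @export
tidy.topo_consensus <- function(x, ...) {
  tibble::tibble(
    position = seq_len(nchar(x$topology)),
    label = split_labels(x$topology),
    agreement = x$agreement
  )
}

#' @describeIn decode_consensus One-row summary (`length`, `class`,
#'   `n_tm_segments`, `has_sp`, `log_score`, `mean_agreement`, `n_methods`).
#' @export
glance.topo_consensus <- function(x, ...) {
  segs <- topo_segments(x$topology)
  tibble::tibble(
    length = nchar(x$topology),
    class = as.character(x$class),
    n_tm_segments = sum(segs$label == "M"),
    has_sp = any(segs$label == "S"),
    log_score = x$log_score,
    mean_agreement = mean(x$agreement),
    n_methods = x$n_methods
  )
}

#' Consensus topologies for a table of predictions
#'
#' Data-frame-first wrapper around [topo_profile()] and
#' [decode_consensus()]: takes the long prediction table used throughout the
#' package (one row per protein x method) and returns one consensus row per
#' protein.
#'
#' @param predictions A data frame with columns `protein_id`, `method` and
#'   `topology` (per-residue label strings, equal length within a protein).
#' @param grammar A [grammar_config()].
#' @param epsilon Profile smoothing pseudocount.
#' @return A tibble with one row per protein: `protein_id`, `topology`
#'   (consensus string), `class`, `n_tm_segments`, `has_sp`, `log_score`,
#'   `mean_agreement`, `n_methods`, and `agreement` (list column of
#'   per-residue agreement tracks). Proteins are kept in first-appearance
#'   order.
#' @export
consensus_topology <- function(predictions, grammar = grammar_config(),
                               epsilon = 1e-6) {
  stopifnot(is.data.frame(predictions),
            all(c("protein_id", "method", "topology") %in% names(predictions)))
  if (nrow(predictions) == 0L) stop("empty prediction table", call. = FALSE)
  predictions |>
    dplyr::mutate(protein_id = factor(.data$protein_id,
                                      levels = unique(.data$protein_id))) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::group_modify(function(d, key) {
      preds <- rlang::set_names(d$topology, d$method)
      res <- decode_consensus(topo_profile(preds), grammar, epsilon)
      dplyr::bind_cols(glance(res)[, c("class", "n_tm_segments", "has_sp",
                                       "log_score", "mean_agreement",
                                       "n_methods")],
                       tibble::tibble(topology = res$topology,
                                      agreement = list(res$agreement)))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(protein_id = as.character(.data$protein_id)) |>
    dplyr::select("protein_id", "topology", "class", "n_tm_segments",
                  "has_sp", "log_score", "mean_agreement", "n_methods",
                  "agreement")
}
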