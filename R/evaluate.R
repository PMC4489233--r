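#' Error kinds of the benchmark taxonomy
#'
#' Verdicts assigned by [judge_topology()]: `CORRECT`; `WRONG_TOPOLOGY`
#' (classification right, topology wrong -- e.g. an extra or missing helix,
#' shifted helices, inverted orientation); `TM_SP_CONFUSION` (an N-terminal
#' membrane helix predicted as a signal peptide or vice versa, the classic
#' cross-prediction error); `TM_NONTM_CONFUSION` (membrane protein predicted
#' globular or vice versa); `SP_NONTM_CONFUSION` (signal peptide missed or
#' invented without any membrane-helix involvement).
#'
#' @format Character vector of the five verdict names, used as factor
#'   levels.
#' @export
error_kinds <- c("CORRECT", "WRONG_TOPOLOGY", "TM_SP_CONFUSION",
                 "TM_NONTM_CONFUSION", "SP_NONTM_CONFUSION")

m_segments <- function(topology) {
  dplyr::filter(topo_segments(topology), .data$label == "M")
}

overlap_len <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2) + 1L)
}

check_pair <- function(ref, pred) {
  check_topology_string(ref, "ref")
  check_topology_string(pred, "pred")
  if (nchar(ref) != nchar(pred)) {
    stop(sprintf("reference length %d does not match prediction length %d",
                 nchar(ref), nchar(pred)), call. = FALSE)
  }
}

#' Is a predicted topology correct under the benchmark criterion?
#'
#' A prediction is correct when (a) signal-peptide presence matches the
#' reference, (b) the number of membrane segments matches, (c) the k-th
#' predicted membrane segment overlaps the k-th reference segment by at
#' least `min_overlap` residues (in-order one-to-one pairing), and (d) for
#' membrane proteins, the N- and C-terminal sides match (the N-terminal side
#' is the first `i`/`o` label, i.e. read after any signal peptide). For
#' references without membrane segments only (a) and (b) apply: a globular
#' or SP-only protein is judged on the absence of membrane segments and on
#' signal-peptide agreement, not on the arbitrary `i`/`o` choice of its
#' single loop.
#'
#' @param ref,pred Topology strings of equal length.
#' @param min_overlap Minimum per-segment overlap in residues.
#' @param require_termini Compare the N-/C-terminal sides for membrane
#'   proteins?
#' @return A single logical.
#' @export
topology_correct <- function(ref, pred, min_overlap = 5L,
                             require_termini = TRUE) {
  check_pair(ref, pred)
  if (min_overlap < 1L) stop("min_overlap must be >= 1", call. = FALSE)

  if (grepl("S", ref, fixed = TRUE) != grepl("S", pred, fixed = TRUE)) {
    return(FALSE)
  }
  rm_ <- m_segments(ref)
  pm <- m_segments(pred)
  if (nrow(rm_) != nrow(pm)) return(FALSE)
  if (nrow(rm_) > 0L) {
    ok <- vapply(seq_len(nrow(rm_)), function(k) {
      overlap_len(rm_$start[k], rm_$end[k], pm$start[k], pm$end[k]) >= min_overlap
    }, logical(1))
    if (!all(ok)) return(FALSE)
    if (require_termini) {
      if (!identical(n_terminal_side(ref), n_terminal_side(pred))) return(FALSE)
      if (!identical(c_terminal_side(ref), c_terminal_side(pred))) return(FALSE)
    }
  }
  TRUE
}

sp_tm_overlap <- function(with_sp, with_m, sp_window = 70L) {
  # does an M segment of `with_m` overlap the S run of `with_sp`, within
  # signal-peptide territory (the N-terminal `sp_window` residues)?
  s_seg <- dplyr::filter(topo_segments(with_sp), .data$label == "S")
  if (nrow(s_seg) == 0L) return(FALSE)
  m_seg <- m_segments(with_m)
  if (nrow(m_seg) == 0L) return(FALSE)
  any(vapply(seq_len(nrow(m_seg)), function(k) {
    m_seg$start[k] <= sp_window &&
      overlap_len(s_seg$start[1L], s_seg$end[1L],
                  m_seg$start[k], m_seg$end[k]) >= 1L
  }, logical(1)))
}

#' Judge a prediction against its reference
#'
#' Applies [topology_correct()] and, on failure, assigns one of the
#' [error_kinds]. Signal-peptide disagreements where the S run of one string
#' overlaps an N-terminal membrane helix of the other (within the first
#' `sp_window` residues) are the SP/TM cross-prediction; signal-peptide
#' disagreements without such a helix are SP/non-TM errors; remaining
#' membrane-presence disagreements are TM/non-TM errors; and when both
#' classifications agree but the topology is still wrong the verdict is
#' `WRONG_TOPOLOGY`. The kinds are mutually exclusive and exhaustive.
#'
#' @inheritParams topology_correct
#' @param sp_window N-terminal span (residues) in which an S/M conflict
#'   counts as SP/TM cross-prediction; matches the maximum signal-peptide
#'   length of the default grammar.
#' @return A list with `ref_class`, `pred_class` (factors over
#'   [topo_classes]), `correct` (logical) and `error_kind` (factor over
#'   [error_kinds]).
#' @export
judge_topology <- function(ref, pred, min_overlap = 5L,
                           require_termini = TRUE, sp_window = 70L) {
  check_pair(ref, pred)
  correct <- topology_correct(ref, pred, min_overlap, require_termini)
  ref_s <- grepl("S", ref, fixed = TRUE)
  pred_s <- grepl("S", pred, fixed = TRUE)
  ref_m <- grepl("M", ref, fixed = TRUE)
  pred_m <- grepl("M", pred, fixed = TRUE)

  kind <- if (correct) {
    "CORRECT"
  } else if (ref_s != pred_s) {
    cross <- if (ref_s) sp_tm_overlap(ref, pred, sp_window)
             else sp_tm_overlap(pred, ref, sp_window)
    if (cross) "TM_SP_CONFUSION" else "SP_NONTM_CONFUSION"
  } else if (ref_m != pred_m) {
    "TM_NONTM_CONFUSION"
  } else {
    "WRONG_TOPOLOGY"
  }
  list(
    ref_class = classify_topology(ref),
    pred_class = classify_topology(pred),
    correct = correct,
    error_kind = factor(kind, levels = error_kinds)
  )
}

#' Evaluate a table of prediction/reference pairs
#'
#' @param data A data frame with columns `protein_id`, `ref` and `pred`
#'   (topology strings of matching length per protein).
#' @inheritParams judge_topology
#' @return A tibble with one row per protein: `protein_id`, `ref_class`,
#'   `pred_class`, `correct`, `error_kind`.
#' @seealso [topology_benchmark()] to aggregate the outcomes.
#' @export
evaluate_topologies <- function(data, min_overlap = 5L,
                                require_termini = TRUE, sp_window = 70L) {
  stopifnot(is.data.frame(data),
            all(c("protein_id", "ref", "pred") %in% names(data)))
  if (nrow(data) == 0L) stop("empty evaluation table", call. = FALSE)
  out <- purrr::map2(data$ref, data$pred, judge_topology,
                     min_overlap = min_overlap,
                     require_termini = require_termini,
                     sp_window = sp_window)
  tibble::tibble(
    protein_id = data$protein_id,
    ref_class = factor(purrr::map_chr(out, ~ as.character(.x$ref_class)),
                       levels = topo_classes),
    pred_class = factor(purrr::map_chr(out, ~ as.character(.x$pred_class)),
                        levels = topo_classes),
    correct = purrr::map_lgl(out, "correct"),
    error_kind = factor(purrr::map_chr(out, ~ as.character(.x$error_kind)),
                        levels = error_kinds)
  )
}

#' Aggregate evaluation outcomes into a benchmark report
#'
#' Produces per-reference-class accuracies, the 4 x 4 class confusion matrix
#' (rows = reference class, columns = predicted class, row-normalised
#' percentages alongside raw counts) and the error-kind breakdown per
#' reference class.
#'
#' @param data Either an outcome tibble from [evaluate_topologies()] or a
#'   raw data frame with `protein_id`, `ref`, `pred` (then the outcomes are
#'   computed first with the remaining arguments).
#' @inheritParams evaluate_topologies
#' @return An object of class `topo_benchmark`: list with `outcomes`
#'   (per-protein tibble), `by_class` (per-reference-class `n`, `n_correct`,
#'   `pct_correct`), `confusion` (long tibble `ref_class`, `pred_class`,
#'   `n`, `pct` row-normalised) and `error_matrix` (long tibble `ref_class`,
#'   `error_kind`, `n`, `pct`).
#' @export
topology_benchmark <- function(data, min_overlap = 5L,
                               require_termini = TRUE, sp_window = 70L) {
  stopifnot(is.data.frame(data))
  outcomes <- if (all(c("ref_class", "pred_class", "correct", "error_kind")
                      %in% names(data))) {
    data
  } else {
    evaluate_topologies(data, min_overlap, require_termini, sp_window)
  }

  by_class <- outcomes |>
    dplyr::group_by(ref_class = .data$ref_class, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(), n_correct = sum(.data$correct),
                     .groups = "drop") |>
    dplyr::mutate(pct_correct = ifelse(.data$n > 0, 100 * .data$n_correct / .data$n, NA_real_))

  confusion <- outcomes |>
    dplyr::count(.data$ref_class, .data$pred_class, .drop = FALSE) |>
    dplyr::group_by(.data$ref_class) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(pct = ifelse(is.nan(.data$pct), NA_real_, .data$pct))

  error_matrix <- outcomes |>
    dplyr::count(.data$ref_class, .data$error_kind, .drop = FALSE) |>
    dplyr::group_by(.data$ref_class) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(pct = ifelse(is.nan(.data$pct), NA_real_, .data$pct))

  structure(
    list(outcomes = tibble::as_tibble(outcomes), by_class = by_class,
         confusion = confusion, error_matrix = error_matrix),
    class = "topo_benchmark"
  )
}

#' @export
print.topo_benchmark <- function(x, ...) {
  cat(sprintf("Topology benchmark: %d proteins, %.1f%% correct overall\n",
              nrow(x$outcomes), 100 * mean(x$outcomes$correct)))
  cat("\nPer-class accuracy:\n")
  bc <- x$by_class[x$by_class$n > 0L, ]
  for (k in seq_len(nrow(bc))) {
    cat(sprintf("  %-9s %4d proteins  %5.1f%% correct\n",
                as.character(bc$ref_class[k]), bc$n[k], bc$pct_correct[k]))
  }
  cat("\nClass confusion (row %):\n")
  wide <- tidyr::pivot_wider(x$confusion[, c("ref_class", "pred_class", "pct")],
                             names_from = "pred_class", values_from = "pct")
  print(as.data.frame(wide), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @describeIn topology_benchmark Per-reference-class accuracy tibble.
#' @param x A `topo_benchmark`.
#' @param ... Unused.
#' @export
tidy.topo_benchmark <- function(x, ...) x$by_class

#' @describeIn topology_benchmark One-row overall summary (`n_proteins`,
#'   `n_correct`, `pct_correct`, `pct_class_correct` -- the percentage whose
#'   predicted class matches the reference class).
#' @export
glance.topo_benchmark <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x$outcomes),
    n_correct = sum(x$outcomes$correct),
    pct_correct = 100 * mean(x$outcomes$correct),
    pct_class_correct = 100 * mean(x$outcomes$ref_class == x$outcomes$pred_class)
  )
}

#' @describeIn topology_benchmark Heatmap of the row-normalised class
#'   confusion matrix.
#' @param object A `topo_benchmark`.
#' @export
autoplot.topo_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$confusion,
                  ggplot2::aes(x = .data$pred_class, y = .data$ref_class,
                               fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$pct), "", sprintf("%.0f%%", .data$pct)))) +
    ggplot2::scale_y_discrete(limits = rev(topo_classes)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 na.value = "grey95", limits = c(0, 100)) +
    ggplot2::labs(x = "predicted class", y = "reference class",
                  fill = "row %")
}
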