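#' Residue labels of the topology alphabet
#'
#' Membrane-protein topologies are written as per-residue label strings over
#' a four-letter alphabet: `S` (cleavable N-terminal signal peptide), `M`
#' (membrane-spanning helix), `i` (loop on the cytoplasmic, "inside" face)
#' and `o` (loop on the non-cytoplasmic, "outside" face).
#'
#' @format A character vector of length 4, in the fixed order `S, M, i, o`.
#' @export
topo_labels <- c("S", "M", "i", "o")

#' The four topology classes
#'
#' Every topology string falls in exactly one class: `TM` (membrane segments,
#' no signal peptide), `SP+TM` (both), `SP-only` (signal peptide, no membrane
#' segment) and `Globular` (neither).
#'
#' @format Character vector of the four class names, used as factor levels
#'   throughout the package.
#' @export
topo_classes <- c("TM", "SP+TM", "SP-only", "Globular")

split_labels <- function(topology) strsplit(topology, "", fixed = TRUE)[[1]]

check_topology_string <- function(topology, arg = "topology") {
  if (!is.character(topology) || length(topology) != 1L || is.na(topology)) {
    stop(sprintf("`%s` must be a single topology string", arg), call. = FALSE)
  }
  if (nchar(topology) == 0L) {
    stop("empty topology", call. = FALSE)
  }
  labs <- split_labels(topology)
  bad <- which(!labs %in% topo_labels)
  if (length(bad) > 0L) {
    stop(sprintf("unknown label '%s' at position %d", labs[bad[1L]], bad[1L]),
         call. = FALSE)
  }
  invisible(labs)
}

#' Decompose a topology string into maximal segments
#'
#' Splits a per-residue label string into its maximal runs of identical
#' labels. Positions are 1-based and inclusive.
#'
#' @param topology A single topology string over `S`, `M`, `i`, `o`.
#' @return A tibble with one row per segment and columns `label`, `start`,
#'   `end` and `length`. Concatenating the segments in order reproduces the
#'   input string exactly.
#' @examples
#' topo_segments("iiiMMMooo")
#' @seealso [segments_to_topology()] for the inverse.
#' @export
topo_segments <- function(topology) {
  labs <- check_topology_string(topology)
  r <- rle(labs)
  ends <- cumsum(r$lengths)
  tibble::tibble(
    label  = r$values,
    start  = ends - r$lengths + 1L,
    end    = ends,
    length = r$lengths
  )
}

#' Rebuild a topology string from a segment table
#'
#' Inverse of [topo_segments()]. The segments must tile `1..length` without
#' gaps or overlaps, in order.
#'
#' @param segments A data frame with columns `label`, `start`, `end`
#'   (1-based, inclusive).
#' @param length Total sequence length the segments must cover.
#' @return A single topology string.
#' @export
segments_to_topology <- function(segments, length) {
  stopifnot(is.data.frame(segments), all(c("label", "start", "end") %in% names(segments)))
  segments <- segments[order(segments$start), , drop = FALSE]
  starts <- as.integer(segments$start)
  ends <- as.integer(segments$end)
  if (nrow(segments) == 0L ||
      starts[1L] != 1L ||
      ends[nrow(segments)] != length ||
      any(ends < starts) ||
      (nrow(segments) > 1L && any(starts[-1L] != ends[-nrow(segments)] + 1L))) {
    stop("segments do not tile sequence", call. = FALSE)
  }
  paste(rep(segments$label, ends - starts + 1L), collapse = "")
}

#' Classify topology strings
#'
#' Assigns each topology string to one of the four classes in
#' [topo_classes], from the presence of membrane (`M`) and signal-peptide
#' (`S`) labels: both present gives `SP+TM`, only `M` gives `TM`, only `S`
#' gives `SP-only`, neither gives `Globular`.
#'
#' @param topology Character vector of topology strings (vectorised).
#' @return A factor with levels [topo_classes].
#' @examples
#' classify_topology(c("iiiiii", "SSSSSSSoooooo"))
#' @export
classify_topology <- function(topology) {
  stopifnot(is.character(topology))
  if (any(!nzchar(topology) | is.na(topology))) stop("empty topology", call. = FALSE)
  has_m <- grepl("M", topology, fixed = TRUE)
  has_s <- grepl("S", topology, fixed = TRUE)
  cls <- dplyr::case_when(
    has_m & !has_s ~ "TM",
    has_m & has_s  ~ "SP+TM",
    !has_m & has_s ~ "SP-only",
    TRUE           ~ "Globular"
  )
  factor(cls, levels = topo_classes)
}

#' Topology grammar configuration
#'
#' The decoder and validator share a small state-machine grammar describing
#' which label strings count as well-formed topologies: a single optional
#' signal peptide at the N-terminus followed by the periplasmic/luminal side,
#' loops that alternate sides across each membrane helix, and length bounds
#' on helices and the signal peptide.
#'
#' @param min_helix_len Minimum membrane-helix length in residues. A
#'   membrane-spanning alpha helix needs roughly 15 residues to cross the
#'   hydrocarbon core, hence the default.
#' @param max_helix_len Maximum helix length, or `Inf` for unbounded.
#' @param min_sp_len,max_sp_len Bounds on signal-peptide length (residues).
#' @param sp_must_start_at_nterm Must an `S` run begin at residue 1?
#' @param post_sp_side Side label required immediately after the signal
#'   peptide; cleaved signal peptides leave the mature N-terminus on the
#'   non-cytoplasmic side, hence `"o"`.
#' @param allow_globular_paths May the decoder return a topology with no
#'   membrane segment at all (an all-`i`/all-`o` path)?
#' @return A list of class `topo_grammar`.
#' @export
grammar_config <- function(min_helix_len = 15L,
                           max_helix_len = Inf,
                           min_sp_len = 5L,
                           max_sp_len = 70L,
                           sp_must_start_at_nterm = TRUE,
                           post_sp_side = "o",
                           allow_globular_paths = TRUE) {
  min_helix_len <- as.integer(min_helix_len)
  min_sp_len <- as.integer(min_sp_len)
  if (min_helix_len < 1L) stop("min_helix_len must be >= 1", call. = FALSE)
  if (is.finite(max_helix_len) && max_helix_len < min_helix_len) {
    stop("max_helix_len must be >= min_helix_len", call. = FALSE)
  }
  if (min_sp_len < 1L) stop("min_sp_len must be >= 1", call. = FALSE)
  if (is.finite(max_sp_len) && max_sp_len < min_sp_len) {
    stop("max_sp_len must be >= min_sp_len", call. = FALSE)
  }
  if (!post_sp_side %in% c("i", "o")) stop("post_sp_side must be 'i' or 'o'", call. = FALSE)
  structure(
    list(
      min_helix_len = min_helix_len,
      max_helix_len = max_helix_len,
      min_sp_len = min_sp_len,
      max_sp_len = max_sp_len,
      sp_must_start_at_nterm = isTRUE(sp_must_start_at_nterm),
      post_sp_side = post_sp_side,
      allow_globular_paths = isTRUE(allow_globular_paths)
    ),
    class = "topo_grammar"
  )
}

#' @export
print.topo_grammar <- function(x, ...) {
  cat("Topology grammar:\n")
  cat(sprintf("  helix length: %d..%s\n", x$min_helix_len,
              if (is.finite(x$max_helix_len)) x$max_helix_len else "Inf"))
  cat(sprintf("  signal peptide length: %d..%s (N-terminal: %s, followed by '%s')\n",
              x$min_sp_len,
              if (is.finite(x$max_sp_len)) x$max_sp_len else "Inf",
              x$sp_must_start_at_nterm, x$post_sp_side))
  cat(sprintf("  globular paths allowed: %s\n", x$allow_globular_paths))
  invisible(x)
}

#' Validate a topology string against the grammar
#'
#' Checks every grammar rule and reports all violations rather than stopping
#' at the first. Raw predictor output need not be grammar-valid; consensus
#' output always is.
#'
#' Rules with the defaults: at most one `S` run, starting at residue 1, with
#' length within the signal-peptide bounds and followed immediately by the
#' configured post-SP side; `i` and `o` runs never touch (a membrane crossing
#' must separate them); the sides flanking every `M` run differ (`i-M-o` or
#' `o-M-i`); every `M` run respects the helix length bounds; `M` never abuts
#' `S` or a sequence terminus (the flanking loops define the orientation and
#' the termini labels).
#'
#' @param topology A single topology string.
#' @param grammar A [grammar_config()].
#' @return A list with elements `valid` (logical) and `violations`
#'   (character vector of human-readable rule violations, empty when valid).
#' @examples
#' validate_topology("iiioooiii")$violations
#' @export
validate_topology <- function(topology, grammar = grammar_config()) {
  check_topology_string(topology)
  segs <- topo_segments(topology)
  n <- nrow(segs)
  v <- character()

  s_rows <- which(segs$label == "S")
  if (length(s_rows) > 1L) {
    v <- c(v, "multiple signal-peptide segments")
  }
  for (k in s_rows) {
    if (grammar$sp_must_start_at_nterm && segs$start[k] != 1L) {
      v <- c(v, "signal peptide does not start at the N-terminus")
    }
    if (segs$length[k] < grammar$min_sp_len) {
      v <- c(v, "signal peptide shorter than minimum")
    }
    if (segs$length[k] > grammar$max_sp_len) {
      v <- c(v, "signal peptide longer than maximum")
    }
    if (k == n) {
      v <- c(v, sprintf("signal peptide not followed by '%s'", grammar$post_sp_side))
    } else if (segs$label[k + 1L] != grammar$post_sp_side) {
      v <- c(v, sprintf("signal peptide not followed by '%s'", grammar$post_sp_side))
    }
    if (k > 1L && segs$label[k - 1L] == "M") {
      v <- c(v, "membrane segment adjacent to signal peptide")
    }
  }

  if (n > 1L) {
    for (k in seq_len(n - 1L)) {
      pair <- segs$label[c(k, k + 1L)]
      if (setequal(pair, c("i", "o"))) v <- c(v, "i adjacent to o")
    }
  }

  for (k in which(segs$label == "M")) {
    if (segs$length[k] < grammar$min_helix_len) {
      v <- c(v, "helix shorter than minimum")
    }
    if (segs$length[k] > grammar$max_helix_len) {
      v <- c(v, "helix longer than maximum")
    }
    left <- if (k > 1L) segs$label[k - 1L] else NA_character_
    right <- if (k < n) segs$label[k + 1L] else NA_character_
    if (is.na(left) || is.na(right)) {
      v <- c(v, "membrane segment at sequence terminus lacks a flanking loop")
    } else if (left == "S") {
      v <- c(v, "membrane segment adjacent to signal peptide")
    } else if (left == right) {
      v <- c(v, "sides do not alternate across membrane segment")
    }
  }

  list(valid = length(v) == 0L, violations = unique(v))
}

#' @rdname validate_topology
#' @return `is_valid_topology()` returns a single logical.
#' @export
is_valid_topology <- function(topology, grammar = grammar_config()) {
  validate_topology(topology, grammar)$valid
}

n_terminal_side <- function(topology) {
  labs <- split_labels(topology)
  side <- labs[labs %in% c("i", "o")]
  if (length(side) == 0L) NA_character_ else side[1L]
}

c_terminal_side <- function(topology) {
  last <- substr(topology, nchar(topology), nchar(topology))
  if (last %in% c("i", "o")) last else NA_character_
}
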