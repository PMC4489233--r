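aa_standard <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Hydrophobicity scale for free energy of membrane insertion
#'
#' A `dg_scale` maps each amino acid to its additive contribution (kcal/mol)
#' to the apparent free energy of translocon-mediated membrane insertion,
#' summed over a sliding window (default 21 residues, about one membrane
#' crossing). Optional positional weights allow a position-dependent profile
#' across the window; the default is a plain sum (all weights 1).
#'
#' @param values Named numeric vector covering all 20 standard one-letter
#'   amino-acid codes (kcal/mol).
#' @param window Odd window width in residues.
#' @param positional_weights Optional numeric vector of length `window`.
#' @param name Scale name, for display.
#' @param unknown Policy for non-standard letters (X, B, Z, ...) in
#'   sequences: `"mean"` substitutes the mean of the 20 standard values
#'   (with a warning at use time), `"error"` stops.
#' @return An object of class `dg_scale`.
#' @seealso [read_dg_scale()], [default_dg_scale()], [dg_track()]
#' @export
dg_scale <- function(values, window = 21L, positional_weights = NULL,
                     name = "user scale", unknown = c("mean", "error")) {
  unknown <- match.arg(unknown)
  if (!is.numeric(values) || is.null(names(values))) {
    stop("`values` must be a named numeric vector", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("scale values must be finite numbers", call. = FALSE)
  missing <- setdiff(aa_standard, names(values))
  if (length(missing) > 0L) {
    stop(sprintf("scale missing residue%s %s",
                 if (length(missing) > 1L) "s" else "",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (is.null(positional_weights)) positional_weights <- rep(1, window)
  if (length(positional_weights) != window || !is.numeric(positional_weights)) {
    stop("positional_weights must be numeric of length `window`", call. = FALSE)
  }
  structure(
    list(values = values[aa_standard], window = window,
         positional_weights = as.numeric(positional_weights),
         name = name, unknown = unknown),
    class = "dg_scale"
  )
}

#' @export
print.dg_scale <- function(x, ...) {
  cat(sprintf("dG insertion scale '%s' (window %d)\n", x$name, x$window))
  print(round(x$values, 3))
  invisible(x)
}

#' Read a hydrophobicity scale from a key-value file
#'
#' Format: plain text, one `LETTER<TAB>value` pair per line (any whitespace
#' accepted), `#` comment lines ignored. All 20 standard residues must be
#' present.
#'
#' @param path Path to the scale file.
#' @inheritParams dg_scale
#' @return A [dg_scale()].
#' @export
read_dg_scale <- function(path, window = 21L, positional_weights = NULL,
                          name = basename(path), unknown = "mean") {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty scale file", call. = FALSE)
  parts <- strsplit(lines, "[ \t]+")
  if (any(lengths(parts) != 2L)) {
    stop(sprintf("malformed scale line: '%s'",
                 lines[which(lengths(parts) != 2L)[1L]]), call. = FALSE)
  }
  letters <- vapply(parts, `[`, character(1), 1L)
  raw <- vapply(parts, `[`, character(1), 2L)
  vals <- suppressWarnings(as.numeric(raw))
  if (any(is.na(vals))) {
    stop(sprintf("non-numeric value '%s' for residue %s",
                 raw[which(is.na(vals))[1L]], letters[which(is.na(vals))[1L]]),
         call. = FALSE)
  }
  if (anyDuplicated(letters)) {
    stop(sprintf("duplicate residue '%s' in scale file",
                 letters[duplicated(letters)][1L]), call. = FALSE)
  }
  dg_scale(rlang::set_names(vals, letters), window = window,
           positional_weights = positional_weights, name = name,
           unknown = unknown)
}

#' The biological (translocon) hydrophobicity scale
#'
#' Loads the per-residue apparent free energies of translocon-mediated
#' membrane insertion measured by Hessa et al. (2007), shipped with the
#' package as a plain-text data file, with the standard 21-residue window.
#'
#' @inheritParams dg_scale
#' @return A [dg_scale()].
#' @references Hessa T et al. (2007) Molecular code for transmembrane-helix
#'   recognition by the Sec61 translocon. Nature 450:1026-1030.
#' @export
default_dg_scale <- function(window = 21L) {
  read_dg_scale(
    system.file("extdata", "dg_scale_biological.tsv",
                package = "topoconsensus", mustWork = TRUE),
    window = window, name = "biological hydrophobicity (Hessa 2007)"
  )
}

#' Free energy of membrane insertion along a sequence
#'
#' Slides a window (default 21 residues) along the protein and, at every
#' position with a complete window, sums the weighted per-residue scale
#' contributions. Low values mark stretches hydrophobic enough to insert
#' into the membrane, i.e. candidate transmembrane helices. Incomplete
#' windows at the termini are not computed.
#'
#' @param sequence A single amino-acid sequence string (uppercase one-letter
#'   codes).
#' @param scale A [dg_scale()].
#' @return A tibble with columns `position` (1-based window centre; centres
#'   run from `(W+1)/2` to `L-(W-1)/2`, so `L - W + 1` rows) and `dg`
#'   (kcal/mol). Zero rows when the sequence is shorter than the window.
#' @examples
#' sc <- dg_scale(setNames(rep(0.5, 20),
#'                strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]), window = 21)
#' dg_track(strrep("A", 41), sc)
#' @export
dg_track <- function(sequence, scale) {
  stopifnot(inherits(scale, "dg_scale"),
            is.character(sequence), length(sequence) == 1L)
  L <- nchar(sequence)
  if (L < 1L) stop("empty sequence", call. = FALSE)
  aa <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  v <- unname(scale$values[aa])
  if (anyNA(v)) {
    bad <- unique(aa[is.na(v)])
    if (scale$unknown == "error") {
      stop(sprintf("unknown residue%s %s in sequence",
                   if (length(bad) > 1L) "s" else "",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    warning(sprintf("unknown residue%s %s: using mean scale value",
                    if (length(bad) > 1L) "s" else "",
                    paste(bad, collapse = ", ")), call. = FALSE)
    v[is.na(v)] <- mean(scale$values)
  }
  W <- scale$window
  if (L < W) {
    return(tibble::tibble(position = integer(), dg = numeric()))
  }
  # stats::filter applies coefficients in reverse order across the window
  sm <- stats::filter(v, rev(scale$positional_weights), method = "convolution",
                      sides = 2)
  centres <- seq.int((W + 1L) %/% 2L, L - (W - 1L) %/% 2L)
  tibble::tibble(position = centres, dg = as.numeric(sm[centres]))
}

#' Free energy tracks for a table of proteins
#'
#' @param proteins A data frame with columns `protein_id` and `sequence`,
#'   e.g. from [read_fasta()].
#' @param scale A [dg_scale()]; defaults to the shipped biological scale.
#' @return A tibble `protein_id`, `position`, `dg` (one row per window
#'   centre per protein).
#' @export
dg_tracks <- function(proteins, scale = default_dg_scale()) {
  stopifnot(is.data.frame(proteins),
            all(c("protein_id", "sequence") %in% names(proteins)))
  proteins |>
    dplyr::select("protein_id", "sequence") |>
    dplyr::mutate(track = purrr::map(.data$sequence, dg_track, scale = scale)) |>
    dplyr::select("protein_id", "track") |>
    tidyr::unnest("track")
}

#' Plot a free-energy insertion track
#'
#' Line plot of the sliding-window insertion free energy, optionally shaded
#' where a topology string places membrane helices.
#'
#' @param track A tibble from [dg_track()] (columns `position`, `dg`), or
#'   from [dg_tracks()] (facetted by `protein_id`).
#' @param topology Optional topology string for a single protein; its `M`
#'   segments are shaded.
#' @return A ggplot object.
#' @export
plot_dg_track <- function(track, topology = NULL) {
  stopifnot(is.data.frame(track), all(c("position", "dg") %in% names(track)))
  p <- ggplot2::ggplot(track, ggplot2::aes(x = .data$position, y = .data$dg))
  if (!is.null(topology)) {
    segs <- dplyr::filter(topo_segments(topology), .data$label == "M")
    if (nrow(segs) > 0L) {
      p <- p + ggplot2::geom_rect(
        data = segs,
        ggplot2::aes(xmin = .data$start, xmax = .data$end,
                     ymin = -Inf, ymax = Inf),
        inherit.aes = FALSE, fill = "grey85"
      )
    }
  }
  p <- p +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sequence position (window centre)",
                  y = expression(Delta * G[insertion] ~ "(kcal/mol)"))
  if ("protein_id" %in% names(track) && length(unique(track$protein_id)) > 1L) {
    p <- p + ggplot2::facet_wrap(~protein_id, scales = "free_x")
  }
  p
}
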