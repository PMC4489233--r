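#' Read protein sequences from a FASTA file
#'
#' Thin tidy wrapper around [Biostrings::readAAStringSet()]: sequences are
#' uppercased, a terminal stop (`*`) is stripped with a warning, duplicate
#' identifiers and residues outside the 20 standard letters plus `X`, `B`,
#' `Z` are errors. The identifier is the first whitespace-delimited token of
#' the header.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `protein_id`, `sequence`, `length`.
#' @export
read_fasta <- function(path) {
  # read as raw strings first: the AA constructor silently drops characters
  # outside its alphabet, and we want to report them instead
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file", call. = FALSE)
  ids <- unname(stringr::str_extract(names(set), "^\\S+"))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate sequence id '%s'", dup[1L]), call. = FALSE)
  }
  seqs <- unname(toupper(as.character(set)))
  stopped <- endsWith(seqs, "*")
  if (any(stopped)) {
    warning(sprintf("stripped terminal '*' from %d sequence(s)", sum(stopped)),
            call. = FALSE)
    seqs[stopped] <- substr(seqs[stopped], 1L, nchar(seqs[stopped]) - 1L)
  }
  ok <- paste0(aa_standard, collapse = "")
  bad <- stringr::str_locate(seqs, sprintf("[^%sXBZ]", ok))[, "start"]
  if (any(!is.na(bad))) {
    k <- which(!is.na(bad))[1L]
    stop(sprintf("sequence '%s' contains invalid character '%s' at position %d",
                 ids[k], substr(seqs[k], bad[k], bad[k]), bad[k]), call. = FALSE)
  }
  if (any(nchar(seqs) == 0L)) {
    stop(sprintf("sequence '%s' is empty", ids[which(nchar(seqs) == 0L)[1L]]),
         call. = FALSE)
  }
  tibble::tibble(protein_id = ids, sequence = seqs, length = nchar(seqs))
}

#' Read a topology table
#'
#' The package's tabular carrier for per-method predictions and reference
#' annotations: a TSV with header `protein_id  method  topology`, `#`
#' comment lines allowed. Each `topology` is a per-residue label string over
#' `S, M, i, o`.
#'
#' @param path Path to the TSV file.
#' @param proteins Optional protein tibble (from [read_fasta()] or
#'   [simulate_proteins()]); when given, every row must name a known protein
#'   and match its sequence length.
#' @return A tibble `protein_id`, `method`, `topology`, rows in file order.
#' @export
read_topology_table <- function(path, proteins = NULL) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("protein_id", "method", "topology")
  if (!all(need %in% names(tab))) {
    stop(sprintf("topology table must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  tab <- tab[, need]
  if (nrow(tab) == 0L) stop("empty topology table", call. = FALSE)
  for (k in seq_len(nrow(tab))) {
    labs <- split_labels(tab$topology[k])
    bad <- which(!labs %in% topo_labels)
    if (length(bad) > 0L) {
      stop(sprintf("unknown label '%s' at position %d (protein %s, method %s)",
                   labs[bad[1L]], bad[1L], tab$protein_id[k], tab$method[k]),
           call. = FALSE)
    }
  }
  if (!is.null(proteins)) {
    unknown <- setdiff(tab$protein_id, proteins$protein_id)
    if (length(unknown) > 0L) {
      stop(sprintf("topology table names unknown protein(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    lens <- rlang::set_names(nchar(proteins$sequence), proteins$protein_id)
    mismatch <- which(nchar(tab$topology) != lens[tab$protein_id])
    if (length(mismatch) > 0L) {
      k <- mismatch[1L]
      stop(sprintf(
        "topology length %d does not match sequence length %d (protein %s, method %s)",
        nchar(tab$topology[k]), lens[[tab$protein_id[k]]],
        tab$protein_id[k], tab$method[k]), call. = FALSE)
    }
  }
  tibble::as_tibble(tab)
}

#' @rdname read_topology_table
#' @param table A data frame with columns `protein_id`, `method`,
#'   `topology`.
#' @return `write_topology_table()` writes the TSV and returns `path`
#'   invisibly.
#' @export
write_topology_table <- function(table, path) {
  stopifnot(is.data.frame(table),
            all(c("protein_id", "method", "topology") %in% names(table)))
  readr::write_tsv(table[, c("protein_id", "method", "topology")], path)
  invisible(path)
}

#' Write sequences to a FASTA file
#'
#' @param proteins A data frame with `protein_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(is.data.frame(proteins),
            all(c("protein_id", "sequence") %in% names(proteins)))
  set <- Biostrings::AAStringSet(rlang::set_names(proteins$sequence,
                                                  proteins$protein_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

wrap_blocks <- function(strings, labels, width = 60L) {
  # align several equal-length strings beneath each other in blocks
  L <- nchar(strings[1L])
  lab_w <- max(nchar(labels)) + 2L
  out <- character()
  for (from in seq.int(1L, L, by = width)) {
    to <- min(from + width - 1L, L)
    out <- c(out,
             vapply(seq_along(strings), function(k) {
               sprintf("%-*s%s", lab_w, labels[k], substr(strings[k], from, to))
             }, character(1)),
             "")
  }
  out
}

#' Write a plain-text consensus report
#'
#' One block per protein: class, score, consensus topology with the
#' per-method predictions aligned beneath it, a 1-based inclusive segment
#' table, and the per-residue agreement track. Output is byte-stable across
#' runs on identical input.
#'
#' @param results Consensus tibble from [consensus_topology()].
#' @param predictions The prediction table the consensus was computed from.
#' @param path Output file path.
#' @param dg Optional tibble from [dg_tracks()]; per-protein values are
#'   appended as a `position dG` table.
#' @return `path`, invisibly.
#' @export
write_consensus_report <- function(results, predictions, path, dg = NULL) {
  stopifnot(is.data.frame(results), nrow(results) > 0L,
            all(c("protein_id", "topology") %in% names(results)))
  lines <- c("# Consensus membrane-protein topology report", "")
  for (k in seq_len(nrow(results))) {
    id <- results$protein_id[k]
    preds <- predictions[predictions$protein_id == id, ]
    segs <- topo_segments(results$topology[k])
    lines <- c(
      lines,
      sprintf("## %s", id),
      sprintf("class: %s", as.character(results$class[k])),
      sprintf("log geometric-mean score: %.6f", results$log_score[k]),
      sprintf("mean agreement: %.3f (%d methods)",
              results$mean_agreement[k], results$n_methods[k]),
      "",
      wrap_blocks(c(results$topology[k], preds$topology),
                  c("consensus", preds$method)),
      "segments (1-based, inclusive):",
      sprintf("  %-6s %6s %6s %6s", "label", "start", "end", "length"),
      sprintf("  %-6s %6d %6d %6d", segs$label, segs$start, segs$end, segs$length),
      ""
    )
    if (!is.null(dg)) {
      tr <- dg[dg$protein_id == id, ]
      if (nrow(tr) > 0L) {
        lines <- c(lines, "dG insertion track (position, kcal/mol):",
                   sprintf("  %6d %8.3f", tr$position, tr$dg), "")
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
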