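#' Build a per-residue topology voting profile
#'
#' Stacks the per-residue topology predictions of several methods into an
#' L x 4 matrix of voting fractions: column `c` holds, for each label in
#' `S, M, i, o`, the fraction of methods that predict that label at residue
#' `c`. This profile is the substrate the consensus decoder maximises over.
#'
#' @param predictions Character vector of topology strings, one per method,
#'   all of the same length. Names, if present, are kept as method names.
#' @return An object of class `topo_profile`: a list with `fractions`
#'   (L x 4 numeric matrix, columns `S, M, i, o`, rows summing to 1),
#'   `n_methods` and `length`.
#' @examples
#' topo_profile(c("iiiMMMooo", "iiiMMMooo", "iiMMMMooo"))
#' @export
topo_profile <- function(predictions) {
  if (!is.character(predictions) || length(predictions) == 0L) {
    stop("at least one prediction is required", call. = FALSE)
  }
  nm <- names(predictions)
  if (is.null(nm)) nm <- paste0("method", seq_along(predictions))
  lens <- nchar(predictions)
  if (length(unique(lens)) != 1L) {
    off <- which(lens != lens[1L])[1L]
    stop(sprintf("prediction '%s' has length %d, expected %d",
                 nm[off], lens[off], lens[1L]), call. = FALSE)
  }
  for (k in seq_along(predictions)) check_topology_string(predictions[k], nm[k])
  L <- lens[1L]
  labmat <- matrix(unlist(strsplit(predictions, "", fixed = TRUE)),
                   nrow = length(predictions), ncol = L, byrow = TRUE)
  fractions <- vapply(topo_labels,
                      function(lab) colSums(labmat == lab) / length(predictions),
                      numeric(L))
  if (L == 1L) fractions <- matrix(fractions, nrow = 1L, dimnames = list(NULL, topo_labels))
  structure(
    list(fractions = fractions, n_methods = length(predictions),
         length = L, methods = nm),
    class = "topo_profile"
  )
}

#' @export
print.topo_profile <- function(x, ...) {
  cat(sprintf("Topology profile: %d residues, %d methods\n", x$length, x$n_methods))
  print(utils::head(x$fractions, 5L))
  if (x$length > 5L) cat(sprintf("... (%d more rows)\n", x$length - 5L))
  invisible(x)
}

#' @describeIn topo_profile Long tibble of per-residue voting fractions
#'   (`position`, `label`, `fraction`).
#' @param x A `topo_profile`.
#' @param ... Unused.
#' @method tidy topo_profile
#' @export
tidy.topo_profile <- function(x, ...) {
  tibble::as_tibble(x$fractions) |>
    dplyr::mutate(position = dplyr::row_number()) |>
    tidyr::pivot_longer(dplyr::all_of(topo_labels),
                        names_to = "label", values_to = "fraction") |>
    dplyr::select("position", "label", "fraction")
}

smooth_profile <- function(fractions, epsilon) {
  if (epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  if (epsilon == 0) return(fractions)
  (fractions + epsilon) / (1 + ncol(fractions) * epsilon)
}

#' Geometric-mean score of a label path against a profile
#'
#' The consensus decoder maximises the geometric mean, over residues, of the
#' profile fraction assigned to the path's label: in log space,
#' `(1/L) * sum_c log p~_c(label_c)`, where `p~` is the profile after
#' pseudocount smoothing (`(p + eps) / (1 + 4 eps)` per column). Smoothing
#' keeps grammar-valid paths finite even when mutually inconsistent one-hot
#' columns would otherwise force a zero somewhere along every valid path.
#'
#' @param profile A [topo_profile()].
#' @param topology A topology string of the same length.
#' @param epsilon Pseudocount added to every fraction before renormalising.
#' @return The mean log smoothed fraction along the path (a single double;
#'   `-Inf` is possible when `epsilon = 0`).
#' @export
score_topology <- function(profile, topology, epsilon = 1e-6) {
  stopifnot(inherits(profile, "topo_profile"))
  labs <- check_topology_string(topology)
  if (length(labs) != profile$length) {
    stop(sprintf("topology length %d does not match profile length %d",
                 length(labs), profile$length), call. = FALSE)
  }
  p <- smooth_profile(profile$fractions, epsilon)
  mean(log(p[cbind(seq_along(labs), match(labs, topo_labels))]))
}
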