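# Independent oracles, kept deliberately separate from the package's own
# code paths: the decoder is checked against exhaustive enumeration of the
# grammar-valid language, the scorer against direct per-column summation,
# and the dG track against naive window sums.

# Enumerate every grammar-valid topology string of length L by construction
# (segment grammar: optional N-terminal S run followed by the post-SP side,
# loops alternating sides across helices within the length bounds, string
# starts and ends with a loop). Cross-validated against brute-force
# filtering of the full 4^L space in the grammar tests.
enumerate_valid_topologies <- local({
  cache <- new.env(parent = emptyenv())
  function(L, grammar) {
    key <- paste(L, grammar$min_helix_len, grammar$max_helix_len,
                 grammar$min_sp_len, grammar$max_sp_len, grammar$post_sp_side,
                 sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    other <- function(s) if (s == "i") "o" else "i"
    bodies <- local({
      memo <- new.env(parent = emptyenv())
      gen <- function(rem, side) {
        k <- paste(rem, side)
        if (!is.null(memo[[k]])) return(memo[[k]])
        out <- character()
        for (l in seq_len(rem)) {
          loop <- strrep(side, l)
          if (l == rem) {
            out <- c(out, loop)
          } else {
            rem2 <- rem - l
            hmax <- min(grammar$max_helix_len, rem2 - 1L)
            if (hmax >= grammar$min_helix_len) {
              for (h in grammar$min_helix_len:hmax) {
                out <- c(out, paste0(loop, strrep("M", h),
                                     gen(rem2 - h, other(side))))
              }
            }
          }
        }
        memo[[k]] <- out
        out
      }
      gen
    })
    res <- c(bodies(L, "i"), bodies(L, "o"))
    sp_max <- min(grammar$max_sp_len, L - 1L)
    if (sp_max >= grammar$min_sp_len) {
      for (sp in grammar$min_sp_len:sp_max) {
        res <- c(res, paste0(strrep("S", sp),
                             bodies(L - sp, grammar$post_sp_side)))
      }
    }
    res <- unique(res)
    cache[[key]] <- res
    res
  }
})

# Direct geometric-mean scorer: plain loop over columns, no smoothing
# shortcuts shared with the package.
oracle_score <- function(fractions, topology, epsilon) {
  labs <- strsplit(topology, "")[[1]]
  total <- 0
  for (c in seq_along(labs)) {
    p <- unname(fractions[c, labs[c]])
    total <- total + log((p + epsilon) / (1 + 4 * epsilon))
  }
  total / length(labs)
}

# Best grammar-valid string by exhaustive search; ties resolved to the set
# of all maximisers so the DP answer only needs to be one of them.
oracle_best <- function(profile, grammar, epsilon) {
  cand <- enumerate_valid_topologies(profile$length, grammar)
  scores <- vapply(cand, oracle_score, numeric(1),
                   fractions = profile$fractions, epsilon = epsilon,
                   USE.NAMES = FALSE)
  best <- max(scores)
  list(score = best, argmax = cand[abs(scores - best) < 1e-12])
}

# Naive sliding-window dG: explicit sum at every full-window centre.
oracle_dg <- function(sequence, scale) {
  aa <- strsplit(sequence, "")[[1]]
  v <- unname(scale$values[aa])
  W <- scale$window
  L <- length(aa)
  if (L < W) return(data.frame(position = integer(), dg = numeric()))
  half <- (W - 1L) / 2L
  centres <- (half + 1L):(L - half)
  dg <- vapply(centres, function(c) {
    sum(scale$positional_weights * v[(c - half):(c + half)])
  }, numeric(1))
  data.frame(position = centres, dg = dg)
}
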