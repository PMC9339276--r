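# Shared fixtures: tiny alignments and record/count builders used across the
# module tests.  Everything is built in code; no files ship with the tests.

`%||%` <- function(x, y) if (is.null(x)) y else x

# A gap-free triplet where all three sequences are identical.
identical_triplet <- function(seq = "ACGTACGTACGTACGTACGT", id = "r1") {
  triplet_alignment(id, seq, seq, seq)
}

# Replace 1-based positions of a string with a character.
poke <- function(seq, pos, char = "-") {
  for (p in pos) substr(seq, p, p) <- char
  seq
}

# Build a record tibble directly (bypassing alignment ingest).
make_records <- function(left, right, ancestral, derived, ingroup = 1L,
                         region_id = "r", radius = nchar(left[1])) {
  n <- max(length(left), length(right), length(ancestral), length(derived))
  out <- tibble::tibble(
    region_id = rep_len(region_id, n),
    column = seq_len(n) - 1L,
    left = rep_len(left, n), right = rep_len(right, n),
    ancestral = rep_len(ancestral, n), derived = rep_len(derived, n),
    ingroup = rep_len(ingroup, n)
  )
  attr(out, "radius") <- radius
  out
}

# Random 4x4 row-stochastic matrix with strictly positive entries (ergodic).
random_stochastic <- function() {
  m <- matrix(stats::rexp(16) + 1e-3, 4, 4)
  m / rowSums(m)
}

# Independent stationary-distribution oracle: long power iteration.
power_iteration_phi <- function(P, iters = 10000) {
  phi <- rep(0.25, 4)
  for (i in seq_len(iters)) phi <- as.vector(phi %*% P)
  phi / sum(phi)
}
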