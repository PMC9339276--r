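# Flanking-context bookkeeping shared by every stage of the pipeline.
#
# A context is the pair of r-mers flanking a focal site: `left` reads 5'->3'
# and ends immediately 5' of the site, `right` reads 5'->3' and starts
# immediately 3' of it.  Radius r = 3 gives the hexanucleotide context
# N3 N2 N1 [N0] N1 N2 N3.

BASES <- c("A", "C", "G", "T")

# transition partner of each base (A<->G, C<->T)
TS_PARTNER <- c(A = "G", C = "T", G = "A", T = "C")

#' Complement bases in a character vector of sequences
#'
#' @param x Character vector of sequences over `A`, `C`, `G`, `T` (a gap `-`
#'   is preserved).
#' @return Character vector of the same length with each base complemented
#'   (no reversal).
#' @export
comp_bases <- function(x) chartr("ACGT", "TGCA", x)

#' Reverse-complement a character vector of k-mers
#'
#' @param x Character vector of sequences over `A`, `C`, `G`, `T`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  vapply(
    strsplit(comp_bases(x), NULL),
    function(s) paste(rev(s), collapse = ""),
    character(1)
  )
}

#' Reverse-complement a context
#'
#' Reading the opposite strand swaps the two flanks and complements them:
#' `rc(left, right) = (revcomp(right), revcomp(left))`.  The operation is an
#' involution.
#'
#' @param left,right Character vectors of flanking r-mers (5'->3').
#' @return A list with components `left` and `right`.
#' @export
context_rc <- function(left, right) {
  stopifnot(length(left) == length(right))
  list(left = revcomp(right), right = revcomp(left))
}

#' Canonicalize contexts under reverse-complement equivalence
#'
#' The canonical representative of the pair `{c, rc(c)}` is the one whose
#' concatenated `left + right` string is lexicographically smaller; this is
#' deterministic and independent of input order.
#'
#' @inheritParams context_rc
#' @return A tibble with columns `left`, `right` (canonical representative)
#'   and `flipped` (`TRUE` where the input context was replaced by its
#'   reverse complement, so base labels must be complemented to follow).
#' @export
canonicalize_context <- function(left, right) {
  rc <- context_rc(left, right)
  flipped <- paste0(rc$left, rc$right) < paste0(left, right)
  tibble::tibble(
    left = ifelse(flipped, rc$left, left),
    right = ifelse(flipped, rc$right, right),
    flipped = flipped
  )
}

#' Enumerate all contexts of a given radius
#'
#' Contexts are returned in the canonical base-4 order (A=0, C=1, G=2, T=3 on
#' the concatenated `left + right` string), so row `i` corresponds to code
#' `i - 1`.
#'
#' @param radius Integer flank width, 1 to 4.
#' @return A tibble with columns `left` and `right`, one row per context
#'   (`4^(2 * radius)` rows).
#' @export
enumerate_contexts <- function(radius) {
  radius <- check_radius(radius)
  k <- 2L * radius
  codes <- 0:(4^k - 1)
  digits <- vapply(
    seq_len(k),
    function(j) (codes %/% 4^(k - j)) %% 4,
    numeric(length(codes))
  )
  chars <- matrix(BASES[digits + 1], nrow = length(codes))
  collapse <- function(cols) {
    do.call(paste0, lapply(cols, function(j) chars[, j]))
  }
  tibble::tibble(
    left = collapse(seq_len(radius)),
    right = collapse(radius + seq_len(radius))
  )
}

#' Canonical contexts and the reverse-complement folding map
#'
#' `canonical_contexts()` lists the distinct context classes under
#' reverse-complement equivalence; `context_fold_map()` maps every raw
#' context to its class.  For radius r there are `(4^(2r) - 4^r) / 2 + 4^r`
#' classes: 2,080 hexanucleotide classes at r = 3, of which 64 are
#' self-complementary.
#'
#' @inheritParams enumerate_contexts
#' @return `canonical_contexts()`: a tibble with columns `left`, `right` and
#'   `self_complementary`.  `context_fold_map()`: a tibble with columns
#'   `left`, `right`, `canon_left`, `canon_right`, `flipped`,
#'   `self_complementary`, one row per raw context.
#' @export
canonical_contexts <- function(radius) {
  map <- context_fold_map(radius)
  out <- unique(map[, c("canon_left", "canon_right", "self_complementary")])
  tibble::tibble(
    left = out$canon_left,
    right = out$canon_right,
    self_complementary = out$self_complementary
  )
}

#' @rdname canonical_contexts
#' @export
context_fold_map <- function(radius) {
  ctx <- enumerate_contexts(radius)
  can <- canonicalize_context(ctx$left, ctx$right)
  tibble::tibble(
    left = ctx$left,
    right = ctx$right,
    canon_left = can$left,
    canon_right = can$right,
    flipped = can$flipped,
    self_complementary = ctx$left == can$left & ctx$right == can$right &
      paste0(ctx$left, ctx$right) ==
        paste0(revcomp(ctx$right), revcomp(ctx$left))
  )
}

#' Number of canonical context classes
#'
#' @inheritParams enumerate_contexts
#' @return Integer: `(4^(2 * radius) - 4^radius) / 2 + 4^radius`.
#' @export
n_canonical_contexts <- function(radius) {
  radius <- check_radius(radius)
  as.integer((4^(2 * radius) - 4^radius) / 2 + 4^radius)
}

check_radius <- function(radius) {
  if (length(radius) != 1L || is.na(radius) || radius != as.integer(radius) ||
      radius < 1 || radius > 4) {
    stop("`radius` must be a single integer between 1 and 4", call. = FALSE)
  }
  as.integer(radius)
}

check_bases <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters other than A/C/G/T: e.g. '%s'",
                 what, x[bad][1]), call. = FALSE)
  }
  invisible(x)
}

# string <-> integer code helpers used by the simulator
seq_to_int <- function(seq) {
  s <- match(strsplit(seq, NULL)[[1]], BASES)
  if (anyNA(s)) stop("sequence contains characters other than A/C/G/T", call. = FALSE)
  s
}

int_to_seq <- function(s) paste(BASES[s], collapse = "")
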