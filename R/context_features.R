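# Composition indices of the flanking hexanucleotide, CpG contingency
# analysis, nearest-neighbor duplex stability, and correlation helpers.

# positions of the N_i pair within a radius-3 context: left flank reads
# 5'->3' (N3 N2 N1), right flank reads 5'->3' (N1 N2 N3)
ni_pair <- function(left, right, i) {
  cbind(substr(left, 4 - i, 4 - i), substr(right, i, i))
}

index_sum <- function(left, right, score, weights) {
  stopifnot(all(nchar(left) == 3), all(nchar(right) == 3),
            length(left) == length(right))
  check_bases(left, "context")
  check_bases(right, "context")
  out <- numeric(length(left))
  for (i in 1:3) {
    p <- ni_pair(left, right, i)
    out <- out + (score(p[, 1]) + score(p[, 2])) * weights[i]
  }
  as.integer(out)
}

#' Flanking-composition indices ATI, RI and RATI
#'
#' Distance-weighted summaries of the hexanucleotide context (radius 3),
#' each ranging 0-28:
#'
#' * `ati()` — A+T index: `sum_i W_i * 2^(4 - i)` where `W_i` is the number
#'   of A/T bases in the `N_i` neighboring pair.  Invariant under reverse
#'   complementation of the context.
#' * `ri()` — purine index: the same weighting of the purine (A/G) count on
#'   the analyzed strand; used for substitutions of pyrimidines (the
#'   pyrimidine index of the other strand is `28 - ri`).
#' * `rati()` — combined purine/A+T index: `sum_i B_i * 2^(3 - i)` where
#'   `B_i` is the sum of the per-base scores A = 2, C = 0, G = 1, T = 1 over
#'   the pair.
#'
#' The weight base is exposed for sensitivity analyses; with the default of
#' 2 the ATI/RI weights are 8, 4, 2 and the RATI weights 4, 2, 1.
#'
#' @param left,right Character vectors of 3-mer flanks (5'->3').
#' @param weight_base Base of the geometric distance weights (default 2).
#' @return Integer vector of index values.
#' @export
ati <- function(left, right, weight_base = 2) {
  index_sum(left, right, function(b) b %in% c("A", "T"),
            weight_base^(4 - (1:3)))
}

#' @rdname ati
#' @export
ri <- function(left, right, weight_base = 2) {
  index_sum(left, right, function(b) b %in% c("A", "G"),
            weight_base^(4 - (1:3)))
}

#' @rdname ati
#' @export
rati <- function(left, right, weight_base = 2) {
  sc <- c(A = 2, C = 0, G = 1, T = 1)
  index_sum(left, right, function(b) sc[b], weight_base^(3 - (1:3)))
}

#' Index table for every context of radius 3
#'
#' @inheritParams ati
#' @return A tibble with `left`, `right`, `ati`, `ri`, `rati` for all 4,096
#'   hexanucleotide contexts.
#' @export
context_index_table <- function(weight_base = 2) {
  ctx <- enumerate_contexts(3)
  tibble::tibble(
    left = ctx$left, right = ctx$right,
    ati = ati(ctx$left, ctx$right, weight_base),
    ri = ri(ctx$left, ctx$right, weight_base),
    rati = rati(ctx$left, ctx$right, weight_base)
  )
}

#' CpG contingency tables
#'
#' Aggregates strand-explicit (uncombined) counts into the two 2x2 tables
#' that quantify CpG hypermutability on each strand:
#'
#' * `g_to_a`: rows CG (focal G immediately preceded by a 5' C) versus DG
#'   (D = A/G/T); columns G->A versus G->B (B = not A, conserved G included).
#' * `c_to_t`: rows CG (focal C immediately followed by a 3' G) versus CH
#'   (H = A/C/T); columns C->T versus C->V (V = not T, conserved C included).
#'
#' @param counts A raw (non-canonical) counts tibble of radius >= 1; the
#'   strand-explicit counts are required because the effect is reported per
#'   strand.
#' @return A list of two 2x2 matrices, `g_to_a` and `c_to_t`.
#' @export
cpg_tables <- function(counts) {
  if (isTRUE(attr(counts, "canonical"))) {
    stop("CpG tables require strand-explicit (uncombined) counts", call. = FALSE)
  }
  if (nrow(counts) == 0L) stop("no counts", call. = FALSE)
  five_prime <- substr(counts$left, nchar(counts$left), nchar(counts$left))
  three_prime <- substr(counts$right, 1, 1)
  tab <- function(sel_focal, sel_cpg, sel_target) {
    cells <- matrix(0, 2, 2)
    for (rr in 1:2) {
      for (cc in 1:2) {
        keep <- sel_focal &
          (if (rr == 1) sel_cpg else !sel_cpg) &
          (if (cc == 1) sel_target else !sel_target)
        cells[rr, cc] <- sum(counts$count[keep])
      }
    }
    cells
  }
  g_to_a <- tab(counts$ancestral == "G", five_prime == "C",
                counts$derived == "A")
  dimnames(g_to_a) <- list(c("CG", "DG"), c("G>A", "G>B"))
  c_to_t <- tab(counts$ancestral == "C", three_prime == "G",
                counts$derived == "T")
  dimnames(c_to_t) <- list(c("CG", "CH"), c("C>T", "C>V"))
  list(g_to_a = g_to_a, c_to_t = c_to_t)
}

#' Rate ratio of a 2x2 contingency table
#'
#' The per-site rate of the focal change in the first row divided by the
#' rate in the second row (e.g. C->T rate in CG contexts over the C->T rate
#' elsewhere), with a delta-method standard error.
#'
#' @param table A 2x2 matrix shaped as in [cpg_tables()]: rows are context
#'   classes, column 1 the focal change, column 2 everything else.
#' @return A list: `ratio`, `se`, and the two per-row rates `rate1`, `rate2`.
#' @export
cpg_rate_ratio <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)))
  n1 <- sum(table[1, ]); n2 <- sum(table[2, ])
  if (table[1, 1] == 0 || table[2, 1] == 0 || n1 == 0 || n2 == 0) {
    stop("rate ratio undefined: zero focal count or empty row", call. = FALSE)
  }
  p1 <- table[1, 1] / n1
  p2 <- table[2, 1] / n2
  ratio <- p1 / p2
  se <- ratio * sqrt((1 - p1) / table[1, 1] + (1 - p2) / table[2, 1])
  list(ratio = ratio, se = se, rate1 = p1, rate2 = p2)
}

#' Odds ratio of a 2x2 table
#'
#' The cross-product ratio `(a / b) / (c / d)` for rows `(a, b)` and
#' `(c, d)`, with no continuity correction.  Returns `NA` (with a warning)
#' when any cell is zero.
#'
#' @param table A 2x2 numeric matrix.
#' @return The odds ratio (numeric scalar).
#' @export
odds_ratio <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)))
  if (any(table == 0)) {
    warning("2x2 table has a zero cell; odds ratio undefined")
    return(NA_real_)
  }
  (table[1, 1] / table[1, 2]) / (table[2, 1] / table[2, 2])
}

#' Pearson chi-square test of heterogeneity for a 2x2 table
#'
#' Pearson chi-square with 1 degree of freedom and no continuity correction.
#'
#' @param table A 2x2 numeric matrix with nonzero margins.
#' @return A list: `statistic`, `p_value`, `df`.
#' @export
chi2_heterogeneity <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("2x2 table has a zero margin", call. = FALSE)
  }
  ht <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df = unname(ht$parameter))
}

# Unified nearest-neighbor free energies (kcal/mol) for DNA duplex
# propagation at 37 C, from the standard unified parameter set
# (SantaLucia's 1998 compilation); initiation and terminal corrections are
# omitted because only relative comparisons across oligomers are used.
NN_DG37 <- c(
  AA = -1.00, AC = -1.44, AG = -1.28, AT = -0.88,
  CA = -1.45, CC = -1.84, CG = -2.17, CT = -1.28,
  GA = -1.30, GC = -2.24, GG = -1.84, GT = -1.44,
  TA = -0.58, TC = -1.30, TG = -1.45, TT = -1.00
)

#' Nearest-neighbor duplex stability of an oligonucleotide
#'
#' Sum of the internal dinucleotide-step free energies (delta-G at 37 C,
#' kcal/mol) over the embedded unified nearest-neighbor table; for a 7-mer
#' this is the 6-step sum.  No initiation or terminal terms are added, so
#' values are comparable across equal-length oligomers only.  By the duplex
#' symmetry of the parameters, an oligomer and its reverse complement score
#' identically.
#'
#' @param oligo Character vector of sequences over `A`, `C`, `G`, `T`
#'   (length >= 2 nt each; the heptanucleotide context-plus-focal-base is
#'   the intended use).
#' @return Numeric vector of delta-G37 values (kcal/mol, negative = more
#'   stable).
#' @export
duplex_stability <- function(oligo) {
  check_bases(oligo, "oligo")
  if (any(nchar(oligo) < 2)) stop("oligomers must be at least 2 nt", call. = FALSE)
  vapply(oligo, function(s) {
    n <- nchar(s)
    steps <- substring(s, 1:(n - 1), 2:n)
    sum(NN_DG37[steps])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Squared Pearson correlation
#'
#' @param x,y Equal-length numeric vectors (length >= 2) with nonzero
#'   variance.
#' @return The squared Pearson correlation coefficient.
#' @export
pearson_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in `x` or `y`", call. = FALSE)
  }
  stats::cor(x, y)^2
}

#' Published CpG contingency counts for noncoding chloroplast DNA
#'
#' Loads the 2x2 contingency counts of CpG-context versus other-context
#' substitutions reported for a large survey of angiosperm chloroplast
#' genome triplets (about one million substitutions in intergenic regions),
#' shipped with the package as a plain-text table.  Columns are the
#' focal-base change on each strand (G->A with its 5' neighbor, C->T with
#' its 3' neighbor); the reported odds ratios are 1.36 and 1.37.
#'
#' @return A list of two 2x2 matrices shaped like [cpg_tables()] output.
#' @export
published_cpg_counts <- function() {
  path <- system.file("extdata", "cpg_counts_cpdna.tsv", package = "ctxsub",
                      mustWork = TRUE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- list()
  for (an in unique(x$analysis)) {
    sub <- x[x$analysis == an, ]
    m <- matrix(sub$count, 2, 2, byrow = TRUE,
                dimnames = list(unique(sub$row_context), unique(sub$outcome)))
    out[[an]] <- m
  }
  out
}
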