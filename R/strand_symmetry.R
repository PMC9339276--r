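# Strand-symmetry machinery: orient genomes by a reference gene set, select
# genes with a consistent strand arrangement, and test whether complementary
# contexts give equivalent equilibrium predictions.

SYMMETRY_REFERENCE_GENES <- c("rps12", "psba", "psbk", "psbd", "psbc")

normalize_gene <- function(x) tolower(trimws(x))

#' Orient genomes by the reference gene arrangement
#'
#' Keeps the genomes in which all five reference genes are annotated, the
#' first two (`rps12`, `psbA`) share one strand, and the remaining three
#' (`psbK`, `psbD`, `psbC`) share the other; the strand carrying
#' `rps12`/`psbA` is relabeled strand "A", the opposite strand "C".
#' Genomes with a missing reference gene, a split arrangement, or
#' conflicting duplicate annotations are excluded (and tallied).
#'
#' @param annotations A data frame with columns `genome_id`, `gene`,
#'   `strand` (`+`/`-` as annotated); gene names are case-normalized.
#' @param reference Character vector of 5 reference genes, the first two
#'   expected on one strand and the last three on the other.
#' @return A tibble with columns `genome_id` and `strand_a` (which annotated
#'   strand is strand A), with an attribute `log` of exclusion tallies.
#' @export
find_symmetry_genomes <- function(annotations,
                                  reference = SYMMETRY_REFERENCE_GENES) {
  stopifnot(all(c("genome_id", "gene", "strand") %in% names(annotations)),
            length(reference) == 5)
  ann <- tibble::tibble(
    genome_id = annotations$genome_id,
    gene = normalize_gene(annotations$gene),
    strand = as.character(annotations$strand)
  )
  stopifnot(all(ann$strand %in% c("+", "-")))
  reference <- normalize_gene(reference)
  kept <- list()
  n_missing <- 0L
  n_split <- 0L
  for (gid in unique(ann$genome_id)) {
    sub <- ann[ann$genome_id == gid, ]
    strands <- lapply(reference, function(g) unique(sub$strand[sub$gene == g]))
    if (any(lengths(strands) != 1L)) {
      n_missing <- n_missing + 1L
      next
    }
    strands <- unlist(strands)
    if (length(unique(strands[1:2])) != 1L ||
        length(unique(strands[3:5])) != 1L ||
        strands[1] == strands[3]) {
      n_split <- n_split + 1L
      next
    }
    kept[[gid]] <- tibble::tibble(genome_id = gid, strand_a = strands[1])
  }
  out <- dplyr::bind_rows(kept)
  attr(out, "log") <- c(genomes = length(unique(ann$genome_id)),
                        kept = nrow(out),
                        excluded_missing_reference = n_missing,
                        excluded_split_reference = n_split)
  out
}

#' Select genes with a consistent strand arrangement
#'
#' From the oriented (symmetry) genomes, keeps the genes annotated in at
#' least `presence_min` of them whose strand-A fraction is at least
#' `consistency_min` or at most `1 - consistency_min` — i.e. genes whose
#' arrangement relative to the reference set is consistent.  Both fractions
#' use the number of symmetry genomes as the denominator, and the result
#' does not depend on genome order.
#'
#' @param annotations As in [find_symmetry_genomes()].
#' @param oriented Output of [find_symmetry_genomes()].
#' @param presence_min Minimum annotation fraction (default 0.90).
#' @param consistency_min Minimum consistent-strand fraction (default 0.80).
#' @return A tibble with columns `gene`, `n_annotated`, `frac_annotated`,
#'   `frac_strand_a`.
#' @export
find_symmetry_genes <- function(annotations, oriented,
                                presence_min = 0.90, consistency_min = 0.80) {
  if (nrow(oriented) == 0L) stop("no oriented genomes", call. = FALSE)
  ann <- tibble::tibble(
    genome_id = annotations$genome_id,
    gene = normalize_gene(annotations$gene),
    strand = as.character(annotations$strand)
  )
  ann <- dplyr::inner_join(ann, oriented, by = "genome_id")
  ann$on_a <- ann$strand == ann$strand_a
  n_genomes <- nrow(oriented)
  per_gene <- dplyr::summarise(
    dplyr::group_by(ann, .data$gene),
    n_annotated = dplyr::n_distinct(.data$genome_id),
    n_on_a = dplyr::n_distinct(.data$genome_id[.data$on_a]),
    .groups = "drop"
  )
  per_gene$frac_annotated <- per_gene$n_annotated / n_genomes
  per_gene$frac_strand_a <- per_gene$n_on_a / n_genomes
  keep <- per_gene$frac_annotated >= presence_min &
    (per_gene$frac_strand_a >= consistency_min |
       per_gene$frac_strand_a <= 1 - consistency_min)
  out <- per_gene[keep, c("gene", "n_annotated", "frac_annotated",
                          "frac_strand_a")]
  dplyr::arrange(out, .data$gene)
}

#' Equilibrium agreement between complementary contexts
#'
#' For every complementary context pair `{c, rc(c)}` with at least
#' `min_subs` substitutions on each side, computes the stationary vector of
#' each strand-explicit matrix independently, complement-transforms the
#' reverse-complement side onto the reported strand, and correlates the two
#' predictions across pairs.  Under a strand-symmetric process the two sides
#' estimate the same equilibrium, so both squared correlations approach 1.
#' Self-complementary contexts are excluded (their two "sides" are the same
#' matrix), as are pairs with a degenerate stationary vector.
#'
#' @param counts A strand-explicit (uncombined) counts tibble.
#' @param min_subs Minimum substitutions per side (default 50).
#' @return A list: `r2_at_percent`, `r2_at_skew`, `n_pairs`, and the paired
#'   `table`.
#' @export
complementary_context_correlation <- function(counts, min_subs = 50) {
  if (isTRUE(attr(counts, "canonical"))) {
    stop("strand-explicit (uncombined) counts are required", call. = FALSE)
  }
  radius <- attr(counts, "radius")
  if (is.null(radius)) radius <- nchar(counts$left[1])
  subs <- dplyr::summarise(
    dplyr::group_by(counts, .data$left, .data$right),
    n_subs = sum(.data$count[.data$ancestral != .data$derived]),
    .groups = "drop"
  )
  can <- canonicalize_context(subs$left, subs$right)
  selfc <- subs$left == revcomp(subs$right)
  subs$key <- paste0(can$left, "|", can$right)
  rows <- list()
  for (key in unique(subs$key[!selfc])) {
    pair <- subs[subs$key == key & !selfc, ]
    if (nrow(pair) != 2L || any(pair$n_subs < min_subs)) next
    # put the canonical representative first
    pair <- pair[order(paste0(pair$left, pair$right)), ]
    side <- lapply(seq_len(2L), function(i) {
      stationary_vector(to_transition_matrix(
        count_matrix(counts, pair$left[i], pair$right[i])
      ))
    })
    if (any(vapply(side, function(s) s$degenerate, logical(1)))) next
    # side 1 is the canonical context; complement-fold side 2 onto its strand
    f1 <- side[[1]]$freqs
    f2 <- side[[2]]$freqs[c(4, 3, 2, 1)]
    s1 <- composition_stats(f1)
    s2 <- composition_stats(f2 / sum(f2))
    rows[[key]] <- tibble::tibble(
      left = pair$left[1], right = pair$right[1],
      n_subs_fwd = pair$n_subs[1], n_subs_rc = pair$n_subs[2],
      at_percent_fwd = s1$at_percent, at_percent_rc = s2$at_percent,
      at_skew_fwd = s1$at_skew, at_skew_rc = s2$at_skew
    )
  }
  tab <- dplyr::bind_rows(rows)
  # a sparse matrix can have a legitimate all-G/C stationary vector, whose
  # A-T skew is undefined; such pairs stay in the table but not in the r^2
  ok_at <- stats::complete.cases(tab[, c("at_percent_fwd", "at_percent_rc")])
  ok_skew <- stats::complete.cases(tab[, c("at_skew_fwd", "at_skew_rc")])
  if (nrow(tab) < 2L || sum(ok_at) < 2L) {
    stop("fewer than 2 complementary pairs pass `min_subs`", call. = FALSE)
  }
  list(
    r2_at_percent = pearson_r2(tab$at_percent_fwd[ok_at],
                               tab$at_percent_rc[ok_at]),
    r2_at_skew = if (sum(ok_skew) >= 2L) {
      pearson_r2(tab$at_skew_fwd[ok_skew], tab$at_skew_rc[ok_skew])
    } else NA_real_,
    n_pairs = nrow(tab),
    table = tab
  )
}
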