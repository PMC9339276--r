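# Equilibrium (stationary) base composition implied by each context's
# transition matrix, and its comparison with the composition actually
# observed at sites in that context.

#' Stationary vector of a transition matrix
#'
#' Solves `phi = phi %*% P` by left eigen-decomposition, falling back to
#' power iteration when the eigen solution is not a clean probability
#' vector.  Values in `(-1e-12, 0)` are clipped to zero and the vector is
#' renormalized to sum 1.  The result is degenerate when any row of `P` is
#' empty (no data: zeros are reported), when the unit eigenvalue is not
#' unique (reducible chain), or when the fixed-point residual exceeds
#' `1e-10`.
#'
#' @param tm A [to_transition_matrix()] result, or a 4x4 row-stochastic
#'   matrix.
#' @return A list of class `stationary_vector`: `freqs` (named A/C/G/T),
#'   `degenerate` (flag), `residual` (`max |phi P - phi|`) and `context`
#'   when available.
#' @export
stationary_vector <- function(tm) {
  ctx <- NULL
  if (inherits(tm, "transition_matrix")) {
    ctx <- tm$context
    if (any(tm$empty)) {
      return(structure(
        list(freqs = stats::setNames(rep(0, 4), BASES), degenerate = TRUE,
             residual = NA_real_, context = ctx),
        class = "stationary_vector"
      ))
    }
    P <- tm$probs
  } else {
    P <- tm
  }
  stopifnot(is.matrix(P), all(dim(P) == c(4, 4)))
  if (anyNA(P)) {
    return(structure(
      list(freqs = stats::setNames(rep(0, 4), BASES), degenerate = TRUE,
           residual = NA_real_, context = ctx),
      class = "stationary_vector"
    ))
  }

  e <- eigen(t(P))
  near_one <- abs(e$values - 1) < 1e-8
  unique_unit <- sum(near_one) == 1L
  phi <- NULL
  if (any(near_one)) {
    v <- e$vectors[, which.min(abs(e$values - 1))]
    if (max(abs(Im(v))) < 1e-10) {
      v <- Re(v)
      if (abs(sum(v)) > 1e-12) {
        v <- v / sum(v)
        if (all(v > -1e-12)) phi <- v
      }
    }
  }
  if (is.null(phi)) {
    # power iteration fallback
    phi <- rep(0.25, 4)
    for (it in seq_len(10000L)) {
      nxt <- as.vector(phi %*% P)
      if (max(abs(nxt - phi)) < 1e-14) {
        phi <- nxt
        break
      }
      phi <- nxt
    }
  }
  phi[phi > -1e-12 & phi < 0] <- 0
  phi <- phi / sum(phi)
  residual <- max(abs(as.vector(phi %*% P) - phi))
  structure(
    list(freqs = stats::setNames(phi, BASES),
         degenerate = !unique_unit || residual > 1e-10,
         residual = residual, context = ctx),
    class = "stationary_vector"
  )
}

#' @export
print.stationary_vector <- function(x, ...) {
  cat("phi:", paste(sprintf("%s=%.4f", BASES, x$freqs), collapse = " "),
      if (x$degenerate) "(degenerate)" else "", "\n")
  invisible(x)
}

#' Composition statistics of a base-frequency vector
#'
#' A+T percentage and the signed skews `100 * (G - C) / (G + C)` and
#' `100 * (A - T) / (A + T)`; a skew is `NA` when its denominator is zero.
#'
#' @param freqs Length-4 frequencies in A, C, G, T order, summing to 1 (a
#'   [stationary_vector()] is also accepted).
#' @return A list: `at_percent`, `gc_skew`, `at_skew`.
#' @export
composition_stats <- function(freqs) {
  if (inherits(freqs, "stationary_vector")) freqs <- freqs$freqs
  stopifnot(length(freqs) == 4, all(freqs >= 0))
  if (abs(sum(freqs) - 1) > 1e-6) stop("`freqs` must sum to 1", call. = FALSE)
  a <- freqs[1]; c_ <- freqs[2]; g <- freqs[3]; t_ <- freqs[4]
  list(
    at_percent = unname(100 * (a + t_)),
    gc_skew = if (g + c_ == 0) NA_real_ else unname(100 * (g - c_) / (g + c_)),
    at_skew = if (a + t_ == 0) NA_real_ else unname(100 * (a - t_) / (a + t_))
  )
}

#' Observed base composition per canonical context
#'
#' Counts the focal base at every eligible site, both ingroup bases counted
#' (two records per site), folded onto canonical contexts exactly as the
#' count matrices are: a record whose context is replaced by its reverse
#' complement contributes its complemented base.  Records from
#' self-complementary contexts are counted twice (once per strand reading),
#' mirroring [combine_complements()].
#'
#' @param records A record tibble from [extract_records()].
#' @param radius Context radius of the records.
#' @param from One of `"derived"` (default: the ingroup bases, two per
#'   site) or `"ancestral"` (the outgroup base, still one per record).
#' @return A tibble: `left`, `right` (canonical), `n_obs`, `n_sites` and
#'   `freq_A` .. `freq_T`.
#' @export
observed_composition <- function(records, radius = attr(records, "radius"),
                                 from = c("derived", "ancestral")) {
  from <- match.arg(from)
  if (nrow(records) == 0L) {
    return(tibble::tibble(left = character(0), right = character(0),
                          n_obs = integer(0), n_sites = numeric(0),
                          freq_A = numeric(0), freq_C = numeric(0),
                          freq_G = numeric(0), freq_T = numeric(0)))
  }
  if (is.null(radius)) radius <- nchar(records$left[1])
  map <- context_fold_map(radius)
  x <- dplyr::inner_join(
    tibble::tibble(left = records$left, right = records$right,
                   base = records[[from]]),
    map, by = c("left", "right")
  )
  x$base <- ifelse(x$flipped, comp_bases(x$base), x$base)
  n_rec <- dplyr::count(x, .data$canon_left, .data$canon_right, name = "n_rec")
  x_dup <- x[x$self_complementary, ]
  x_dup$base <- comp_bases(x_dup$base)
  x <- dplyr::bind_rows(x, x_dup)
  agg <- dplyr::count(x, .data$canon_left, .data$canon_right, .data$base,
                      name = "n")
  wide <- dplyr::summarise(
    dplyr::group_by(agg, .data$canon_left, .data$canon_right),
    n_obs = sum(.data$n),
    freq_A = sum(.data$n[.data$base == "A"]) / sum(.data$n),
    freq_C = sum(.data$n[.data$base == "C"]) / sum(.data$n),
    freq_G = sum(.data$n[.data$base == "G"]) / sum(.data$n),
    freq_T = sum(.data$n[.data$base == "T"]) / sum(.data$n),
    .groups = "drop"
  )
  wide <- dplyr::left_join(wide, n_rec, by = c("canon_left", "canon_right"))
  tibble::tibble(
    left = wide$canon_left, right = wide$canon_right,
    n_obs = wide$n_obs, n_sites = wide$n_rec / 2,
    freq_A = wide$freq_A, freq_C = wide$freq_C,
    freq_G = wide$freq_G, freq_T = wide$freq_T
  )
}

#' Predicted versus observed composition across contexts
#'
#' For every canonical context with at least `min_subs` substitutions, pairs
#' the stationary composition predicted from its transition matrix with the
#' composition observed at its sites, and reports the squared Pearson
#' correlation per statistic (A+T %, G-C skew, A-T skew).  Degenerate
#' stationary vectors are kept in the table (flagged) but excluded from the
#' correlations.
#'
#' @param counts A canonical counts tibble (see [combine_complements()]).
#' @param records The record tibble the counts were accumulated from.
#' @param min_subs Minimum off-diagonal (substitution) count per context.
#' @param from Passed to [observed_composition()].
#' @return A list: `table` (one row per retained context with predicted and
#'   observed statistics) and `r2` (named vector: `at_percent`, `gc_skew`,
#'   `at_skew`).
#' @export
predicted_vs_observed <- function(counts, records, min_subs = 50,
                                  from = "derived") {
  if (!isTRUE(attr(counts, "canonical"))) {
    counts <- combine_complements(counts)
  }
  subs <- dplyr::summarise(
    dplyr::group_by(counts, .data$left, .data$right),
    n_subs = sum(.data$count[.data$ancestral != .data$derived]),
    .groups = "drop"
  )
  keep <- subs[subs$n_subs >= min_subs, ]
  if (nrow(keep) < 2L) {
    stop("fewer than 2 contexts pass `min_subs`", call. = FALSE)
  }
  obs <- observed_composition(records, from = from)
  rows <- lapply(seq_len(nrow(keep)), function(i) {
    lft <- keep$left[i]; rgt <- keep$right[i]
    phi <- stationary_vector(to_transition_matrix(count_matrix(counts, lft, rgt)))
    pred <- composition_stats(phi$freqs)
    o <- obs[obs$left == lft & obs$right == rgt, ]
    if (nrow(o) == 0L) return(NULL)
    ofreq <- c(o$freq_A, o$freq_C, o$freq_G, o$freq_T)
    ostat <- composition_stats(ofreq / sum(ofreq))
    tibble::tibble(
      left = lft, right = rgt, n_subs = keep$n_subs[i], n_sites = o$n_sites,
      degenerate = phi$degenerate,
      pred_at_percent = pred$at_percent, obs_at_percent = ostat$at_percent,
      pred_gc_skew = pred$gc_skew, obs_gc_skew = ostat$gc_skew,
      pred_at_skew = pred$at_skew, obs_at_skew = ostat$at_skew
    )
  })
  tab <- dplyr::bind_rows(rows)
  ok <- !tab$degenerate
  r2_of <- function(px, ox) {
    keep <- ok & !is.na(px) & !is.na(ox)
    if (sum(keep) < 2L) return(NA_real_)
    if (stats::sd(px[keep]) == 0 || stats::sd(ox[keep]) == 0) return(NA_real_)
    pearson_r2(px[keep], ox[keep])
  }
  list(
    table = tab,
    r2 = c(at_percent = r2_of(tab$pred_at_percent, tab$obs_at_percent),
           gc_skew = r2_of(tab$pred_gc_skew, tab$obs_gc_skew),
           at_skew = r2_of(tab$pred_at_skew, tab$obs_at_skew))
  )
}
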