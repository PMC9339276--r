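# Context-dependent count matrices and their summaries.  Counts are held in
# tidy form — one row per (context, ancestral, derived) cell with a positive
# count — because only a small fraction of the 4^(2r) x 16 cells is ever
# populated at desk scale.  Base order is A, C, G, T everywhere.

#' Accumulate context-dependent substitution counts
#'
#' Aggregates substitution records into per-context 4x4 ancestral-by-derived
#' counts (diagonal = conserved sites).  Counts conserve records exactly:
#' the sum over all cells equals the number of records.
#'
#' @param records A record tibble from [extract_records()] (columns `left`,
#'   `right`, `ancestral`, `derived`).
#' @param radius Context radius the records were extracted at; checked
#'   against the flank widths.
#' @return A tibble with columns `left`, `right`, `ancestral`, `derived`,
#'   `count`, with attributes `radius` and `canonical = FALSE`.
#' @export
accumulate_counts <- function(records, radius = attr(records, "radius")) {
  if (is.null(radius)) stop("`radius` must be supplied", call. = FALSE)
  radius <- check_radius(radius)
  counts <- dplyr::count(
    records,
    .data$left, .data$right, .data$ancestral, .data$derived,
    name = "count"
  )
  if (nrow(counts) > 0) {
    if (any(nchar(counts$left) != radius) || any(nchar(counts$right) != radius)) {
      stop("records carry flanks of a different radius than `radius`",
           call. = FALSE)
    }
    check_bases(counts$left, "context")
    check_bases(counts$right, "context")
  }
  counts <- dplyr::arrange(counts, .data$left, .data$right,
                           .data$ancestral, .data$derived)
  attr(counts, "radius") <- radius
  attr(counts, "canonical") <- FALSE
  counts
}

#' Combine complementary context matrices
#'
#' Pools each context with its reverse complement: the canonical
#' representative keeps its counts as-is and receives the complement
#' transform of its partner's counts (`counts[i, j]` added to
#' `counts[comp(i), comp(j)]` of the canonical context).  A
#' self-complementary context is symmetrized by adding its own complement
#' transform, so its counts appear twice — once per strand reading.
#'
#' @param counts A counts tibble from [accumulate_counts()].
#' @return A counts tibble over canonical contexts (attribute
#'   `canonical = TRUE`).
#' @export
combine_complements <- function(counts) {
  radius <- attr(counts, "radius")
  if (is.null(radius)) radius <- nchar(counts$left[1])
  if (isTRUE(attr(counts, "canonical"))) {
    stop("`counts` is already canonical", call. = FALSE)
  }
  can <- canonicalize_context(counts$left, counts$right)
  selfc <- !can$flipped &
    counts$left == revcomp(counts$right) & counts$right == revcomp(counts$left)

  as_is <- counts[!can$flipped, ]
  flip_rows <- function(rows, can_rows) {
    tibble::tibble(
      left = can_rows$left, right = can_rows$right,
      ancestral = comp_bases(rows$ancestral),
      derived = comp_bases(rows$derived),
      count = rows$count
    )
  }
  flipped <- flip_rows(counts[can$flipped, ], can[can$flipped, ])
  self_dup <- flip_rows(counts[selfc, ], can[selfc, ])
  out <- dplyr::bind_rows(as_is, flipped, self_dup)
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$left, .data$right, .data$ancestral, .data$derived),
    count = sum(.data$count), .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$left, .data$right,
                        .data$ancestral, .data$derived)
  attr(out, "radius") <- radius
  attr(out, "canonical") <- TRUE
  out
}

#' Extract one 4x4 count matrix
#'
#' @param counts A counts tibble.
#' @param left,right The context flanks.
#' @return A 4x4 integer matrix (ancestral rows, derived columns, A/C/G/T
#'   order) with attribute `context`.
#' @export
count_matrix <- function(counts, left, right) {
  cm <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  sel <- counts$left == left & counts$right == right
  rows <- counts[sel, ]
  cm[cbind(rows$ancestral, rows$derived)] <- rows$count
  attr(cm, "context") <- c(left = left, right = right)
  cm
}

#' Row-normalize a count matrix into a transition matrix
#'
#' `probs[i, j] = counts[i, j] / sum(counts[i, ])`; all-zero rows are flagged
#' empty (probabilities `NA`), never turned into `NaN`.
#'
#' @param cm A 4x4 count matrix (ancestral rows, derived columns).
#' @return A list of class `transition_matrix` with `probs` (4x4), `row_n`
#'   (row sums), `empty` (logical per row), `counts` and the `context`
#'   attribute carried over.
#' @export
to_transition_matrix <- function(cm) {
  stopifnot(is.matrix(cm), all(dim(cm) == c(4, 4)), all(cm >= 0))
  row_n <- rowSums(cm)
  empty <- row_n == 0
  probs <- cm / ifelse(row_n == 0, NA_real_, row_n)
  dimnames(probs) <- list(BASES, BASES)
  structure(
    list(probs = probs, row_n = stats::setNames(row_n, BASES),
         empty = stats::setNames(empty, BASES), counts = cm,
         context = attr(cm, "context")),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  ctx <- x$context
  if (!is.null(ctx)) cat(sprintf("context %s[N]%s\n", ctx["left"], ctx["right"]))
  print(round(x$probs, 4))
  invisible(x)
}

#' Wald confidence interval for a substitution rate
#'
#' `p +/- 1.96 * sqrt(p * (1 - p) / n)`, clipped to `[0, 1]`.
#'
#' @param p Estimated probability (rate), in `[0, 1]`.
#' @param n Row sum the rate was estimated from (>= 1).
#' @return A numeric vector `c(low, high)` (a 2-column matrix for vector
#'   input).
#' @export
rate_ci <- function(p, n) {
  stopifnot(all(p >= 0), all(p <= 1))
  if (any(n < 1)) stop("`n` must be at least 1", call. = FALSE)
  half <- 1.96 * sqrt(p * (1 - p) / n)
  out <- cbind(low = pmax(0, p - half), high = pmin(1, p + half))
  if (length(p) == 1L) out[1, ] else out
}

#' Transition/transversion rate summary for one matrix row
#'
#' For the given ancestral base, the transition rate is the probability of
#' the transition partner (A<->G, C<->T), the transversion rate the sum of
#' the two transversion probabilities, and Ts:Tv their ratio (`NA` when the
#' row has no transversions).  After complement combining, the A and G rows
#' duplicate the T and C rows, so summaries are reported for pyrimidines.
#'
#' @param tm A [to_transition_matrix()] result.
#' @param from_base Ancestral base, `"T"` or `"C"`.
#' @return A one-row tibble: `from_base`, `ts_rate`, `tv_rate`, `total_rate`,
#'   `ts_tv`, `n_ts`, `n_tv`, `n_row`.
#' @export
rate_summary <- function(tm, from_base = c("T", "C")) {
  stopifnot(inherits(tm, "transition_matrix"))
  from_base <- match.arg(from_base)
  if (tm$empty[from_base]) {
    stop(sprintf("row %s is empty (no records)", from_base), call. = FALSE)
  }
  partner <- TS_PARTNER[[from_base]]
  tv_targets <- setdiff(BASES, c(from_base, partner))
  n_ts <- tm$counts[from_base, partner]
  n_tv <- sum(tm$counts[from_base, tv_targets])
  n_row <- unname(tm$row_n[from_base])
  tibble::tibble(
    from_base = from_base,
    ts_rate = n_ts / n_row, tv_rate = n_tv / n_row,
    total_rate = (n_ts + n_tv) / n_row,
    ts_tv = ifelse(n_tv == 0, NA_real_, n_ts / n_tv),
    n_ts = n_ts, n_tv = n_tv, n_row = n_row
  )
}

#' Per-context rate summaries for all contexts
#'
#' @param counts A counts tibble (canonical or raw).
#' @param from Ancestral bases to summarize (default pyrimidines).
#' @return A tibble with one row per (context, ancestral base) that has at
#'   least one record: context flanks, `from_base`, rates, Ts:Tv and counts
#'   as in [rate_summary()].
#' @export
rate_summaries <- function(counts, from = c("T", "C")) {
  rows <- counts[counts$ancestral %in% from, ]
  partner <- TS_PARTNER[rows$ancestral]
  kind <- ifelse(rows$derived == rows$ancestral, "cons",
                 ifelse(rows$derived == partner, "ts", "tv"))
  agg <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(left = rows$left, right = rows$right,
                     from_base = rows$ancestral, kind = kind,
                     count = rows$count),
      .data$left, .data$right, .data$from_base
    ),
    n_ts = sum(.data$count[.data$kind == "ts"]),
    n_tv = sum(.data$count[.data$kind == "tv"]),
    n_row = sum(.data$count),
    .groups = "drop"
  )
  dplyr::mutate(
    agg,
    ts_rate = .data$n_ts / .data$n_row,
    tv_rate = .data$n_tv / .data$n_row,
    total_rate = (.data$n_ts + .data$n_tv) / .data$n_row,
    ts_tv = ifelse(.data$n_tv == 0, NA_real_, .data$n_ts / .data$n_tv)
  )
}

#' Fold variation in rates across contexts
#'
#' For each statistic (Ts rate, Tv rate, total rate, Ts:Tv) and each row
#' scope (from T, from C, and their union), reports the ratio of the highest
#' to the lowest value across the contexts that pass the sample-size
#' threshold, together with the extreme contexts.  Two threshold modes are
#' supported: `"ts50tv50"` keeps rows with at least `min_ts` transitions and
#' `min_tv` transversions; `"row100"` keeps rows with at least `min_row`
#' substitutions (Ts + Tv).  Rows with undefined Ts:Tv are excluded from the
#' Ts:Tv scan.
#'
#' @param summaries A tibble from [rate_summaries()].
#' @param mode Threshold mode.
#' @param min_ts,min_tv,min_row Thresholds for the two modes.
#' @return A tibble: `mode`, `from`, `statistic`, `fold`, `n_contexts`,
#'   `max_context`, `max_value`, `min_context`, `min_value`.
#' @export
fold_variation_table <- function(summaries, mode = c("ts50tv50", "row100"),
                                 min_ts = 50, min_tv = 50, min_row = 100) {
  mode <- match.arg(mode)
  pass <- if (mode == "ts50tv50") {
    summaries$n_ts >= min_ts & summaries$n_tv >= min_tv
  } else {
    summaries$n_ts + summaries$n_tv >= min_row
  }
  s <- summaries[pass, ]
  if (nrow(s) == 0L) stop("no context passes the threshold", call. = FALSE)
  scopes <- list(`T` = "T", C = "C", `T and C` = c("T", "C"))
  stats_ <- c(ts_rate = "ts_rate", tv_rate = "tv_rate",
              total_rate = "total_rate", ts_tv = "ts_tv")
  rows <- list()
  for (sc in names(scopes)) {
    ss <- s[s$from_base %in% scopes[[sc]], ]
    if (nrow(ss) == 0L) next
    for (st in names(stats_)) {
      v <- ss[[st]]
      keep <- !is.na(v)
      if (!any(keep)) next
      vv <- v[keep]
      ctx <- paste0(ss$left[keep], "[", ss$from_base[keep], "]", ss$right[keep])
      imax <- which.max(vv)
      imin <- which.min(vv)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        mode = mode, from = sc, statistic = st,
        fold = vv[imax] / vv[imin], n_contexts = sum(keep),
        max_context = ctx[imax], max_value = vv[imax],
        min_context = ctx[imin], min_value = vv[imin]
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Slice radius-r matrices by the outer neighbor pair
#'
#' Controls for an internal context of radius r - 1 and returns the 16
#' radius-r count matrices obtained by adding each possible (5' outer base,
#' 3' outer base) pair: outer pair `(x, y)` selects the context
#' `x + internal_left | internal_right + y`.  Summing the 16 slices
#' recovers the marginal matrix of the internal context.
#'
#' @param counts A counts tibble at radius r.
#' @param internal_left,internal_right Flanks of the internal context
#'   (radius r - 1; empty strings for r = 1).
#' @return A named list of 16 4x4 count matrices; names are `"x|y"` over the
#'   outer pairs in A/C/G/T order.
#' @export
slice_by_outer_pair <- function(counts, internal_left, internal_right) {
  radius <- attr(counts, "radius")
  if (is.null(radius)) radius <- nchar(counts$left[1])
  if (nchar(internal_left) != radius - 1 || nchar(internal_right) != radius - 1) {
    stop(sprintf("internal context must have radius %d (got %d/%d)",
                 radius - 1, nchar(internal_left), nchar(internal_right)),
         call. = FALSE)
  }
  out <- list()
  for (x in BASES) {
    for (y in BASES) {
      out[[paste(x, y, sep = "|")]] <-
        count_matrix(counts, paste0(x, internal_left), paste0(internal_right, y))
    }
  }
  out
}
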