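# Ingest triplet alignments (two ingroups + outgroup) and turn eligible
# alignment columns into per-site substitution records.  The ancestral state
# at a site is the outgroup base; each eligible column yields two records,
# one per ingroup, and conserved sites are emitted too (they populate the
# matrix diagonals).

#' Construct a triplet alignment
#'
#' @param region_id Label for the region.
#' @param ingroup1,ingroup2,outgroup Equal-length gapped sequences (character
#'   strings over `A`, `C`, `G`, `T`, `-`; any other symbol makes a column
#'   ineligible downstream).
#' @return An object of class `triplet_alignment`.
#' @export
triplet_alignment <- function(region_id, ingroup1, ingroup2, outgroup) {
  seqs <- toupper(c(ingroup1 = ingroup1, ingroup2 = ingroup2, outgroup = outgroup))
  n <- nchar(seqs)
  if (length(unique(n)) != 1L) {
    stop(sprintf("region '%s': sequences have unequal lengths (%s)",
                 region_id, paste(n, collapse = ", ")), call. = FALSE)
  }
  m <- do.call(rbind, strsplit(seqs, NULL))
  rownames(m) <- c("ingroup1", "ingroup2", "outgroup")
  structure(list(region_id = region_id, m = m, length = unname(n[1])),
            class = "triplet_alignment")
}

#' @export
print.triplet_alignment <- function(x, ...) {
  cat(sprintf("<triplet_alignment '%s', %d columns>\n", x$region_id, x$length))
  invisible(x)
}

#' Read triplet alignments from FASTA
#'
#' Reads one file or every `.fa`/`.fasta`/`.fna` file in a directory.  Record
#' ids must be `<region>|<role>` with the three roles present exactly once
#' per region; several regions may share a file.  Regions with `min_length`
#' or fewer columns are skipped and tallied in the attached log.
#'
#' @param path A FASTA file or a directory of FASTA files.
#' @param roles Named character vector mapping the canonical roles
#'   `ingroup1`, `ingroup2`, `outgroup` to the role tags used in the ids.
#' @param min_length Regions must have strictly more alignment columns than
#'   this to be kept (default 70).
#' @return A list of [triplet_alignment()] objects with an attribute `log`
#'   (named integer vector: `regions_read`, `regions_kept`,
#'   `regions_too_short`).
#' @export
read_triplet_alignments <- function(path,
                                    roles = c(ingroup1 = "ingroup1",
                                              ingroup2 = "ingroup2",
                                              outgroup = "outgroup"),
                                    min_length = 70) {
  stopifnot(all(c("ingroup1", "ingroup2", "outgroup") %in% names(roles)))
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE)
    if (length(files) == 0L) stop("no FASTA files found in ", path, call. = FALSE)
  } else if (file.exists(path)) {
    files <- path
  } else {
    stop("path does not exist: ", path, call. = FALSE)
  }
  recs <- do.call(c, lapply(files, Biostrings::readBStringSet))
  ids <- names(recs)
  parts <- strsplit(ids, "|", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    stop("FASTA ids must have the form <region>|<role>; offending id: ",
         ids[lengths(parts) < 2L][1], call. = FALSE)
  }
  region <- vapply(parts, function(p) paste(p[-length(p)], collapse = "|"), "")
  role <- vapply(parts, function(p) p[length(p)], "")
  out <- list()
  too_short <- 0L
  for (rg in unique(region)) {
    sel <- region == rg
    have <- stats::setNames(match(roles, role[sel]), names(roles))
    if (anyNA(have)) {
      stop(sprintf("region '%s' is missing role(s): %s", rg,
                   paste(names(have)[is.na(have)], collapse = ", ")),
           call. = FALSE)
    }
    seqs <- as.character(recs[sel][have])
    ta <- triplet_alignment(rg, seqs[1], seqs[2], seqs[3])
    if (ta$length <= min_length) {
      too_short <- too_short + 1L
    } else {
      out[[rg]] <- ta
    }
  }
  attr(out, "log") <- c(regions_read = length(unique(region)),
                        regions_kept = length(out),
                        regions_too_short = too_short)
  out
}

# Vectorized eligibility over all columns of one triplet.  A column is
# eligible iff:
#   (a) >= 8 of the 10 surrounding columns (5 each side, focal excluded) are
#       non-gap bases in BOTH ingroups;
#   (b) >= 7 of those 10 columns carry identical non-gap bases in the two
#       ingroups (>= 70% similarity; a gap never matches);
#   (c) the `radius` nearest columns on each side are non-gap and identical
#       in all THREE sequences (conserved context);
#   (d) the focal column is a base in all three sequences;
#   (e) the focal column is at least max(5, radius) columns from both ends.
# Exclusions are tallied against the first failing filter in the order
# edge -> focal_gap -> window_pairs -> window_similarity -> context.
eligible_columns <- function(triplet, radius) {
  radius <- check_radius(radius)
  m <- triplet$m
  L <- triplet$length
  is_base <- matrix(m %in% BASES, nrow = 3L)
  pair_ok <- is_base[1L, ] & is_base[2L, ]
  match_ok <- pair_ok & m[1L, ] == m[2L, ]
  all_base <- pair_ok & is_base[3L, ]
  all_same <- all_base & m[1L, ] == m[2L, ] & m[2L, ] == m[3L, ]

  w <- max(5L, radius)
  interior <- seq_len(L) > w & seq_len(L) <= L - w
  win <- function(x, half) {
    # sum of x over [c - half, c + half] minus the focal column
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(L) - half, 1L)
    hi <- pmin(seq_len(L) + half, L)
    cs[hi + 1L] - cs[lo] - x
  }
  n_pair <- win(pair_ok, 5L)
  n_match <- win(match_ok, 5L)
  ctx_ok <- win(all_same, radius) == 2L * radius

  eligible <- interior & all_base & n_pair >= 8L & n_match >= 7L & ctx_ok
  fail_edge <- !interior
  fail_focal <- interior & !all_base
  fail_pair <- interior & all_base & n_pair < 8L
  fail_match <- interior & all_base & n_pair >= 8L & n_match < 7L
  fail_ctx <- interior & all_base & n_pair >= 8L & n_match >= 7L & !ctx_ok
  list(
    eligible = eligible,
    tally = c(columns_scanned = L,
              excluded_edge = sum(fail_edge),
              excluded_focal_gap = sum(fail_focal),
              excluded_window_pairs = sum(fail_pair),
              excluded_window_similarity = sum(fail_match),
              excluded_context = sum(fail_ctx),
              eligible = sum(eligible))
  )
}

#' Test whether one alignment column is eligible
#'
#' Applies the site filters (gap windows around the focal column, ingroup
#' similarity, conserved flanking context in all three sequences) to a
#' single 0-based column.  See [extract_site_records()] for the filters.
#'
#' @param triplet A [triplet_alignment()].
#' @param column 0-based alignment column index.
#' @param radius Context radius.
#' @return Logical scalar.
#' @export
site_eligible <- function(triplet, column, radius = 3) {
  stopifnot(inherits(triplet, "triplet_alignment"))
  if (length(column) != 1L || is.na(column) || column < 0 ||
      column >= triplet$length) {
    stop(sprintf("`column` must be in [0, %d)", triplet$length), call. = FALSE)
  }
  eligible_columns(triplet, radius)$eligible[column + 1L]
}

#' Extract substitution records from a triplet alignment
#'
#' For every eligible column, two records are emitted: the outgroup base is
#' taken as ancestral and each ingroup base as derived (conserved sites
#' included).  When the outgroup differs from both ingroups the column still
#' yields two records, one substitution per ingroup — the increment rule has
#' no consensus requirement.
#'
#' @param triplet A [triplet_alignment()].
#' @param radius Context radius (flanking bases required conserved across
#'   all three sequences).
#' @return A tibble with columns `region_id`, `column` (0-based), `left`,
#'   `right` (the flanking r-mers), `ancestral`, `derived`, `ingroup`
#'   (1 or 2), plus a `log` attribute with the per-filter column tallies.
#' @export
extract_site_records <- function(triplet, radius = 3) {
  stopifnot(inherits(triplet, "triplet_alignment"))
  radius <- check_radius(radius)
  el <- eligible_columns(triplet, radius)
  cols <- which(el$eligible)
  seqs <- apply(triplet$m, 1L, paste, collapse = "")
  recs <- tibble::tibble(
    region_id = rep(triplet$region_id, 2L * length(cols)),
    column = rep(cols - 1L, each = 2L),
    left = rep(substring(seqs["outgroup"], cols - radius, cols - 1L), each = 2L),
    right = rep(substring(seqs["outgroup"], cols + 1L, cols + radius), each = 2L),
    ancestral = rep(substring(seqs["outgroup"], cols, cols), each = 2L),
    derived = as.vector(rbind(substring(seqs["ingroup1"], cols, cols),
                              substring(seqs["ingroup2"], cols, cols))),
    ingroup = rep(c(1L, 2L), length(cols))
  )
  attr(recs, "log") <- el$tally
  attr(recs, "radius") <- radius
  recs
}

#' Extract substitution records from many triplets
#'
#' @param triplets A list of [triplet_alignment()] objects (e.g. from
#'   [read_triplet_alignments()] or a simulated dataset via
#'   [dataset_triplets()]).
#' @param radius Context radius.
#' @return A tibble as in [extract_site_records()], rows from all triplets,
#'   with the summed filter tallies in the `log` attribute.
#' @export
extract_records <- function(triplets, radius = 3) {
  radius <- check_radius(radius)
  parts <- lapply(triplets, extract_site_records, radius = radius)
  out <- dplyr::bind_rows(parts)
  tallies <- do.call(rbind, lapply(parts, attr, "log"))
  if (!is.null(tallies)) {
    total <- colSums(tallies)
    storage.mode(total) <- "integer"
    attr(out, "log") <- total
  }
  attr(out, "radius") <- radius
  out
}

#' Convert a simulated dataset to triplet alignments
#'
#' @param dataset A `triplet_dataset` from [generate_triplet_dataset()].
#' @return A list of [triplet_alignment()] objects.
#' @export
dataset_triplets <- function(dataset) {
  stopifnot(inherits(dataset, "triplet_dataset"))
  out <- lapply(dataset$regions, function(r) {
    triplet_alignment(r$region_id, r$alignment[["ingroup1"]],
                      r$alignment[["ingroup2"]], r$alignment[["outgroup"]])
  })
  names(out) <- vapply(dataset$regions, `[[`, "", "region_id")
  out
}
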