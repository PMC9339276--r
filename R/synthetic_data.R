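# Synthetic three-taxon data with a known context-dependent substitution
# process.  Evolution is simulated exactly (thinned Gillespie): every event
# rate depends on the CURRENT flanking context, and neighbor contexts are
# refreshed after each event, so neighbor dependence is honored without any
# per-site independence approximation.

#' Construct a context-dependent rate model
#'
#' A model maps (left flank, right flank, current base, target base) to a
#' nonnegative substitution rate per unit of raw simulation time.  Branch
#' lengths passed to [evolve_sequence()] are expressed in expected
#' substitutions/site under the model's mean rate (mean of the per-site total
#' rate over all contexts and focal bases, weighting contexts uniformly), so
#' models need not be normalized.
#'
#' @param radius Integer flank width the rates depend on (1 to 4).
#' @param rate_fn Vectorized function `(left, right, from, to) -> rate`;
#'   called only with `from != to`; must return nonnegative numbers.
#' @param name Label stored with the model.
#' @param params Named list of model parameters (kept for provenance).
#' @return An object of class `context_rate_model`.
#' @seealso [builtin_model()] for the shipped presets.
#' @export
context_rate_model <- function(radius, rate_fn, name = "custom", params = list()) {
  radius <- check_radius(radius)
  stopifnot(is.function(rate_fn))
  structure(
    list(radius = radius, rate_fn = rate_fn, name = name, params = params,
         cache = new.env(parent = emptyenv())),
    class = "context_rate_model"
  )
}

#' @export
print.context_rate_model <- function(x, ...) {
  cat(sprintf("<context_rate_model '%s', radius %d>\n", x$name, x$radius))
  if (length(x$params)) {
    cat("  params:", paste(names(x$params), unlist(x$params), sep = "=",
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Built-in rate model presets
#'
#' `builtin_models()` lists the available presets; `builtin_model()`
#' constructs one:
#'
#' * `"uniform"`: every one of the 12 base changes has rate `mu` in every
#'   context.  With the default `mu = 1/3` the per-site total rate is exactly
#'   1, so branch lengths equal expected substitutions/site.
#' * `"cpg"`: as `"uniform"`, but transitions are multiplied by `k` when the
#'   focal base is a C immediately followed by a 3' G, or (symmetrically) a G
#'   immediately preceded by a 5' C.  Emulates CpG deamination
#'   hypermutability; `k = 1` recovers `"uniform"`.
#' * `"ati_tv"`: transversion rates scale linearly with the A+T index of the
#'   flanking hexanucleotide, from `mu` at ATI = 0 to `mu * tv_ratio` at
#'   ATI = 28 (radius 3 only).  Emulates the elevated transversion rate of
#'   A+T-rich contexts.
#' * `"hky"`: context-independent HKY-style rates
#'   `rate(i -> j) = mu * pi[j] * (kappa for transitions, 1 otherwise)`;
#'   its analytic stationary distribution is `pi`.
#'
#' @param name Preset name.
#' @param radius Flank width (radius 3 fixed for `"ati_tv"`).
#' @param mu Baseline rate per change.
#' @param k CpG transition multiplier (`"cpg"`).
#' @param tv_ratio Transversion fold between ATI = 28 and ATI = 0 (`"ati_tv"`).
#' @param pi Length-4 base frequencies in A, C, G, T order (`"hky"`).
#' @param kappa Transition/transversion rate multiplier (`"hky"`).
#' @return `builtin_model()`: a [context_rate_model()].
#'   `builtin_models()`: character vector of preset names.
#' @export
builtin_model <- function(name, radius = 3, mu = 1 / 3, k = 1.4, tv_ratio = 4,
                          pi = c(0.25, 0.25, 0.25, 0.25), kappa = 2) {
  if (!name %in% builtin_models()) {
    stop(sprintf("unknown model preset '%s' (available: %s)", name,
                 paste(builtin_models(), collapse = ", ")), call. = FALSE)
  }
  is_ts <- function(from, to) unname(TS_PARTNER[from] == to)
  switch(
    name,
    uniform = context_rate_model(
      radius,
      function(left, right, from, to) rep_len(mu, max(length(left), length(from))),
      name = "uniform", params = list(mu = mu)
    ),
    cpg = context_rate_model(
      radius,
      function(left, right, from, to) {
        boosted <- is_ts(from, to) &
          ((from == "C" & substr(right, 1, 1) == "G") |
             (from == "G" & substr(left, nchar(left), nchar(left)) == "C"))
        mu * ifelse(boosted, k, 1)
      },
      name = "cpg", params = list(mu = mu, k = k)
    ),
    ati_tv = {
      if (radius != 3) stop("the 'ati_tv' preset is defined for radius 3", call. = FALSE)
      context_rate_model(
        3,
        function(left, right, from, to) {
          mult <- ifelse(is_ts(from, to), 1,
                         1 + (tv_ratio - 1) * ati(left, right) / 28)
          mu * mult
        },
        name = "ati_tv", params = list(mu = mu, tv_ratio = tv_ratio)
      )
    },
    hky = {
      stopifnot(length(pi) == 4, all(pi > 0), abs(sum(pi) - 1) < 1e-8)
      pv <- stats::setNames(as.numeric(pi), BASES)
      context_rate_model(
        radius,
        function(left, right, from, to) {
          mu * unname(pv[to]) * ifelse(is_ts(from, to), kappa, 1)
        },
        name = "hky", params = list(mu = mu, pi = pv, kappa = kappa)
      )
    }
  )
}

#' @rdname builtin_model
#' @export
builtin_models <- function() c("uniform", "cpg", "ati_tv", "hky")

# Tabulate the model over every context: Q[ctx_code, from, to] plus per-site
# total rates.  Cached in the model object (contexts enumerate to at most
# 4^8 = 65,536 rows).
model_rate_array <- function(model) {
  if (!is.null(model$cache$ra)) return(model$cache$ra)
  r <- model$radius
  ctx <- enumerate_contexts(r)
  n <- nrow(ctx)
  Q <- array(0, dim = c(n, 4, 4))
  for (fi in 1:4) {
    for (ti in 1:4) {
      if (ti == fi) next
      q <- model$rate_fn(ctx$left, ctx$right, rep(BASES[fi], n), rep(BASES[ti], n))
      q <- rep_len(as.numeric(q), n)
      if (any(!is.finite(q)) || any(q < 0)) {
        stop("rate_fn returned a negative or non-finite rate", call. = FALSE)
      }
      Q[, fi, ti] <- q
    }
  }
  site_rate <- apply(Q, c(1, 2), sum)
  # row layout used by the simulator hot loop: (from - 1) * n + ctx_code
  Qflat <- matrix(0, nrow = n * 4, ncol = 4)
  for (fi in 1:4) Qflat[(fi - 1L) * n + seq_len(n), ] <- Q[, fi, ]
  ra <- list(
    n_ctx = n, Q = Q, Qflat = Qflat, site_rate = site_rate,
    mean_rate = mean(site_rate), r_max = max(site_rate)
  )
  model$cache$ra <- ra
  ra
}

#' Generate a random ancestral sequence
#'
#' Bases are drawn i.i.d., either from a two-parameter GC model (equal A/T
#' and equal G/C) or from explicit base frequencies.
#'
#' @param length Sequence length in nucleotides (> 0).
#' @param gc_content Expected G+C fraction in `[0, 1]`; ignored when
#'   `base_freqs` is given.
#' @param seed Optional integer seed (local to this call).
#' @param base_freqs Optional length-4 frequencies in A, C, G, T order.
#' @return A single character string over `A`, `C`, `G`, `T`.
#' @export
generate_ancestor <- function(length, gc_content = 0.35, seed = NULL,
                              base_freqs = NULL) {
  if (length(length) != 1L || is.na(length) || length <= 0) {
    stop("`length` must be a positive integer", call. = FALSE)
  }
  if (is.null(base_freqs)) {
    stopifnot(gc_content >= 0, gc_content <= 1)
    base_freqs <- c((1 - gc_content) / 2, gc_content / 2,
                    gc_content / 2, (1 - gc_content) / 2)
  }
  stopifnot(length(base_freqs) == 4, all(base_freqs >= 0), sum(base_freqs) > 0)
  if (!is.null(seed)) withr::local_seed(seed)
  int_to_seq(sample.int(4L, length, replace = TRUE, prob = base_freqs))
}

#' Evolve a sequence under a context-dependent model
#'
#' Simulates the continuous-time neighbor-dependent substitution process
#' exactly, by thinning: candidate events arrive as a Poisson process at the
#' per-site rate bound `max(site rate)` and are accepted with probability
#' (current site rate)/(bound), which reproduces the Gillespie dynamics while
#' keeping per-event cost constant.  After every accepted substitution the
#' contexts of all sites within `radius` are refreshed.  Sites within
#' `radius` of either end have undefined context and never mutate.
#'
#' @param seq Character string over `A`, `C`, `G`, `T` of length
#'   `> 2 * radius`.
#' @param model A [context_rate_model()].
#' @param branch Branch length in expected substitutions/site under the
#'   model's mean rate (>= 0).
#' @param seed Optional integer seed (local to this call).
#' @return The evolved sequence (character string) with attribute
#'   `n_events`, the number of substitution events that occurred.
#' @export
evolve_sequence <- function(seq, model, branch, seed = NULL) {
  stopifnot(inherits(model, "context_rate_model"))
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L) {
    stop("`seq` must be a single non-empty character string", call. = FALSE)
  }
  if (length(branch) != 1L || is.na(branch) || branch < 0) {
    stop("`branch` must be a single nonnegative number", call. = FALSE)
  }
  r <- model$radius
  s <- seq_to_int(seq)
  L <- length(s)
  if (L <= 2L * r) {
    stop(sprintf("sequence length (%d) must exceed 2 * radius (%d)", L, 2L * r),
         call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  if (branch == 0) {
    out <- seq
    attr(out, "n_events") <- 0L
    return(out)
  }

  ra <- model_rate_array(model)
  n_ctx <- ra$n_ctx
  sr <- ra$site_rate
  Qflat <- ra$Qflat
  r_max <- ra$r_max
  t_raw <- branch / ra$mean_rate
  active <- (r + 1L):(L - r)
  n_act <- length(active)

  # context codes (base-4 on concatenated left+right flank) for active sites
  code <- integer(L)
  acc <- numeric(n_act)
  for (d in seq_len(r)) {
    acc <- acc + (s[active - d] - 1) * 4^(r + d - 1) +
      (s[active + d] - 1) * 4^(r - d)
  }
  code[active] <- as.integer(acc) + 1L
  # weight applied to code[j] when the base at offset -d / +d from j changes
  w_left <- 4^(r + seq_len(r) - 1)   # offset -d
  w_right <- 4^(r - seq_len(r))      # offset +d

  n_events <- 0L
  n_cand <- stats::rpois(1, n_act * r_max * t_raw)
  lo <- r  # active sites start at lo + 1
  chunk <- 2e6L
  done <- 0L
  while (done < n_cand) {
    m <- min(chunk, n_cand - done)
    sites <- lo + sample.int(n_act, m, replace = TRUE)
    u_acc <- stats::runif(m) * r_max
    u_tgt <- stats::runif(m)
    for (kk in seq_len(m)) {
      i <- sites[kk]
      fi <- s[i]
      ci <- code[i]
      rt <- sr[ci, fi]
      if (u_acc[kk] < rt) {
        qrow <- Qflat[(fi - 1L) * n_ctx + ci, ]
        cs <- cumsum(qrow)
        new <- 1L
        x <- u_tgt[kk] * rt
        while (new < 4L && x >= cs[new]) new <- new + 1L
        if (new != fi) {  # guards against rounding at the boundary
          delta <- new - fi
          s[i] <- new
          n_events <- n_events + 1L
          for (d in seq_len(r)) {
            j <- i + d
            if (j <= L - r) code[j] <- code[j] + delta * w_left[d]
            j <- i - d
            if (j > r) code[j] <- code[j] + delta * w_right[d]
          }
        }
      }
    }
    done <- done + m
  }
  out <- int_to_seq(s)
  attr(out, "n_events") <- n_events
  out
}

#' Simulation parameters for a triplet dataset
#'
#' Defaults emulate the kind of data the pipeline targets: many independent
#' intergenic alignments a few hundred nucleotides long, about 0.066
#' substitutions/site between the two ingroups (0.033 on each ingroup
#' branch), an A+T-rich composition, and occasional short indels.
#'
#' @param n_regions Number of independent regions.
#' @param region_length Ancestral length of each region (nt).
#' @param ingroup_branch Expected substitutions/site on each ingroup branch.
#' @param outgroup_branch Expected substitutions/site on the outgroup branch.
#' @param gc_content Ancestral G+C fraction in `(0, 1)`.
#' @param indel_rate Expected indel events per site on each ingroup branch.
#' @param burnin_branch Branch length used to equilibrate the ancestor under
#'   the model before the triplet branches are simulated (0 = start from the
#'   i.i.d. ancestor).
#' @param seed Master seed; per-region streams are derived from it
#'   deterministically.
#' @param base_freqs Optional explicit ancestral base frequencies (A, C, G, T
#'   order), overriding `gc_content`.
#' @return A validated list of class `simulation_params`.
#' @export
simulation_params <- function(n_regions = 50, region_length = 500,
                              ingroup_branch = 0.033, outgroup_branch = 0.066,
                              gc_content = 0.35, indel_rate = 0,
                              burnin_branch = 0, seed = 1, base_freqs = NULL) {
  stopifnot(
    n_regions >= 1, region_length > 0,
    ingroup_branch >= 0, outgroup_branch >= 0, burnin_branch >= 0,
    gc_content > 0, gc_content < 1, indel_rate >= 0,
    length(seed) == 1, is.finite(seed)
  )
  structure(
    list(n_regions = as.integer(n_regions),
         region_length = as.integer(region_length),
         ingroup_branch = ingroup_branch, outgroup_branch = outgroup_branch,
         gc_content = gc_content, indel_rate = indel_rate,
         burnin_branch = burnin_branch, seed = as.integer(seed),
         base_freqs = base_freqs),
    class = "simulation_params"
  )
}

#' Simulate a collection of triplet alignments
#'
#' For each region an ancestor is drawn (and optionally equilibrated under
#' the model for `burnin_branch` substitutions/site), then evolved once to
#' the outgroup and twice independently to the two ingroups (star-like
#' ingroup: both share the single ancestral node).  Optional indels are
#' applied to the ingroups only, and the emitted alignment is built from the
#' known event history, so the true homology is exact by construction.
#'
#' @param params A [simulation_params()] object.
#' @param model A [context_rate_model()].
#' @return An object of class `triplet_dataset`: a list with `regions` (each
#'   holding `region_id`, an `alignment` character vector named `ingroup1`,
#'   `ingroup2`, `outgroup`, and a `truth` record of the ancestor and event
#'   counts), plus the `params` and `model_name`.
#' @export
generate_triplet_dataset <- function(params, model) {
  stopifnot(inherits(params, "simulation_params"),
            inherits(model, "context_rate_model"))
  model_rate_array(model)  # build the cache once, outside the region loop
  regions <- vector("list", params$n_regions)
  withr::local_preserve_seed()
  for (kreg in seq_len(params$n_regions)) {
    set.seed((params$seed + 7919L * kreg) %% .Machine$integer.max)
    anc <- generate_ancestor(params$region_length, params$gc_content,
                             base_freqs = params$base_freqs)
    n_burn <- 0L
    if (params$burnin_branch > 0) {
      anc <- evolve_sequence(anc, model, params$burnin_branch)
      n_burn <- attr(anc, "n_events")
    }
    outg <- evolve_sequence(anc, model, params$outgroup_branch)
    in1 <- evolve_sequence(anc, model, params$ingroup_branch)
    in2 <- evolve_sequence(anc, model, params$ingroup_branch)
    ind1 <- draw_indels(nchar(anc), params$indel_rate, params$gc_content)
    ind2 <- draw_indels(nchar(anc), params$indel_rate, params$gc_content)
    aln <- build_triplet_alignment(as.character(in1), as.character(in2),
                                   as.character(outg), ind1, ind2)
    regions[[kreg]] <- list(
      region_id = sprintf("region%d", kreg),
      alignment = aln,
      truth = list(
        ancestor = as.character(anc),
        n_events = c(burnin = n_burn,
                     outgroup = attr(outg, "n_events"),
                     ingroup1 = attr(in1, "n_events"),
                     ingroup2 = attr(in2, "n_events")),
        n_indels = c(ingroup1 = length(ind1$type), ingroup2 = length(ind2$type))
      )
    )
  }
  structure(
    list(regions = regions, params = params, model_name = model$name),
    class = "triplet_dataset"
  )
}

# Draw indel events for one ingroup branch: Poisson count, deletion or
# insertion with equal probability, geometric lengths (mean 2).
draw_indels <- function(L, rate, gc) {
  n <- if (rate > 0) stats::rpois(1, L * rate) else 0L
  if (n == 0L) {
    return(list(type = character(0), pos = integer(0), len = integer(0),
                ins = character(0)))
  }
  type <- sample(c("del", "ins"), n, replace = TRUE)
  len <- stats::rgeom(n, 0.5) + 1L
  pos <- sample.int(L, n, replace = TRUE)  # del: start; ins: after this base
  ins <- vapply(seq_len(n), function(i) {
    if (type[i] == "ins") generate_ancestor(len[i], gc) else ""
  }, character(1))
  list(type = type, pos = pos, len = len, ins = ins)
}

# Assemble the gapped triplet alignment from the true coordinates: ancestor
# columns carry the (possibly deleted) ingroup bases; each insertion gets its
# own columns, gapped in the other two rows.
build_triplet_alignment <- function(in1, in2, outg, ind1, ind2) {
  L <- nchar(outg)
  lay1 <- layout_indels(in1, L, ind1)
  lay2 <- layout_indels(in2, L, ind2)
  gaps <- function(n) strrep("-", n)
  block <- function(chars, insA, insB, own) {
    # per ancestor position: own char, then ingroup1's insertion columns,
    # then ingroup2's (gapped in the rows that did not insert)
    if (own == 1L) paste0(chars, insA, gaps(nchar(insB)))
    else if (own == 2L) paste0(chars, gaps(nchar(insA)), insB)
    else paste0(chars, gaps(nchar(insA)), gaps(nchar(insB)))
  }
  # leading insertions (after position 0)
  lead <- c(paste0(lay1$ins0, gaps(nchar(lay2$ins0))),
            paste0(gaps(nchar(lay1$ins0)), lay2$ins0),
            gaps(nchar(lay1$ins0) + nchar(lay2$ins0)))
  out_chars <- strsplit(outg, NULL)[[1]]
  c(
    ingroup1 = paste0(lead[1], paste(block(lay1$chars, lay1$ins, lay2$ins, 1L),
                                     collapse = "")),
    ingroup2 = paste0(lead[2], paste(block(lay2$chars, lay1$ins, lay2$ins, 2L),
                                     collapse = "")),
    outgroup = paste0(lead[3], paste(block(out_chars, lay1$ins, lay2$ins, 0L),
                                     collapse = ""))
  )
}

# Per-ancestor-position character (or "-") and per-position insertion strings
# for one ingroup.
layout_indels <- function(seq, L, ind) {
  chars <- strsplit(seq, NULL)[[1]]
  ins <- character(L)
  ins0 <- ""
  for (i in seq_along(ind$type)) {
    if (ind$type[i] == "del") {
      span <- ind$pos[i]:min(L, ind$pos[i] + ind$len[i] - 1L)
      chars[span] <- "-"
    } else if (ind$pos[i] == 0L) {
      ins0 <- paste0(ins0, ind$ins[i])
    } else {
      ins[ind$pos[i]] <- paste0(ins[ind$pos[i]], ind$ins[i])
    }
  }
  list(chars = chars, ins = ins, ins0 = ins0)
}

#' Write a triplet dataset to FASTA files plus a ground-truth sidecar
#'
#' One multi-FASTA alignment per region (`region<k>.fasta`, records
#' `region<k>|ingroup1`, `region<k>|ingroup2`, `region<k>|outgroup`) and a
#' `ground_truth.json` with the model name, parameters and per-region event
#' counts.
#'
#' @param dataset A `triplet_dataset` from [generate_triplet_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_triplet_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "triplet_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (reg in dataset$regions) {
    path <- file.path(dir, paste0(reg$region_id, ".fasta"))
    x <- Biostrings::BStringSet(reg$alignment)
    names(x) <- paste(reg$region_id, names(reg$alignment), sep = "|")
    Biostrings::writeXStringSet(x, path, width = 80L)
    paths <- c(paths, path)
  }
  truth <- list(
    model = dataset$model_name,
    params = dataset$params[setdiff(names(dataset$params), "base_freqs")],
    regions = lapply(dataset$regions, function(r) {
      list(region_id = r$region_id,
           n_events = as.list(r$truth$n_events),
           n_indels = as.list(r$truth$n_indels))
    })
  )
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, truth_path))
}
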