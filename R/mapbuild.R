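#' Merge screened datasets into one segregation matrix for a linkage group
#'
#' Takes the union of loci and the concatenation of individuals over
#' datasets: a locus typed in only some datasets has missing calls in the
#' column blocks of the others. Individuals are namespaced
#' `dataset:individual`; a clash after namespacing is an error.
#'
#' @param gam Gamete-call tibble covering one or more datasets (rows of all
#'   datasets bound together, as produced by the readers / reconstruction).
#' @param group Linkage group to merge.
#' @return A `merged_matrix`: wide tibble with columns `locus` then one
#'   column per individual (integer calls, `NA` = missing). Attributes:
#'   `group`, `datasets`, `blocks` (individual to dataset map), and
#'   `cross_linked` (`FALSE` when no locus is shared between datasets, in
#'   which case no two-point estimate links across datasets).
#' @export
merge_matrices <- function(gam, group) {
  assert_cols(gam, c("dataset", "linkage_group", "locus", "locus_index",
                     "individual", "call"))
  g <- dplyr::filter(gam, .data$linkage_group == group)
  if (nrow(g) == 0) abort_bad_arg("no data for linkage group %s", group)
  g <- dplyr::mutate(g, ind_id = namespace_individuals(.data$dataset,
                                                       .data$individual))
  clash <- g |>
    dplyr::distinct(.data$dataset, .data$ind_id) |>
    dplyr::count(.data$ind_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(clash) > 0) {
    abort_bad_arg("individual id(s) present in two datasets after namespacing: %s",
                  paste(clash$ind_id, collapse = ", "))
  }
  # union of loci, ordered by first appearance (dataset order, then map order)
  locus_order <- g |>
    dplyr::distinct(.data$dataset, .data$locus, .data$locus_index) |>
    dplyr::arrange(.data$dataset, .data$locus_index) |>
    dplyr::distinct(.data$locus) |>
    dplyr::pull("locus")
  wide <- g |>
    dplyr::select("locus", "ind_id", "call") |>
    tidyr::pivot_wider(names_from = "ind_id", values_from = "call") |>
    dplyr::arrange(match(.data$locus, locus_order))
  blocks <- g |>
    dplyr::distinct(.data$ind_id, .data$dataset) |>
    dplyr::arrange(match(.data$ind_id, names(wide)[-1]))
  # is any locus typed in more than one dataset?
  cross <- g |>
    dplyr::distinct(.data$dataset, .data$locus) |>
    dplyr::count(.data$locus) |>
    dplyr::summarise(any = any(.data$n > 1)) |>
    dplyr::pull("any")
  n_datasets <- length(unique(g$dataset))
  if (!cross && n_datasets > 1) {
    warning(sprintf(
      "linkage group %s: datasets share no locus; no two-point estimate links across datasets",
      group), call. = FALSE)
  }
  structure(wide,
            class = c("merged_matrix", class(wide)),
            group = group,
            datasets = unique(g$dataset),
            blocks = blocks,
            cross_linked = isTRUE(cross) || n_datasets == 1)
}

# loci x individuals integer matrix from a merged_matrix
merged_calls <- function(m) {
  calls <- as.matrix(m[, -1, drop = FALSE])
  storage.mode(calls) <- "integer"
  rownames(calls) <- m$locus
  calls
}

# all-pairs recombinant / informative counts via matrix products
two_point_counts <- function(calls) {
  A <- calls
  A[is.na(A)] <- 0L
  M <- 1L * !is.na(calls)
  B <- M - A                       # 1 where call == 0
  conc <- A %*% t(A) + B %*% t(B)  # identical non-missing calls
  disc <- A %*% t(B) + B %*% t(A)  # differing non-missing calls
  list(disc = disc, conc = conc, n = conc + disc)
}

#' Two-point recombination table of a merged matrix
#'
#' For every locus pair, counts concordant and discordant calls over the
#' individuals where both loci are typed. Because linkage phase between
#' datasets is arbitrary, the recombinant count is `min(discordant,
#' concordant)`; the phase label records which side was the smaller.
#' With interference close to one (as in salmonids) the recombination
#' fraction itself is the mapping function, so these estimates are also the
#' map distances (in Morgans) used by the ordering objective.
#'
#' @param m A [merge_matrices()] result.
#' @return Tibble with columns `locus_a`, `locus_b` (each unordered pair
#'   once), `r_hat`, `n_informative`, `phase` (`"coupling"`, `"repulsion"`,
#'   or `NA` when no shared typing: then `r_hat = 0.5` with weight 0).
#' @export
two_point_table <- function(m) {
  calls <- merged_calls(m)
  tp <- two_point_counts(calls)
  loci <- rownames(calls)
  idx <- which(upper.tri(tp$n), arr.ind = TRUE)
  disc <- tp$disc[idx]
  conc <- tp$conc[idx]
  n <- tp$n[idx]
  rcount <- pmin(disc, conc)
  tibble::tibble(
    locus_a = loci[idx[, 1]],
    locus_b = loci[idx[, 2]],
    r_hat = dplyr::if_else(n > 0, rcount / n, 0.5),
    n_informative = as.integer(n),
    phase = dplyr::case_when(
      n == 0 ~ NA_character_,
      disc <= conc ~ "coupling",
      TRUE ~ "repulsion"
    )
  )
}

#' Two-point estimate for one locus pair
#'
#' @param m A [merge_matrices()] result.
#' @param a,b Locus names (must differ).
#' @return One-row tibble as in [two_point_table()].
#' @export
estimate_two_point <- function(m, a, b) {
  if (identical(a, b)) abort_bad_arg("loci must differ")
  tp <- two_point_table(m)
  row <- dplyr::filter(tp, (.data$locus_a == a & .data$locus_b == b) |
                           (.data$locus_a == b & .data$locus_b == a))
  if (nrow(row) == 0) abort_bad_arg("locus %s or %s not in matrix", a, b)
  dplyr::mutate(row, locus_a = a, locus_b = b)
}

# Phase-align the merged calls: within each dataset's column block, walk the
# loci typed in that dataset in matrix row order and complement any locus
# vector sitting in repulsion (more discordant than concordant calls) to its
# predecessor. Relative polarity within a dataset is all that matters for
# cross-dataset counts (complementing a whole block leaves discordance
# unchanged), so this makes the discordance fraction a proper unfolded
# distance: distant same-group pairs under strong interference can exceed
# 50% discordance, and folding them back (as the phase-free min() estimator
# does) would make chromosome ends masquerade as tightly linked.
align_phases <- function(calls, blocks) {
  for (ds in unique(blocks$dataset)) {
    cols <- blocks$ind_id[blocks$dataset == ds]
    sub <- calls[, cols, drop = FALSE]
    typed <- which(rowSums(!is.na(sub)) > 0)
    prev <- NA_integer_
    for (i in typed) {
      if (!is.na(prev)) {
        x <- calls[prev, cols]
        y <- calls[i, cols]
        ok <- !is.na(x) & !is.na(y)
        if (sum(x[ok] != y[ok]) > sum(x[ok] == y[ok])) {
          calls[i, cols] <- 1L - calls[i, cols]
        }
      }
      prev <- i
    }
  }
  calls
}

# unfolded discordance-fraction matrix on phase-aligned calls (the ordering
# search distance), plus the informativeness matrix
aligned_disc_matrix <- function(m) {
  calls <- align_phases(merged_calls(m), attr(m, "blocks"))
  tp <- two_point_counts(calls)
  D <- ifelse(tp$n > 0, tp$disc / pmax(tp$n, 1), NA_real_)
  diag(D) <- 0
  list(D = D, N = tp$n)
}

# square symmetric matrices of r and informativeness from a two-point table
two_point_matrices <- function(tp, loci) {
  n <- length(loci)
  R <- matrix(0.5, n, n, dimnames = list(loci, loci))
  Ninf <- matrix(0L, n, n, dimnames = list(loci, loci))
  ia <- match(tp$locus_a, loci)
  ib <- match(tp$locus_b, loci)
  R[cbind(ia, ib)] <- R[cbind(ib, ia)] <- tp$r_hat
  Ninf[cbind(ia, ib)] <- Ninf[cbind(ib, ia)] <- tp$n_informative
  diag(R) <- 0
  list(R = R, N = Ninf)
}

#' Order the markers of a merged matrix
#'
#' Finds a locus order minimizing the expected two-point map length, the sum
#' of adjacent recombination fractions. Four engines are available:
#' simulated annealing (default), taboo search, exhaustive sliding-window
#' permutations ("flips"), and an exact dynamic program over subsets that is
#' guaranteed optimal for up to 12 loci (accepted up to 15, refused above).
#' Heuristics are deterministic given `seed`. Zero-information pairs are
#' barred from adjacency by a large internal penalty; if the group cannot be
#' ordered without one, the junction is flagged. The output is canonicalized
#' so the first locus name sorts before the last (an order and its reversal
#' are the same map).
#'
#' @param m A [merge_matrices()] result.
#' @param method `"annealing"`, `"taboo"`, `"flips"` or `"exact"`.
#' @param params Optional list of engine parameters: annealing `t0` (1.0),
#'   `cooling` (0.95), `moves_per_t` (300), `t_min` (1e-3); taboo `tenure`
#'   (15); flips `width` (5); any engine `weighted` (`FALSE`; weight each
#'   pair's contribution by its informativeness).
#' @param seed Integer seed for the random initial order and any stochastic
#'   moves.
#' @return Tibble with columns `locus`, `rank`. Attributes: `objective`
#'   (sum of adjacent `r_hat`), `method`, `flagged_junctions` (tibble of
#'   adjacent pairs with no shared typing).
#' @export
order_markers <- function(m, method = c("annealing", "taboo", "flips", "exact"),
                          params = list(), seed = 0) {
  method <- match.arg(method)
  tp <- two_point_table(m)
  loci <- m$locus
  n <- length(loci)
  mats <- two_point_matrices(tp, loci)
  comp <- informative_components(mats$N > 0)
  if (length(unique(comp)) > 1) {
    groups <- split(loci, comp)
    abort_bad_arg("loci are not all linked; disconnected components: %s",
                  paste(purrr::map_chr(groups, ~ paste(.x, collapse = ",")),
                        collapse = " | "))
  }
  # the search distance is the phase-aligned, unfolded discordance fraction;
  # on adjacent pairs of a correct order it coincides with r_hat, but unlike
  # the folded estimate it keeps distant pairs distant under strong
  # interference
  S <- aligned_disc_matrix(m)$D
  S[is.na(S)] <- 0.5
  if (isTRUE(params$weighted)) {
    w <- mats$N / max(mats$N)
    S <- S * w + 0.5 * (1 - w)
  }
  S[mats$N == 0] <- 100  # bar zero-information adjacencies
  diag(S) <- 0
  ord <- withr::with_seed(seed, {
    init <- sample.int(n)
    switch(method,
      exact = order_exact(S),
      annealing = order_anneal(S, init,
                               t0 = params$t0 %||% 1,
                               cooling = params$cooling %||% 0.95,
                               moves_per_t = params$moves_per_t %||% 300,
                               t_min = params$t_min %||% 1e-3),
      taboo = order_taboo(S, init, tenure = params$tenure %||% 15),
      flips = order_flips(S, greedy_chain(S), width = params$width %||% 5)
    )
  })
  if (method != "exact") {
    # cheap deterministic polish: windowed permutations until stable
    ord <- order_flips(S, ord, width = min(5, n))
  }
  ord <- canonicalize_order(ord, loci)
  flagged <- tibble::tibble(
    locus_a = loci[ord[-n]][mats$N[cbind(ord[-n], ord[-1])] == 0],
    locus_b = loci[ord[-1]][mats$N[cbind(ord[-n], ord[-1])] == 0]
  )
  out <- tibble::tibble(locus = loci[ord], rank = seq_len(n))
  attr(out, "objective") <- path_objective(mats$R, ord)
  attr(out, "search_objective") <- path_objective(S, ord)
  attr(out, "method") <- method
  attr(out, "flagged_junctions") <- flagged
  out
}

#' Arbitrate near-tie adjacent swaps by additivity voting
#'
#' The two-point map-length objective decides the orientation of a tight
#' adjacent locus pair from a single noisy comparison. Under the
#' near-complete-interference model the whole package assumes, every other
#' locus of the group carries the same information: a reference locus to the
#' left of the pair should be closer (in discordance) to the pair's first
#' member than to its second. This polish sweeps the order and swaps any
#' adjacent pair whose surrounding references vote, by majority, for the
#' other orientation; it resolves local ambiguities the length objective
#' cannot, at negligible risk of disturbing a well-supported order.
#'
#' @param m The [merge_matrices()] result the order came from.
#' @param order Order tibble from [order_markers()] (or character vector).
#' @param pairs `"terminal"` (default) restricts arbitration to the two
#'   outermost pairs, where the length objective has only one flanking
#'   estimate and is weakest; `"all"` sweeps every adjacent pair.
#' @param window Number of neighbouring positions on each side consulted as
#'   references (default 8; distant references saturate and carry no
#'   signal).
#' @param max_sweeps Sweeps over the order before giving up (default 5).
#' @return The (possibly corrected) order as a tibble with `locus`, `rank`;
#'   attribute `swapped` lists the pairs flipped.
#' @export
polish_marker_order <- function(m, order, pairs = c("terminal", "all"),
                                window = 8, max_sweeps = 5) {
  pairs <- match.arg(pairs)
  loci <- if (is.data.frame(order)) order$locus else order
  ad <- aligned_disc_matrix(m)
  D <- ad$D
  idx <- match(loci, m$locus)
  n <- length(idx)
  swapped <- list()
  if (n >= 3) {
    todo <- if (pairs == "terminal") unique(c(1L, n - 1L)) else seq_len(n - 1)
    for (sweep in seq_len(max_sweeps)) {
      changed <- FALSE
      for (i in todo) {
        a <- idx[i]; b <- idx[i + 1]
        left <- idx[max(1, i - window):i][-(i - max(1, i - window) + 1)]
        right <- idx[(i + 1):min(n, i + 1 + window)][-1]
        refs <- c(left, right)
        side <- rep(c(1, -1), c(length(left), length(right)))
        da <- D[refs, a]; db <- D[refs, b]
        ok <- !is.na(da) & !is.na(db)
        # the expected gap D(k,b) - D(k,a) is r(a,b) * (1 - 2m), with m the
        # reference-to-pair distance: weight votes by that attenuation, which
        # also silences references past the point where discordance stops
        # growing with distance (strong interference on long arms)
        w <- pmax(0, 1 - 2 * pmin(da[ok], db[ok]))
        v <- sum(side[ok] * (db[ok] - da[ok]) * w)
        if (v < 0) {
          idx[c(i, i + 1)] <- c(b, a)
          swapped[[length(swapped) + 1]] <- m$locus[c(a, b)]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  idx <- canonicalize_order(idx, m$locus)
  out <- tibble::tibble(locus = m$locus[idx], rank = seq_len(n))
  attr(out, "swapped") <- swapped
  out
}

#' Mask singleton-discordant calls as putative genotyping errors
#'
#' Under (near-)complete crossover interference a call that disagrees with
#' both of its tightly flanking observed calls in the same gamete would
#' require a double crossover within a short interval: on a single
#' chromosome arm this is (essentially) impossible, so such singleton
#' discordances are genotyping errors with very high probability. They are
#' masked (set missing), never corrected, before position estimation —
#' leaving them in inflates every interval by roughly twice the error rate.
#'
#' @param m A [merge_matrices()] result.
#' @param order Ordered loci (tibble from [order_markers()] or character
#'   vector) giving the provisional map order.
#' @param positions Positions tibble from [compute_positions()] for gap
#'   checks.
#' @param max_gap_cM Flanking calls further than this are not trusted as
#'   error evidence (default 20).
#' @param datasets Datasets whose columns may be masked; default all.
#'   Pseudo-gamete reconstructions must be excluded: their recombinant
#'   flips deliberately stack in the same gamete columns, so singleton
#'   patterns there are signal, not error.
#' @return The merged matrix with flagged calls set to `NA`; attribute
#'   `n_masked` counts them.
#' @export
mask_singleton_errors <- function(m, order, positions, max_gap_cM = 20,
                                  datasets = NULL) {
  loci <- if (is.data.frame(order)) order$locus else order
  calls <- merged_calls(m)[loci, , drop = FALSE]
  pos <- positions$position_cM[match(loci, positions$locus)]
  blocks <- attr(m, "blocks")
  cols <- if (is.null(datasets)) seq_len(ncol(calls)) else {
    which(colnames(calls) %in% blocks$ind_id[blocks$dataset %in% datasets])
  }
  masked <- calls
  n_masked <- 0L
  for (j in cols) {
    obs <- which(!is.na(calls[, j]))
    if (length(obs) < 3) next
    v <- calls[obs, j]
    p <- pos[obs]
    for (t in 2:(length(obs) - 1)) {
      if (v[t] != v[t - 1] && v[t] != v[t + 1] &&
          (p[t] - p[t - 1]) <= max_gap_cM && (p[t + 1] - p[t]) <= max_gap_cM) {
        masked[obs[t], j] <- NA_integer_
        n_masked <- n_masked + 1L
      }
    }
  }
  out <- m
  out[match(loci, out$locus), -1] <- as.data.frame(masked)
  attr(out, "n_masked") <- n_masked
  out
}

#' Objective (expected map length) of a locus order
#'
#' @param order Character vector of loci or a tibble with a `locus` column.
#' @param estimates Two-point table from [two_point_table()].
#' @return Sum of adjacent `r_hat` (Morgans).
#' @export
map_order_objective <- function(order, estimates) {
  loci <- if (is.data.frame(order)) order$locus else order
  mats <- two_point_matrices(estimates, loci)
  path_objective(mats$R, seq_along(loci))
}

#' Cumulative positions along an ordered linkage group
#'
#' The mapping function is the recombination percentage itself (appropriate
#' under near-complete interference): each adjacent fraction contributes
#' `100 * r_hat` cM, and the first locus sits at 0.
#'
#' @param order Character vector of loci or tibble with `locus` (the output
#'   of [order_markers()]).
#' @param estimates Two-point table covering the adjacent pairs.
#' @return Tibble with columns `locus`, `position_cM` (non-decreasing,
#'   starts at 0).
#' @export
compute_positions <- function(order, estimates) {
  loci <- if (is.data.frame(order)) order$locus else order
  mats <- two_point_matrices(estimates, loci)
  n <- length(loci)
  steps <- if (n > 1) 100 * mats$R[cbind(seq_len(n - 1), 2:n)] else numeric(0)
  tibble::tibble(locus = loci, position_cM = cumsum(c(0, steps)))
}

#' Label chromosome arms around a centromeric range
#'
#' The centromeric region is delimited by two loci of the group; loci
#' strictly before it form the first (p) arm, loci strictly after the second
#' (q) arm, and everything within (inclusive) is labelled centromeric.
#' Acrocentric chromosomes are handled by a terminal range: an empty first
#' arm is allowed (and reported via a message).
#'
#' @param positioned Tibble with `locus` ordered along the group (e.g. from
#'   [compute_positions()]).
#' @param centromere_range Character vector `c(start_locus, end_locus)`;
#'   both must be on the group and `start` must not come after `end`.
#' @return `positioned` with an `arm` column (`"p"`, `"centromeric"`, `"q"`).
#' @export
partition_arms <- function(positioned, centromere_range) {
  assert_cols(positioned, "locus")
  i <- match(centromere_range[1], positioned$locus)
  j <- match(centromere_range[2], positioned$locus)
  if (is.na(i) || is.na(j)) {
    abort_bad_arg("centromere range locus not on group: %s",
                  paste(centromere_range[is.na(c(i, j))], collapse = ", "))
  }
  if (i > j) {
    # group orientation is arbitrary; a range listed against the built
    # orientation is simply swapped
    tmp <- i; i <- j; j <- tmp
  }
  arm <- rep("q", nrow(positioned))
  arm[seq_len(nrow(positioned)) < i] <- "p"
  arm[seq(i, j)] <- "centromeric"
  if (i == 1) message("centromere at group start: first arm is empty (acrocentric)")
  dplyr::mutate(positioned, arm = arm)
}

#' Build the synthetic map
#'
#' Runs merge, two-point estimation, ordering, positioning and (when
#' centromere ranges are supplied) arm labelling for each linkage group, and
#' assembles the result into a `synthetic_map` object.
#'
#' @param gam Gamete-call tibble over all (screened) datasets.
#' @param groups Linkage groups to build; default all groups present.
#' @param centromeres Optional tibble with columns `linkage_group`,
#'   `start_locus`, `end_locus`. Groups without a row get `arm = NA` and are
#'   excluded from arm-level analyses.
#' @param method,params,seed Passed to [order_markers()].
#' @param polish Adjacent-pair arbitration after ordering
#'   ([polish_marker_order()]): `"terminal"` (default), `"all"`, or
#'   `"none"`.
#' @param mask_errors Mask singleton-discordant calls
#'   ([mask_singleton_errors()]) before position estimation (default
#'   `TRUE`); only raw-genotype datasets are touched when `meta` is given.
#' @param meta Optional tibble with columns `dataset`, `kind`
#'   (`"raw_genotypes"` or `"pseudo"`); pseudo-gamete datasets are never
#'   error-masked.
#' @return A `synthetic_map`: tibble with columns `linkage_group`, `locus`,
#'   `position_cM`, `arm`, ordered within group. Attributes: `estimates`
#'   (named list of two-point tables; post-masking when `mask_errors`),
#'   `objective` (named numeric), `method`, `seed`.
#' @export
build_synthetic_map <- function(gam, groups = NULL, centromeres = NULL,
                                method = "annealing", params = list(),
                                seed = 0, polish = c("terminal", "all", "none"),
                                mask_errors = TRUE, meta = NULL) {
  polish <- match.arg(polish)
  maskable <- if (is.null(meta)) NULL else {
    meta$dataset[meta$kind == "raw_genotypes"]
  }
  groups <- groups %||% sort(unique(gam$linkage_group))
  estimates <- list()
  objective <- numeric(0)
  rows <- purrr::map(groups, function(g) {
    m <- merge_matrices(gam, g)
    tp <- two_point_table(m)
    estimates[[g]] <<- tp
    if (nrow(m) == 1) {
      pos <- tibble::tibble(locus = m$locus, position_cM = 0)
      objective[g] <<- 0
    } else {
      ord <- order_markers(m, method = method, params = params, seed = seed)
      if (polish != "none") {
        ord <- polish_marker_order(m, ord, pairs = polish)
      }
      pos <- compute_positions(ord, tp)
      if (mask_errors) {
        m <- mask_singleton_errors(m, ord, pos, datasets = maskable)
        tp <- two_point_table(m)
        estimates[[g]] <<- tp
        pos <- compute_positions(ord, tp)
      }
      objective[g] <<- map_order_objective(ord, tp)
    }
    if (!is.null(centromeres) && g %in% centromeres$linkage_group) {
      cr <- dplyr::filter(centromeres, .data$linkage_group == g)
      pos <- partition_arms(pos, c(cr$start_locus[1], cr$end_locus[1]))
    } else {
      pos$arm <- NA_character_
    }
    dplyr::mutate(pos, linkage_group = g, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  new_synthetic_map(out, estimates = estimates, objective = objective,
                    method = method, seed = seed)
}

new_synthetic_map <- function(x, estimates = list(), objective = numeric(0),
                              method = NA_character_, seed = NA_integer_) {
  structure(
    x,
    class = c("synthetic_map", class(tibble::as_tibble(x))),
    estimates = estimates, objective = objective,
    method = method, seed = seed
  )
}

#' Construct a synthetic_map object from a plain table
#'
#' Useful when a map is read back from disk or built by other means.
#'
#' @param x Tibble with columns `linkage_group`, `locus`, `position_cM` and
#'   optionally `arm`.
#' @return A `synthetic_map`.
#' @export
as_synthetic_map <- function(x) {
  assert_cols(x, c("linkage_group", "locus", "position_cM"))
  if (!"arm" %in% names(x)) x$arm <- NA_character_
  bad <- x |>
    dplyr::group_by(.data$linkage_group) |>
    dplyr::summarise(ok = !is.unsorted(.data$position_cM), .groups = "drop")
  if (any(!bad$ok)) {
    abort_bad_arg("positions must be non-decreasing within each group")
  }
  new_synthetic_map(tibble::as_tibble(x))
}

#' @export
print.synthetic_map <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<synthetic_map> %d loci, %d linkage groups, %.1f cM\n",
              g$n_loci, g$n_groups, g$total_length_cM))
  NextMethod()
}

#' @rdname tidy.synthetic_map
#' @method glance synthetic_map
#' @export
glance.synthetic_map <- function(x, ...) {
  per_group <- x |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$linkage_group) |>
    dplyr::summarise(len = max(.data$position_cM), .groups = "drop")
  dup <- sum(!is.na(dup_base(x$locus)))
  tibble::tibble(
    n_loci = nrow(x),
    n_groups = nrow(per_group),
    n_duplicated_loci = dup,
    n_duplicate_pairs = length(unique(stats::na.omit(dup_base(x$locus)))),
    total_length_cM = sum(per_group$len)
  )
}

#' Tidiers for synthetic maps
#'
#' `tidy()` returns the per-locus table; `glance()` a one-row summary with
#' locus, group and duplicated-locus counts plus total map length.
#'
#' @param x A `synthetic_map`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy synthetic_map
#' @export
tidy.synthetic_map <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Write a synthetic map as TSV
#'
#' @param map A `synthetic_map` (or compatible tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synthetic_map <- function(map, path) {
  assert_cols(map, c("linkage_group", "locus", "position_cM"))
  readr::write_tsv(tibble::as_tibble(map), path, progress = FALSE)
  invisible(path)
}

#' Export a map in MapChart text format
#'
#' Writes the plain-text drawing input used by MapChart: a `group` header
#' per linkage group followed by `locus position` lines.
#'
#' @param map A `synthetic_map` (or tibble with `linkage_group`, `locus`,
#'   `position_cM`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapchart <- function(map, path) {
  assert_cols(map, c("linkage_group", "locus", "position_cM"))
  lines <- map |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$linkage_group) |>
    dplyr::group_map(function(g, key) {
      c(sprintf("group %s", key$linkage_group),
        sprintf("%s %.3f", g$locus, g$position_cM),
        "")
    }) |>
    unlist()
  writeLines(lines, path)
  invisible(path)
}
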