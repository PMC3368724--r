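# Cross-dataset consistency screening: linkage-group assignment and marker
# order, with auditable resolution rules.

# longest common subsequence length of two vectors of distinct symbols
lcs_length <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) return(0L)
  L <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      L[i + 1, j + 1] <- if (a[i] == b[j]) L[i, j] + 1L
                         else max(L[i, j + 1], L[i + 1, j])
    }
  }
  L[n + 1, m + 1]
}

# all distinct maximal common subsequences (as sets of symbols; symbols are
# unique within each sequence), capped
lcs_all_keeps <- function(a, b, cap = 64L) {
  n <- length(a); m <- length(b)
  L <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      L[i + 1, j + 1] <- if (a[i] == b[j]) L[i, j] + 1L
                         else max(L[i, j + 1], L[i + 1, j])
    }
  }
  seen <- new.env(parent = emptyenv())
  out <- list()
  rec <- function(i, j, acc) {
    if (length(out) >= cap) return()
    if (i == 0 || j == 0) {
      key <- paste(sort(acc), collapse = "\r")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1]] <<- acc
      }
      return()
    }
    if (a[i] == b[j]) {
      rec(i - 1, j - 1, c(a[i], acc))
    } else {
      if (L[i, j + 1] == L[i + 1, j + 1]) rec(i - 1, j, acc)
      if (L[i + 1, j] == L[i + 1, j + 1] && length(out) < cap) rec(i, j - 1, acc)
    }
  }
  rec(n, m, character(0))
  out
}

# orientation-free order comparison of two permutations of the same locus
# set: returns the union of all minimal deviant sets and the tie-rule-chosen
# one (smallest rank displacement, then lexicographic)
lcs_deviants <- function(a, b) {
  if (lcs_length(a, rev(b)) > lcs_length(a, b)) b <- rev(b)
  keeps <- lcs_all_keeps(a, b)
  deviant_sets <- purrr::map(keeps, ~ setdiff(a, .x))
  if (length(deviant_sets) == 0 || length(deviant_sets[[1]]) == 0) {
    return(list(union = character(0), chosen = character(0)))
  }
  displacement <- purrr::map_dbl(deviant_sets, function(d) {
    sum(abs(match(d, a) - match(d, b)))
  })
  keyed <- purrr::map_chr(deviant_sets, ~ paste(sort(.x), collapse = ","))
  pick <- order(displacement, keyed)[1]
  list(union = sort(unique(unlist(deviant_sets))),
       chosen = sort(deviant_sets[[pick]]))
}

#' Check linkage-group assignment consistency across datasets
#'
#' Reports every locus assigned to different linkage groups in different
#' datasets, plus all loci belonging to source linkage groups flagged as
#' merged/ambiguous (those groups are excluded wholesale, as unresolvable).
#'
#' @param orders Output of [locus_orders()] over all datasets.
#' @param dropped_groups Optional tibble with columns `dataset`,
#'   `linkage_group` naming merged/ambiguous source groups.
#' @return A discrepancy tibble with columns `locus`, `linkage_group`,
#'   `kind` (`"group_conflict"`), `datasets` (comma-joined), `deviant_dataset`
#'   (`NA`), `resolution` (`"dropped_group"` or `NA`), `evidence` (number of
#'   datasets involved), `chosen` (`TRUE`).
#' @export
check_group_consistency <- function(orders, dropped_groups = NULL) {
  assert_cols(orders, c("dataset", "linkage_group", "locus"))
  conflicts <- orders |>
    dplyr::distinct(.data$dataset, .data$linkage_group, .data$locus) |>
    dplyr::group_by(.data$locus) |>
    dplyr::filter(dplyr::n_distinct(.data$linkage_group) > 1) |>
    dplyr::summarise(
      linkage_group = paste(sort(unique(.data$linkage_group)), collapse = ","),
      datasets = paste(sort(unique(.data$dataset)), collapse = ","),
      evidence = dplyr::n_distinct(.data$dataset), .groups = "drop") |>
    dplyr::mutate(kind = "group_conflict", deviant_dataset = NA_character_,
                  resolution = NA_character_, chosen = TRUE)
  dropped <- tibble::tibble()
  if (!is.null(dropped_groups) && nrow(dropped_groups) > 0) {
    dropped <- orders |>
      dplyr::semi_join(dropped_groups, by = c("dataset", "linkage_group")) |>
      dplyr::distinct(.data$dataset, .data$linkage_group, .data$locus) |>
      dplyr::transmute(
        locus = .data$locus, linkage_group = .data$linkage_group,
        kind = "group_conflict", datasets = .data$dataset,
        deviant_dataset = .data$dataset, resolution = "dropped_group",
        evidence = 1L, chosen = TRUE)
  }
  out <- dplyr::bind_rows(
    dplyr::select(conflicts, "locus", "linkage_group", "kind", "datasets",
                  "deviant_dataset", "resolution", "evidence", "chosen"),
    dropped)
  # a locus inside a dropped group needs no second, conflicting report
  if (nrow(dropped) > 0 && nrow(conflicts) > 0) {
    out <- dplyr::filter(
      out, !(is.na(.data$resolution) & .data$locus %in% dropped$locus))
  }
  out
}

#' Check marker-order consistency within a linkage group
#'
#' For every pair of datasets sharing at least three loci on the group,
#' computes the longest common subsequence of the shared-locus orders,
#' allowing whole-group reversal (orientation is meaningless for a linkage
#' group). Loci outside the LCS are order-discrepant; when several minimal
#' deviant sets exist, the tie rule prefers the set with the smallest summed
#' rank displacement, then the lexicographically first one — only that set
#' is marked `chosen` and acted on by [resolve_discrepancies()].
#'
#' @param orders Output of [locus_orders()].
#' @param group Linkage group name.
#' @return Discrepancy tibble (see [check_group_consistency()] for columns);
#'   `deviant_dataset` names the single deviant dataset when one dataset
#'   conflicts with two or more concordant ones, and `evidence` counts the
#'   datasets supporting the majority order.
#' @export
check_order_consistency <- function(orders, group) {
  assert_cols(orders, c("dataset", "linkage_group", "locus", "locus_index"))
  og <- orders |>
    dplyr::filter(.data$linkage_group == group) |>
    dplyr::arrange(.data$dataset, .data$locus_index)
  seqs <- split(og$locus, og$dataset)
  ds <- names(seqs)
  if (length(ds) < 2) return(empty_reports())
  per_pair <- list()
  for (i in seq_len(length(ds) - 1)) {
    for (j in (i + 1):length(ds)) {
      shared <- intersect(seqs[[i]], seqs[[j]])
      if (length(shared) < 3) next
      a <- seqs[[i]][seqs[[i]] %in% shared]
      b <- seqs[[j]][seqs[[j]] %in% shared]
      dv <- lcs_deviants(a, b)
      if (length(dv$union) == 0) next
      per_pair[[length(per_pair) + 1]] <- tibble::tibble(
        locus = dv$union, ds_a = ds[i], ds_b = ds[j],
        chosen = dv$union %in% dv$chosen)
    }
  }
  if (length(per_pair) == 0) return(empty_reports())
  flags <- dplyr::bind_rows(per_pair)
  membership <- og |> dplyr::distinct(.data$dataset, .data$locus)
  agg <- flags |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      involved = list(purrr::map2(.data$ds_a, .data$ds_b, c)),
      chosen = any(.data$chosen), .groups = "drop")
  rows <- purrr::pmap(agg, function(locus, involved, chosen) {
    with_loc <- membership$dataset[membership$locus == locus]
    in_all <- Reduce(intersect, involved)
    deviant <- NA_character_
    evidence <- length(with_loc)
    if (length(in_all) == 1 && length(with_loc) >= 3) {
      deviant <- in_all
      evidence <- length(with_loc) - 1L
    }
    tibble::tibble(
      locus = locus, linkage_group = group, kind = "order_conflict",
      datasets = paste(sort(with_loc), collapse = ","),
      deviant_dataset = deviant, resolution = NA_character_,
      evidence = as.integer(evidence), chosen = chosen)
  })
  dplyr::bind_rows(rows)
}

empty_reports <- function() {
  tibble::tibble(locus = character(), linkage_group = character(),
                 kind = character(), datasets = character(),
                 deviant_dataset = character(), resolution = character(),
                 evidence = integer(), chosen = logical())
}

# place `locus` in `ord` (which must not contain it) at the position implied
# by reference order `ref`
reposition_locus <- function(ord, locus, ref) {
  if (lcs_length(ord, rev(ref)) > lcs_length(ord, ref)) ref <- rev(ref)
  pos <- match(locus, ref)
  pred <- NA_character_
  if (!is.na(pos) && pos > 1) {
    before <- ref[seq_len(pos - 1)]
    before <- before[before %in% ord]
    if (length(before) > 0) pred <- before[length(before)]
  }
  at <- if (is.na(pred)) 0L else match(pred, ord)
  append(ord, locus, after = at)
}

# adjacency recombinant-count objective of an order under one dataset's calls
order_count_objective <- function(calls, ord) {
  ord <- ord[ord %in% rownames(calls)]
  if (length(ord) < 2) return(0)
  tot <- 0
  for (i in seq_len(length(ord) - 1)) {
    x <- calls[ord[i], ]; y <- calls[ord[i + 1], ]
    ok <- !is.na(x) & !is.na(y)
    d <- sum(x[ok] != y[ok]); c <- sum(x[ok] == y[ok])
    tot <- tot + min(d, c)
  }
  tot
}

# minimum number of single-call changes to `locus` in one dataset that make
# the other dataset's relative placement at least as well supported as its
# own; searched in both directions, raw-genotype datasets only
min_flip_count <- function(gam, group, locus, ds_a, ds_b, max_flips = 3L) {
  best <- Inf
  for (dir in 1:2) {
    d_from <- if (dir == 1) ds_a else ds_b
    d_ref <- if (dir == 1) ds_b else ds_a
    gD <- dplyr::filter(gam, .data$dataset == d_from,
                        .data$linkage_group == group)
    gR <- dplyr::filter(gam, .data$dataset == d_ref,
                        .data$linkage_group == group)
    ordD <- gD |> dplyr::distinct(.data$locus, .data$locus_index) |>
      dplyr::arrange(.data$locus_index) |> dplyr::pull("locus")
    ordR <- gR |> dplyr::distinct(.data$locus, .data$locus_index) |>
      dplyr::arrange(.data$locus_index) |> dplyr::pull("locus")
    shared <- intersect(ordD, ordR)
    if (!(locus %in% shared) || length(shared) < 3) next
    cur <- ordD[ordD %in% shared]
    tgt <- reposition_locus(setdiff(cur, locus), locus, ordR[ordR %in% shared])
    wide <- gD |>
      dplyr::filter(.data$locus %in% shared) |>
      dplyr::select("locus", "individual", "call") |>
      tidyr::pivot_wider(names_from = "individual", values_from = "call")
    calls <- as.matrix(wide[, -1])
    rownames(calls) <- wide$locus
    need <- order_count_objective(calls, tgt) - order_count_objective(calls, cur)
    if (need <= 0) {
      best <- min(best, 0L)
      next
    }
    flippable <- which(!is.na(calls[locus, ]))
    gains <- purrr::map_dbl(flippable, function(jcol) {
      flipped <- calls
      flipped[locus, jcol] <- 1L - flipped[locus, jcol]
      need_j <- order_count_objective(flipped, tgt) -
        order_count_objective(flipped, cur)
      need - need_j
    })
    gains <- sort(gains[gains > 0], decreasing = TRUE)
    cum <- cumsum(gains)
    k <- which(need - cum <= 0)[1]
    if (!is.na(k)) best <- min(best, k)
  }
  if (is.infinite(best)) max_flips + 1L else as.integer(min(best, max_flips + 1L))
}

#' Resolve screened discrepancies
#'
#' Applies the resolution rules to the reports of
#' [check_group_consistency()] and [check_order_consistency()]:
#'
#' * loci of merged/ambiguous source groups are dropped
#'   (`dropped_group`);
#' * a single deviant dataset against two or more concordant ones loses the
#'   locus (`removed_from_deviant`);
#' * a conflict between exactly two datasets is reconciled when it can be
#'   explained by at most `flip_threshold` inconsistent genotype calls
#'   (`ignored_small`; the locus is realigned to the consensus order, calls
#'   are counted but never altered) — only computable when both datasets
#'   carry raw genotypes, pseudo-gamete reconstructions go straight to the
#'   next rule;
#' * everything else, and every linkage-group conflict, duplicates the locus
#'   under dataset-suffixed names (`suffix_split`).
#'
#' @param reports Bound rows of the two check functions.
#' @param gam Gamete-call tibble over all datasets.
#' @param meta Optional tibble with columns `dataset`, `kind`
#'   (`"raw_genotypes"` or `"pseudo"`); datasets absent from it are treated
#'   as raw.
#' @param flip_threshold Maximum reconcilable genotype-call count (default
#'   2).
#' @return List with `data` (cleaned gamete tibble) and `log` (audit tibble:
#'   `locus`, `linkage_group`, `kind`, `datasets`, `resolution`, `evidence`).
#' @export
resolve_discrepancies <- function(reports, gam, meta = NULL,
                                  flip_threshold = 2L) {
  if (nrow(reports) == 0) {
    return(list(data = gam, log = new_audit()))
  }
  kind_of <- function(ds) {
    if (is.null(meta)) return("raw_genotypes")
    k <- meta$kind[match(ds, meta$dataset)]
    ifelse(is.na(k), "raw_genotypes", k)
  }
  log <- list()
  push <- function(locus, group, kind, datasets, resolution, evidence) {
    log[[length(log) + 1]] <<- tibble::tibble(
      locus = locus, linkage_group = group, kind = kind,
      datasets = datasets, resolution = resolution,
      evidence = as.integer(evidence))
  }
  suffix_split <- function(locus) {
    involved <- gam |>
      dplyr::filter(.data$locus == !!locus) |>
      dplyr::distinct(.data$dataset) |> dplyr::pull("dataset")
    gam <<- dplyr::mutate(gam, locus = dplyr::if_else(
      .data$locus == !!locus,
      paste(.data$locus, .data$dataset, sep = "_"), .data$locus))
    involved
  }

  # 1. dropped groups
  dropped <- dplyr::filter(reports, !is.na(.data$resolution),
                           .data$resolution == "dropped_group")
  for (r in seq_len(nrow(dropped))) {
    gam <- dplyr::filter(gam, !(.data$dataset == dropped$deviant_dataset[r] &
                                  .data$locus == dropped$locus[r]))
    push(dropped$locus[r], dropped$linkage_group[r], "group_conflict",
         dropped$datasets[r], "dropped_group", dropped$evidence[r])
  }

  # 2. remaining group conflicts: suffix split
  gconf <- dplyr::filter(reports, .data$kind == "group_conflict",
                         is.na(.data$resolution))
  for (r in seq_len(nrow(gconf))) {
    suffix_split(gconf$locus[r])
    push(gconf$locus[r], gconf$linkage_group[r], "group_conflict",
         gconf$datasets[r], "suffix_split", gconf$evidence[r])
  }

  # 3./4. order conflicts (chosen deviant sets only)
  oconf <- dplyr::filter(reports, .data$kind == "order_conflict", .data$chosen)
  for (r in seq_len(nrow(oconf))) {
    loc <- oconf$locus[r]
    group <- oconf$linkage_group[r]
    ds_with <- strsplit(oconf$datasets[r], ",")[[1]]
    if (!is.na(oconf$deviant_dataset[r]) && oconf$evidence[r] >= 2) {
      gam <- dplyr::filter(gam, !(.data$dataset == oconf$deviant_dataset[r] &
                                    .data$locus == loc))
      push(loc, group, "order_conflict", oconf$datasets[r],
           "removed_from_deviant", oconf$evidence[r])
    } else if (length(ds_with) == 2) {
      raw_pair <- all(kind_of(ds_with) == "raw_genotypes")
      flips <- if (raw_pair) {
        min_flip_count(gam, group, loc, ds_with[1], ds_with[2],
                       max_flips = flip_threshold + 1L)
      } else {
        flip_threshold + 1L
      }
      if (flips <= flip_threshold) {
        gam <- realign_locus(gam, group, loc, ds_with[1], ds_with[2])
        push(loc, group, "order_conflict", oconf$datasets[r],
             "ignored_small", flips)
      } else {
        suffix_split(loc)
        push(loc, group, "order_conflict", oconf$datasets[r],
             "suffix_split", flips)
      }
    } else {
      suffix_split(loc)
      push(loc, group, "order_conflict", oconf$datasets[r],
           "suffix_split", oconf$evidence[r])
    }
  }
  list(data = gam, log = dplyr::bind_rows(new_audit(), dplyr::bind_rows(log)))
}

# move `locus` in ds_to's order so its placement follows ds_from's, then
# renumber the group's locus_index in ds_to
realign_locus <- function(gam, group, locus, ds_from, ds_to) {
  ords <- function(ds) {
    gam |>
      dplyr::filter(.data$dataset == ds, .data$linkage_group == group) |>
      dplyr::distinct(.data$locus, .data$locus_index) |>
      dplyr::arrange(.data$locus_index) |> dplyr::pull("locus")
  }
  ref <- ords(ds_from)
  cur <- ords(ds_to)
  if (!(locus %in% cur) || !(locus %in% ref)) return(gam)
  new_ord <- reposition_locus(setdiff(cur, locus), locus, ref)
  idx <- stats::setNames(seq_along(new_ord), new_ord)
  dplyr::mutate(gam, locus_index = dplyr::if_else(
    .data$dataset == ds_to & .data$linkage_group == group,
    as.integer(idx[.data$locus]), .data$locus_index))
}

#' Write a screening audit log
#'
#' @param log Audit tibble from [resolve_discrepancies()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_audit_log <- function(log, path) {
  readr::write_tsv(log, path, progress = FALSE)
  invisible(path)
}
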