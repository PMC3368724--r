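# Duplicated-locus homeology analysis: arm-level Oxford grids and the exact
# binomial enrichment test for 3rd-WGD homeolog affinity.

new_oxford_grid <- function(cells, kind, unassigned = NULL, species = NULL) {
  structure(cells,
            class = c("oxford_grid", class(tibble::as_tibble(cells))),
            kind = kind,
            unassigned = unassigned %||% tibble::tibble(),
            species = species)
}

#' @export
print.oxford_grid <- function(x, ...) {
  cat(sprintf("<oxford_grid: %s> %d cell(s), %d marker(s)\n",
              attr(x, "kind"), nrow(x), sum(x$count)))
  NextMethod()
}

#' Unassigned duplicate pairs of an arm grid
#'
#' @param grid An [arm_oxford_grid()] result.
#' @return Tibble of duplicate pairs with a centromeric or arm-less member.
#' @export
grid_unassigned <- function(grid) {
  attr(grid, "unassigned") %||% tibble::tibble()
}

#' Arm-level Oxford grid of duplicated loci
#'
#' Counts, for each unordered pair of chromosome arms, the duplicate-locus
#' pairs (`"/1"`-`"/2"` twins left by the lineage-specific whole-genome
#' duplication) with one member on each arm. Pairs with a centromeric or
#' unlabelled member go to the unassigned bucket (see [grid_unassigned()]);
#' the cell grand total plus that bucket equals the number of duplicate
#' pairs, a conservation identity worth asserting on every run.
#'
#' @param map A `synthetic_map` with arm labels.
#' @return An `oxford_grid` tibble with columns `arm_a`, `arm_b`
#'   (`arm_a <= arm_b`), `count`, `markers` (list of duplicate base names).
#' @export
arm_oxford_grid <- function(map) {
  assert_cols(map, c("linkage_group", "locus", "arm"))
  m <- tibble::as_tibble(map) |>
    dplyr::mutate(base = dup_base(.data$locus)) |>
    dplyr::filter(!is.na(.data$base))
  pairs <- m |>
    dplyr::group_by(.data$base) |>
    dplyr::filter(dplyr::n() == 2) |>
    dplyr::summarise(
      arm_1 = arm_label(.data$linkage_group[1], .data$arm[1]),
      ok_1 = .data$arm[1] %in% c("p", "q"),
      arm_2 = arm_label(.data$linkage_group[2], .data$arm[2]),
      ok_2 = .data$arm[2] %in% c("p", "q"),
      .groups = "drop")
  assigned <- dplyr::filter(pairs, .data$ok_1 & .data$ok_2)
  unassigned <- dplyr::filter(pairs, !(.data$ok_1 & .data$ok_2)) |>
    dplyr::select("base", "arm_1", "arm_2")
  cells <- assigned |>
    dplyr::mutate(arm_a = pmin(.data$arm_1, .data$arm_2),
                  arm_b = pmax(.data$arm_1, .data$arm_2)) |>
    dplyr::group_by(.data$arm_a, .data$arm_b) |>
    dplyr::summarise(count = dplyr::n(), markers = list(sort(.data$base)),
                     .groups = "drop")
  new_oxford_grid(cells, kind = "arm", unassigned = unassigned)
}

#' Classify homeology cells by support and prior knowledge
#'
#' Follows the support rules used for duplicated-arm grids: cells backed by
#' a single marker are unreliable orphans and are set aside; the rest are
#' annotated against an optional prior-knowledge table as previously known,
#' confirmed (previously only suggested, now with independent support), or
#' new.
#'
#' @param grid An [arm_oxford_grid()] result.
#' @param prior Optional tibble with columns `arm_a`, `arm_b`, `status`
#'   (`"known"` or `"suggested"`); order of the two arms is irrelevant.
#' @param min_support Minimum marker count for a cell to be retained
#'   (default 2).
#' @return The grid with an `annotation` column: `"orphan"`,
#'   `"previously_known"`, `"confirmed"`, or `"new"`.
#' @export
classify_homeologies <- function(grid, prior = NULL, min_support = 2) {
  assert_cols(grid, c("arm_a", "arm_b", "count"))
  status <- rep(NA_character_, nrow(grid))
  if (!is.null(prior) && nrow(prior) > 0) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    pk <- stats::setNames(prior$status, key(prior$arm_a, prior$arm_b))
    status <- unname(pk[key(grid$arm_a, grid$arm_b)])
  }
  ann <- dplyr::case_when(
    grid$count < min_support ~ "orphan",
    status == "known" ~ "previously_known",
    status == "suggested" ~ "confirmed",
    TRUE ~ "new"
  )
  out <- dplyr::mutate(tibble::as_tibble(grid), annotation = ann)
  new_oxford_grid(out, kind = attr(grid, "kind"),
                  unassigned = attr(grid, "unassigned"),
                  species = attr(grid, "species"))
}

#' Exact binomial upper-tail probability
#'
#' P(X >= k_obs) for X ~ Binomial(n, p), as an exact sum of point masses
#' computed in log space. This is the enrichment test asking whether trout
#' chromosome arms hit *homeologous* model-species chromosome pairs (3rd
#' whole-genome duplication relics) more often than chance: under the null,
#' the second chromosome hit by an arm is the homeolog of the first with
#' probability 1/n_chromosomes.
#'
#' @param k_obs Observed count (0 <= k_obs <= n).
#' @param n Number of trials.
#' @param p Success probability in (0, 1).
#' @return The tail probability, a single number.
#' @examples
#' binomial_tail(12, 24, 1 / 24)  # about 4.6e-11
#' @export
binomial_tail <- function(k_obs, n, p) {
  if (length(k_obs) != 1 || length(n) != 1 || length(p) != 1) {
    abort_bad_arg("binomial_tail is scalar")
  }
  if (is.na(k_obs) || is.na(n) || is.na(p) ||
      k_obs < 0 || k_obs > n || n < 1 || p <= 0 || p >= 1 ||
      k_obs != round(k_obs) || n != round(n)) {
    abort_bad_arg("invalid parameters: need 0 <= k_obs <= n, 0 < p < 1")
  }
  if (k_obs == 0) return(1)
  k <- seq(k_obs, n)
  log_terms <- lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)
  exp(logsumexp(log_terms))
}

#' Write an Oxford grid as TSV
#'
#' @param grid An `oxford_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_oxford_grid <- function(grid, path) {
  out <- tibble::as_tibble(grid)
  if ("markers" %in% names(out)) {
    out$markers <- purrr::map_chr(out$markers, paste, collapse = ",")
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
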