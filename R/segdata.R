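#' Read a doubled-haploid segregation matrix
#'
#' Reads a tab-separated segregation file into a tidy tibble of gamete calls.
#' The expected layout is one row per locus: the first two columns are the
#' linkage group and the locus name, the remaining columns are one call per
#' individual, with the header row naming the individuals. Calls are `0`/`1`
#' (doubled-haploid offspring are fully homozygous, so a genotype *is* a
#' gamete) or a missing symbol.
#'
#' @param path Path to a TSV file.
#' @param dataset_id Identifier of the source dataset (e.g. `"INRA"`).
#' @param missing Character vector of symbols read as missing calls.
#'   Empty cells and literal `NA` are always treated as missing, with a
#'   warning.
#' @return A tibble with columns `dataset`, `linkage_group`, `locus`,
#'   `locus_index` (within-group map order as listed in the file),
#'   `individual` and `call` (integer 0/1 or `NA`).
#' @seealso [write_gamete_matrix()], [read_distance_map()]
#' @export
read_gamete_matrix <- function(path, dataset_id, missing = "-") {
  if (!file.exists(path)) abort_bad_arg("file not found: %s", path)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 3) {
    abort_bad_arg("segregation file %s needs linkage_group, locus and >=1 individual column", path)
  }
  names(raw)[1:2] <- c("linkage_group", "locus")
  dup <- raw$locus[duplicated(raw$locus)]
  if (length(dup) > 0) {
    abort_bad_arg("duplicate locus name(s) in %s: %s", path,
                  paste(unique(dup), collapse = ", "))
  }
  inds <- names(raw)[-(1:2)]
  long <- raw |>
    dplyr::group_by(.data$linkage_group) |>
    dplyr::mutate(locus_index = dplyr::row_number()) |>
    dplyr::ungroup() |>
    tidyr::pivot_longer(dplyr::all_of(inds), names_to = "individual",
                        values_to = "raw_call")

  n_blank <- sum(is.na(long$raw_call) | long$raw_call == "")
  if (n_blank > 0) {
    warning(sprintf("%d empty call(s) in %s read as missing", n_blank, path),
            call. = FALSE)
  }
  is_missing <- is.na(long$raw_call) | long$raw_call == "" | long$raw_call %in% missing
  bad <- !is_missing & !long$raw_call %in% c("0", "1")
  if (any(bad)) {
    b <- long[which(bad)[1], ]
    abort_bad_arg(
      "invalid call symbol \"%s\" at locus %s, individual %s in %s (allowed: 0, 1, %s)",
      b$raw_call, b$locus, b$individual, path, paste(missing, collapse = " "))
  }
  out <- long |>
    dplyr::mutate(dataset = dataset_id,
                  call = as.integer(dplyr::if_else(is_missing, NA_character_,
                                                   .data$raw_call))) |>
    dplyr::select("dataset", "linkage_group", "locus", "locus_index",
                  "individual", "call")
  validate_gametes(out)
  out
}

#' Write a segregation matrix back to its TSV layout
#'
#' @param x A gamete-call tibble as returned by [read_gamete_matrix()] or
#'   [gametes_from_profile()].
#' @param path Output path.
#' @param missing Symbol written for missing calls.
#' @return `path`, invisibly.
#' @export
write_gamete_matrix <- function(x, path, missing = "-") {
  assert_cols(x, c("linkage_group", "locus", "locus_index", "individual", "call"))
  wide <- x |>
    dplyr::mutate(call = dplyr::if_else(is.na(.data$call), missing,
                                        as.character(.data$call))) |>
    dplyr::arrange(.data$linkage_group, .data$locus_index) |>
    tidyr::pivot_wider(id_cols = c("linkage_group", "locus"),
                       names_from = "individual", values_from = "call")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

validate_gametes <- function(x) {
  assert_cols(x, c("dataset", "linkage_group", "locus", "locus_index",
                   "individual", "call"), "gamete calls")
  bad <- x |>
    dplyr::group_by(.data$dataset, .data$locus) |>
    dplyr::summarise(all_na = all(is.na(.data$call)), .groups = "drop") |>
    dplyr::filter(.data$all_na)
  if (nrow(bad) > 0) {
    warning(sprintf("locus with no non-missing call: %s",
                    paste(bad$locus, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Read a distance-only linkage map
#'
#' Reads an ordered published map given as loci per linkage group with the
#' distance from each locus to the next one. Distances are either Kosambi
#' centiMorgans or plain recombination fractions, depending on how the source
#' map was published.
#'
#' @param path TSV with columns `linkage_group`, `locus`, `interval`; the
#'   interval of the last locus of each group must be empty or `NA`.
#' @param dataset_id Identifier of the source dataset.
#' @param distance_kind `"kosambi_cM"` or `"recomb_fraction"`.
#' @return A tibble with columns `dataset`, `linkage_group`, `locus`,
#'   `locus_index`, `interval` (`NA` on the last locus of a group) and
#'   `distance_kind`.
#' @export
read_distance_map <- function(path, dataset_id,
                              distance_kind = c("kosambi_cM", "recomb_fraction")) {
  distance_kind <- match.arg(distance_kind)
  if (!file.exists(path)) abort_bad_arg("file not found: %s", path)
  raw <- readr::read_tsv(path, col_types = "ccd", progress = FALSE,
                         show_col_types = FALSE)
  names(raw)[1:3] <- c("linkage_group", "locus", "interval")
  out <- raw |>
    dplyr::group_by(.data$linkage_group) |>
    dplyr::mutate(locus_index = dplyr::row_number(),
                  is_last = dplyr::row_number() == dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::mutate(dataset = dataset_id, distance_kind = distance_kind)
  validate_distance_map(out)
  out |>
    dplyr::select("dataset", "linkage_group", "locus", "locus_index",
                  "interval", "distance_kind")
}

validate_distance_map <- function(x) {
  inner <- dplyr::filter(x, !.data$is_last)
  if (any(is.na(inner$interval))) {
    abort_bad_arg("missing interval before the last locus of a group (locus %s)",
                  inner$locus[which(is.na(inner$interval))[1]])
  }
  if (any(inner$interval < 0, na.rm = TRUE)) {
    abort_bad_arg("negative distance at locus %s",
                  inner$locus[which(inner$interval < 0)[1]])
  }
  if (x$distance_kind[1] == "recomb_fraction" &&
      any(inner$interval > 0.5, na.rm = TRUE)) {
    abort_bad_arg("recombination fraction > 0.5 at locus %s",
                  inner$locus[which(inner$interval > 0.5)[1]])
  }
  invisible(x)
}

#' Write a distance map TSV
#'
#' @param x Tibble from [read_distance_map()] (or with the same columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_map <- function(x, path) {
  assert_cols(x, c("linkage_group", "locus", "locus_index", "interval"))
  x |>
    dplyr::arrange(.data$linkage_group, .data$locus_index) |>
    dplyr::select("linkage_group", "locus", "interval") |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' Standardize locus names against a synonym table
#'
#' Replaces alias locus names by their canonical form, as is needed before
#' any cross-dataset comparison: independently published maps often use
#' different names (or bare short names lacking the lab suffix) for the same
#' locus. Every rename is recorded in a machine-readable log attached as the
#' `"rename_log"` attribute (see [rename_log()]).
#'
#' @param x A tibble with a `locus` column (gamete calls, distance map,
#'   marker table, ...).
#' @param synonyms Tibble with columns `alias`, `canonical`.
#' @return `x` with `locus` rewritten; attribute `rename_log` holds a tibble
#'   with columns `old`, `new`, `rule`.
#' @examples
#' syn <- tibble::tibble(alias = "Ocl1", canonical = "Ocl1UW")
#' standardize_locus_names(tibble::tibble(locus = c("Ocl1", "Other")), syn)
#' @export
standardize_locus_names <- function(x, synonyms) {
  assert_cols(x, "locus")
  assert_cols(synonyms, c("alias", "canonical"), "synonyms")
  amb <- synonyms |>
    dplyr::distinct(.data$alias, .data$canonical) |>
    dplyr::count(.data$alias) |>
    dplyr::filter(.data$n > 1)
  if (nrow(amb) > 0) {
    abort_bad_arg("alias mapped to several canonical names: %s",
                  paste(amb$alias, collapse = ", "))
  }
  syn <- dplyr::distinct(synonyms, .data$alias, .data$canonical) |>
    dplyr::filter(.data$alias != .data$canonical)
  chained <- intersect(syn$canonical, syn$alias)
  if (length(chained) > 0) {
    abort_bad_arg("synonym chain/cycle: canonical name(s) %s are themselves aliases",
                  paste(chained, collapse = ", "))
  }
  map <- stats::setNames(syn$canonical, syn$alias)
  hit <- x$locus %in% names(map)
  log <- tibble::tibble(old = unique(x$locus[hit])) |>
    dplyr::mutate(new = unname(map[.data$old]), rule = "synonym")
  out <- dplyr::mutate(x, locus = dplyr::if_else(hit, unname(map[.data$locus]),
                                                 .data$locus))
  attr(out, "rename_log") <- log
  out
}

#' Rename log of a standardized table
#'
#' @param x Result of [standardize_locus_names()].
#' @return Tibble with columns `old`, `new`, `rule`.
#' @export
rename_log <- function(x) {
  attr(x, "rename_log") %||% tibble::tibble(old = character(),
                                            new = character(),
                                            rule = character())
}

#' Detect redundant loci within a dataset
#'
#' Two distinct locus names used in the *same* map that share a database
#' accession are the same physical marker entered twice; such redundant loci
#' must be collapsed before map merging. Duplicated-locus twins (`"/1"`,
#' `"/2"` suffixes), which legitimately share an accession, are never
#' reported.
#'
#' @param markers Tibble with columns `dataset`, `locus`, `accession`
#'   (one row per locus-accession link; loci without accession yield no
#'   pairs).
#' @return Tibble with columns `dataset`, `locus_a`, `locus_b`
#'   (`locus_a < locus_b`), `accession`; zero rows when nothing is redundant.
#' @export
detect_redundant_loci <- function(markers) {
  assert_cols(markers, c("dataset", "locus", "accession"))
  pairs <- markers |>
    dplyr::filter(!is.na(.data$accession), .data$accession != "") |>
    dplyr::distinct(.data$dataset, .data$locus, .data$accession) |>
    dplyr::inner_join(
      markers |>
        dplyr::filter(!is.na(.data$accession), .data$accession != "") |>
        dplyr::distinct(.data$dataset, .data$locus, .data$accession),
      by = c("dataset", "accession"), relationship = "many-to-many") |>
    dplyr::filter(.data$locus.x < .data$locus.y) |>
    dplyr::rename(locus_a = "locus.x", locus_b = "locus.y") |>
    dplyr::filter(!is_dup_twin_pair(.data$locus_a, .data$locus_b)) |>
    dplyr::distinct(.data$dataset, .data$locus_a, .data$locus_b, .data$accession)
  pairs
}

#' Per-dataset locus orders
#'
#' Extracts the within-group map order of each dataset, the structure the
#' screening functions compare.
#'
#' @param x Gamete calls or distance-map tibble (anything with `dataset`,
#'   `linkage_group`, `locus`, `locus_index`).
#' @return Tibble with one row per dataset x locus: `dataset`,
#'   `linkage_group`, `locus`, `locus_index`.
#' @export
locus_orders <- function(x) {
  assert_cols(x, c("dataset", "linkage_group", "locus", "locus_index"))
  dplyr::distinct(x, .data$dataset, .data$linkage_group, .data$locus,
                  .data$locus_index) |>
    dplyr::arrange(.data$dataset, .data$linkage_group, .data$locus_index)
}
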