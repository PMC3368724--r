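#' Inverse Kosambi map function
#'
#' Converts a Kosambi map distance into a recombination fraction,
#' r = 0.5 (e^{4k} - 1) / (e^{4k} + 1), i.e. 0.5 tanh(2k). Distances are in
#' Morgans; divide centiMorgans by 100 first (see [as_recomb_profile()]).
#'
#' @param k Non-negative Kosambi distance(s) in Morgans.
#' @return Recombination fraction(s) in \[0, 0.5).
#' @seealso [recomb_to_kosambi()]
#' @examples
#' kosambi_to_recomb(0.25)  # 0.5 * tanh(0.5)
#' @export
kosambi_to_recomb <- function(k) {
  if (any(k < 0, na.rm = TRUE)) {
    abort_bad_arg("Kosambi distance must be >= 0 (got %g)", min(k, na.rm = TRUE))
  }
  0.5 * tanh(2 * k)
}

#' Kosambi map function
#'
#' The forward Kosambi function m(r) = 0.25 ln((1 + 2r) / (1 - 2r)),
#' inverse of [kosambi_to_recomb()]. Returns Morgans.
#'
#' @param r Recombination fraction(s) in \[0, 0.5).
#' @return Kosambi distance(s) in Morgans.
#' @export
recomb_to_kosambi <- function(r) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE)) {
    abort_bad_arg("recombination fraction must be in [0, 0.5)")
  }
  0.25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Build a recombination profile from a distance map
#'
#' Turns a distance-only map into per-interval recombination fractions ready
#' for pseudo-gamete reconstruction: Kosambi cM intervals are divided by 100
#' and passed through the inverse Kosambi function; recombination-fraction
#' intervals are used as given.
#'
#' @param dmap Tibble from [read_distance_map()].
#' @param family_size Number of DH offspring N of the mapping family the
#'   map was estimated from.
#' @return A recombination profile: tibble with columns `dataset`,
#'   `linkage_group`, `locus`, `locus_index`, `r_to_next` (`NA` on last locus
#'   of each group) and `family_size`.
#' @export
as_recomb_profile <- function(dmap, family_size) {
  assert_cols(dmap, c("dataset", "linkage_group", "locus", "locus_index",
                      "interval", "distance_kind"))
  if (family_size < 2) abort_bad_arg("family_size must be >= 2")
  kind <- dmap$distance_kind[1]
  r <- if (kind == "kosambi_cM") {
    kosambi_to_recomb(dmap$interval / 100)
  } else {
    dmap$interval
  }
  dmap |>
    dplyr::mutate(r_to_next = r, family_size = as.integer(family_size)) |>
    dplyr::select("dataset", "linkage_group", "locus", "locus_index",
                  "r_to_next", "family_size")
}

#' Rescale the family size of a recombination profile
#'
#' Reassigns the nominal family size used for pseudo-gamete reconstruction,
#' e.g. to down-weight a large family relative to the other datasets being
#' merged. Loci and recombination fractions are untouched. When the new size
#' is small enough that some interval's recombinant count rounds to zero
#' while the old one did not, the information loss is reported via a message.
#'
#' @param profile Tibble from [as_recomb_profile()].
#' @param new_N New family size (>= 2).
#' @return The profile with `family_size` replaced.
#' @export
rescale_profile <- function(profile, new_N) {
  assert_cols(profile, c("r_to_next", "family_size"))
  if (new_N < 2) abort_bad_arg("new_N must be >= 2")
  old_N <- profile$family_size[1]
  r <- profile$r_to_next[!is.na(profile$r_to_next)]
  lost <- sum(round_half_up(r * old_N) > 0 & round_half_up(r * new_N) == 0)
  if (lost > 0) {
    message(sprintf(
      "rescaling N = %d -> %d rounds %d interval(s) down to 0 recombinants",
      old_N, new_N, lost))
  }
  dplyr::mutate(profile, family_size = as.integer(new_N))
}

# deterministic flip of k recombinants into `prev`, alternating the leftmost
# unflipped 0 -> 1 and the leftmost unflipped 1 -> 0
flip_recombinants <- function(prev, k) {
  if (k > length(prev)) {
    abort_bad_arg("impossible recombinant count %d for family size %d",
                  k, length(prev))
  }
  v <- prev
  touched <- rep(FALSE, length(prev))
  want <- 0L  # flip a zero first, as in the worked example
  for (i in seq_len(k)) {
    pos <- which(!touched & prev == want)[1]
    if (is.na(pos)) {
      abort_bad_arg("no unflipped %d left while placing recombinant %d of %d",
                    want, i, k)
    }
    v[pos] <- 1L - v[pos]
    touched[pos] <- TRUE
    want <- 1L - want
  }
  v
}

#' Reconstruct pseudo-gamete vectors from a recombination profile
#'
#' Recovers a gamete matrix compatible with a distance-only map so that it
#' can be merged with raw genotype data. The first locus of each linkage
#' group is a balanced vector of N/2 zeros followed by N/2 ones (for odd N,
#' one extra zero); each subsequent locus copies the previous vector with
#' `round(r * N)` recombinant flips, alternately turning the leftmost
#' unflipped 0 into 1 and the leftmost unflipped 1 into 0. The Hamming
#' distance between adjacent locus vectors is therefore exactly
#' `round(r * N)`, so two-point estimation on the reconstruction returns the
#' encoded fractions up to rounding.
#'
#' @param profile Tibble from [as_recomb_profile()] /
#'   [rescale_profile()].
#' @return A gamete-call tibble with the same columns as
#'   [read_gamete_matrix()]; individuals are named `<dataset>_g<i>`.
#' @examples
#' dm <- tibble::tibble(dataset = "ARS", linkage_group = "RT01",
#'                      locus = c("A", "B"), locus_index = 1:2,
#'                      interval = c(4, NA), distance_kind = "kosambi_cM")
#' g <- gametes_from_profile(as_recomb_profile(dm, family_size = 50))
#' @export
gametes_from_profile <- function(profile) {
  assert_cols(profile, c("dataset", "linkage_group", "locus", "locus_index",
                         "r_to_next", "family_size"))
  if (any(profile$r_to_next < 0 | profile$r_to_next > 0.5, na.rm = TRUE)) {
    abort_bad_arg("recombination fractions must be in [0, 0.5]")
  }
  N <- profile$family_size[1]
  inds <- sprintf("%s_g%03d", profile$dataset[1], seq_len(N))
  groups <- split(profile, profile$linkage_group)
  out <- purrr::map(groups, function(gp) {
    gp <- dplyr::arrange(gp, .data$locus_index)
    m <- matrix(NA_integer_, nrow = nrow(gp), ncol = N)
    m[1, ] <- c(rep(0L, ceiling(N / 2)), rep(1L, floor(N / 2)))
    if (nrow(gp) > 1) {
      for (i in 2:nrow(gp)) {
        k <- as.integer(round_half_up(gp$r_to_next[i - 1] * N))
        m[i, ] <- flip_recombinants(m[i - 1, ], k)
      }
    }
    tibble::tibble(
      dataset = gp$dataset[1], linkage_group = gp$linkage_group[1],
      locus = rep(gp$locus, each = N), locus_index = rep(gp$locus_index, each = N),
      individual = rep(inds, times = nrow(gp)), call = as.integer(t(m))
    )
  })
  dplyr::bind_rows(out)
}
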