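# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_bad_arg <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "synmapr_error")
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort_bad_arg("`%s` is missing required column(s): %s",
                  what, paste(miss, collapse = ", "))
  }
  invisible(df)
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# strip the "/1" or "/2" duplicate suffix; NA when the locus has no suffix
dup_base <- function(locus) {
  has <- grepl("/[12]$", locus)
  ifelse(has, sub("/[12]$", "", locus), NA_character_)
}

is_dup_twin_pair <- function(a, b) {
  ba <- dup_base(a); bb <- dup_base(b)
  !is.na(ba) & !is.na(bb) & ba == bb
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# arm unit labels used in Oxford grids, e.g. "RT01p"
arm_label <- function(linkage_group, arm) paste0(linkage_group, arm)

# dataset-namespaced individual ids
namespace_individuals <- function(dataset, individual) {
  paste(dataset, individual, sep = ":")
}

new_audit <- function() {
  tibble::tibble(
    locus = character(), linkage_group = character(),
    kind = character(), datasets = character(),
    resolution = character(), evidence = integer()
  )
}
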