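# Ground-truth simulator: true maps with planted duplication/synteny
# structure, doubled-haploid segregation data, and BLAST-tabular homology
# fixtures. Everything is a pure function of (parameters, seed).

#' Simulate a ground-truth linkage map
#'
#' Generates a map with known marker order and positions, a centromeric
#' range per group, a planted duplicated-locus structure (the 4th-WGD
#' homeolog relic: a fraction of markers come in `"/1"`-`"/2"` twins on
#' distinct arms), and a planted cross-species layout: each arm is syntenic
#' to one model chromosome, model chromosomes are paired into within-species
#' homeologs (3rd WGD), and each homeolog pair descends from one ancestral
#' proto-chromosome, so the planted synteny is consistent with the planted
#' ancestor map by construction.
#'
#' Adjacent spacings are `min_spacing_cM` plus a random share of the
#' remaining length, so each group spans `length_cM` exactly.
#'
#' @param n_groups Number of linkage groups.
#' @param markers_per_group Markers per group.
#' @param length_cM Map length of each group (span, cM).
#' @param dup_fraction Fraction of markers that belong to duplicate pairs.
#' @param seed Integer seed; identical seeds give identical maps.
#' @param n_model_chrom Model-species chromosome count (default: one per
#'   arm, rounded up to even).
#' @param min_spacing_cM Minimum adjacent spacing (default 5).
#' @return A `true_map`: list with elements `map` (tibble `linkage_group`,
#'   `locus`, `position_cM`, `arm`, `model_chrom`, `model_bp`), `centromeres`
#'   (`linkage_group`, `start_locus`, `end_locus`), `homeologs` (`chrom_a`,
#'   `chrom_b`), `ancestor` (`model_chrom`, `proto`), `params`.
#' @export
simulate_true_map <- function(n_groups = 2, markers_per_group = 20,
                              length_cM = 100, dup_fraction = 0,
                              seed = 1, n_model_chrom = NULL,
                              min_spacing_cM = 5) {
  if (n_groups < 1 || markers_per_group < 2 || length_cM <= 0 ||
      dup_fraction < 0 || dup_fraction > 1) {
    abort_bad_arg("invalid simulation parameters")
  }
  n_int <- markers_per_group - 1
  if (length_cM < n_int * min_spacing_cM) {
    abort_bad_arg("length_cM too short for %d intervals at >= %g cM",
                  n_int, min_spacing_cM)
  }
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(n_groups), function(g) {
      lg <- sprintf("RT%02d", g)
      slack <- length_cM - n_int * min_spacing_cM
      u <- runif(n_int)
      spacing <- min_spacing_cM + slack * u / sum(u)
      pos <- cumsum(c(0, spacing))
      loci <- sprintf("%s_M%02d", lg, seq_len(markers_per_group))
      # centromere: the two consecutive loci straddling the middle
      ci <- which.min(abs(pos - length_cM / 2))
      ci <- min(max(ci, 1), markers_per_group - 1)
      arm <- rep("q", markers_per_group)
      arm[seq_len(markers_per_group) < ci] <- "p"
      arm[c(ci, ci + 1)] <- "centromeric"
      tibble::tibble(linkage_group = lg, locus = loci, position_cM = pos,
                     arm = arm)
    })
    map <- dplyr::bind_rows(rows)
    centromeres <- map |>
      dplyr::filter(.data$arm == "centromeric") |>
      dplyr::group_by(.data$linkage_group) |>
      dplyr::summarise(start_locus = dplyr::first(.data$locus),
                       end_locus = dplyr::last(.data$locus), .groups = "drop")

    # planted duplicate pairs on distinct arms
    n_pairs <- floor(n_groups * markers_per_group * dup_fraction / 2)
    if (n_pairs > 0) {
      eligible <- which(map$arm %in% c("p", "q"))
      arm_units <- arm_label(map$linkage_group, map$arm)
      chosen <- sample(eligible)
      used <- logical(nrow(map))
      made <- 0
      for (i in chosen) {
        if (made >= n_pairs) break
        if (used[i]) next
        partner <- chosen[!used[chosen] & chosen != i &
                            arm_units[chosen] != arm_units[i]]
        if (length(partner) == 0) next
        j <- partner[1]
        made <- made + 1
        base <- sprintf("Dup%03d", made)
        map$locus[i] <- paste0(base, "/1")
        map$locus[j] <- paste0(base, "/2")
        used[c(i, j)] <- TRUE
      }
      centromeres <- centromeres  # locus names in ranges never duplicated
    }

    # planted synteny: one model chromosome per arm
    arm_units <- map |>
      dplyr::filter(.data$arm %in% c("p", "q")) |>
      dplyr::distinct(.data$linkage_group, .data$arm) |>
      dplyr::mutate(unit = arm_label(.data$linkage_group, .data$arm))
    K <- n_model_chrom %||% (2 * ceiling(nrow(arm_units) / 2))
    K <- max(K, 2)
    if (K %% 2 == 1) K <- K + 1
    chroms <- sprintf("Chr%02d", seq_len(K))
    arm_units$model_chrom <- chroms[(seq_len(nrow(arm_units)) - 1) %% K + 1]
    map <- map |>
      dplyr::left_join(dplyr::select(arm_units, "linkage_group", "arm",
                                     "model_chrom"),
                       by = c("linkage_group", "arm")) |>
      dplyr::group_by(.data$linkage_group, .data$arm) |>
      dplyr::mutate(model_bp = dplyr::if_else(
        is.na(.data$model_chrom), NA_real_,
        dplyr::row_number() * 1e6)) |>
      dplyr::ungroup()
    homeologs <- tibble::tibble(
      chrom_a = chroms[seq(1, K, by = 2)],
      chrom_b = chroms[seq(2, K, by = 2)])
    ancestor <- tibble::tibble(
      model_chrom = chroms,
      proto = rep(LETTERS[seq_len(K / 2)], each = 2))

    structure(list(map = map, centromeres = centromeres,
                   homeologs = homeologs, ancestor = ancestor,
                   params = list(n_groups = n_groups,
                                 markers_per_group = markers_per_group,
                                 length_cM = length_cM,
                                 dup_fraction = dup_fraction,
                                 n_model_chrom = K,
                                 min_spacing_cM = min_spacing_cM,
                                 seed = seed)),
              class = "true_map")
  })
}

#' @export
print.true_map <- function(x, ...) {
  cat(sprintf("<true_map> %d loci, %d groups, %d duplicate pairs, %d model chromosomes\n",
              nrow(x$map), length(unique(x$map$linkage_group)),
              length(unique(stats::na.omit(dup_base(x$map$locus)))),
              x$params$n_model_chrom))
  invisible(x)
}

#' Simulate a doubled-haploid segregation dataset
#'
#' Draws N gametes per linkage group from the true map. Adjacent-interval
#' recombination probabilities are the cM intervals divided by 100 (the
#' recombination-percentage mapping function, appropriate under strong
#' interference). Two interference models are available: `"complete"`
#' (at most one crossover per chromosome arm per gamete — the salmonid
#' situation; requires each arm's interval probabilities to sum to at most
#' 1) and `"none"` (independent recombination per interval, for
#' calibration). Genotyping error flips calls symmetrically; missingness
#' masks calls, both independently per call.
#'
#' @param true_map A [simulate_true_map()] result.
#' @param dataset_id Dataset identifier stamped on the output.
#' @param N Family size (gametes).
#' @param missing_rate,error_rate Per-call rates in \[0, 1\].
#' @param interference `"complete"` or `"none"`.
#' @param seed Integer seed.
#' @return A gamete-call tibble ([read_gamete_matrix()] layout), loci in
#'   true map order.
#' @export
simulate_dh_dataset <- function(true_map, dataset_id = "SIM", N = 50,
                                missing_rate = 0, error_rate = 0,
                                interference = c("complete", "none"),
                                seed = 1) {
  interference <- match.arg(interference)
  stopifnot(inherits(true_map, "true_map"))
  if (missing_rate < 0 || missing_rate > 1 || error_rate < 0 || error_rate > 1) {
    abort_bad_arg("rates must be in [0, 1]")
  }
  inds <- sprintf("%s_i%03d", dataset_id, seq_len(N))
  withr::with_seed(seed, {
    groups <- split(true_map$map, true_map$map$linkage_group)
    out <- purrr::imap(groups, function(gm, lg) {
      gm <- dplyr::arrange(gm, .data$position_cM)
      L <- nrow(gm)
      r <- diff(gm$position_cM) / 100
      # interval side: attach centromere-spanning intervals to the p side
      cm_mid <- mean(gm$position_cM[gm$arm == "centromeric"])
      side <- ifelse(gm$position_cM[-L] < cm_mid, "p", "q")
      origin <- matrix(0L, nrow = L, ncol = N)
      start <- sample(0:1, N, replace = TRUE)
      xo <- matrix(FALSE, nrow = L - 1, ncol = N)
      if (interference == "none") {
        xo[] <- runif((L - 1) * N) < r
      } else {
        for (s in c("p", "q")) {
          iv <- which(side == s)
          if (length(iv) == 0) next
          p_iv <- r[iv]
          tot <- sum(p_iv)
          if (tot > 1) {
            abort_bad_arg(
              "arm %s of %s: interval probabilities sum to %.2f > 1; use interference = \"none\"",
              s, lg, tot)
          }
          pick <- sample(c(iv, 0L), N, replace = TRUE,
                         prob = c(p_iv, 1 - tot))
          hit <- pick > 0
          xo[cbind(pick[hit], which(hit))] <- TRUE
        }
      }
      cum <- apply(xo, 2, cumsum)
      origin[1, ] <- start
      origin[-1, ] <- (rep(start, each = L - 1) + cum) %% 2
      if (error_rate > 0) {
        flip <- matrix(runif(L * N) < error_rate, L, N)
        origin <- (origin + flip) %% 2
      }
      calls <- origin
      if (missing_rate > 0) {
        calls[matrix(runif(L * N) < missing_rate, L, N)] <- NA_integer_
      }
      tibble::tibble(
        dataset = dataset_id, linkage_group = lg,
        locus = rep(gm$locus, each = N),
        locus_index = rep(seq_len(L), each = N),
        individual = rep(inds, times = L),
        call = as.integer(t(calls)))
    })
    dplyr::bind_rows(out)
  })
}

#' Simulate a BLAST-tabular homology fixture
#'
#' Writes a parseable tabular file where every mapped marker hits its
#' planted model-chromosome location below the significance cutoff, plus
#' planted decoys with known fate: *orphan* decoys redirect a marker's hit
#' to an otherwise unhit chromosome (creating a single-marker cell that
#' orphan removal must delete) and *tie* decoys give a marker two hits with
#' identical e-value and HSP score (which uniqueness filtration must drop).
#' Decoy counts are Poisson with the given expectations; decoys only touch
#' arms that keep at least `keep_min` planted markers so the planted
#' homologies stay supported.
#'
#' @param true_map A [simulate_true_map()] result.
#' @param path Output file path.
#' @param orphan_noise,tie_noise Expected decoy counts (>= 0).
#' @param seed Integer seed.
#' @param program BLAST program emulated (default `"blastn"`).
#' @param keep_min Minimum planted markers an arm must retain (default 2).
#' @return `path` invisibly; attributes `truth` (tibble `query`, `chrom`,
#'   `fate` in planted/orphan/tie) describing every planted row.
#' @export
simulate_homology_table <- function(true_map, path, orphan_noise = 0,
                                    tie_noise = 0, seed = 1,
                                    program = "blastn", keep_min = 2) {
  stopifnot(inherits(true_map, "true_map"))
  if (orphan_noise < 0 || tie_noise < 0) abort_bad_arg("noise must be >= 0")
  m <- dplyr::filter(true_map$map, !is.na(.data$model_chrom))
  chroms <- sprintf("Chr%02d", seq_len(true_map$params$n_model_chrom))
  withr::with_seed(seed, {
    m <- m |>
      dplyr::mutate(arm_unit = arm_label(.data$linkage_group, .data$arm),
                    fate = "planted")
    # sister arm's chromosome (kept out of orphan decoys so metacentric
    # re-assignment cannot absorb them)
    sisters <- m |>
      dplyr::distinct(.data$linkage_group, .data$arm, .data$model_chrom) |>
      dplyr::group_by(.data$linkage_group) |>
      dplyr::mutate(sister_chrom = rev(.data$model_chrom)) |>
      dplyr::ungroup()
    m <- dplyr::left_join(m, dplyr::select(sisters, "linkage_group", "arm",
                                           "sister_chrom"),
                          by = c("linkage_group", "arm"))
    n_orphan <- stats::rpois(1, orphan_noise)
    n_tie <- stats::rpois(1, tie_noise)
    remaining <- table(m$arm_unit)
    decoy_order <- sample(nrow(m))
    taken <- character(0)
    pick_marker <- function() {
      for (i in decoy_order) {
        q <- m$locus[i]
        if (q %in% taken) next
        if (m$fate[i] != "planted") next
        if (remaining[m$arm_unit[i]] <= keep_min) next
        taken <<- c(taken, q)
        remaining[m$arm_unit[i]] <<- remaining[m$arm_unit[i]] - 1
        return(i)
      }
      NA_integer_
    }
    orphan_used <- list()  # arm_unit -> chroms already used as decoys
    for (k in seq_len(n_orphan)) {
      i <- pick_marker()
      if (is.na(i)) break
      au <- m$arm_unit[i]
      banned <- c(m$model_chrom[i], m$sister_chrom[i], orphan_used[[au]])
      cand <- setdiff(chroms, banned)
      if (length(cand) == 0) next
      wrong <- sample(cand, 1)
      orphan_used[[au]] <- c(orphan_used[[au]], wrong)
      m$model_chrom[i] <- wrong
      m$model_bp[i] <- 1e6
      m$fate[i] <- "orphan"
    }
    tie_rows <- list()
    for (k in seq_len(n_tie)) {
      i <- pick_marker()
      if (is.na(i)) break
      m$fate[i] <- "tie"
      other <- sample(setdiff(chroms, m$model_chrom[i]), 1)
      tie_rows[[length(tie_rows) + 1]] <-
        dplyr::mutate(m[i, ], model_chrom = other)
    }
    rows <- dplyr::bind_rows(m, dplyr::bind_rows(tie_rows))
    evalue <- 1e-20
    pident <- 95
    alen <- 200L
    tab <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.1e\t%.1f",
                   rows$locus, rows$model_chrom, pident, alen, 5L, 1L,
                   1L, alen, as.integer(rows$model_bp),
                   as.integer(rows$model_bp) + alen - 1L, evalue, 360.5)
    header <- c(sprintf("# %s", toupper(program)),
                "# Fields: query id, subject id, % identity, alignment length, mismatches, gap opens, q. start, q. end, s. start, s. end, evalue, bit score",
                sprintf("# %d hits found", length(tab)))
    writeLines(c(header, tab), path)
    truth <- m |>
      dplyr::select(query = "locus", chrom = "model_chrom", "fate")
    out <- invisible(path)
    attr(out, "truth") <- truth
    out
  })
}
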