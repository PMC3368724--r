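# fixture builders shared across test files; everything is generated in code

write_seg_fixture <- function(lines, path = withr::local_tempfile(fileext = ".tsv",
                                                                  .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

# small wide segregation file: loci x individuals
seg_lines <- function(calls, group = "RT01",
                      loci = sprintf("L%02d", seq_len(nrow(calls))),
                      inds = sprintf("ind%d", seq_len(ncol(calls)))) {
  header <- paste(c("linkage_group", "locus", inds), collapse = "\t")
  rows <- vapply(seq_len(nrow(calls)), function(i) {
    paste(c(group, loci[i], calls[i, ]), collapse = "\t")
  }, character(1))
  c(header, rows)
}

# gamete tibble straight from a calls matrix (no file round trip)
gam_from_matrix <- function(calls, dataset = "D1", group = "RT01",
                            loci = sprintf("L%02d", seq_len(nrow(calls))),
                            inds = sprintf("%s_i%d", dataset, seq_len(ncol(calls)))) {
  tibble::tibble(
    dataset = dataset, linkage_group = group,
    locus = rep(loci, each = ncol(calls)),
    locus_index = rep(seq_along(loci), each = ncol(calls)),
    individual = rep(inds, times = nrow(calls)),
    call = as.integer(t(calls)))
}

# deterministic DH gametes for loci at given cumulative cM positions:
# one gamete per crossover pattern is too rigid, so draw binomially
sim_gam_simple <- function(positions, N, dataset = "D1", group = "RT01",
                           loci = sprintf("L%02d", seq_along(positions)),
                           seed = 1) {
  withr::with_seed(seed, {
    L <- length(positions)
    r <- diff(positions) / 100
    calls <- matrix(0L, L, N)
    calls[1, ] <- sample(0:1, N, replace = TRUE)
    for (i in 2:L) {
      rec <- runif(N) < r[i - 1]
      calls[i, ] <- ifelse(rec, 1L - calls[i - 1, ], calls[i - 1, ])
    }
    gam_from_matrix(calls, dataset = dataset, group = group, loci = loci)
  })
}

# brute-force optimal open-path order over all permutations (oracle)
brute_force_best_order <- function(S) {
  n <- nrow(S)
  perms <- synmapr:::permutations_of(n)
  best <- Inf
  best_p <- NULL
  for (p in perms) {
    obj <- sum(S[cbind(p[-n], p[-1])])
    if (obj < best - 1e-12) {
      best <- obj
      best_p <- p
    }
  }
  list(order = best_p, objective = best)
}

# brute-force BLAST filtration oracle: explicit enumeration of the rules
brute_force_filter <- function(hits, cutoff = 1e-5) {
  keep <- list()
  for (q in unique(hits$query)) {
    h <- hits[hits$query == q & hits$evalue <= cutoff, , drop = FALSE]
    if (nrow(h) == 0) next
    h <- h[h$evalue == min(h$evalue), , drop = FALSE]
    h <- h[h$hsp_score == max(h$hsp_score), , drop = FALSE]
    if (nrow(h) == 1) keep[[q]] <- h
  }
  dplyr::bind_rows(keep)
}

make_pipeline_inputs <- function(dir, seed = 1) {
  tm <- simulate_true_map(n_groups = 2, markers_per_group = 10,
                          length_cM = 60, dup_fraction = 0.2, seed = seed)
  # raw-genotype datasets
  g1 <- simulate_dh_dataset(tm, "INRA", N = 40, seed = seed + 1)
  g2 <- simulate_dh_dataset(tm, "UoG", N = 40, missing_rate = 0.1,
                            seed = seed + 2)
  write_gamete_matrix(g1, file.path(dir, "inra.tsv"))
  write_gamete_matrix(g2, file.path(dir, "uog.tsv"))
  # distance-only dataset derived from the truth (Kosambi cM intervals)
  dm <- tm$map |>
    dplyr::group_by(linkage_group) |>
    dplyr::mutate(interval = 100 * recomb_to_kosambi(
      pmin(dplyr::lead(position_cM) - position_cM, 49.9) / 100)) |>
    dplyr::ungroup() |>
    dplyr::transmute(dataset = "ARS", linkage_group, locus,
                     locus_index = dplyr::row_number(), interval,
                     distance_kind = "kosambi_cM")
  write_distance_map(dm, file.path(dir, "ars.tsv"))
  readr::write_tsv(tm$centromeres, file.path(dir, "centromeres.tsv"))
  readr::write_tsv(tibble::tibble(alias = character(),
                                  canonical = character()),
                   file.path(dir, "synonyms.tsv"))
  simulate_homology_table(tm, file.path(dir, "medaka_blastn.tsv"),
                          orphan_noise = 2, seed = seed + 5)
  readr::write_tsv(tm$homeologs, file.path(dir, "homeologs.tsv"))
  readr::write_tsv(tm$ancestor, file.path(dir, "ancestor.tsv"))
  config <- list(
    seed = 1,
    datasets = list(
      list(id = "INRA", path = file.path(dir, "inra.tsv"),
           kind = "raw_genotypes", family_size = 40),
      list(id = "UoG", path = file.path(dir, "uog.tsv"),
           kind = "raw_genotypes", family_size = 40),
      list(id = "ARS", path = file.path(dir, "ars.tsv"),
           kind = "distance_map", distance_kind = "kosambi_cM",
           family_size = 50, weight_size = 40)),
    synonyms = file.path(dir, "synonyms.tsv"),
    centromeres = file.path(dir, "centromeres.tsv"),
    ordering = list(method = "annealing", seed = 1),
    synteny = list(species = list(
      list(name = "medaka", blastn = file.path(dir, "medaka_blastn.tsv"),
           homeologs = file.path(dir, "homeologs.tsv"),
           ancestor = file.path(dir, "ancestor.tsv")))))
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  list(tm = tm, config = config, config_path = file.path(dir, "config.yaml"))
}
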