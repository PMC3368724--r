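test_that("merging unions loci and concatenates namespaced individuals", {
  g1 <- gam_from_matrix(matrix(0L, 10, 50), dataset = "D1",
                        loci = sprintf("A%02d", 1:10))
  g2 <- gam_from_matrix(matrix(1L, 12, 50), dataset = "D2",
                        loci = c(sprintf("A%02d", 1:5), sprintf("B%02d", 1:7)))
  m <- merge_matrices(dplyr::bind_rows(g1, g2), "RT01")
  expect_equal(nrow(m), 17)   # 10 + 12 - 5 shared
  expect_equal(ncol(m) - 1, 100)
  # block structure: loci typed only in D1 are missing in the D2 block
  blocks <- attr(m, "blocks")
  d1_cols <- blocks$ind_id[blocks$dataset == "D1"]
  d2_cols <- blocks$ind_id[blocks$dataset == "D2"]
  only_d1 <- m[m$locus %in% sprintf("A%02d", 6:10), ]
  expect_true(all(is.na(as.matrix(only_d1[, d2_cols]))))
  expect_true(all(!is.na(as.matrix(only_d1[, d1_cols]))))
  # single dataset is the identity on its calls
  m1 <- merge_matrices(g1, "RT01")
  expect_equal(nrow(m1), 10)
  expect_equal(ncol(m1) - 1, 50)
})

test_that("merging disjoint datasets warns that nothing links across them", {
  g1 <- gam_from_matrix(matrix(0L, 3, 10), dataset = "D1",
                        loci = c("A", "B", "C"))
  g2 <- gam_from_matrix(matrix(1L, 3, 10), dataset = "D2",
                        loci = c("X", "Y", "Z"))
  expect_warning(m <- merge_matrices(dplyr::bind_rows(g1, g2), "RT01"),
                 "share no locus")
  expect_false(attr(m, "cross_linked"))
})

test_that("two-point estimates count recombinants with phase detection", {
  calls <- rbind(c(0L, 0L, 0L, 1L, 1L, 1L),
                 c(0L, 0L, 0L, 1L, 1L, 1L),
                 c(1L, 1L, 1L, 0L, 0L, 0L),
                 c(0L, 0L, 1L, 1L, 1L, 1L))
  m <- merge_matrices(gam_from_matrix(calls, loci = c("A", "B", "C", "D")), "RT01")
  ab <- estimate_two_point(m, "A", "B")
  expect_equal(ab$r_hat, 0)
  expect_equal(ab$phase, "coupling")
  ac <- estimate_two_point(m, "A", "C")
  expect_equal(ac$r_hat, 0)   # complement: zero recombinants in repulsion
  expect_equal(ac$phase, "repulsion")
  ad <- estimate_two_point(m, "A", "D")
  expect_equal(ad$r_hat, 1 / 6)
  expect_equal(ad$n_informative, 6L)
  # r_hat * n_informative is an integer count for all pairs
  tp <- two_point_table(m)
  expect_equal(tp$r_hat * tp$n_informative,
               round(tp$r_hat * tp$n_informative))
})

test_that("zero-information pairs fall back to r = 0.5 with weight 0", {
  calls <- rbind(c(0L, 1L, NA, NA),
                 c(NA, NA, 0L, 1L))
  m <- merge_matrices(gam_from_matrix(calls, loci = c("A", "B")), "RT01")
  est <- estimate_two_point(m, "A", "B")
  expect_equal(est$r_hat, 0.5)
  expect_equal(est$n_informative, 0L)
  expect_true(is.na(est$phase))
})

test_that("reconstructed adjacent loci re-estimate their encoded fraction", {
  prof <- tibble::tibble(dataset = "ARS", linkage_group = "RT01",
                         locus = c("A", "B"), locus_index = 1:2,
                         r_to_next = c(0.04, NA), family_size = 50L)
  m <- merge_matrices(gametes_from_profile(prof), "RT01")
  expect_equal(estimate_two_point(m, "A", "B")$r_hat, 0.04)
})

test_that("exact ordering matches exhaustive search on random instances", {
  for (seed in 1:8) {
    S <- withr::with_seed(seed, {
      n <- sample(4:7, 1)
      D <- matrix(runif(n * n, 0.01, 0.49), n, n)
      D <- (D + t(D)) / 2
      diag(D) <- 0
      D
    })
    bf <- brute_force_best_order(S)
    ord <- synmapr:::order_exact(S)
    expect_equal(synmapr:::path_objective(S, ord), bf$objective,
                 tolerance = 1e-12)
  }
})

test_that("ordering recovers a simulated true order and never worsens an input", {
  tm <- simulate_true_map(n_groups = 1, markers_per_group = 6, length_cM = 25,
                          seed = 11)
  gam <- simulate_dh_dataset(tm, "D1", N = 100, seed = 4)
  m <- merge_matrices(gam, "RT01")
  truth <- dplyr::arrange(tm$map, position_cM)$locus
  for (method in c("exact", "annealing", "taboo", "flips")) {
    ord <- order_markers(m, method = method, seed = 7)
    expect_true(identical(ord$locus, truth) || identical(ord$locus, rev(truth)),
                label = sprintf("method %s recovers truth", method))
  }
  # canonical orientation: first name sorts before last
  ord <- order_markers(m, method = "exact")
  expect_true(ord$locus[1] < ord$locus[6])
  # 2-locus group: the single order, objective r_hat
  m2 <- merge_matrices(dplyr::filter(gam, locus %in% truth[1:2]), "RT01")
  o2 <- order_markers(m2, method = "exact")
  expect_equal(nrow(o2), 2)
  expect_equal(attr(o2, "objective"),
               estimate_two_point(m2, truth[1], truth[2])$r_hat)
})

test_that("disconnected linkage is an error listing the components", {
  calls <- rbind(c(0L, 1L, NA, NA),
                 c(0L, 1L, NA, NA),
                 c(NA, NA, 0L, 1L))
  m <- merge_matrices(gam_from_matrix(calls, loci = c("A", "B", "C")), "RT01")
  expect_error(order_markers(m, method = "exact"), "A,B.*C",
               class = "synmapr_error")
})

test_that("exact ordering refuses oversized groups", {
  S <- matrix(0.1, 16, 16); diag(S) <- 0
  expect_error(synmapr:::order_exact(S), "at most 15", class = "synmapr_error")
})

test_that("positions accumulate 100 r cM from zero and arms split around the centromere", {
  est <- tibble::tibble(locus_a = c("A", "B"), locus_b = c("B", "C"),
                        r_hat = c(0.04, 0.10), n_informative = 50L,
                        phase = "coupling")
  pos <- compute_positions(c("A", "B", "C"), est)
  expect_equal(pos$position_cM, c(0, 4, 14))
  # all-zero fractions collapse to a point
  est0 <- dplyr::mutate(est, r_hat = 0)
  expect_equal(compute_positions(c("A", "B", "C"), est0)$position_cM,
               c(0, 0, 0))

  pos10 <- tibble::tibble(locus = sprintf("L%02d", 1:10),
                          position_cM = seq(0, 45, by = 5))
  arms <- partition_arms(pos10, c("L05", "L06"))
  expect_equal(sum(arms$arm == "p"), 4)
  expect_equal(sum(arms$arm == "q"), 4)
  expect_equal(sum(arms$arm == "centromeric"), 2)
  # acrocentric: terminal centromere, empty first arm allowed
  expect_message(acro <- partition_arms(pos10, c("L01", "L02")),
                 "acrocentric")
  expect_equal(sum(acro$arm == "p"), 0)
  expect_equal(sum(acro$arm == "q"), 8)
  expect_error(partition_arms(pos10, c("L05", "Lxx")), "Lxx",
               class = "synmapr_error")
})

test_that("interval lengths sum to the group length on built maps", {
  tm <- simulate_true_map(n_groups = 1, markers_per_group = 10, length_cM = 60,
                          seed = 5)
  gam <- simulate_dh_dataset(tm, "D1", N = 80, seed = 6)
  map <- build_synthetic_map(gam, centromeres = tm$centromeres, seed = 2)
  m <- tibble::as_tibble(map)
  expect_equal(sum(diff(m$position_cM)), max(m$position_cM))
  expect_equal(m$position_cM[1], 0)
  expect_false(is.unsorted(m$position_cM))
  g <- glance(map)
  expect_equal(g$n_loci, 10)
  expect_equal(g$n_groups, 1)
  # writers produce the documented layouts
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_synthetic_map(map, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(back), 10)
  mct <- withr::local_tempfile(fileext = ".txt")
  write_mapchart(map, mct)
  lines <- readLines(mct)
  expect_equal(lines[1], "group RT01")
  expect_match(lines[2], "^RT01_M\\d+ \\d+\\.\\d{3}$")
})

test_that("tidiers return the per-locus table and summary counts", {
  tm <- simulate_true_map(n_groups = 2, markers_per_group = 6, length_cM = 30,
                          dup_fraction = 0.4, seed = 9)
  map <- as_synthetic_map(dplyr::select(tm$map, linkage_group, locus,
                                        position_cM, arm))
  td <- tidy(map)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "synthetic_map"))
  g <- glance(map)
  expect_equal(g$n_duplicated_loci, 2 * g$n_duplicate_pairs)
  expect_equal(g$n_loci, 12)
})

test_that("heuristic orders are never worse than an arbitrary input order", {
  for (seed in 1:5) {
    tm <- simulate_true_map(1, 10, 70, seed = seed)
    gam <- simulate_dh_dataset(tm, "D", N = 40, missing_rate = 0.1, seed = seed)
    m <- merge_matrices(gam, "RT01")
    tp <- two_point_table(m)
    shuffled <- withr::with_seed(seed, sample(m$locus))
    base_obj <- map_order_objective(shuffled, tp)
    for (method in c("annealing", "taboo", "flips")) {
      o <- order_markers(m, method = method, seed = seed)
      expect_lte(attr(o, "objective"), base_obj + 1e-9)
    }
  }
})
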