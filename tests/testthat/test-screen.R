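# helper: declared order of a dataset in a group
declared_order <- function(gam, ds, group) {
  gam |>
    dplyr::filter(dataset == ds, linkage_group == group) |>
    dplyr::distinct(locus, locus_index) |>
    dplyr::arrange(locus_index) |>
    dplyr::pull(locus)
}

# reorder the declared locus_index of one dataset without touching calls
set_order <- function(gam, ds, group, new_order) {
  idx <- stats::setNames(seq_along(new_order), new_order)
  dplyr::mutate(gam, locus_index = dplyr::if_else(
    dataset == ds & linkage_group == group,
    as.integer(idx[locus]), locus_index))
}

test_that("linkage-group conflicts are reported once per locus, agreement is silent", {
  orders <- tibble::tibble(
    dataset = c("D1", "D2", "D1", "D2", "D1"),
    linkage_group = c("RT03", "RT07", "RT05", "RT05", "RT09"),
    locus = c("M1", "M1", "M2", "M2", "OnlyHere"),
    locus_index = 1L)
  rep <- check_group_consistency(orders)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$locus, "M1")
  expect_equal(rep$kind, "group_conflict")
  expect_equal(rep$evidence, 2L)
  # merged/ambiguous source groups are dropped wholesale
  rep2 <- check_group_consistency(
    orders, dropped_groups = tibble::tibble(dataset = "D1",
                                            linkage_group = "RT09"))
  drop_row <- dplyr::filter(rep2, resolution == "dropped_group")
  expect_equal(drop_row$locus, "OnlyHere")
})

test_that("order conflicts are found by orientation-free LCS with the documented tie rule", {
  mk <- function(ds, loci) tibble::tibble(
    dataset = ds, linkage_group = "RT01", locus = loci,
    locus_index = seq_along(loci))
  # ABCDE vs ABDCE: both C and D reported, minimal deviant set has size 1
  orders <- dplyr::bind_rows(mk("D1", c("A", "B", "C", "D", "E")),
                             mk("D2", c("A", "B", "D", "C", "E")))
  rep <- check_order_consistency(orders, "RT01")
  expect_setequal(rep$locus, c("C", "D"))
  expect_equal(sum(rep$chosen), 1)
  # reversal is the same order
  rev_orders <- dplyr::bind_rows(mk("D1", c("A", "B", "C", "D", "E")),
                                 mk("D2", c("E", "D", "C", "B", "A")))
  expect_equal(nrow(check_order_consistency(rev_orders, "RT01")), 0)
  # identical orders
  same <- dplyr::bind_rows(mk("D1", c("A", "B", "C")), mk("D2", c("A", "B", "C")))
  expect_equal(nrow(check_order_consistency(same, "RT01")), 0)
  # brute-force check of the LCS on the 5-locus instance: the maximal
  # common subsequences of ABCDE / ABDCE are exactly ABDE and ABCE
  keeps <- synmapr:::lcs_all_keeps(c("A", "B", "C", "D", "E"),
                                   c("A", "B", "D", "C", "E"))
  expect_setequal(purrr::map_chr(keeps, paste, collapse = ""),
                  c("ABDE", "ABCE"))
})

test_that("a single deviant dataset against several concordant ones loses the locus", {
  tm <- simulate_true_map(n_groups = 1, markers_per_group = 5, length_cM = 40,
                          seed = 21)
  truth <- dplyr::arrange(tm$map, position_cM)$locus
  gam <- dplyr::bind_rows(purrr::map(1:4, function(i) {
    simulate_dh_dataset(tm, paste0("D", i), N = 30, seed = 30 + i)
  }))
  # displace one locus to the end of D4's declared order
  bad <- c(setdiff(truth, truth[3]), truth[3])
  gam <- set_order(gam, "D4", "RT01", bad)
  rep <- check_order_consistency(locus_orders(gam), "RT01")
  expect_true(truth[3] %in% rep$locus)
  row <- dplyr::filter(rep, locus == truth[3])
  expect_equal(row$deviant_dataset, "D4")
  expect_equal(row$evidence, 3L)
  res <- resolve_discrepancies(rep, gam)
  expect_equal(res$log$resolution[res$log$locus == truth[3]],
               "removed_from_deviant")
  # removed from the deviant set only
  expect_false(truth[3] %in% declared_order(res$data, "D4", "RT01"))
  expect_true(truth[3] %in% declared_order(res$data, "D1", "RT01"))
  # cleaned data re-screens clean
  expect_equal(nrow(check_order_consistency(locus_orders(res$data), "RT01")), 0)
})

test_that("a two-dataset conflict explained by few genotypes is ignored and merged", {
  tm <- simulate_true_map(n_groups = 1, markers_per_group = 5, length_cM = 40,
                          seed = 22)
  truth <- dplyr::arrange(tm$map, position_cM)$locus
  g1 <- simulate_dh_dataset(tm, "D1", N = 30, seed = 41)
  # same genotypes in D2 except one injected flip on the third locus,
  # declared with the 3rd/4th loci swapped
  g2 <- dplyr::mutate(simulate_dh_dataset(tm, "D2", N = 30, seed = 41),
                      dataset = "D2")
  flip_at <- which(g2$locus == truth[3])[1]
  g2$call[flip_at] <- 1L - g2$call[flip_at]
  g2 <- set_order(g2, "D2", "RT01", truth[c(1, 2, 4, 3, 5)])
  gam <- dplyr::bind_rows(g1, g2)
  rep <- check_order_consistency(locus_orders(gam), "RT01")
  expect_gt(nrow(rep), 0)
  res <- resolve_discrepancies(rep, gam)
  expect_true("ignored_small" %in% res$log$resolution)
  expect_true(all(res$log$evidence[res$log$resolution == "ignored_small"] <= 2))
  # orders merged: clean on re-screen, no locus lost or duplicated
  expect_equal(nrow(check_order_consistency(locus_orders(res$data), "RT01")), 0)
  expect_setequal(unique(res$data$locus), truth)
})

test_that("a genuine local inversion between two datasets splits the locus", {
  tm <- simulate_true_map(n_groups = 1, markers_per_group = 5, length_cM = 80,
                          min_spacing_cM = 15, seed = 23)
  truth <- dplyr::arrange(tm$map, position_cM)$locus
  g1 <- simulate_dh_dataset(tm, "D1", N = 40, seed = 51)
  # D2 drawn from a different true order (3rd and 4th loci really inverted)
  tm2 <- tm
  tm2$map$locus <- replace(tm2$map$locus,
                           match(truth[3:4], tm2$map$locus), truth[4:3])
  g2 <- simulate_dh_dataset(tm2, "D2", N = 40, seed = 52)
  gam <- dplyr::bind_rows(g1, g2)
  rep <- check_order_consistency(locus_orders(gam), "RT01")
  expect_gt(nrow(rep), 0)
  res <- resolve_discrepancies(rep, gam)
  split_rows <- dplyr::filter(res$log, resolution == "suffix_split")
  expect_gt(nrow(split_rows), 0)
  expect_gt(min(split_rows$evidence), 2)
  # both dataset-suffixed twins exist in the cleaned data
  loc <- split_rows$locus[1]
  expect_setequal(
    grep(paste0("^", loc, "_"), unique(res$data$locus), value = TRUE),
    paste(loc, c("D1", "D2"), sep = "_"))
  expect_equal(nrow(check_order_consistency(locus_orders(res$data), "RT01")), 0)
})

test_that("pseudo-gamete datasets are never genotype-reconciled", {
  tm <- simulate_true_map(n_groups = 1, markers_per_group = 5, length_cM = 40,
                          seed = 24)
  truth <- dplyr::arrange(tm$map, position_cM)$locus
  g1 <- simulate_dh_dataset(tm, "D1", N = 30, seed = 61)
  g2 <- dplyr::mutate(simulate_dh_dataset(tm, "D2", N = 30, seed = 61),
                      dataset = "D2")
  g2 <- set_order(g2, "D2", "RT01", truth[c(1, 2, 4, 3, 5)])
  gam <- dplyr::bind_rows(g1, g2)
  rep <- check_order_consistency(locus_orders(gam), "RT01")
  meta <- tibble::tibble(dataset = c("D1", "D2"),
                         kind = c("raw_genotypes", "pseudo"))
  res <- resolve_discrepancies(rep, gam, meta = meta)
  expect_false("ignored_small" %in% res$log$resolution)
  expect_true("suffix_split" %in% res$log$resolution)
})

test_that("the resolution log balances the locus accounting identity", {
  tm <- simulate_true_map(n_groups = 1, markers_per_group = 6, length_cM = 50,
                          seed = 25)
  truth <- dplyr::arrange(tm$map, position_cM)$locus
  gam <- dplyr::bind_rows(purrr::map(1:3, function(i) {
    simulate_dh_dataset(tm, paste0("D", i), N = 30, seed = 70 + i)
  }))
  bad <- c(setdiff(truth, truth[2]), truth[2])
  gam <- set_order(gam, "D3", "RT01", bad)
  rep <- dplyr::bind_rows(
    check_group_consistency(locus_orders(gam)),
    check_order_consistency(locus_orders(gam), "RT01"))
  res <- resolve_discrepancies(rep, gam)
  n_in <- length(unique(gam$locus))
  n_removed_names <- sum(res$log$resolution %in%
                           c("removed_from_deviant", "dropped_group") &
                           !res$log$locus %in% res$data$locus)
  n_split <- sum(res$log$resolution == "suffix_split")
  split_added <- sum(purrr::map_int(
    res$log$locus[res$log$resolution == "suffix_split"], function(l) {
      length(grep(paste0("^", l, "_"), unique(res$data$locus))) - 1L
    }))
  n_out <- length(unique(res$data$locus))
  expect_equal(n_out, n_in - n_removed_names + split_added)
})
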