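blast_row <- function(q, s, pident = 95, len = 200, sstart = 1e6,
                      evalue = 1e-20) {
  sprintf("%s\t%s\t%.2f\t%d\t5\t1\t1\t%d\t%d\t%d\t%.2e\t360.5",
          q, s, pident, len, len, sstart, sstart + len - 1, evalue)
}

write_blast <- function(rows, path = withr::local_tempfile(fileext = ".tsv",
                                                           .local_envir = parent.frame())) {
  writeLines(c("# BLASTN 2.2.25", "# Fields: ...", rows), path)
  path
}

test_that("BLAST tabular parsing handles the commented dialect", {
  p <- write_blast(c(blast_row("q1", "Chr01"), blast_row("q2", "Chr02"),
                     blast_row("q3", "Chr03", evalue = 1e-20)))
  hits <- parse_blast_tabular(p, "blastn")
  expect_equal(nrow(hits), 3)
  expect_equal(hits$chrom, c("Chr01", "Chr02", "Chr03"))
  expect_equal(hits$evalue[3], 1e-20)
  expect_equal(hits$hsp_score, hits$pident * hits$align_length)
  # comments only -> zero hits
  empty <- write_blast(character(0))
  expect_equal(nrow(parse_blast_tabular(empty, "blastn")), 0)
  # malformed row errors with its line number
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# header", "q1\tChr01\tonly-three"), bad)
  expect_error(parse_blast_tabular(bad, "blastn"), "line 2",
               class = "synmapr_error")
})

test_that("protein hits collapse to genes with locations; blastn passes through", {
  p <- write_blast(c(blast_row("q1", "P1"), blast_row("q1", "P2"),
                     blast_row("q2", "P9")))
  hits <- parse_blast_tabular(p, "blastx")
  p2g <- tibble::tibble(protein_id = c("P1", "P2"), gene_id = "G1",
                        chrom = "Chr05", start = c(4e6, 4e6))
  expect_warning(coll <- collapse_to_gene(hits, p2g), "absent")
  expect_equal(coll$subject[1:2], c("G1", "G1"))
  expect_equal(coll$gene_id[1:2], c("G1", "G1"))
  expect_equal(coll$chrom[1:2], c("Chr05", "Chr05"))
  expect_equal(coll$subject[3], "P9")  # unmapped protein kept, warned
  # blastn rows are untouched
  pn <- write_blast(blast_row("q1", "Chr01"))
  hn <- parse_blast_tabular(pn, "blastn")
  expect_identical(collapse_to_gene(hn, p2g), hn)
})

test_that("filtration applies the min-evalue, max-HSP, uniqueness rules", {
  hits <- parse_blast_tabular(write_blast(c(
    blast_row("q1", "Chr01", evalue = 1e-20),
    blast_row("q1", "Chr02", evalue = 1e-10),
    blast_row("q2", "Chr01", evalue = 1e-20, pident = 95, len = 200),
    blast_row("q2", "Chr03", evalue = 1e-20, pident = 90, len = 150),
    blast_row("q3", "Chr02", evalue = 1e-20, pident = 95, len = 200),
    blast_row("q3", "Chr04", evalue = 1e-20, pident = 95, len = 200),
    blast_row("q4", "Chr01", evalue = 1e-3))), "blastn")
  f <- filter_hits(hits)
  expect_setequal(f$query, c("q1", "q2"))
  expect_equal(f$chrom[f$query == "q1"], "Chr01")      # rule 1
  expect_equal(f$chrom[f$query == "q2"], "Chr01")      # rule 2: 19000 > 13500
  expect_false("q3" %in% f$query)                       # rule 3: exact tie
  expect_false("q4" %in% f$query)                       # cutoff
  dropped <- dropped_queries(f)
  expect_setequal(dropped$query, c("q3", "q4"))
  expect_equal(dropped$reason[dropped$query == "q3"], "ambiguous")
  expect_equal(dropped$reason[dropped$query == "q4"], "below_cutoff")
  # idempotence: filtering a filtered set is the identity
  f2 <- filter_hits(f)
  expect_equal(tibble::as_tibble(f2), tibble::as_tibble(f),
               ignore_attr = TRUE)
  expect_equal(anyDuplicated(f$query), 0)
})

test_that("filtration equals the brute-force enumeration on random inputs", {
  for (seed in 1:10) {
    hits <- withr::with_seed(seed, {
      n <- 60
      tibble::tibble(
        query = sample(sprintf("q%02d", 1:15), n, replace = TRUE),
        program = "blastn",
        subject = sample(sprintf("Chr%02d", 1:6), n, replace = TRUE),
        chrom = NA_character_,
        pident = sample(c(80, 90, 95), n, replace = TRUE),
        align_length = sample(c(100L, 150L, 200L), n, replace = TRUE),
        sstart = 1e6, send = 1e6 + 100,
        evalue = sample(c(1e-30, 1e-20, 1e-10, 1e-4), n, replace = TRUE),
        gene_id = NA_character_) |>
        dplyr::mutate(chrom = subject,
                      hsp_score = pident * align_length)
    })
    got <- filter_hits(hits) |> dplyr::arrange(query)
    want <- brute_force_filter(hits) |> dplyr::arrange(query)
    expect_equal(tibble::as_tibble(got)[names(want)], want, ignore_attr = TRUE)
  }
})

planted_fixture <- function(seed = 1, orphan = 0, tie = 0) {
  tm <- simulate_true_map(n_groups = 2, markers_per_group = 14,
                          length_cM = 90, seed = seed)
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  res <- simulate_homology_table(tm, path, orphan_noise = orphan,
                                 tie_noise = tie, seed = seed + 100)
  map <- as_synthetic_map(dplyr::select(tm$map, linkage_group, locus,
                                        position_cM, arm))
  list(tm = tm, path = path, truth = attr(res, "truth"), map = map)
}

test_that("species grids count mapped filtered markers per arm and chromosome", {
  fx <- planted_fixture(seed = 3)
  hits <- filter_hits(parse_blast_tabular(fx$path, "blastn"))
  g <- species_oxford_grid(hits, fx$map, species = "medaka")
  expect_equal(sum(g$count),
               sum(fx$truth$query %in%
                     fx$map$locus[fx$map$arm %in% c("p", "q")]))
  # every planted (arm, chrom) synteny is a cell
  planted <- fx$tm$map |>
    dplyr::filter(arm %in% c("p", "q")) |>
    dplyr::distinct(arm_unit = synmapr:::arm_label(linkage_group, arm),
                    model_chrom)
  expect_setequal(paste(g$arm, g$model_chrom),
                  paste(planted$arm_unit, planted$model_chrom))
  # markers missing from the map are excluded and logged
  hits2 <- dplyr::bind_rows(hits, dplyr::mutate(hits[1, ], query = "ghost"))
  g2 <- species_oxford_grid(hits2, fx$map)
  expect_equal(attr(g2, "excluded")$query, "ghost")
  expect_equal(sum(g2$count), sum(g$count))
})

test_that("grid refinement reassigns lone metacentric markers then removes orphans", {
  cells <- tibble::tibble(
    arm = c("RT01p", "RT01q", "RT02p"),
    model_chrom = c("Chr01", "Chr01", "Chr07"),
    count = c(6L, 1L, 1L),
    markers = list(sprintf("m%d", 1:6), "m7", "m8"))
  g <- synmapr:::new_oxford_grid(cells, kind = "species")
  ref <- refine_grid(g)
  expect_equal(nrow(ref), 1)
  expect_equal(ref$arm, "RT01p")
  expect_equal(ref$count, 7L)             # 6 + the reassigned marker
  expect_true("m7" %in% ref$markers[[1]])
  expect_equal(attr(ref, "reassigned")$query, "m7")
  expect_equal(attr(ref, "orphans")$query, "m8")
  # grand total never increases
  expect_lte(sum(ref$count), sum(g$count))
  # a grid with all cells supported on distinct chromosomes is untouched
  solid <- synmapr:::new_oxford_grid(tibble::tibble(
    arm = c("RT01p", "RT01q"), model_chrom = c("Chr01", "Chr02"),
    count = c(3L, 2L), markers = list(c("a", "b", "c"), c("d", "e"))),
    kind = "species")
  expect_equal(tibble::as_tibble(refine_grid(solid))[1:3],
               tibble::as_tibble(solid)[1:3], ignore_attr = TRUE)
})

test_that("homeolog reduction keeps the expected homologous chromosome", {
  cells <- tibble::tibble(
    arm = c("RT06q", "RT06q", "RT06q", "RT09p", "RT09p"),
    model_chrom = c("groupVI", "groupV", "groupVIII", "Chr01", "Chr02"),
    count = c(5L, 2L, 4L, 3L, 3L),
    markers = list("a", "b", "c", "d", "e"))
  g <- synmapr:::new_oxford_grid(cells, kind = "species")
  hom <- tibble::tibble(chrom_a = c("groupV", "Chr01"),
                        chrom_b = c("groupVI", "Chr02"))
  red <- reduce_to_expected_homeolog(g, hom)
  # groupV (2) loses to its homeolog groupVI (5); groupVIII is unrelated
  expect_setequal(red$model_chrom[red$arm == "RT06q"],
                  c("groupVI", "groupVIII"))
  # exact tie keeps both, flagged
  tie <- dplyr::filter(red, arm == "RT09p")
  expect_equal(nrow(tie), 2)
  expect_true(all(tie$tie_flag))
  # never increases cells per arm
  expect_lte(nrow(red), nrow(g))
})

test_that("ancestor projection translates chromosomes and counts single-ancestor arms", {
  cells <- tibble::tibble(
    arm = c("RT01p", "RT01p", "RT02q", "RT03p", "RT03p", "RT03p", "RT03p"),
    model_chrom = c("Ola13", "Ola21", "Ola13", "Ola01", "Ola05", "Ola09", "Ola17"),
    count = 2L, markers = list("x"))
  anc <- tibble::tibble(
    model_chrom = c("Ola13", "Ola21", "Ola01", "Ola05", "Ola09", "Ola17"),
    proto = c("A", "A", "B", "C", "D", "E"))
  g <- synmapr:::new_oxford_grid(cells, kind = "species")
  proj <- project_ancestor(g, anc)
  # two chromosomes of proto A on RT01p -> one proto, two fragments
  expect_equal(proj$n_fragments[proj$arm == "RT01p"], 2L)
  expect_setequal(attr(proj, "single_ancestor_arms"), c("RT01p", "RT02q"))
  # a four-chromosome arm keeps its four ancestral labels
  expect_equal(sort(proj$proto[proj$arm == "RT03p"]), c("B", "C", "D", "E"))
  expect_error(project_ancestor(g, anc[-1, ]), "Ola13",
               class = "synmapr_error")
})

test_that("comparative-map export converts bp to cM and names markers by gene", {
  map <- as_synthetic_map(tibble::tibble(
    linkage_group = "RT01", locus = c("mA", "mB"),
    position_cM = c(0, 10), arm = c("p", "p")))
  hits <- tibble::tibble(query = c("mA", "mB"), program = c("blastx", "blastn"),
                         subject = c("G1", "Chr02"), chrom = "Chr02",
                         pident = 95, align_length = 200L,
                         sstart = c(1e6, 0), send = c(1e6 + 199, 199),
                         evalue = 1e-20, hsp_score = 19000,
                         gene_id = c("G1", NA))
  grid <- synmapr:::new_oxford_grid(tibble::tibble(
    arm = "RT01p", model_chrom = "Chr02", count = 2L,
    markers = list(c("mA", "mB"))), kind = "species")
  out <- withr::local_tempfile(fileext = ".txt")
  export_comparative_map(grid, hits, map, out)
  lines <- readLines(out)
  expect_true("group Chr02(RT01)" %in% lines)
  expect_true("0 0.000" %in% lines)    # bp 0 -> 0 cM, named by start position
  expect_true("G1 2.000" %in% lines)   # bp 1e6 / 0.5e6 -> 2 cM, gene name
})

test_that("program conflicts resolve by neighbourhood synteny, ties to blastx", {
  map <- as_synthetic_map(tibble::tibble(
    linkage_group = "RT01",
    locus = c("n1", "n2", "x1", "n3", "n4"),
    position_cM = c(0, 2, 3, 4, 6), arm = "p"))
  mk_hit <- function(q, chrom, program) tibble::tibble(
    query = q, program = program, subject = chrom, chrom = chrom,
    pident = 95, align_length = 200L, sstart = 1e6, send = 1e6 + 199,
    evalue = 1e-20, hsp_score = 19000,
    gene_id = if (program == "blastx") paste0("G_", q) else NA_character_)
  hits_n <- dplyr::bind_rows(purrr::map(c("n1", "n2", "n3", "n4"),
                                        mk_hit, chrom = "Chr01",
                                        program = "blastn"),
                             mk_hit("x1", "Chr01", "blastn"))
  hits_x <- mk_hit("x1", "Chr09", "blastx")
  comb <- combine_program_hits(hits_n, hits_x, map)
  row <- dplyr::filter(comb, query == "x1")
  expect_equal(row$chrom, "Chr01")           # neighbours vote Chr01
  expect_equal(row$chosen_by, "synteny_vote")
  # without informative neighbours the translated hit wins
  lonely <- as_synthetic_map(tibble::tibble(
    linkage_group = "RT09", locus = "x1", position_cM = 0, arm = "p"))
  comb2 <- combine_program_hits(mk_hit("x1", "Chr01", "blastn"),
                                mk_hit("x1", "Chr09", "blastx"), lonely)
  expect_equal(comb2$chrom, "Chr09")
  expect_equal(comb2$chosen_by, "blastx_tie")
})
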