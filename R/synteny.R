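# Cross-species synteny: BLAST tabular parsing, best-hit filtration, Oxford
# grids versus model-species chromosomes, pruning rules, ancestor projection
# and comparative-map export.

#' Parse BLAST tabular output (-m 9 / outfmt 7 dialect)
#'
#' Reads the 12-column tabular BLAST format, ignoring `#` comment lines.
#' The subject field is taken as the model-species chromosome for nucleotide
#' searches and as the protein/gene identifier for translated searches
#' (resolve those with [collapse_to_gene()]).
#'
#' @param path Path to the tabular file.
#' @param program `"blastn"` or `"blastx"`.
#' @return Tibble of raw hits: `query`, `program`, `subject`, `chrom`,
#'   `pident`, `align_length`, `sstart`, `send`, `evalue`,
#'   `hsp_score` (= pident x align_length), `gene_id` (`NA` until collapsed).
#' @export
parse_blast_tabular <- function(path, program = c("blastn", "blastx")) {
  program <- match.arg(program)
  if (!file.exists(path)) abort_bad_arg("file not found: %s", path)
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- lines[keep]
  if (length(rows) == 0) {
    return(tibble::tibble(
      query = character(), program = character(), subject = character(),
      chrom = character(), pident = numeric(), align_length = integer(),
      sstart = numeric(), send = numeric(), evalue = numeric(),
      hsp_score = numeric(), gene_id = character()))
  }
  parts <- strsplit(rows, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12)
  if (length(bad) > 0) {
    abort_bad_arg("malformed BLAST tabular row at line %d of %s (%d fields, expected 12)",
                  which(keep)[bad[1]], path, lengths(parts)[bad[1]])
  }
  m <- do.call(rbind, parts)
  num <- function(j) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (any(is.na(v))) {
      abort_bad_arg("non-numeric value \"%s\" in column %d at line %d of %s",
                    m[which(is.na(v))[1], j], j,
                    which(keep)[which(is.na(v))[1]], path)
    }
    v
  }
  prog <- program
  tibble::tibble(
    query = m[, 1], program = prog, subject = m[, 2],
    chrom = if (prog == "blastn") m[, 2] else NA_character_,
    pident = num(3), align_length = as.integer(num(4)),
    sstart = num(9), send = num(10), evalue = num(11),
    hsp_score = num(3) * num(4), gene_id = NA_character_)
}

#' Collapse translated-search hits from proteins to genes
#'
#' Ensembl-style protein identifiers are renamed to their gene identifier
#' (one gene encodes several peptides through alternative splicing), so that
#' the best-hit filtration operates at the gene level. When the lookup table
#' also carries `chrom`/`start` columns, the genomic location of the gene is
#' attached to the hit.
#'
#' @param hits Tibble from [parse_blast_tabular()] (`blastx` rows are
#'   collapsed; `blastn` rows pass through unchanged).
#' @param protein2gene Tibble with columns `protein_id`, `gene_id` and
#'   optionally `chrom`, `start`.
#' @return `hits` with `subject`/`gene_id` (and location, when available)
#'   rewritten; proteins absent from the table are retained unchanged with
#'   one summary warning.
#' @export
collapse_to_gene <- function(hits, protein2gene) {
  assert_cols(protein2gene, c("protein_id", "gene_id"))
  bx <- hits$program == "blastx"
  idx <- match(hits$subject, protein2gene$protein_id)
  found <- bx & !is.na(idx)
  n_missing <- sum(bx & is.na(idx))
  if (n_missing > 0) {
    warning(sprintf("%d blastx hit(s) to proteins absent from the lookup table kept unchanged",
                    n_missing), call. = FALSE)
  }
  out <- hits
  out$gene_id[found] <- protein2gene$gene_id[idx[found]]
  out$subject[found] <- protein2gene$gene_id[idx[found]]
  if ("chrom" %in% names(protein2gene)) {
    out$chrom[found] <- protein2gene$chrom[idx[found]]
  }
  if ("start" %in% names(protein2gene)) {
    out$sstart[found] <- protein2gene$start[idx[found]]
  }
  out
}

#' Best-hit filtration of BLAST results
#'
#' Applies the three-step filtration that keeps only markers with a single
#' unambiguous location: (1) per query, keep only hits at the minimal
#' e-value; (2) among those, keep the hits with the highest HSP score
#' (percent identity times alignment length); (3) keep the query only if
#' exactly one hit survives, otherwise drop it entirely. An e-value cutoff
#' is applied first. The output has unique queries and re-filtering it is
#' the identity.
#'
#' @param hits Tibble of hits (after [collapse_to_gene()] for blastx).
#' @param evalue_cutoff Significance cutoff (default `1e-5`).
#' @return Filtered hits, one row per surviving query. Attribute
#'   `dropped_queries`: tibble of queries dropped at step 3 (ambiguous) or
#'   by the cutoff.
#' @export
filter_hits <- function(hits, evalue_cutoff = 1e-5) {
  assert_cols(hits, c("query", "subject", "evalue", "hsp_score"))
  pre <- unique(hits$query)
  sig <- dplyr::filter(hits, .data$evalue <= evalue_cutoff)
  surv <- sig |>
    dplyr::group_by(.data$query) |>
    dplyr::filter(.data$evalue == min(.data$evalue)) |>
    dplyr::filter(.data$hsp_score == max(.data$hsp_score)) |>
    dplyr::ungroup()
  counts <- dplyr::count(surv, .data$query)
  unique_q <- counts$query[counts$n == 1]
  out <- dplyr::filter(surv, .data$query %in% unique_q)
  dropped <- tibble::tibble(
    query = setdiff(pre, out$query),
    reason = dplyr::if_else(setdiff(pre, out$query) %in% counts$query,
                            "ambiguous", "below_cutoff"))
  attr(out, "dropped_queries") <- dropped
  out
}

#' Queries dropped by the last filtration
#'
#' @param hits A [filter_hits()] result.
#' @return Tibble with columns `query`, `reason`.
#' @export
dropped_queries <- function(hits) {
  attr(hits, "dropped_queries") %||% tibble::tibble(query = character(),
                                                    reason = character())
}

#' Combine nucleotide and translated hits for the same markers
#'
#' When the two search programs place a marker on different model
#' chromosomes, preference goes to the location consistent with the local
#' synteny of the marker's map neighbourhood: the majority chromosome among
#' the nearest mapped markers with unambiguous locations decides; on a tie
#' (or with no informative neighbours) the translated hit wins, carrying
#' gene-level evidence.
#'
#' @param hits_n,hits_x Filtered blastn / blastx hits ([filter_hits()]).
#' @param map Synthetic map locating the query markers.
#' @param k_neighbors Number of nearest mapped neighbours consulted
#'   (default 5).
#' @return One hit per marker, with a `chosen_by` column
#'   (`"single_program"`, `"agreement"`, `"synteny_vote"`, `"blastx_tie"`).
#' @export
combine_program_hits <- function(hits_n, hits_x, map, k_neighbors = 5) {
  both <- intersect(hits_n$query, hits_x$query)
  only_n <- dplyr::filter(hits_n, !.data$query %in% both) |>
    dplyr::mutate(chosen_by = "single_program")
  only_x <- dplyr::filter(hits_x, !.data$query %in% both) |>
    dplyr::mutate(chosen_by = "single_program")
  resolved <- list()
  if (length(both) > 0) {
    map_tbl <- tibble::as_tibble(map)
    agreed_tbl <- dplyr::bind_rows(only_n, only_x)
    for (q in both) {
      hn <- dplyr::filter(hits_n, .data$query == q)
      hx <- dplyr::filter(hits_x, .data$query == q)
      if (identical(hn$chrom[1], hx$chrom[1])) {
        resolved[[q]] <- dplyr::mutate(hx, chosen_by = "agreement")
        next
      }
      here <- dplyr::filter(map_tbl, .data$locus == q)
      vote <- NA_character_
      if (nrow(here) == 1) {
        nb <- map_tbl |>
          dplyr::filter(.data$linkage_group == here$linkage_group[1],
                        .data$locus != q) |>
          dplyr::mutate(dist = abs(.data$position_cM - here$position_cM[1])) |>
          dplyr::left_join(dplyr::select(agreed_tbl, "query", "chrom"),
                           by = c(locus = "query")) |>
          dplyr::filter(!is.na(.data$chrom)) |>
          dplyr::arrange(.data$dist) |>
          utils::head(k_neighbors)
        if (nrow(nb) > 0) {
          tab <- sort(table(nb$chrom), decreasing = TRUE)
          if (length(tab) == 1 || tab[1] > tab[2]) vote <- names(tab)[1]
        }
      }
      if (!is.na(vote) && vote == hn$chrom[1]) {
        resolved[[q]] <- dplyr::mutate(hn, chosen_by = "synteny_vote")
      } else if (!is.na(vote) && vote == hx$chrom[1]) {
        resolved[[q]] <- dplyr::mutate(hx, chosen_by = "synteny_vote")
      } else {
        resolved[[q]] <- dplyr::mutate(hx, chosen_by = "blastx_tie")
      }
    }
  }
  dplyr::bind_rows(only_n, only_x, dplyr::bind_rows(resolved))
}

#' Oxford grid of trout arms versus model-species chromosomes
#'
#' Places each filtered marker on its chromosome arm of the synthetic map
#' and counts markers per (arm, model chromosome) cell. Markers absent from
#' the map, or mapped but centromeric/arm-less, are excluded and logged.
#'
#' @param hits Filtered hits with one row per marker.
#' @param map A `synthetic_map` with arm labels.
#' @param species Optional species label stored on the grid.
#' @return An `oxford_grid` with columns `arm`, `model_chrom`, `count`,
#'   `markers` (list). Attribute `excluded`: tibble of markers left out with
#'   a reason.
#' @export
species_oxford_grid <- function(hits, map, species = NULL) {
  assert_cols(hits, c("query", "chrom"))
  m <- tibble::as_tibble(map)
  joined <- hits |>
    dplyr::left_join(dplyr::select(m, "locus", "linkage_group", "arm"),
                     by = c(query = "locus"))
  excluded <- joined |>
    dplyr::filter(is.na(.data$linkage_group) | !.data$arm %in% c("p", "q")) |>
    dplyr::transmute(query = .data$query,
                     reason = dplyr::if_else(is.na(.data$linkage_group),
                                             "not_on_map", "no_arm"))
  ok <- joined |>
    dplyr::filter(!is.na(.data$linkage_group), .data$arm %in% c("p", "q")) |>
    dplyr::mutate(arm_unit = arm_label(.data$linkage_group, .data$arm))
  cells <- ok |>
    dplyr::group_by(arm = .data$arm_unit, model_chrom = .data$chrom) |>
    dplyr::summarise(count = dplyr::n(), markers = list(sort(.data$query)),
                     .groups = "drop")
  g <- new_oxford_grid(cells, kind = "species", species = species)
  attr(g, "excluded") <- excluded
  g
}

#' Prune a species Oxford grid: metacentric re-assignment and orphan removal
#'
#' Two cleaning steps, both logged: (1) when both arms of a metacentric
#' chromosome hit the same model chromosome and one arm's support is a
#' single marker (the other having at least two), that marker is taken to be
#' mis-assigned around the centromere and its count moves to the other arm;
#' (2) cells supported by a single marker are orphan homologies, treated as
#' noise and removed.
#'
#' @param grid A [species_oxford_grid()] result.
#' @param min_support Cells below this count are orphans (default 2).
#' @return The pruned grid; attributes `reassigned` and `orphans` log the
#'   markers moved and removed.
#' @export
refine_grid <- function(grid, min_support = 2) {
  cells <- tibble::as_tibble(grid) |>
    dplyr::mutate(linkage_group = sub("[pq]$", "", .data$arm),
                  side = sub("^.*(p|q)$", "\\1", .data$arm))
  reassigned <- list()
  # step 1: metacentric re-assignment
  split_keys <- cells |>
    dplyr::count(.data$linkage_group, .data$model_chrom) |>
    dplyr::filter(.data$n == 2)
  for (r in seq_len(nrow(split_keys))) {
    sel <- which(cells$linkage_group == split_keys$linkage_group[r] &
                   cells$model_chrom == split_keys$model_chrom[r])
    cnt <- cells$count[sel]
    if (min(cnt) == 1 && max(cnt) >= 2) {
      lo <- sel[which.min(cnt)]
      hi <- sel[which.max(cnt)]
      mover <- cells$markers[[lo]]
      reassigned[[length(reassigned) + 1]] <- tibble::tibble(
        query = mover, from_arm = cells$arm[lo], to_arm = cells$arm[hi],
        model_chrom = cells$model_chrom[lo])
      cells$count[hi] <- cells$count[hi] + 1L
      cells$markers[[hi]] <- sort(c(cells$markers[[hi]], mover))
      cells$count[lo] <- 0L
    }
  }
  cells <- dplyr::filter(cells, .data$count > 0)
  # step 2: orphan removal
  orphan_rows <- dplyr::filter(cells, .data$count < min_support)
  orphans <- tibble::tibble(
    query = unlist(orphan_rows$markers) %||% character(0),
    arm = rep(orphan_rows$arm, lengths(orphan_rows$markers)),
    model_chrom = rep(orphan_rows$model_chrom, lengths(orphan_rows$markers)))
  cells <- cells |>
    dplyr::filter(.data$count >= min_support) |>
    dplyr::select("arm", "model_chrom", "count", "markers")
  g <- new_oxford_grid(cells, kind = "species", species = attr(grid, "species"))
  attr(g, "reassigned") <- dplyr::bind_rows(reassigned)
  attr(g, "orphans") <- orphans
  g
}

#' Keep only the expected homolog of a model-species homeolog pair
#'
#' Model-species chromosome pairs descending from the teleost (3rd)
#' whole-genome duplication often both show homology with one trout arm;
#' only the member with the stronger marker support (the "expected
#' homologous chromosome") is informative for alignment drawings. The weaker
#' cell of each such pair is removed per arm; exact ties keep both cells,
#' flagged.
#'
#' @param grid A refined species grid ([refine_grid()]).
#' @param homeologs Tibble with columns `chrom_a`, `chrom_b`, one row per
#'   within-species homeolog pair.
#' @return The parsimonious grid with a `tie_flag` column; attribute
#'   `removed_homeolog_cells` logs the discarded cells.
#' @export
reduce_to_expected_homeolog <- function(grid, homeologs) {
  assert_cols(homeologs, c("chrom_a", "chrom_b"))
  cells <- tibble::as_tibble(grid) |>
    dplyr::mutate(tie_flag = FALSE)
  removed <- list()
  for (arm in unique(cells$arm)) {
    for (r in seq_len(nrow(homeologs))) {
      ia <- which(cells$arm == arm &
                    cells$model_chrom == homeologs$chrom_a[r] & cells$count > 0)
      ib <- which(cells$arm == arm &
                    cells$model_chrom == homeologs$chrom_b[r] & cells$count > 0)
      if (length(ia) == 0 || length(ib) == 0) next
      if (cells$count[ia] == cells$count[ib]) {
        cells$tie_flag[c(ia, ib)] <- TRUE
      } else {
        loser <- if (cells$count[ia] < cells$count[ib]) ia else ib
        removed[[length(removed) + 1]] <- cells[loser, c("arm", "model_chrom", "count")]
        cells$count[loser] <- 0L
      }
    }
  }
  cells <- dplyr::filter(cells, .data$count > 0) |>
    dplyr::select("arm", "model_chrom", "count", "markers", "tie_flag")
  g <- new_oxford_grid(cells, kind = "species", species = attr(grid, "species"))
  attr(g, "removed_homeolog_cells") <- dplyr::bind_rows(removed)
  g
}

#' Project trout arms onto teleost-ancestor proto-chromosomes
#'
#' Translates each arm's retained model-species chromosomes (normally the
#' parsimonious medaka grid: medaka has kept the ancestral chromosome
#' boundaries) into proto-chromosome labels, giving the ancestral
#' composition of every arm.
#'
#' @param grid A parsimonious species grid.
#' @param ancestor Tibble with columns `model_chrom`, `proto` (one model
#'   chromosome may map to several proto-chromosome labels).
#' @return Tibble with columns `arm`, `proto`, `n_fragments` (model
#'   chromosomes of that proto hitting the arm). Attribute
#'   `single_ancestor_arms`: character vector of arms traced back to exactly
#'   one proto-chromosome.
#' @export
project_ancestor <- function(grid, ancestor) {
  assert_cols(ancestor, c("model_chrom", "proto"))
  cells <- tibble::as_tibble(grid)
  missing <- setdiff(cells$model_chrom, ancestor$model_chrom)
  if (length(missing) > 0) {
    abort_bad_arg("model chromosome(s) absent from the ancestor map: %s",
                  paste(missing, collapse = ", "))
  }
  proj <- cells |>
    dplyr::select("arm", "model_chrom") |>
    dplyr::left_join(ancestor, by = "model_chrom",
                     relationship = "many-to-many") |>
    dplyr::group_by(.data$arm, .data$proto) |>
    dplyr::summarise(n_fragments = dplyr::n(), .groups = "drop")
  singles <- proj |>
    dplyr::count(.data$arm) |>
    dplyr::filter(.data$n == 1) |>
    dplyr::pull("arm")
  attr(proj, "single_ancestor_arms") <- singles
  proj
}

#' Export comparative-map alignments in MapChart text format
#'
#' For each trout linkage group, writes the trout group itself followed by
#' one pseudo-group per retained model chromosome, where each homologous
#' marker is displayed at `subject start bp / 0.5e6` cM and named by its
#' gene identifier when a protein was identified, otherwise by its start
#' position.
#'
#' @param grid Parsimonious species grid ([reduce_to_expected_homeolog()]).
#' @param hits Filtered hits carrying `sstart` (bp) and `gene_id`.
#' @param map A `synthetic_map`.
#' @param path Output path.
#' @param bp_per_cM Conversion rate (default `0.5e6`).
#' @return `path`, invisibly.
#' @export
export_comparative_map <- function(grid, hits, map, path, bp_per_cM = 0.5e6) {
  m <- tibble::as_tibble(map)
  cells <- tibble::as_tibble(grid)
  lines <- character(0)
  for (g in unique(m$linkage_group)) {
    gm <- dplyr::filter(m, .data$linkage_group == g)
    lines <- c(lines, sprintf("group %s", g),
               sprintf("%s %.3f", gm$locus, gm$position_cM), "")
    arms <- unique(arm_label(g, gm$arm[gm$arm %in% c("p", "q")]))
    chroms <- cells |>
      dplyr::filter(.data$arm %in% arms) |>
      dplyr::pull("model_chrom") |>
      unique()
    for (chr in chroms) {
      keep <- unlist(cells$markers[cells$arm %in% arms &
                                     cells$model_chrom == chr])
      hh <- dplyr::filter(hits, .data$query %in% keep) |>
        dplyr::mutate(
          display = dplyr::if_else(is.na(.data$gene_id),
                                   format(.data$sstart, scientific = FALSE,
                                          trim = TRUE),
                                   .data$gene_id),
          pos = .data$sstart / bp_per_cM) |>
        dplyr::arrange(.data$pos)
      lines <- c(lines, sprintf("group %s(%s)", chr, g),
                 sprintf("%s %.3f", hh$display, hh$pos), "")
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Count syntenic fragments of a grid
#'
#' One fragment is one retained (arm, model chromosome) cell: the number of
#' blocks needed to align the two genomes at the stage the grid represents.
#'
#' @param grid An `oxford_grid`.
#' @return Integer fragment count.
#' @export
count_syntenic_fragments <- function(grid) {
  nrow(tibble::as_tibble(grid))
}
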