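# End-to-end orchestration from a declarative configuration.

#' Read and validate a pipeline configuration
#'
#' The configuration is a single declarative YAML file (or an equivalent
#' list). Required: `datasets`, a list of entries with `id`, `path`, `kind`
#' (`raw_genotypes` or `distance_map`), `family_size`, and for distance maps
#' `distance_kind` and optionally `weight_size` (reweighting family size for
#' pseudo-gamete reconstruction). Optional: `synonyms` (TSV alias/canonical),
#' `centromeres` (TSV linkage_group/start_locus/end_locus), `dropped_groups`
#' (list of dataset/linkage_group), `ordering` (`method`, `seed`, engine
#' params), `homeology` (`min_support`, `prior` TSV), `synteny` (list of
#' species entries with `name`, `blastn` and/or `blastx` paths, optional
#' `protein2gene`, `homeologs`, `ancestor` TSVs, `evalue_cutoff`), `outdir`.
#' Every referenced path must exist; validation happens before any compute.
#'
#' @param config Path to a YAML file or a list with the same structure.
#' @return The validated config list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort_bad_arg("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$datasets) || length(config$datasets) == 0) {
    abort_bad_arg("config needs at least one dataset")
  }
  need_file <- function(p, what) {
    if (!is.null(p) && !file.exists(p)) {
      abort_bad_arg("%s file not found: %s", what, p)
    }
  }
  for (d in config$datasets) {
    if (is.null(d$id) || is.null(d$path) || is.null(d$kind) ||
        is.null(d$family_size)) {
      abort_bad_arg("each dataset needs id, path, kind, family_size")
    }
    if (!d$kind %in% c("raw_genotypes", "distance_map")) {
      abort_bad_arg("dataset %s: unknown kind %s", d$id, d$kind)
    }
    need_file(d$path, sprintf("dataset %s", d$id))
  }
  need_file(config$synonyms, "synonyms")
  need_file(config$centromeres, "centromeres")
  need_file(config$homeology$prior, "homeology prior")
  for (sp in config$synteny$species %||% list()) {
    if (is.null(sp$name)) abort_bad_arg("each synteny species needs a name")
    if (is.null(sp$blastn) && is.null(sp$blastx)) {
      abort_bad_arg("species %s: need blastn and/or blastx results", sp$name)
    }
    need_file(sp$blastn, sprintf("%s blastn", sp$name))
    need_file(sp$blastx, sprintf("%s blastx", sp$name))
    need_file(sp$protein2gene, sprintf("%s protein2gene", sp$name))
    need_file(sp$homeologs, sprintf("%s homeologs", sp$name))
    need_file(sp$ancestor, sprintf("%s ancestor", sp$name))
  }
  config
}

#' Run the full synthetic-map pipeline
#'
#' Sequences ingestion, name standardization, pseudo-gamete reconstruction,
#' consistency screening, map construction, duplicated-locus homeology
#' analysis and (when configured) per-species synteny analysis, writing all
#' artifacts and audit logs to the output directory. The run is
#' deterministic given the configuration, including its seed.
#'
#' @param config Path to a YAML config or a config list
#'   (see [read_pipeline_config()]).
#' @param outdir Output directory (overrides `config$outdir`).
#' @return Invisibly, a list with the in-memory results: `map`
#'   (`synthetic_map`), `arm_grid`, `screen_log`, and per-species synteny
#'   results; the same content is on disk in `outdir`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  config <- read_pipeline_config(config)
  outdir <- outdir %||% config$outdir %||%
    abort_bad_arg("no output directory given")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  opath <- function(...) file.path(outdir, ...)
  stage <- "ingest"
  result <- rlang::try_fetch({
    synonyms <- if (!is.null(config$synonyms)) {
      readr::read_tsv(config$synonyms, col_types = "cc", progress = FALSE,
                      show_col_types = FALSE)
    }
    meta <- purrr::map_dfr(config$datasets, function(d) {
      tibble::tibble(dataset = d$id,
                     kind = ifelse(d$kind == "distance_map", "pseudo",
                                   "raw_genotypes"),
                     family_size = as.integer(d$family_size))
    })
    stage <- "reconstruct"
    rename_logs <- list()
    gam <- purrr::map_dfr(config$datasets, function(d) {
      g <- if (d$kind == "raw_genotypes") {
        read_gamete_matrix(d$path, d$id, missing = d$missing %||% "-")
      } else {
        dm <- read_distance_map(d$path, d$id,
                                distance_kind = d$distance_kind %||% "kosambi_cM")
        prof <- as_recomb_profile(dm, family_size = d$family_size)
        if (!is.null(d$weight_size) && d$weight_size != d$family_size) {
          prof <- rescale_profile(prof, d$weight_size)
        }
        gametes_from_profile(prof)
      }
      if (!is.null(synonyms)) {
        g <- standardize_locus_names(g, synonyms)
        rename_logs[[d$id]] <<- dplyr::mutate(rename_log(g), dataset = d$id)
      }
      g
    })
    readr::write_tsv(dplyr::bind_rows(rename_logs) %||% tibble::tibble(),
                     opath("rename_log.tsv"), progress = FALSE)

    stage <- "screen"
    orders <- locus_orders(gam)
    dropped_groups <- if (!is.null(config$dropped_groups)) {
      purrr::map_dfr(config$dropped_groups,
                     ~ tibble::tibble(dataset = .x$dataset,
                                      linkage_group = .x$linkage_group))
    }
    reports <- check_group_consistency(orders, dropped_groups)
    for (g in sort(unique(orders$linkage_group))) {
      reports <- dplyr::bind_rows(reports, check_order_consistency(orders, g))
    }
    res <- resolve_discrepancies(reports, gam, meta = meta)
    gam <- res$data
    write_audit_log(res$log, opath("screen_audit.tsv"))

    stage <- "build"
    centromeres <- if (!is.null(config$centromeres)) {
      readr::read_tsv(config$centromeres, col_types = "ccc", progress = FALSE,
                      show_col_types = FALSE)
    }
    ord_cfg <- config$ordering %||% list()
    map <- build_synthetic_map(
      gam, centromeres = centromeres,
      method = ord_cfg$method %||% "annealing",
      params = ord_cfg$params %||% list(),
      seed = ord_cfg$seed %||% config$seed %||% 0,
      meta = meta)
    write_synthetic_map(map, opath("synthetic_map.tsv"))
    write_mapchart(map, opath("synthetic_map.mapchart.txt"))
    readr::write_tsv(glance(map), opath("map_summary.tsv"), progress = FALSE)

    stage <- "homeology"
    arm_grid <- arm_oxford_grid(map)
    prior <- if (!is.null(config$homeology$prior)) {
      readr::read_tsv(config$homeology$prior, col_types = "ccc",
                      progress = FALSE, show_col_types = FALSE)
    }
    arm_grid <- classify_homeologies(
      arm_grid, prior = prior,
      min_support = config$homeology$min_support %||% 2)
    write_oxford_grid(arm_grid, opath("arm_oxford_grid.tsv"))

    stage <- "synteny"
    synteny <- list()
    for (sp in config$synteny$species %||% list()) {
      cutoff <- sp$evalue_cutoff %||% 1e-5
      hits_n <- hits_x <- NULL
      if (!is.null(sp$blastn)) {
        hits_n <- filter_hits(parse_blast_tabular(sp$blastn, "blastn"),
                              evalue_cutoff = cutoff)
      }
      if (!is.null(sp$blastx)) {
        hx <- parse_blast_tabular(sp$blastx, "blastx")
        if (!is.null(sp$protein2gene)) {
          p2g <- readr::read_tsv(sp$protein2gene, progress = FALSE,
                                 show_col_types = FALSE)
          hx <- collapse_to_gene(hx, p2g)
        }
        hits_x <- filter_hits(hx, evalue_cutoff = cutoff)
      }
      hits <- if (!is.null(hits_n) && !is.null(hits_x)) {
        combine_program_hits(hits_n, hits_x, map)
      } else {
        hits_n %||% hits_x
      }
      for (h in list(hits_n, hits_x)) {
        if (!is.null(h)) {
          readr::write_tsv(dropped_queries(h),
                           opath(sprintf("%s_dropped_queries_%s.tsv",
                                         sp$name, h$program[1] %||% "none")),
                           progress = FALSE)
        }
      }
      grid_raw <- species_oxford_grid(hits, map, species = sp$name)
      grid_ref <- refine_grid(grid_raw)
      write_oxford_grid(grid_raw, opath(sprintf("%s_grid_raw.tsv", sp$name)))
      write_oxford_grid(grid_ref, opath(sprintf("%s_grid_refined.tsv", sp$name)))
      grid_final <- grid_ref
      if (!is.null(sp$homeologs)) {
        hom <- readr::read_tsv(sp$homeologs, col_types = "cc",
                               progress = FALSE, show_col_types = FALSE)
        grid_final <- reduce_to_expected_homeolog(grid_ref, hom)
        write_oxford_grid(grid_final,
                          opath(sprintf("%s_grid_parsimonious.tsv", sp$name)))
      }
      projection <- NULL
      if (!is.null(sp$ancestor)) {
        anc <- readr::read_tsv(sp$ancestor, col_types = "cc",
                               progress = FALSE, show_col_types = FALSE)
        projection <- project_ancestor(grid_final, anc)
        readr::write_tsv(projection,
                         opath(sprintf("%s_ancestor_projection.tsv", sp$name)),
                         progress = FALSE)
      }
      export_comparative_map(grid_final, hits, map,
                             opath(sprintf("%s_comparative_map.txt", sp$name)))
      synteny[[sp$name]] <- list(hits = hits, grid_raw = grid_raw,
                                 grid_refined = grid_ref,
                                 grid_final = grid_final,
                                 projection = projection,
                                 n_fragments = count_syntenic_fragments(grid_final))
    }
    list(map = map, arm_grid = arm_grid, screen_log = res$log,
         synteny = synteny, outdir = outdir)
  }, error = function(cnd) {
    rlang::abort(sprintf("pipeline stage \"%s\" failed: %s",
                         stage, rlang::cnd_message(cnd)), parent = cnd)
  })
  invisible(result)
}
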