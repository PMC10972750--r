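# Delimited-text interchange formats (the dialect of spot/surface exports
# from imaging software), YAML run configuration, and the end-to-end
# pipeline with its run manifest.

cell_table_columns <- c("id", "cell_type", "x_um", "y_um", "z_um",
                        "radius_um", "confetti")

#' Read a cell table
#'
#' Reads and validates the delimited cell-table dialect: header
#' `id,cell_type,x_um,y_um,z_um,radius_um,confetti`, coordinates in um.
#' `radius_um` may be empty (filled from the catalogue) and `confetti`
#' may be absent (treated as unlabelled). Unknown cell types, duplicate
#' ids and non-numeric coordinates are schema errors naming the
#' offending rows.
#'
#' @param path file path.
#' @param catalog cell-type catalogue used for validation and radii.
#' @return a validated cell tibble.
#' @export
load_cell_table <- function(path, catalog = cell_type_catalog()) {
  if (!file.exists(path)) {
    rlang::abort(paste0("no such file: ", path), class = "marrowmap_schema_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  req <- c("id", "cell_type", "x_um", "y_um", "z_um")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    rlang::abort(paste0("cell table lacks required column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "marrowmap_schema_error")
  }
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) {
    rlang::abort(paste0("duplicate cell id(s): ", paste(unique(dup), collapse = ", ")),
                 class = "marrowmap_schema_error")
  }
  for (cc in c("x_um", "y_um", "z_um", if ("radius_um" %in% names(df)) "radius_um")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !(df[[cc]] %in% c(NA, "", "NA")))
    if (length(bad)) {
      rlang::abort(paste0("non-numeric ", cc, " in row(s): ",
                          paste(utils::head(bad, 5), collapse = ", ")),
                   class = "marrowmap_schema_error")
    }
    df[[cc]] <- v
  }
  unknown <- which(!df$cell_type %in% catalog$cell_type)
  if (length(unknown)) {
    rlang::abort(paste0("unknown cell type(s) ",
                        paste(unique(df$cell_type[unknown]), collapse = ", "),
                        " in row(s): ", paste(utils::head(unknown, 5), collapse = ", ")),
                 class = "marrowmap_schema_error")
  }
  if (!"confetti" %in% names(df)) df$confetti <- "none"
  df$confetti[is.na(df$confetti)] <- "none"
  bad_col <- setdiff(unique(df$confetti), c("none", confetti_colours))
  if (length(bad_col)) {
    rlang::abort(paste0("unknown confetti colour(s): ", paste(bad_col, collapse = ", ")),
                 class = "marrowmap_schema_error")
  }
  df <- fill_radii(df, catalog)
  tibble::as_tibble(df[, cell_table_columns])
}

#' Write a cell table
#' @param cells cell tibble.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  readr::write_csv(cells[, cell_table_columns], path, progress = FALSE)
  invisible(path)
}

#' Read a vessel table
#'
#' Long-form dialect: `segment_id,vclass,radius_um,point_index,x_um,y_um,z_um`.
#' @param path file path.
#' @return a [vessel_network()].
#' @export
load_vessel_table <- function(path) {
  df <- readr::read_csv(path, col_types = "ccdiddd", progress = FALSE)
  vessel_network(df)
}

#' Write a vessel table
#' @param network a [vessel_network()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_vessel_table <- function(network, path) {
  readr::write_csv(tibble::as_tibble(network), path, progress = FALSE)
  invisible(path)
}

#' Load a generator configuration from YAML
#'
#' Reads a YAML file of [marrow_config()] overrides; a top-level `preset`
#' key selects a base preset first.
#'
#' @param path YAML file.
#' @return a `marrow_config`.
#' @export
load_marrow_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- if (!is.null(y$preset)) marrow_preset(y$preset) else marrow_config()
  y$preset <- NULL
  if (length(y)) {
    cfg <- unclass(base)
    for (nm in names(y)) {
      if (is.list(cfg[[nm]]) && is.list(y[[nm]])) {
        cfg[[nm]][names(y[[nm]])] <- y[[nm]]
      } else cfg[[nm]] <- y[[nm]]
    }
    validate_marrow_config(cfg)
    base <- structure(cfg, class = "marrow_config")
  }
  base
}

file_digest <- function(paths) {
  unname(tools::md5sum(paths))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes simulate -> distances/null/enrichment -> sites -> clonality ->
#' census/report on a configuration, writing stage artifacts (delimited
#' tables, truth JSON sidecar) and a run manifest referencing every
#' artifact with an md5 digest. Any stage error aborts with the stage
#' name; the partial manifest is still written.
#'
#' @param config a [marrow_config()], preset name, or YAML path.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the whole run.
#' @param stages subset of stages to run; later stages read earlier
#'   stages' artifacts from `out_dir`.
#' @param alpha significance level for enrichment calls.
#' @param n_reps null replicates.
#' @return the run manifest (list), invisibly; artifacts under `out_dir`.
#' @export
run_pipeline <- function(config = marrow_config(), out_dir, seed = 1,
                         stages = c("simulate", "analyze", "sites",
                                    "clonality", "report"),
                         alpha = 0.05, n_reps = 150) {
  if (is.character(config) && file.exists(config)) config <- load_marrow_config(config)
  if (is.character(config)) config <- marrow_preset(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("marrowmap")),
                   seed = seed, alpha = alpha, n_reps = n_reps,
                   config = unclass(config), stages = list())
  paths <- list(cells = file.path(out_dir, "cells.csv"),
                vessels = file.path(out_dir, "vessels.csv"),
                truth = file.path(out_dir, "truth.json"),
                enrichment = file.path(out_dir, "enrichment.csv"),
                sites = file.path(out_dir, "sites.csv"),
                census = file.path(out_dir, "census.csv"),
                clonality = file.path(out_dir, "clonality.csv"),
                manifest = file.path(out_dir, "manifest.json"))
  finish_stage <- function(name, files, info = list()) {
    manifest$stages[[name]] <<- c(list(outputs = stats::setNames(file_digest(files),
                                                                 basename(files))), info)
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE)
      rlang::abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
                   parent = e, class = "marrowmap_stage_error")
    })
  }
  vol <- tissue_volume(config$volume$extent)

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      scene <- simulate_marrow(config, seed = seed)
      write_cell_table(scene$cells, paths$cells)
      write_vessel_table(scene$vessels, paths$vessels)
      jsonlite::write_json(scene$truth, paths$truth, auto_unbox = TRUE,
                           digits = NA, pretty = FALSE)
      finish_stage("simulate", c(paths$cells, paths$vessels, paths$truth),
                   list(n_cells = nrow(scene$cells)))
    })
  }
  cells <- load_cell_table(paths$cells)
  vessels <- load_vessel_table(paths$vessels)

  if ("analyze" %in% stages) {
    run_stage("analyze", function() {
      pool <- build_pool(cells)
      mp <- intersect(multipotent_types(), unique(cells$cell_type))
      counts <- table(cells$cell_type[cells$cell_type %in% mp])
      rows <- list()
      if (length(counts)) {
        reps <- sample_random_cells(pool, stats::setNames(as.integer(counts), names(counts)),
                                    n_reps = n_reps, seed = seed + 1L)
        hspc <- cells[cells$cell_type %in% mp, , drop = FALSE]
        for (target in c("sinusoid", "arteriole", "MK")) {
          obs <- tryCatch({
            if (target == "MK") nearest_by_type(cells, mp, "MK")
            else distance_to_vessel(hspc, vessels, target)
          }, marrowmap_empty_target = function(e) NULL)
          if (is.null(obs)) next
          nul <- null_distances(reps, target, cells = cells, vessels = vessels,
                                volume = vol)
          enr <- compare_to_null(obs, nul, alpha = alpha)
          rows[[target]] <- dplyr::mutate(tidy(enr), target = target)
        }
      }
      enrichment <- dplyr::bind_rows(rows)
      readr::write_csv(enrichment, paths$enrichment, progress = FALSE)
      finish_stage("analyze", paths$enrichment,
                   list(n_hspc = sum(as.integer(counts))))
    })
  }

  if ("sites" %in% stages) {
    run_stage("sites", function() {
      params <- site_params()
      strings <- detect_cfu_e_strings(cells, vessels, params)
      ery <- assemble_erythroid_sites(strings, cells, params)
      bsites <- detect_b_sites(cells, vessels, params)
      neu <- detect_myeloid_sites(cells, vessels, params, "neutrophil")
      mdc <- detect_myeloid_sites(cells, vessels, params, "monoDC")
      census <- site_census(list(erythroid = ery, B = bsites,
                                 neutrophil = neu, monoDC = mdc), vol)
      all_members <- dplyr::bind_rows(
        dplyr::mutate(ery$members, lineage = "erythroid"),
        dplyr::mutate(bsites$members[, c("site_id", "cell_id", "cell_type", "gap_um")],
                      lineage = "B"),
        if (nrow(neu$members)) dplyr::mutate(neu$members[, c("site_id", "cell_id", "cell_type", "gap_um")],
                                             lineage = "neutrophil"),
        if (nrow(mdc$members)) dplyr::mutate(mdc$members[, c("site_id", "cell_id", "cell_type", "gap_um")],
                                             lineage = "monoDC"))
      readr::write_csv(all_members, paths$sites, progress = FALSE)
      readr::write_csv(census, paths$census, progress = FALSE)
      finish_stage("sites", c(paths$sites, paths$census),
                   list(n_sites = stats::setNames(as.list(census$n_sites), census$lineage)))
    })
  }

  if ("clonality" %in% stages) {
    run_stage("clonality", function() {
      members <- readr::read_csv(paths$sites, col_types = readr::cols(), progress = FALSE)
      rows <- members |>
        dplyr::group_by(.data$lineage, .data$site_id) |>
        dplyr::group_map(function(g, key) {
          cl <- classify_site_clonality(g$cell_id, cells)
          dplyr::mutate(tidy(cl), lineage = key$lineage, site_id = key$site_id)
        }) |>
        dplyr::bind_rows()
      readr::write_csv(rows, paths$clonality, progress = FALSE)
      finish_stage("clonality", paths$clonality,
                   list(n_classified = nrow(rows)))
    })
  }

  if ("report" %in% stages) {
    run_stage("report", function() {
      # the manifest is the report artifact; it cannot carry its own digest
      manifest$stages$report <<- list(outputs = basename(paths$manifest))
      jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, force = TRUE)
    })
  }
  invisible(manifest)
}
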