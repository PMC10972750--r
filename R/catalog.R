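#' Cell-type catalogue
#'
#' Reference table of the haematopoietic stem/progenitor and maturing cell
#' types handled by the package: per-type mean diameter (with s.d.) measured
#' in 3D on whole-mount sternal images, lineage assignment, and a stage-order
#' index within each lineage. Radius corrections throughout the package use
#' the catalogue mean radius (`diameter_um / 2`) whenever a record does not
#' carry its own measured radius.
#'
#' The 22 imaging-measured types have `source == "measured"`. Two auxiliary
#' entries are package defaults (`source == "default"`): `MK`
#' (megakaryocytes, segmented as surfaces rather than spots, assigned a
#' 30 um working diameter) and `BM` (a generic haematopoietic background
#' cell used by the synthetic generator for the unclassified pool).
#'
#' @return A tibble with columns `cell_type`, `diameter_um`,
#'   `diameter_sd_um`, `lineage`, `stage_index`, `source`.
#' @export
#' @examples
#' cell_type_catalog()
cell_type_catalog <- function() {
  measured <- tibble::tribble(
    ~cell_type,           ~diameter_um, ~diameter_sd_um, ~lineage,      ~stage_index,
    "CD41- LT-HSC",        8.67,         1.23,           "multipotent",  1,
    "CD41+ LT-HSC",        8.94,         0.91,           "multipotent",  1,
    "ST-HSC",              8.68,         1.10,           "multipotent",  2,
    "MPP2",                7.98,         1.05,           "multipotent",  3,
    "MPP3",                8.48,         1.32,           "multipotent",  3,
    "MkP",                14.45,         3.88,           "megakaryocytic", 4,
    "pre Meg-E",           9.49,         1.34,           "erythroid",    4,
    "pre CFU-E",          13.92,         1.70,           "erythroid",    5,
    "CFU-E",              12.67,         1.88,           "erythroid",    6,
    "early erythroblast",  8.86,         1.61,           "erythroid",    7,
    "late erythroblast",   7.92,         1.36,           "erythroid",    8,
    "reticulocyte",        5.17,         0.76,           "erythroid",    9,
    "RBC",                 4.38,         0.60,           "erythroid",   10,
    "CLP",                 7.40,         0.97,           "B",            4,
    "pre-pro B",           8.90,         0.61,           "B",            5,
    "pro B",               7.71,         1.23,           "B",            6,
    "pre B",               6.10,         0.61,           "B",            7,
    "MDP",                12.13,         1.19,           "monoDC",       4,
    "GP",                 11.70,         0.99,           "neutrophil",   4,
    "PN",                 10.21,         1.08,           "neutrophil",   5,
    "monocyte",            9.30,         1.17,           "monoDC",       5,
    "cDC",                12.33,         2.69,           "monoDC",       5
  )
  measured$source <- "measured"
  extras <- tibble::tribble(
    ~cell_type, ~diameter_um, ~diameter_sd_um, ~lineage,          ~stage_index, ~source,
    "MK",        30.0,         5.0,            "megakaryocytic",   10,          "default",
    "BM",         8.0,         2.0,            "haematopoietic",    0,          "default"
  )
  dplyr::bind_rows(measured, extras)
}

#' Look up the catalogue mean radius for cell types
#'
#' @param cell_type character vector of catalogue cell-type names.
#' @param catalog catalogue table, defaults to [cell_type_catalog()].
#' @return numeric vector of radii in um (mean diameter / 2).
#' @export
catalog_radius <- function(cell_type, catalog = cell_type_catalog()) {
  idx <- match(cell_type, catalog$cell_type)
  if (anyNA(idx)) {
    bad <- unique(cell_type[is.na(idx)])
    rlang::abort(
      paste0("Unknown cell type(s): ", paste(bad, collapse = ", ")),
      class = "marrowmap_unknown_type"
    )
  }
  catalog$diameter_um[idx] / 2
}

#' Multipotent HSPC type names
#'
#' The stem and multipotent-progenitor types treated as "multipotent HSPC"
#' in dispersion analyses (stage indices 1-3 of the multipotent lineage).
#'
#' @return character vector of type names.
#' @export
multipotent_types <- function() {
  cat <- cell_type_catalog()
  cat$cell_type[cat$lineage == "multipotent"]
}

#' Fill missing radii from the catalogue
#'
#' Records lacking a measured radius receive the catalogue mean radius for
#' their type.
#'
#' @param cells cell table with at least `cell_type`; `radius_um` optional.
#' @param catalog catalogue table.
#' @return the cell table with a complete `radius_um` column.
#' @export
fill_radii <- function(cells, catalog = cell_type_catalog()) {
  if (!"radius_um" %in% names(cells)) cells$radius_um <- NA_real_
  missing <- is.na(cells$radius_um)
  if (any(missing)) {
    cells$radius_um[missing] <- catalog_radius(cells$cell_type[missing], catalog)
  }
  cells
}
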