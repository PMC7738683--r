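#' Canonical cortical network names
#'
#' The seven large-scale networks of the 100-parcel cortical parcellation, in
#' the fixed order used throughout the package (network index 1..7).
#'
#' @return Character vector of length 7.
#' @export
canonical_networks <- function() {
  c("Visual", "SomMot", "DorsalAttn", "Salience", "Limbic", "Control", "Default")
}

#' Load a cortical parcellation lookup table
#'
#' Reads a parcel-level atlas: one row per region with its name, hemisphere
#' and network assignment. The bundled default is a synthetic stand-in for the
#' 100-parcel / 7-network cortical parcellation: it has the correct structure
#' (100 parcels, the seven canonical networks, left/right hemispheres,
#' realistic per-network parcel counts) but its parcel names are generated,
#' not the atlas release labels.
#'
#' Region indices are 0-based in the file (atlas file order); the returned
#' tibble keeps the 0-based `index` column and row order equals file order.
#'
#' @param path Path to a delimited table with columns `index`, `name`,
#'   `hemisphere`, `network`, or `"bundled"` for the packaged default.
#' @param allow_any_size Allow atlases with other than 100 regions (for
#'   reduced test atlases). Default `FALSE`.
#' @return A tibble of class `lb_atlas` with columns `index`, `name`,
#'   `hemisphere`, `network` and an integer `network_index` (1-based position
#'   in [canonical_networks()]).
#' @export
load_atlas <- function(path = "bundled", allow_any_size = FALSE) {
  if (identical(path, "bundled")) {
    path <- system.file("extdata", "schaefer100x7_synthetic.tsv",
                        package = "lonelybrain", mustWork = TRUE)
  }
  at <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("index", "name", "hemisphere", "network")
  if (!all(need %in% names(at))) {
    abort(paste0("atlas file must have columns ",
                 paste(need, collapse = ", ")))
  }
  bad <- setdiff(unique(at$network), canonical_networks())
  if (length(bad)) {
    abort(paste0("unknown network name(s) in atlas: ",
                 paste(bad, collapse = ", ")))
  }
  if (!all(at$hemisphere %in% c("left", "right"))) {
    abort("hemisphere must be 'left' or 'right'")
  }
  if (nrow(at) != 100 && !allow_any_size) {
    abort(paste0("expected 100 regions, found ", nrow(at),
                 " (use allow_any_size = TRUE for reduced atlases)"))
  }
  if (anyDuplicated(at$index) || !setequal(at$index, seq_len(nrow(at)) - 1)) {
    abort("region index must be 0-based, unique and contiguous")
  }
  at <- at[order(at$index), ]
  at$network_index <- match(at$network, canonical_networks())
  out <- as_tibble(at)
  class(out) <- c("lb_atlas", class(out))
  out
}

#' Networks actually present in an atlas, in canonical order
#' @param atlas An atlas tibble from [load_atlas()].
#' @return Character vector.
#' @export
atlas_networks <- function(atlas) {
  canonical_networks()[sort(unique(atlas$network_index))]
}

#' Load the white-matter tract catalog
#'
#' One tract name per row. The bundled default lists the 48 tracts of the
#' ICBM-DTI-81 white-matter label atlas, including the fornix (column and
#' body) and the bilateral fornix (cres) / stria terminalis.
#'
#' @param path Path to a file with a `tract` column (or a headerless list of
#'   names), or `"bundled"`.
#' @return A tibble with column `tract` (48 rows for the bundled catalog).
#' @export
load_tract_catalog <- function(path = "bundled") {
  if (identical(path, "bundled")) {
    path <- system.file("extdata", "jhu48_tracts.tsv",
                        package = "lonelybrain", mustWork = TRUE)
  }
  tc <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"tract" %in% names(tc)) {
    if (ncol(tc) == 1) names(tc) <- "tract" else abort("expected a 'tract' column")
  }
  if (nrow(tc) == 0) abort("tract catalog is empty")
  if (anyDuplicated(tc$tract)) {
    abort(paste0("duplicate tract names: ",
                 paste(unique(tc$tract[duplicated(tc$tract)]), collapse = ", ")))
  }
  as_tibble(tc)
}

# indices (1-based) of the fornix-carrying tracts in a catalog
fornix_indices <- function(catalog) {
  grep("fornix", catalog$tract, ignore.case = TRUE)
}
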