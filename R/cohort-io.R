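#' Write a cohort to delimited text files
#'
#' Writes up to four TSV tables into `dir`: `phenotypes.tsv` (participant id,
#' loneliness, sex, age and confounds), `volumes.tsv` (100 region columns),
#' `fc_edges.tsv` (4950 edge columns, row-major lower triangle, header
#' `edge_i_j` with 1-based region indices) and `fa.tsv` (48 tract columns).
#' Values are written in full double precision, so a write-read round trip
#' reproduces the numbers exactly. If the cohort carries ground truth, a
#' `truth.json` sidecar is written too.
#'
#' @param cohort An `lb_cohort` from [generate_cohort()], or a compatible
#'   list.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ph <- cohort$cohort
  readr::write_tsv(ph, file.path(dir, "phenotypes.tsv"), progress = FALSE)
  wr <- function(m, fname) {
    df <- as.data.frame(m)
    df <- cbind(participant_id = ph$participant_id, df)
    readr::write_tsv(df, file.path(dir, fname), progress = FALSE)
  }
  if (!is.null(cohort$volumes)) wr(cohort$volumes, "volumes.tsv")
  if (!is.null(cohort$fc_edges)) {
    m <- cohort$fc_edges
    ei <- edge_index((1 + sqrt(1 + 8 * ncol(m))) / 2)
    colnames(m) <- paste0("edge_", ei$i, "_", ei$j)
    wr(m, "fc_edges.tsv")
  }
  if (!is.null(cohort$fa)) wr(cohort$fa, "fa.tsv")
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    tr$config <- unclass(tr$config)
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' Read a cohort from delimited text files
#'
#' Loads the phenotype table and whichever feature tables are given, aligns
#' all of them on the shared participant identifier, drops participants with
#' missing phenotype values (listwise, with a message reporting the count),
#' and checks dimensions against the atlas and tract catalog.
#'
#' @param phenotypes_path Path to the phenotype TSV (must contain
#'   `participant_id` and `loneliness`).
#' @param volumes_path,fc_path,fa_path Optional paths to the feature tables.
#' @param fc_format `"edges"` (default; one column per lower-triangle edge) or
#'   `"matrix"` (R^2 columns holding full row-major coupling matrices, which
#'   are then vectorized).
#' @param atlas,catalog References for dimension checks.
#' @return A list of class `lb_cohort` with `cohort`, `volumes`, `fc_edges`,
#'   `fa` (NULL where not given) and `truth = NULL`.
#' @export
read_cohort <- function(phenotypes_path, volumes_path = NULL, fc_path = NULL,
                        fa_path = NULL, fc_format = c("edges", "matrix"),
                        atlas = load_atlas(), catalog = load_tract_catalog()) {
  fc_format <- match.arg(fc_format)
  ph <- readr::read_tsv(phenotypes_path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("participant_id", "loneliness") %in% names(ph))) {
    abort("phenotype file must contain participant_id and loneliness columns")
  }
  n0 <- nrow(ph)
  ph <- ph[stats::complete.cases(ph), ]
  if (nrow(ph) < n0) {
    message("read_cohort: dropped ", n0 - nrow(ph),
            " participant(s) with missing phenotype values (",
            nrow(ph), " retained)")
  }

  read_block <- function(path, expected_cols, what) {
    if (is.null(path)) return(NULL)
    tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (!"participant_id" %in% names(tb)) {
      abort(paste0(what, " file lacks a participant_id column"))
    }
    missing_ids <- setdiff(ph$participant_id, tb$participant_id)
    if (length(missing_ids)) {
      abort(paste0(what, " file is missing participant(s): ",
                   paste(head(missing_ids, 5), collapse = ", "),
                   if (length(missing_ids) > 5) ", ..." else ""))
    }
    tb <- tb[match(ph$participant_id, tb$participant_id), ]
    m <- as.matrix(tb[, setdiff(names(tb), "participant_id")])
    if (!is.null(expected_cols) && ncol(m) != expected_cols) {
      abort(paste0(what, " has ", ncol(m), " feature columns; expected ",
                   expected_cols))
    }
    m
  }

  R <- nrow(atlas)
  E <- R * (R - 1) / 2
  volumes <- read_block(volumes_path, R, "volumes")
  fc <- read_block(fc_path, if (fc_format == "edges") E else R * R, "fc")
  if (!is.null(fc) && fc_format == "matrix") {
    fc <- t(apply(fc, 1, function(row) {
      vectorize_connectome(matrix(row, R, R, byrow = TRUE))
    }))
  }
  fa <- read_block(fa_path, nrow(catalog), "fa")

  structure(list(cohort = as_tibble(ph), volumes = volumes, fc_edges = fc,
                 fa = fa, truth = NULL),
            class = "lb_cohort")
}
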