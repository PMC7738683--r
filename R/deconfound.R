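#' Build a nuisance design matrix
#'
#' Assembles the confound design used for residualization: an intercept,
#' z-scored continuous confounds (optionally polynomial age terms), and
#' one-hot site/categorical columns with the first level (alphabetically)
#' dropped as reference.
#'
#' @param cohort Data frame with one row per participant.
#' @param confound_names Character vector of column names in `cohort`. May be
#'   empty (intercept-only design).
#' @param age_degree If `"age"` is among the confounds, include polynomial
#'   age terms up to this degree (each z-scored). Default 1.
#' @return A list of class `lb_confounds` with `design` (n x q matrix) and
#'   `names`.
#' @export
build_confound_matrix <- function(cohort, confound_names = character(),
                                  age_degree = 1) {
  missing_cols <- setdiff(confound_names, names(cohort))
  if (length(missing_cols)) {
    abort(paste0("confound column(s) not found: ",
                 paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(cohort)
  cols <- list(intercept = rep(1, n))
  for (cf in confound_names) {
    x <- cohort[[cf]]
    if (is.numeric(x)) {
      deg <- if (identical(cf, "age")) age_degree else 1
      for (d in seq_len(deg)) {
        nm <- if (d == 1) cf else paste0(cf, "^", d)
        cols[[nm]] <- as.numeric(scale(x^d))
      }
    } else {
      x <- factor(x)
      lev <- sort(levels(x))
      for (l in lev[-1]) cols[[paste0(cf, ":", l)]] <- as.numeric(x == l)
    }
  }
  design <- do.call(cbind, cols)
  colnames(design) <- names(cols)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dep <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    abort(paste0("confound design is rank-deficient; collinear column(s): ",
                 paste(dep, collapse = ", ")))
  }
  structure(list(design = design, names = colnames(design)),
            class = "lb_confounds")
}

#' Remove nuisance variation from a feature matrix
#'
#' Replaces each feature column by its least-squares residual after projecting
#' onto the confound design. Residuals are exactly orthogonal to every
#' confound column; applying the operation twice changes nothing.
#'
#' @param features Numeric matrix (participants x features).
#' @param confounds An `lb_confounds` from [build_confound_matrix()], or a
#'   plain design matrix.
#' @return Matrix of residuals, same dimensions and column names.
#' @export
residualize <- function(features, confounds) {
  features <- as.matrix(features)
  design <- if (inherits(confounds, "lb_confounds")) confounds$design else as.matrix(confounds)
  if (nrow(features) != nrow(design)) {
    abort("features and confounds have different numbers of rows")
  }
  if (nrow(design) <= ncol(design)) {
    abort("need more participants than confound columns")
  }
  res <- qr.resid(qr(design), features)
  dimnames(res) <- dimnames(features)
  res
}

#' Z-score feature columns
#'
#' Centers each column to mean zero and scales to unit sample standard
#' deviation (n - 1 denominator).
#'
#' @param features Numeric matrix.
#' @return Matrix with column means 0 and sample sd 1.
#' @export
standardize <- function(features) {
  features <- as.matrix(features)
  sds <- apply(features, 2, sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- colnames(features)[sds == 0 | !is.finite(sds)]
    if (is.null(bad)) bad <- which(sds == 0 | !is.finite(sds))
    abort(paste0("constant (zero-variance) column(s): ",
                 paste(bad, collapse = ", ")))
  }
  scale(features, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Deconfound a feature block
#'
#' The standard cleaning applied identically to volumes, connectome edges and
#' tract FA before modeling: residualize on the confound design, then z-score
#' the residuals (the re-standardization can be switched off).
#'
#' @param features Numeric matrix (participants x features).
#' @param cohort Data frame holding the confound columns.
#' @param confound_names Character vector of confound columns.
#' @param standardize_after Z-score residuals afterwards. Default `TRUE`.
#' @param age_degree Passed to [build_confound_matrix()].
#' @return Cleaned feature matrix.
#' @export
deconfound <- function(features, cohort, confound_names = character(),
                       standardize_after = TRUE, age_degree = 1) {
  cm <- build_confound_matrix(cohort, confound_names, age_degree = age_degree)
  out <- residualize(features, cm)
  if (standardize_after) out <- standardize(out)
  out
}

#' Default nuisance variable set
#'
#' The confound list applied in every analysis arm: body mass index, head
#' size, task and resting-state head motion, head position (x, y, z), scanner
#' table position, and acquisition site.
#'
#' @return Character vector of column names as produced by [generate_cohort()].
#' @export
default_confounds <- function() {
  c("bmi", "head_size", "motion_task", "motion_rest",
    "head_pos_x", "head_pos_y", "head_pos_z", "table_pos", "site")
}
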