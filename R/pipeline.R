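#' Configure an end-to-end pipeline run
#'
#' Exactly one of `input_dir` (a directory of cohort tables as written by
#' [write_cohort()]) or `simulate` (a [generator_config()]) must be given.
#'
#' @param simulate Optional [generator_config()] describing a cohort to
#'   simulate.
#' @param input_dir Optional directory with `phenotypes.tsv` plus feature
#'   tables.
#' @param confounds Confound column names (default [default_confounds()]).
#' @param model Volume-model form, `"network"` or `"region"`.
#' @param stratify_sex Also run the sex-stratified analyses.
#' @param chains,tune,draws Volume-model sampler settings.
#' @param permutations Permutation count for the connectivity mode.
#' @param bootstrap Bootstrap count for the tract intervals.
#' @param output_dir Where to write results.
#' @param seed Master seed; per-stage seeds are derived from it by stable
#'   hashing of stage names.
#' @return List of class `lb_pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, input_dir = NULL,
                            confounds = default_confounds(),
                            model = c("network", "region"),
                            stratify_sex = FALSE,
                            chains = 4, tune = 1000, draws = 1000,
                            permutations = 1000, bootstrap = 100,
                            output_dir = tempfile("lonelybrain_run_"),
                            seed = 1L) {
  if (is.null(simulate) == is.null(input_dir)) {
    abort("give exactly one of simulate= or input_dir=")
  }
  structure(list(simulate = simulate, input_dir = input_dir,
                 confounds = confounds, model = match.arg(model),
                 stratify_sex = stratify_sex,
                 chains = chains, tune = tune, draws = draws,
                 permutations = permutations, bootstrap = bootstrap,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "lb_pipeline_config")
}

# deterministic hash of the numeric outputs for the manifest
numeric_fingerprint <- function(x) {
  v <- unlist(x, use.names = FALSE)
  v <- v[is.finite(v)]
  s <- sprintf("%.12g", v)
  h <- 0
  for (ch in utf8ToInt(paste(s, collapse = ","))) h <- (h * 31 + ch) %% 2147483647
  h
}

#' Run the full multimodal analysis pipeline
#'
#' simulate (or load) -> deconfound -> hierarchical volume model + PLS
#' connectivity mode + tract associations, writing a results bundle:
#' `volume_summary.tsv`, `network_ranking.tsv`, `flagged_regions.tsv`,
#' `pls_mode.tsv`, `pls_blocks.tsv`, `pls_permutation.json`,
#' `tract_associations.tsv`, `truth.json` (simulated runs), `manifest.json`
#' and a human-readable `report.md`. With `stratify_sex = TRUE`, PLS and
#' tract arms are additionally run per sex (subdirectories `men/`, `women/`)
#' and the volume model estimates sex-specific parameters jointly.
#'
#' A stage failure aborts with a stage-labeled error; outputs already written
#' are renamed with a `.partial` suffix.
#'
#' @param config An [pipeline_config()].
#' @return Invisibly, a list with the fitted objects and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "lb_pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(obj, fname, writer) {
    path <- file.path(config$output_dir, fname)
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    writer(obj, path)
    written <<- c(written, path)
    path
  }
  on_fail <- function(stage, e) {
    for (f in written) file.rename(f, paste0(f, ".partial"))
    abort(paste0("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)))
  }
  stage <- function(name, code) {
    tryCatch(force(code), error = function(e) on_fail(name, e))
  }

  atlas <- load_atlas()
  catalog <- load_tract_catalog()

  co <- stage("input", {
    if (!is.null(config$simulate)) {
      generate_cohort(config$simulate, seed = derive_seed(config$seed, "simulate"))
    } else {
      read_cohort(
        phenotypes_path = file.path(config$input_dir, "phenotypes.tsv"),
        volumes_path = file.path(config$input_dir, "volumes.tsv"),
        fc_path = file.path(config$input_dir, "fc_edges.tsv"),
        fa_path = file.path(config$input_dir, "fa.tsv"),
        atlas = atlas, catalog = catalog)
    }
  })
  if (!is.null(co$truth)) {
    emit(co$truth, "truth.json", function(o, p) {
      o$config <- unclass(o$config)
      jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA)
    })
  }

  clean <- stage("deconfound", {
    lapply(co[c("volumes", "fc_edges", "fa")], function(m) {
      if (is.null(m)) NULL
      else deconfound(m, co$cohort, config$confounds)
    })
  })

  results <- list(cohort = co)

  # --- volume arm ----------------------------------------------------------
  if (!is.null(clean$volumes)) {
    fit <- stage("fit-volumes", {
      fit_volume_model(clean$volumes, co$cohort, atlas,
                       model = config$model,
                       stratify_sex = config$stratify_sex,
                       chains = config$chains, tune = config$tune,
                       draws = config$draws,
                       seed = derive_seed(config$seed, "fit-volumes"))
    })
    results$volume_fit <- fit
    td <- tidy(fit)
    emit(td, "volume_summary.tsv", function(o, p) readr::write_tsv(o, p, progress = FALSE))
    if (config$model == "network") {
      rks <- lapply(fit$groups, function(g) {
        dplyr::mutate(network_ranking(fit, group = if (fit$stratify_sex) g),
                      group = g, .before = 1)
      })
      results$network_ranking <- dplyr::bind_rows(rks)
      emit(results$network_ranking, "network_ranking.tsv",
           function(o, p) readr::write_tsv(o, p, progress = FALSE))
    }
    emit(threshold_regions(fit), "flagged_regions.tsv",
         function(o, p) readr::write_tsv(o, p, progress = FALSE))
  }

  # --- connectivity and tract arms (pooled + optional per-sex) -------------
  subsets <- list(pooled = rep(TRUE, nrow(co$cohort)))
  if (config$stratify_sex) {
    subsets$men <- co$cohort$sex == 1
    subsets$women <- co$cohort$sex == 0
  }
  for (sub in names(subsets)) {
    keep <- subsets[[sub]]
    pref <- if (sub == "pooled") "" else paste0(sub, "/")
    y <- co$cohort$loneliness[keep]
    if (!is.null(clean$fc_edges)) {
      perm <- stage(paste0("fit-fc[", sub, "]"), {
        permutation_test(clean$fc_edges[keep, , drop = FALSE], y,
                         B = config$permutations,
                         seed = derive_seed(config$seed, paste0("fit-fc/", sub)))
      })
      results[[paste0("pls_", sub)]] <- perm
      blocks <- network_block_summary(perm$mode, atlas)
      emit(tibble(edge = seq_along(perm$mode$x_weights),
                  weight = perm$mode$x_weights),
           paste0(pref, "pls_mode.tsv"),
           function(o, p) readr::write_tsv(o, p, progress = FALSE))
      emit(as.data.frame(blocks), paste0(pref, "pls_blocks.tsv"),
           function(o, p) readr::write_tsv(cbind(network = rownames(blocks), o),
                                           p, progress = FALSE))
      emit(perm, paste0(pref, "pls_permutation.json"), function(o, p) {
        jsonlite::write_json(list(observed = o$observed, p_value = o$p_value,
                                  B = o$B, null_stats = o$null_stats),
                             p, auto_unbox = TRUE, digits = NA)
      })
    }
    if (!is.null(clean$fa)) {
      ta <- stage(paste0("fit-tracts[", sub, "]"), {
        tract_associations(clean$fa[keep, , drop = FALSE], y, catalog,
                           bootstrap = config$bootstrap,
                           seed = derive_seed(config$seed, paste0("fit-tracts/", sub)))
      })
      results[[paste0("tracts_", sub)]] <- ta
      emit(ta, paste0(pref, "tract_associations.tsv"),
           function(o, p) readr::write_tsv(o, p, progress = FALSE))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("lonelybrain")),
    seed = config$seed,
    model = config$model,
    stratify_sex = config$stratify_sex,
    settings = config[c("chains", "tune", "draws", "permutations", "bootstrap",
                        "confounds")],
    fingerprint = numeric_fingerprint(list(
      if (!is.null(results$volume_fit)) tidy(results$volume_fit)$mean,
      if (!is.null(results$pls_pooled)) results$pls_pooled$null_stats,
      if (!is.null(results$tracts_pooled)) results$tracts_pooled$pearson_rho))
  )
  emit(manifest, "manifest.json",
       function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA))

  emit(results, "report.md", function(o, p) {
    lines <- c("# lonelybrain pipeline report", "",
               paste0("n = ", nrow(co$cohort), "; prevalence = ",
                      sprintf("%.3f", mean(co$cohort$loneliness))), "")
    if (!is.null(o$network_ranking)) {
      lines <- c(lines, "## Network ranking (posterior sigma)", "",
                 utils::capture.output(as.data.frame(o$network_ranking)), "")
    }
    if (!is.null(o$pls_pooled)) {
      lines <- c(lines, "## Connectivity mode", "",
                 paste0("mode_corr = ", sprintf("%.4f", o$pls_pooled$observed),
                        "; permutation p = ",
                        sprintf("%.4g", o$pls_pooled$p_value),
                        " (B = ", o$pls_pooled$B, ")"), "")
    }
    if (!is.null(o$tracts_pooled)) {
      top <- dplyr::arrange(as_tibble(o$tracts_pooled), .data$rank)[1:5, ]
      lines <- c(lines, "## Top tract associations", "",
                 utils::capture.output(as.data.frame(
                   top[, c("tract", "pearson_rho", "ci_low", "ci_high",
                           "p_bonferroni", "rank")])))
    }
    writeLines(lines, p)
  })

  results$output_dir <- config$output_dir
  results$manifest <- manifest
  invisible(results)
}
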