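# Shared fixtures, generated in code.

# Write a reduced atlas file (n_per_net regions per chosen network) and load it.
tiny_atlas <- function(networks = c("Visual", "Default"), n_per_net = 5) {
  rows <- do.call(rbind, lapply(networks, function(nw) {
    data.frame(name = sprintf("LH_%s_%d", nw, seq_len(n_per_net)),
               hemisphere = "left", network = nw)
  }))
  rows <- cbind(index = seq_len(nrow(rows)) - 1L, rows)
  f <- tempfile(fileext = ".tsv")
  write.table(rows, f, sep = "\t", quote = FALSE, row.names = FALSE)
  load_atlas(f, allow_any_size = TRUE)
}

# Small cohort with the default planted effects unless overridden.
quick_cohort <- function(n = 500, seed = 42, ...) {
  generate_cohort(generator_config(n = n, seed = seed, ...))
}

# Minimal phenotype frame for model fits that bypass the generator.
fake_cohort_frame <- function(n, y = NULL, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    loneliness = if (is.null(y)) rbinom(n, 1, 0.2) else y,
    sex = rbinom(n, 1, 0.5),
    age_z = as.numeric(scale(runif(n, 40, 69)))
  )
}
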