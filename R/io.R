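# Tabular I/O with provenance comment blocks.

write_table_with_provenance <- function(df, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(provenance))
    writeLines(sprintf("# %s: %s", nm, provenance[[nm]]), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a lifespan table
#'
#' CSV schema: `replicate`, `generation`, `x`, `death_time`, `oldest_old`,
#' preceded by `#`-prefixed provenance comments (config hash, seed,
#' package version).  Infinite death times are serialized as `Inf`.
#'
#' @param result an [run_evolution()] result.
#' @param path output file.
#' @param provenance optional named list of extra provenance fields.
#' @return the path, invisibly.
#' @export
write_lifespan_table <- function(result, path, provenance = list()) {
  prov <- c(list(table = "lifespans",
                 package = paste("evohet",
                                 as.character(utils::packageVersion("evohet"))),
                 hash = config_hash(list(result$config, result$hazard)),
                 seed = result$config$seed), provenance)
  write_table_with_provenance(result$final, path, prov)
}

#' @rdname write_lifespan_table
#' @param check validate the schema and report the first malformed row?
#' @export
read_lifespan_table <- function(path, check = TRUE) {
  if (!file.exists(path))
    config_error(sprintf("lifespan table not found: %s", path))
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("replicate", "generation", "x", "death_time", "oldest_old")
  missing <- setdiff(need, names(df))
  if (length(missing))
    config_error(sprintf("lifespan table %s lacks column(s): %s", path,
                         paste(missing, collapse = ", ")))
  if (check) {
    bad <- which(!is.finite(df$x) | df$x < 0 | df$x > 1 |
                   is.na(df$death_time) | df$death_time <= 0)
    if (length(bad))
      config_error(sprintf(
        "malformed lifespan table %s: first bad row at data line %d", path,
        bad[1]))
  }
  df$oldest_old <- as.logical(df$oldest_old)
  df
}

#' Write a trait-distribution table
#'
#' CSV schema: `generation`, `bin_left`, `bin_right`, `frequency`.
#'
#' @param hist matrix of histogram masses (generations x bins) or a
#'   [trait_distribution()].
#' @param path output file.
#' @param provenance named list of provenance fields.
#' @return the path, invisibly.
#' @export
write_distribution_table <- function(hist, path, provenance = list()) {
  if (inherits(hist, "trait_distribution")) {
    n <- length(hist$grid)
    df <- data.frame(generation = NA_integer_,
                     bin_left = (seq_len(n) - 1) / n,
                     bin_right = seq_len(n) / n, frequency = hist$mass)
  } else {
    nb <- ncol(hist)
    df <- do.call(rbind, lapply(seq_len(nrow(hist)), function(g)
      data.frame(generation = g - 1L, bin_left = (seq_len(nb) - 1) / nb,
                 bin_right = seq_len(nb) / nb, frequency = hist[g, ])))
  }
  write_table_with_provenance(df, path,
                              c(list(table = "trait_distribution"),
                                provenance))
}

#' Write a mortality table
#'
#' CSV schema: `t`, `hazard`, `log_hazard` (plus `deaths`, `exposure` for
#' estimated curves).
#'
#' @param curve a `mortality_curve`.
#' @param path output file.
#' @param provenance named list of provenance fields.
#' @return the path, invisibly.
#' @export
write_mortality_table <- function(curve, path, provenance = list()) {
  df <- as.data.frame(curve)
  names(df)[names(df) == "time"] <- "t"
  write_table_with_provenance(df, path,
                              c(list(table = "mortality"), provenance))
}
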