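# Flat key = value serialization of a simulation config, e.g.
#
#   monomers[1].name = Morph
#   monomers[1].molar_mass = 141.17
#   monomers[1].feed_fraction = 0.77
#   ...
#   ratios.r1 = 1
#   length.mean_dp = 63
#   n_chains = 20000
#
# Lines starting with '#' and blank lines are ignored.

#' Write a simulation config to a flat key-value file
#'
#' @param config A [sim_config].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  lines <- character(0)
  for (i in seq_along(config$monomers)) {
    m <- config$monomers[[i]]
    lines <- c(lines,
               sprintf("monomers[%d].name = %s", i, m$name),
               sprintf("monomers[%d].molar_mass = %.10g", i, m$molar_mass),
               sprintf("monomers[%d].feed_fraction = %.10g", i,
                       m$feed_fraction))
  }
  lines <- c(lines,
             sprintf("ratios.r1 = %.10g", config$ratios$r1),
             sprintf("ratios.r2 = %.10g", config$ratios$r2),
             sprintf("length.mean_dp = %.10g", config$length_model$mean_dp),
             sprintf("length.dispersity = %.10g",
                     config$length_model$dispersity),
             sprintf("length.family = %s", config$length_model$family),
             sprintf("n_chains = %d", config$n_chains),
             sprintf("target_conversion = %.10g", config$target_conversion),
             sprintf("pool_mode = %s", config$pool_mode),
             sprintf("seed = %d", config$seed))
  writeLines(lines, path)
  invisible(path)
}

#' Read a simulation config from a flat key-value file
#'
#' @param path Config file path (format of [write_sim_config]).
#' @return A [sim_config].
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+?)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) stopf("malformed config line: '%s'", lines[bad][1])
  keys <- vapply(kv, `[[`, character(1), 2)
  vals <- vapply(kv, `[[`, character(1), 3)
  get_val <- function(key, numeric = TRUE, default = NULL) {
    hit <- which(keys == key)
    if (!length(hit)) {
      if (!is.null(default)) return(default)
      stopf("config missing key '%s'", key)
    }
    v <- vals[hit[1]]
    if (numeric) as.numeric(v) else v
  }
  monomers <- list()
  i <- 1L
  while (sprintf("monomers[%d].name", i) %in% keys) {
    monomers[[i]] <- monomer_spec(
      get_val(sprintf("monomers[%d].name", i), numeric = FALSE),
      get_val(sprintf("monomers[%d].molar_mass", i)),
      get_val(sprintf("monomers[%d].feed_fraction", i)))
    i <- i + 1L
  }
  if (length(monomers) != 2L) {
    stopf("config must declare exactly two monomers (found %d)",
          length(monomers))
  }
  sim_config(
    monomers = monomers,
    ratios = reactivity_ratios(get_val("ratios.r1", default = 1),
                               get_val("ratios.r2", default = 1)),
    length_model = chain_length_model(
      get_val("length.mean_dp"),
      get_val("length.dispersity", default = 1),
      get_val("length.family", numeric = FALSE, default = "schulz_zimm")),
    n_chains = get_val("n_chains"),
    target_conversion = get_val("target_conversion", default = 0.98),
    pool_mode = get_val("pool_mode", numeric = FALSE,
                        default = "infinite_feed"),
    seed = get_val("seed", default = 1))
}
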