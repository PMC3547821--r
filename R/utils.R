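# Internal helpers: error conditions, seed streams, config hashing.

stop_evohet <- function(msg, class, call = sys.call(-1)) {
  cond <- structure(class = c(class, "evohet_error", "error", "condition"),
                    list(message = msg, call = call))
  stop(cond)
}

config_error <- function(msg) stop_evohet(msg, "evohet_config_error")

extinction_error <- function(msg) stop_evohet(msg, "evohet_extinction_error")

#' @noRd
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    config_error(sprintf("`%s` must be a single number", name))
  if (x < lower || x > upper)
    config_error(sprintf("`%s` = %g outside [%g, %g]", name, x, lower, upper))
  if (integer && x != round(x))
    config_error(sprintf("`%s` must be an integer", name))
  invisible(x)
}

# Deterministic per-replicate seed stream derived from the master seed.
# Kept strictly below 2^31 (R integer range).
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + i * 69621) %% 2147483647)
}

# 31-bit polynomial rolling hash of a deparsed object; provenance stamp
# for output tables.
config_hash <- function(obj) {
  s <- paste(deparse(obj), collapse = " ")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

l1_distance <- function(p, q) sum(abs(p - q))

# Histogram masses of trait values on uniform bins over [0, 1].
trait_hist <- function(x, nbins) {
  idx <- pmin(pmax(ceiling(x * nbins), 1L), nbins)
  tabulate(idx, nbins) / length(x)
}
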