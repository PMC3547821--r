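#' Evolution run configuration
#'
#' Collects the parameters of the evolutionary algorithm: population size,
#' number of non-overlapping generations, mutation process, reproduction
#' mode, maturation delay, engine and replication.
#'
#' @param N population size per generation (>= 2).
#' @param G number of generations to evolve (>= 1).
#' @param pm per-birth mutation probability in \[0, 1\].
#' @param kernel mutation kernel: `"uniform_reset"` redraws the offspring
#'   trait uniformly on \[0, 1\]; `"gaussian"` perturbs the parental trait by
#'   a Normal(0, `kernel_sd`) step reflected into \[0, 1\].
#' @param kernel_sd standard deviation of the Gaussian kernel.
#' @param reproduction `"asexual"` (offspring copies its parent) or
#'   `"sexual"` (two weight-proportional parents drawn without replacement;
#'   offspring trait is their mean).
#' @param maturation delay before the reproduction clock starts (>= 0);
#'   deaths accrue from age 0, so a positive delay imposes pre-reproductive
#'   selection.
#' @param engine `"continuous"` (Gillespie, unit-rate reproduction events)
#'   or `"discrete"` (integer time steps, per-step survival tests,
#'   Poisson(1) reproduction events per step).
#' @param repro_per_step for the discrete engine only: fixed number of
#'   reproduction events per step, or `NA` (default) for Poisson(1).
#' @param replicates number of independent replicate simulations.
#' @param seed master seed; per-replicate streams are derived
#'   deterministically from it.
#' @return an object of class `evolution_config`.
#' @export
evolution_config <- function(N = 500, G = 400, pm = 0.01,
                             kernel = c("uniform_reset", "gaussian"),
                             kernel_sd = 0.3,
                             reproduction = c("asexual", "sexual"),
                             maturation = 0,
                             engine = c("continuous", "discrete"),
                             repro_per_step = NA, replicates = 300,
                             seed = 1L) {
  kernel <- match.arg(kernel)
  reproduction <- match.arg(reproduction)
  engine <- match.arg(engine)
  check_number(N, "N", lower = 2, integer = TRUE)
  check_number(G, "G", lower = 1, integer = TRUE)
  check_number(pm, "pm", lower = 0, upper = 1)
  check_number(kernel_sd, "kernel_sd", lower = 0)
  check_number(maturation, "maturation", lower = 0)
  check_number(replicates, "replicates", lower = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  structure(list(N = as.integer(N), G = as.integer(G), pm = pm,
                 kernel = kernel, kernel_sd = kernel_sd,
                 reproduction = reproduction, maturation = maturation,
                 engine = engine, repro_per_step = repro_per_step,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "evolution_config")
}

#' @export
print.evolution_config <- function(x, ...) {
  cat(sprintf(
    "<evolution_config> N = %d, G = %d, pm = %g, kernel = %s, %s, %s engine, %d replicate(s), seed = %d\n",
    x$N, x$G, x$pm, x$kernel, x$reproduction, x$engine, x$replicates,
    x$seed))
  invisible(x)
}

kernel_code <- function(config) {
  if (config$kernel == "uniform_reset") 0L else 1L
}

#' Initial population
#'
#' Draws `N` founding individuals with traits uniform on \[0, 1\] and death
#' times drawn from the individual mortality law (all individuals of a
#' generation are synchronized at age zero).  Uses R's global random number
#' stream.
#'
#' @param config an [evolution_config()].
#' @param hp a [hazard_params()].
#' @return a generation record: list with `individuals` (data.frame `x`,
#'   `death_time`, `oldest_old`), `fill_time` (`NA` for the founders),
#'   `extinct`, `generation_index`.
#' @export
init_population <- function(config, hp) {
  x <- runif(config$N)
  dt <- if (config$engine == "discrete")
    .cpp_discrete_death_ages(x, fam_code(hp), hp$a, hp$b, hp$k,
                             hp$ext)$death_time
  else draw_death_time(hp, x)
  generation_record(x, dt, fill_time = NA_real_, extinct = FALSE,
                    generation_index = 0L)
}

generation_record <- function(x, death_time, fill_time, extinct,
                              generation_index,
                              oldest_old = rep(NA, length(x))) {
  structure(list(
    individuals = data.frame(x = x, death_time = death_time,
                             oldest_old = oldest_old),
    fill_time = fill_time, extinct = extinct,
    generation_index = generation_index),
    class = "generation_record")
}

#' @export
print.generation_record <- function(x, ...) {
  cat(sprintf(
    "<generation_record> generation %d: %d individual(s)%s, fill_time = %s\n",
    x$generation_index, nrow(x$individuals),
    if (x$extinct) " (EXTINCT, partial)" else "",
    format(x$fill_time)))
  invisible(x)
}

#' Weight-proportional parent choice
#'
#' Chooses an index among alive individuals with probability proportional to
#' the trait: \eqn{P(i) = x_i / \sum_j x_j}.  When every alive trait is zero
#' the choice is uniform, so a sole surviving individual reproduces with
#' probability one independently of its trait.  An empty alive set signals
#' extinction (condition class `evohet_extinction_error`).
#'
#' @param alive_traits traits of the currently alive individuals.
#' @return the chosen index.
#' @export
choose_parent <- function(alive_traits) {
  if (length(alive_traits) == 0L)
    extinction_error("no alive individuals: population extinct")
  tot <- sum(alive_traits)
  if (tot <= 0) return(sample.int(length(alive_traits), 1L))
  sample.int(length(alive_traits), 1L, prob = alive_traits / tot)
}

#' Offspring mutation
#'
#' With probability `1 - pm` the offspring inherits the parental trait
#' unchanged; with probability `pm` the trait is redrawn by the mutation
#' kernel (uniform reset, or Gaussian perturbation reflected into \[0, 1\]).
#' Vectorized over `parent_x`.
#'
#' @param parent_x parental trait(s) in \[0, 1\].
#' @param config an [evolution_config()] (fields `pm`, `kernel`,
#'   `kernel_sd`).
#' @return offspring trait(s) in \[0, 1\].
#' @export
mutate_offspring <- function(parent_x, config) {
  check_xt(parent_x, 0)
  n <- length(parent_x)
  hit <- runif(n) < config$pm
  out <- parent_x
  if (any(hit)) {
    if (config$kernel == "uniform_reset") {
      out[hit] <- runif(sum(hit))
    } else {
      y <- abs(parent_x[hit] + rnorm(sum(hit), 0, config$kernel_sd))
      y <- y %% 2
      out[hit] <- ifelse(y > 1, 2 - y, y)
    }
  }
  out
}

run_generation_engine <- function(parents, config, hp, engine) {
  if (nrow(parents$individuals) == 0L)
    extinction_error("parent generation is empty: population extinct")
  ind <- parents$individuals
  res <- if (engine == "continuous")
    .cpp_generation_continuous(
      ind$x, ind$death_time, config$N, config$pm, kernel_code(config),
      config$kernel_sd, config$reproduction == "sexual", config$maturation,
      fam_code(hp), hp$a, hp$b, hp$k, hp$ext)
  else
    .cpp_generation_discrete(
      ind$x, ind$death_time, config$N, config$pm, kernel_code(config),
      config$kernel_sd, config$reproduction == "sexual", config$maturation,
      if (is.na(config$repro_per_step)) -1L
      else as.integer(config$repro_per_step),
      fam_code(hp), hp$a, hp$b, hp$k, hp$ext)
  if (engine == "discrete" && res$n_clamped > 0)
    warning(sprintf(
      "discrete engine: hazard exceeded 1 and was clamped %d time(s)",
      as.integer(res$n_clamped)), call. = FALSE)
  out <- generation_record(res$x, res$death_time, res$fill_time,
                           res$extinct, parents$generation_index + 1L)
  attr(out, "parent_oldest_old") <- res$parent_oldest_old
  if (engine == "discrete") attr(out, "n_clamped") <- res$n_clamped
  out
}

#' Build one generation (continuous time)
#'
#' Gillespie construction of generation \eqn{g+1} from generation \eqn{g}:
#' reproduction events arrive at overall unit rate (Exp(1) inter-event
#' gaps), starting at the maturation delay; at each event one alive parent
#' is chosen with probability proportional to its trait, its offspring
#' inherits (or recombines) the trait, mutates with probability `pm`, and
#' has its own death time drawn.  The loop ends when `N` offspring exist
#' (`fill_time` = event clock) or when the alive set empties (flagged
#' extinction, partial generation returned).  Parents with
#' `death_time > fill_time` — the oldest-old, who never reproduce again —
#' are flagged in the attribute `parent_oldest_old`.
#'
#' @param parents a generation record with pre-drawn death times.
#' @param config an [evolution_config()].
#' @param hp a [hazard_params()].
#' @return a generation record for the offspring generation.
#' @export
run_generation_continuous <- function(parents, config, hp) {
  run_generation_engine(parents, config, hp, "continuous")
}

#' Build one generation (discrete time)
#'
#' Integer time steps: at each step every alive individual passes a survival
#' test with death probability `min(hazard, 1)` (clamping is counted and
#' warned about), then a Poisson(1) number of reproduction events occurs
#' among survivors (a fixed count if `config$repro_per_step` is set).
#' Offspring fill the next generation until `N`.
#'
#' @inheritParams run_generation_continuous
#' @return a generation record for the offspring generation.
#' @export
run_generation_discrete <- function(parents, config, hp) {
  run_generation_engine(parents, config, hp, "discrete")
}

#' Evolve a population to quasi-stationarity
#'
#' Runs `replicates` independent simulations of `G` generations each, with
#' per-replicate seeds derived from the master seed.  Per generation the
#' ensemble-averaged trait histogram is recorded; after the final
#' generation one extra generation-filling is simulated (offspring
#' discarded) solely to flag the oldest-old of generation `G`.  The final
#' generation's individuals are pooled over replicates.
#'
#' When a filling stalls (every parent dead before `N` offspring exist) the
#' population simply shrinks: evolution continues with the partial
#' generation, and a replicate counts as extinct only when a generation is
#' left empty — population size can decrease over generations until
#' extinction.
#'
#' @param config an [evolution_config()].
#' @param hp a [hazard_params()].
#' @param hist_bins number of uniform trait-histogram bins on \[0, 1\].
#' @return an object of class `evolution_result`: list with
#'   \describe{
#'     \item{final}{data.frame (`replicate`, `generation`, `x`,
#'       `death_time`, `oldest_old`) pooled over surviving replicates.}
#'     \item{ensemble_hist}{(G+1) x `hist_bins` matrix of ensemble-averaged
#'       trait histogram masses, generations 0..G.}
#'     \item{mean_x}{ensemble mean trait per generation 0..G.}
#'     \item{extinctions}{data.frame (`replicate`, `generation`) of
#'       extinction events.}
#'     \item{fill_time}{mean fill time over recorded generations.}
#'     \item{config, hazard, seeds}{provenance.}
#'   }
#' @export
run_evolution <- function(config, hp, hist_bins = 50L) {
  stopifnot(inherits(config, "evolution_config"),
            inherits(hp, "hazard_params"))
  G <- config$G
  R <- config$replicates
  hist_sum <- matrix(0, G + 1L, hist_bins)
  hist_n <- integer(G + 1L)
  mean_sum <- numeric(G + 1L)
  finals <- vector("list", R)
  ext_rep <- integer(0)
  ext_gen <- integer(0)
  seeds <- vapply(seq_len(R), function(r) derive_seed(config$seed, r),
                  integer(1))
  fill_sum <- 0
  fill_n <- 0L

  stall_rep <- integer(0)
  stall_gen <- integer(0)

  for (r in seq_len(R)) {
    set.seed(seeds[r])
    gen <- init_population(config, hp)
    alive_to_end <- TRUE
    for (g in 0:G) {
      if (g > 0) {
        gen <- run_generation_engine(gen, config, hp, config$engine)
        if (gen$extinct) {
          # filling stalled: the population shrinks but evolution continues
          # with the partial generation; a replicate dies only when empty
          stall_rep <- c(stall_rep, r)
          stall_gen <- c(stall_gen, g)
          if (nrow(gen$individuals) == 0L) {
            ext_rep <- c(ext_rep, r)
            ext_gen <- c(ext_gen, g)
            alive_to_end <- FALSE
            break
          }
        } else {
          fill_sum <- fill_sum + gen$fill_time
          fill_n <- fill_n + 1L
        }
      }
      hist_sum[g + 1L, ] <- hist_sum[g + 1L, ] +
        trait_hist(gen$individuals$x, hist_bins)
      hist_n[g + 1L] <- hist_n[g + 1L] + 1L
      mean_sum[g + 1L] <- mean_sum[g + 1L] + mean(gen$individuals$x)
    }
    if (alive_to_end) {
      # one extra filling, only to flag generation G's oldest-old
      extra <- suppressWarnings(
        run_generation_engine(gen, config, hp, config$engine))
      oo <- if (extra$extinct) rep(FALSE, nrow(gen$individuals))
            else as.logical(attr(extra, "parent_oldest_old"))
      fin <- gen$individuals
      fin$oldest_old <- oo
      fin$replicate <- r
      fin$generation <- G
      finals[[r]] <- fin
    }
  }

  if (all(lengths(finals) == 0L))
    extinction_error(sprintf(
      "all %d replicates went extinct (%s: a = %g, b = %g, N = %d)",
      R, hp$family, hp$a, hp$b, config$N))

  final <- do.call(rbind, finals[lengths(finals) > 0L])
  rownames(final) <- NULL
  structure(list(
    final = final[, c("replicate", "generation", "x", "death_time",
                      "oldest_old")],
    ensemble_hist = hist_sum / pmax(hist_n, 1L),
    hist_bins = hist_bins,
    mean_x = mean_sum / pmax(hist_n, 1L),
    extinctions = data.frame(replicate = ext_rep, generation = ext_gen),
    stalls = data.frame(replicate = stall_rep, generation = stall_gen),
    fill_time = if (fill_n > 0) fill_sum / fill_n else NA_real_,
    config = config, hazard = hp, seeds = seeds),
    class = "evolution_result")
}

#' @export
print.evolution_result <- function(x, ...) {
  cat(sprintf(
    "<evolution_result> %s a = %g b = %g | N = %d, G = %d, pm = %g, %d/%d replicates survived\n",
    x$hazard$family, x$hazard$a, x$hazard$b, x$config$N, x$config$G,
    x$config$pm, length(unique(x$final$replicate)), x$config$replicates))
  cat(sprintf("  mean trait (final generation): %.3f; mean fill time: %.1f\n",
              mean(x$final$x), x$fill_time))
  invisible(x)
}

#' Consecutive-generation stabilization diagnostics
#'
#' L1 distances between consecutive ensemble-averaged trait histograms, and
#' the first generation from which the distance stays below a threshold for
#' the rest of the run (`NA` if it never does).
#'
#' @param result an [run_evolution()] result.
#' @param threshold L1 stabilization threshold.
#' @return list with `distances` (length G vector; entry g compares
#'   generations g-1 and g) and `stabilization_generation`.
#' @export
stabilization_generation <- function(result, threshold = 0.01) {
  h <- result$ensemble_hist
  G <- nrow(h) - 1L
  d <- vapply(seq_len(G), function(g) l1_distance(h[g + 1L, ], h[g, ]),
              numeric(1))
  below <- rev(cumprod(rev(d < threshold))) == 1
  gen <- if (any(below)) which(below)[1L] else NA_integer_
  list(distances = d, stabilization_generation = gen)
}
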