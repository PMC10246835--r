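# Forward-time Moran-process simulator of the serial-passage competition:
# fitness-proportional multinomial reproduction between bottlenecks, random
# downsampling (multivariate hypergeometric) at dilutions, no mutation.

#' Serial-passage simulation configuration
#'
#' Defaults mirror the study's protocol: 1e6 starting cells growing to a
#' 1e8-cell cap over 12 generations, then 1/100 dilutions every six
#' generations with regrowth to the cap between bottlenecks. Tests and the
#' bundled analyses use desk-scale sizes (1e4 -> 1e6); the dynamics probed
#' (selection response, drift, bottlenecks, clonal interference) are
#' properties of the sampling structure, not the absolute census size.
#'
#' @param fitness named positive vector of relative fitness w_i per variant.
#' @param n_init initial population size (cells).
#' @param n_cap population cap (cells).
#' @param generations_to_cap generations of the initial growth phase.
#' @param dilution_factor fold dilution at each bottleneck (> 1).
#' @param dilution_every generations between bottlenecks after the cap.
#' @param total_generations simulated generations.
#' @param replicates number of replicate populations.
#' @param initial_frequencies "equalized" or a named frequency vector.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(fitness, n_init = 1e6, n_cap = 1e8,
                       generations_to_cap = 12L, dilution_factor = 100,
                       dilution_every = 6L, total_generations = 24L,
                       replicates = 10L,
                       initial_frequencies = "equalized") {
  stopifnot(length(fitness) >= 1L, !is.null(names(fitness)))
  if (any(fitness <= 0)) stop("all fitness values must be positive")
  if (n_init >= n_cap) stop("n_init must be below n_cap")
  if (dilution_factor <= 1) stop("dilution_factor must exceed 1")
  if (!identical(initial_frequencies, "equalized")) {
    stopifnot(is.numeric(initial_frequencies),
              setequal(names(initial_frequencies), names(fitness)))
    if (abs(sum(initial_frequencies) - 1) > 1e-6)
      stop("initial frequencies must sum to 1")
    initial_frequencies <- initial_frequencies[names(fitness)]
  }
  structure(list(fitness = fitness, n_init = n_init, n_cap = n_cap,
                 generations_to_cap = as.integer(generations_to_cap),
                 dilution_factor = dilution_factor,
                 dilution_every = as.integer(dilution_every),
                 total_generations = as.integer(total_generations),
                 replicates = as.integer(replicates),
                 initial_frequencies = initial_frequencies),
            class = "sim_config")
}

# exact multivariate hypergeometric downsample (without replacement)
#' @importFrom stats rhyper rmultinom
downsample_counts <- function(counts, target) {
  remaining <- sum(counts)
  want <- target
  out <- integer(length(counts))
  for (i in seq_along(counts)) {
    remaining <- remaining - counts[i]
    x <- stats::rhyper(1L, counts[i], remaining, want)
    out[i] <- x
    want <- want - x
  }
  names(out) <- names(counts)
  out
}

#' Run the serial-passage competition simulation
#'
#' Each growth generation draws offspring multinomially with probabilities
#' proportional to n_i(t) * w_i, with the census scaled by a per-generation
#' growth factor chosen so the population reaches the cap at the next
#' bottleneck ((n_cap / n_init)^(1 / generations_to_cap) for the initial
#' phase). At each bottleneck the population is randomly downsampled
#' without replacement by `dilution_factor`. No de novo mutation. Identical
#' config + seed gives identical trajectories.
#'
#' @param config a `sim_config`.
#' @param seed integer seed for all randomness.
#' @param mode "moran" (stochastic) or "deterministic" (expected counts,
#'   real-valued; dilutions become exact divisions) for sensitivity checks.
#' @return list of replicate trajectories; each is a (generations + 1) x
#'   variants matrix of counts with attribute `engine` =
#'   "generation-multinomial-v1".
#' @export
simulate_moran <- function(config, seed = 1L, mode = c("moran",
                                                       "deterministic")) {
  stopifnot(inherits(config, "sim_config"))
  mode <- match.arg(mode)
  set.seed(as.integer(seed))
  w <- config$fitness
  k <- length(w)
  f0 <- if (identical(config$initial_frequencies, "equalized"))
    rep(1 / k, k) else unname(config$initial_frequencies)
  lapply(seq_len(config$replicates), function(rep_i) {
    counts <- if (mode == "moran")
      drop(stats::rmultinom(1L, size = config$n_init, prob = f0))
    else f0 * config$n_init
    names(counts) <- names(w)
    traj <- matrix(0, nrow = config$total_generations + 1L, ncol = k,
                   dimnames = list(NULL, names(w)))
    traj[1L, ] <- counts
    # generations until the next bottleneck, and the growth factor that
    # reaches the cap there
    gens_left <- config$generations_to_cap
    g <- (config$n_cap / sum(counts))^(1 / gens_left)
    for (t in seq_len(config$total_generations)) {
      N_next <- round(sum(counts) * g)
      prob <- counts * w
      counts <- if (mode == "moran")
        drop(stats::rmultinom(1L, size = N_next, prob = prob))
      else N_next * prob / sum(prob)
      gens_left <- gens_left - 1L
      if (gens_left == 0L) {
        target <- floor(sum(counts) / config$dilution_factor)
        counts <- if (mode == "moran") downsample_counts(counts, target)
        else counts * (target / sum(counts))
        gens_left <- config$dilution_every
        g <- (config$n_cap / max(sum(counts), 1))^(1 / gens_left)
      }
      if (sum(counts) <= 0) stop("population extinct (should be impossible)")
      traj[t + 1L, ] <- counts
    }
    attr(traj, "engine") <- "generation-multinomial-v1"
    traj
  })
}

#' Summarize simulated trajectories
#'
#' Per replicate: population mean fitness w-bar(t) = sum f_i(t) w_i
#' normalized to 1 at t = 0, and Shannon diversity H(t) in nats; plus the
#' across-replicate mean and sd of both.
#'
#' @param trajectories list from [simulate_moran()].
#' @param fitness the fitness vector used in the simulation.
#' @return list with `per_replicate` (list of data.frames: generation,
#'   w_bar, H) and `summary` (data.frame: generation, w_bar_mean, w_bar_sd,
#'   H_mean, H_sd).
#' @export
summarize_trajectories <- function(trajectories, fitness) {
  stopifnot(length(trajectories) >= 1L)
  per_rep <- lapply(trajectories, function(traj) {
    f <- traj / rowSums(traj)
    wbar <- as.vector(f %*% fitness[colnames(traj)])
    wbar <- wbar / wbar[1L]
    H <- apply(f, 1L, shannon)
    data.frame(generation = seq_len(nrow(traj)) - 1L, w_bar = wbar, H = H)
  })
  wb <- vapply(per_rep, `[[`, numeric(nrow(trajectories[[1L]])), "w_bar")
  hh <- vapply(per_rep, `[[`, numeric(nrow(trajectories[[1L]])), "H")
  list(per_replicate = per_rep,
       summary = data.frame(
         generation = per_rep[[1L]]$generation,
         w_bar_mean = rowMeans(wb),
         w_bar_sd = apply(wb, 1L, stats::sd),
         H_mean = rowMeans(hh),
         H_sd = apply(hh, 1L, stats::sd)))
}
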