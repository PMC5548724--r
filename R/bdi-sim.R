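#' Simulate one trajectory of the BDI process
#'
#' Exact (Gillespie-type) continuous-time event simulation of family sizes
#' under per-element birth, death and cis-innovation plus global de-novo
#' innovation. cis-innovation of a size-1 family is a relabel: it is counted
#' but leaves the state unchanged, so family count F changes by +1 only when
#' the source family had at least 2 members. De-novo innovation adds one
#' element in a new family (the master-equation inflow `+nu` into class 1).
#'
#' The default stopping rule is a relaxation horizon of `20 / mu` time units
#' or 200 events per initial element, whichever comes first: F/N
#' decorrelates on the cis-innovation timescale `1/mu`, so 20 such times is
#' deep in the stationary regime.
#'
#' @param rates a [bdi_rates()] object.
#' @param init_sizes initial family sizes (positive integers); the default
#'   envelope construction starts from a single ancestral family.
#' @param t_max simulation horizon in model time units.
#' @param max_events hard event cap.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return A `bdi_sim` object: `sizes` (final multiset), `N`, `F`,
#'   `extinct`, `t`, and per-type event counters.
#' @examples
#' sim <- bdi_simulate(bdi_rates_balanced(0.74), init_sizes = 100, seed = 1)
#' sim$F / sim$N
#' @export
bdi_simulate <- function(rates, init_sizes,
                         t_max = 20 / max(rates$mu, 1e-12),
                         max_events = 200 * sum(init_sizes),
                         seed = NULL) {
  stopifnot(inherits(rates, "bdi_rates"), length(init_sizes) >= 1,
            all(init_sizes >= 1))
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_bdi_simulate(as.integer(init_sizes), rates$lambda, rates$delta,
                          rates$mu, rates$nu, t_max, max_events)
  structure(
    list(sizes = res$sizes, N = sum(res$sizes), F = length(res$sizes),
         extinct = res$extinct, t = res$t, n_events = res$n_events,
         births = res$births, deaths = res$deaths,
         cis_splits = res$cis_splits, cis_relabels = res$cis_relabels,
         denovo = res$denovo, fam_deaths = res$fam_deaths,
         init_N = sum(init_sizes),
         init_F = length(init_sizes), rates = rates),
    class = "bdi_sim"
  )
}

#' @export
print.bdi_sim <- function(x, ...) {
  cat(sprintf(
    "BDI trajectory: N %d -> %d, F %d -> %d after %g events (t = %.3g)%s\n",
    x$init_N, x$N, x$init_F, x$F, x$n_events, x$t,
    if (x$extinct) " [extinct]" else ""))
  invisible(x)
}

#' Simulated neutral envelope of F/N versus repertoire size
#'
#' Replays the construction behind the per-DBD comparison: many independent
#' BDI trajectories in the balanced regime (`lambda = delta`, so the element
#' count is a critical random walk), each started from a single ancestral
#' family whose size cycles through `init_range`, run to relaxation. Each
#' surviving replicate contributes its final `(N, F/N)`; replicates are
#' binned by final N (log-spaced bins) into mean and standard-deviation
#' bands. Extinct replicates have no defined F/N and are excluded but
#' counted.
#'
#' @param theta redundancy parameter in (0, 1).
#' @param init_range initial ancestral-family sizes to cycle over
#'   (default 1:500).
#' @param n_rep total replicate budget (default 1000).
#' @param lambda birth (= death) rate; sets the time unit.
#' @param n_bins number of log-spaced bins on final N.
#' @param seed integer seed.
#' @param all_singleton_start if TRUE start each replicate from `init`
#'   singletons instead of one ancestral family of size `init`.
#' @return An `fn_envelope` object: `replicates` (init_N, final_N, final_F,
#'   fn, extinct per replicate), `bands` (N, mean_fn, sd_fn, n per bin),
#'   `theta`, `n_extinct`, `seed`.
#' @export
fn_envelope <- function(theta, init_range = 1:500, n_rep = 1000L,
                        lambda = 1, n_bins = 24L, seed = 1L,
                        all_singleton_start = FALSE) {
  check_theta(theta)
  rates <- bdi_rates_balanced(theta, lambda)
  set.seed(seed)
  inits <- rep_len(init_range, n_rep)
  reps <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    init <- if (all_singleton_start) rep(1L, inits[r]) else inits[r]
    sim <- bdi_simulate(rates, init)
    reps[[r]] <- data.frame(
      init_N = inits[r], final_N = sim$N, final_F = sim$F,
      fn = if (sim$N > 0) sim$F / sim$N else NA_real_,
      extinct = sim$extinct)
  }
  reps <- do.call(rbind, reps)
  alive <- reps[!reps$extinct & reps$final_N > 0, ]
  brk <- exp(seq(log(max(1, min(alive$final_N)) - 0.5),
                 log(max(alive$final_N) + 0.5), length.out = n_bins + 1L))
  bin <- cut(alive$final_N, breaks = unique(brk), include.lowest = TRUE)
  agg <- do.call(rbind, lapply(split(alive, bin), function(g) {
    if (nrow(g) == 0L) return(NULL)
    data.frame(N = mean(g$final_N), mean_fn = mean(g$fn),
               sd_fn = stats::sd(g$fn), n = nrow(g))
  }))
  agg <- agg[!is.na(agg$N) & agg$n > 0, ]
  structure(
    list(replicates = reps, bands = agg, theta = theta,
         n_extinct = sum(reps$extinct), seed = seed),
    class = "fn_envelope"
  )
}

#' @export
print.fn_envelope <- function(x, ...) {
  cat(sprintf(
    "F/N envelope at theta = %.3f: %d replicates (%d extinct), %d bins\n",
    x$theta, nrow(x$replicates), x$n_extinct, nrow(x$bands)))
  invisible(x)
}

#' Check that fitted theta does not depend on repertoire size
#'
#' Simulates the balanced BDI process to relaxation at several total element
#' counts, refits theta on each final family-size sample, and tabulates the
#' recovered estimates: under constant rates the stationary law (and hence
#' theta-hat) is independent of N.
#'
#' @param theta true redundancy parameter.
#' @param N_values initial total sizes to test.
#' @param n_rep replicates per N.
#' @param seed integer seed.
#' @return A data frame with one row per N: `N`, `mean_theta`, `sd_theta`,
#'   `n_ok` (replicates that survived and were fittable).
#' @export
theta_invariance_check <- function(theta, N_values, n_rep = 20L, seed = 1L) {
  check_theta(theta)
  rates <- bdi_rates_balanced(theta)
  set.seed(seed)
  out <- lapply(N_values, function(N) {
    est <- numeric(0)
    for (r in seq_len(n_rep)) {
      sim <- bdi_simulate(rates, N)
      if (!sim$extinct && sim$N > 0 && mean(sim$sizes) > 1) {
        est <- c(est, theta_mle(mean(sim$sizes)))
      }
    }
    data.frame(N = N, mean_theta = mean(est), sd_theta = stats::sd(est),
               n_ok = length(est))
  })
  do.call(rbind, out)
}
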