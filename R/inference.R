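#' Summarize a multiset of family sizes
#'
#' @param sizes vector of positive integer family sizes.
#' @return An object of class `size_sample` with fields `sizes`, `N` (total
#'   elements), `F` (family count), `kbar` (= N/F), `M` (largest family) and
#'   `f` (named vector of counts per size).
#' @examples
#' size_sample(c(3, 1)) # N = 4, F = 2, kbar = 2
#' @export
size_sample <- function(sizes) {
  if (inherits(sizes, "size_sample")) return(sizes)
  sizes <- as.integer(sizes)
  if (length(sizes) == 0L) stop("empty size sample", call. = FALSE)
  if (any(is.na(sizes) | sizes < 1L)) {
    stop("family sizes must be positive integers", call. = FALSE)
  }
  tab <- table(sizes)
  structure(
    list(sizes = sizes, N = sum(sizes), F = length(sizes),
         kbar = sum(sizes) / length(sizes), M = max(sizes),
         f = stats::setNames(as.integer(tab), names(tab))),
    class = "size_sample"
  )
}

#' @export
print.size_sample <- function(x, ...) {
  cat(sprintf(
    "Size sample: N = %d elements in F = %d families (kbar = %.4f, max = %d)\n",
    x$N, x$F, x$kbar, x$M))
  invisible(x)
}

#' Maximum-likelihood estimate of the redundancy parameter theta
#'
#' For the untruncated logarithmic series the MLE depends on the data only
#' through the mean family size `kbar` and has the closed form
#' \deqn{\hat\theta = 1 - \exp\{1/\bar k + W_{-1}(-(1/\bar k) e^{-1/\bar k})\}}
#' with `W_{-1}` the real lower branch of the Lambert W function (the
#' argument lies in `(-1/e, 0)` for `kbar > 1`, so the branch is real and
#' the moment condition `mean_size(theta) = kbar` is solved exactly). With a
#' finite truncation `M` the same moment condition is solved numerically.
#'
#' @param x a `size_sample`, a vector of family sizes (length > 1), or a
#'   single numeric `kbar` > 1.
#' @param M truncation mode: `Inf` (default, closed form) or a finite
#'   support cap.
#' @return The estimate `theta` in (0, 1).
#' @examples
#' theta_mle(906 / 424) # ~0.745, the human whole-repertoire regime
#' @export
theta_mle <- function(x, M = Inf) {
  kbar <- if (inherits(x, "size_sample")) x$kbar
          else if (length(x) == 1L) as.numeric(x)
          else size_sample(x)$kbar
  check_M(M)
  if (!is.finite(kbar) || kbar <= 1) {
    stop("degenerate sample: mean family size must exceed 1 ",
         "(an all-singleton sample has no interior MLE, theta -> 0)",
         call. = FALSE)
  }
  if (is.infinite(M)) {
    a <- -(1 / kbar) * exp(-1 / kbar)
    if (a <= -exp(-1) || a >= 0) {
      stop("Lambert W argument outside (-1/e, 0); kbar must exceed 1",
           call. = FALSE)
    }
    th <- 1 - exp(1 / kbar + pracma::lambertWn(a))
    return(min(max(th, .Machine$double.eps), 1 - 1e-15))
  }
  kmax <- bdi_mean_size(1 - 1e-12, M) # -> M / H_M as theta -> 1
  if (kbar >= kmax) {
    stop(sprintf(
      "kbar = %.4f is not attainable under truncation M = %d (max %.4f)",
      kbar, M, kmax), call. = FALSE)
  }
  stats::uniroot(function(t) bdi_mean_size(t, M) - kbar,
                 interval = c(1e-12, 1 - 1e-12), tol = 1e-12)$root
}

#' Log-likelihood of a size sample under the stationary law
#'
#' Mainly used as an independent cross-check that the closed-form MLE
#' maximizes the likelihood.
#'
#' @param theta redundancy parameter(s); vectorized.
#' @param sample a `size_sample` or vector of sizes.
#' @param M truncation or `Inf`.
#' @return Log-likelihood value for each `theta`.
#' @export
bdi_loglik <- function(theta, sample, M = Inf) {
  s <- size_sample(sample)
  vapply(theta, function(t) {
    check_theta(t)
    sum(log(bdi_pmf(s$sizes, t, M)))
  }, numeric(1))
}

#' Kolmogorov-Smirnov distance between a size sample and the model
#'
#' `D = sup_i |ECDF(i) - CDF(i)|` over the discrete support `1..max(sizes)`
#' (beyond the largest observed size the difference can only shrink, and at
#' a finite truncation both CDFs are 1).
#'
#' @param sample a `size_sample` or vector of sizes.
#' @param theta model parameter in (0, 1).
#' @param M truncation or `Inf`.
#' @return The KS statistic, `>= 0`.
#' @export
ks_statistic <- function(sample, theta, M = Inf) {
  s <- size_sample(sample)
  support <- seq_len(s$M)
  emp <- cumsum(tabulate(s$sizes, nbins = s$M)) / s$F
  mod <- bdi_cdf(support, theta, M)
  max(abs(emp - mod))
}

#' Parametric-bootstrap goodness-of-fit test for the BDI size law
#'
#' Fits `theta` by maximum likelihood, measures the KS distance between the
#' sample and the fitted law, then draws `n_boot` synthetic samples of the
#' same number of families from the fitted law; each replicate is refit and
#' its KS distance is computed against its own best fit (the
#' semi-parametric bootstrap of Clauset-style power-law fitting). The
#' p-value is the fraction of replicate distances greater than or equal to
#' the empirical one (ties count, a conservative choice).
#'
#' @param sample a `size_sample` or vector of sizes with `kbar > 1`.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed; every stochastic routine here takes one.
#' @param M truncation mode used for fit and replicates (`Inf` default).
#' @param M_sample finite support cap used when drawing replicates; default
#'   the sample's element total `N`, the largest size any family could have.
#' @return A `bdi_fit` object: `theta`, `kbar`, `n_fam`, `D`, `p_value`,
#'   `n_boot`, `n_degenerate` (replicates redrawn because all families came
#'   out size 1), `seed`, `truncation`.
#' @export
gof_pvalue <- function(sample, n_boot = 1000L, seed = 1L, M = Inf,
                       M_sample = NULL) {
  s <- size_sample(sample)
  if (is.null(M_sample)) M_sample <- if (is.finite(M)) M else s$N
  th <- theta_mle(s, M = M)
  D <- ks_statistic(s, th, M = M)
  set.seed(seed)
  # replicate sampling shares one CDF table; refits use the closed form
  n_exceed <- 0L
  n_degen <- 0L
  max_attempts <- 100L * n_boot
  b <- 0L
  attempts <- 0L
  while (b < n_boot && attempts < max_attempts) {
    attempts <- attempts + 1L
    rep_sizes <- bdi_sample_sizes(s$F, th, M = M_sample)
    if (mean(rep_sizes) <= 1) { n_degen <- n_degen + 1L; next }
    b <- b + 1L
    th_b <- theta_mle(mean(rep_sizes), M = M)
    D_b <- ks_statistic(rep_sizes, th_b, M = M)
    if (D_b >= D) n_exceed <- n_exceed + 1L
  }
  if (b < n_boot) {
    stop("bootstrap redraw cap exceeded: sample too close to degenerate",
         call. = FALSE)
  }
  structure(
    list(theta = th, kbar = s$kbar, n_fam = s$F, D = D,
         p_value = n_exceed / n_boot, n_boot = n_boot,
         n_degenerate = n_degen, seed = seed, truncation = M),
    class = "bdi_fit"
  )
}

#' @export
print.bdi_fit <- function(x, ...) {
  cat(sprintf(
    paste0("BDI fit: theta = %.4f (kbar = %.4f, F = %d)\n",
           "  KS D = %.4f, bootstrap p = %.4g (%d replicates, seed %d)\n"),
    x$theta, x$kbar, x$n_fam, x$D, x$p_value, x$n_boot, x$seed))
  invisible(x)
}

#' Trim scan: locate the model-consistent core of a size distribution
#'
#' Scans a grid over `T` (families of size `>= T` are excluded; the
#' size-exclusion threshold) and `N_s` (number of size-1 families removed;
#' singletons are exchangeable so removal just decrements `f_1`). Each cell
#' refits theta on the reduced sample and computes a bootstrap
#' goodness-of-fit p-value. The selected `T*` is the largest grid `T` whose
#' column reaches the acceptance level for some `N_s`; the accepted `N_s`
#' interval at `T*` is reported.
#'
#' @param sample a `size_sample` or vector of sizes.
#' @param T_grid size-exclusion thresholds to scan (descending or not).
#' @param Ns_grid numbers of singletons to remove; values exceeding the
#'   available singleton count are dropped with a warning.
#' @param accept_p acceptance level for the fit p-value (default 0.75).
#' @param n_boot bootstrap replicates per cell.
#' @param seed integer seed; cells use derived sub-seeds.
#' @param M truncation mode passed to [gof_pvalue()].
#' @return A `trim_scan` object: `grid` (data frame T, Ns, theta, p_value,
#'   n_fam, valid), `T_star`, `Ns_accepted` (range at `T_star` or NULL),
#'   `accept_p`, `seed`.
#' @export
trim_scan <- function(sample, T_grid, Ns_grid, accept_p = 0.75,
                      n_boot = 200L, seed = 1L, M = Inf) {
  s <- size_sample(sample)
  stopifnot(length(T_grid) >= 1, length(Ns_grid) >= 1)
  n1 <- sum(s$sizes == 1L)
  if (any(Ns_grid > n1)) {
    warning(sprintf(
      "dropping Ns values exceeding the %d available singletons", n1),
      call. = FALSE)
    Ns_grid <- Ns_grid[Ns_grid <= n1]
  }
  if (length(Ns_grid) == 0L) stop("no valid Ns values", call. = FALSE)
  grid <- expand.grid(T = sort(unique(T_grid)),
                      Ns = sort(unique(Ns_grid)))
  grid$theta <- NA_real_; grid$p_value <- NA_real_
  grid$n_fam <- NA_integer_; grid$valid <- FALSE
  for (r in seq_len(nrow(grid))) {
    kept <- s$sizes[s$sizes < grid$T[r]]
    ones <- which(kept == 1L)
    if (length(ones) >= grid$Ns[r] && grid$Ns[r] > 0) {
      kept <- kept[-ones[seq_len(grid$Ns[r])]]
    } else if (length(ones) < grid$Ns[r]) {
      next # trimming removed more singletons than remain: invalid cell
    }
    if (length(kept) < 2L || mean(kept) <= 1) next
    fit <- gof_pvalue(kept, n_boot = n_boot,
                      seed = seed + 1000L + r, M = M)
    grid$theta[r] <- fit$theta
    grid$p_value[r] <- fit$p_value
    grid$n_fam[r] <- fit$n_fam
    grid$valid[r] <- TRUE
  }
  by_T <- split(grid, grid$T)
  accepted_T <- vapply(by_T, function(g) {
    any(g$valid & g$p_value >= accept_p)
  }, logical(1))
  T_star <- if (any(accepted_T)) {
    max(as.numeric(names(by_T))[accepted_T])
  } else NA_real_
  Ns_acc <- NULL
  if (!is.na(T_star)) {
    g <- by_T[[as.character(T_star)]]
    Ns_acc <- range(g$Ns[g$valid & g$p_value >= accept_p])
  }
  structure(
    list(grid = grid, T_star = T_star, Ns_accepted = Ns_acc,
         accept_p = accept_p, seed = seed, n_boot = n_boot),
    class = "trim_scan"
  )
}

#' @export
print.trim_scan <- function(x, ...) {
  cat(sprintf("Trim scan over %d cells (accept p >= %.2f):\n",
              nrow(x$grid), x$accept_p))
  if (is.na(x$T_star)) {
    cat("  no acceptable cell found\n")
  } else {
    cat(sprintf("  T* = %g, accepted Ns in [%d, %d]\n",
                x$T_star, x$Ns_accepted[1], x$Ns_accepted[2]))
  }
  invisible(x)
}

#' Place DNA-binding-domain classes against simulated neutral bands
#'
#' Each DBD class contributes `N` TFs split into `F` motif families; its
#' empirical `F/N` is compared with the mean and standard deviation of the
#' simulated neutral envelope (see [fn_envelope()]) at the class's `N`
#' (interpolated on log N between envelope bins). Classes beyond 3 standard
#' deviations are called outliers; `N = 1` classes are flagged
#' uninformative (`F/N` is 1 by construction).
#'
#' @param dbd_table data frame with columns `dbd_class`, `N`, `F`.
#' @param envelope an `fn_envelope` object simulated at the reference theta.
#' @return The input with added columns `fn`, `band_mean`, `band_sd`, `z`
#'   and `position` (within_1sd / within_3sd / outlier_high / outlier_low /
#'   uninformative).
#' @export
per_dbd_split <- function(dbd_table, envelope) {
  stopifnot(is.data.frame(dbd_table),
            all(c("dbd_class", "N", "F") %in% names(dbd_table)),
            inherits(envelope, "fn_envelope"))
  if (any(dbd_table$F > dbd_table$N)) {
    stop("F cannot exceed N within a DBD class", call. = FALSE)
  }
  bands <- envelope$bands[!is.na(envelope$bands$mean_fn), ]
  out <- dbd_table
  out$fn <- out$F / out$N
  out$band_mean <- stats::approx(log(bands$N), bands$mean_fn,
                                 xout = log(out$N), rule = 2)$y
  out$band_sd <- stats::approx(log(bands$N), bands$sd_fn,
                               xout = log(out$N), rule = 2)$y
  out$z <- (out$fn - out$band_mean) / out$band_sd
  out$position <- ifelse(
    out$N <= 1, "uninformative",
    ifelse(abs(out$z) <= 1, "within_1sd",
    ifelse(abs(out$z) <= 3, "within_3sd",
    ifelse(out$z > 3, "outlier_high", "outlier_low"))))
  out
}

#' Cross-species scaling of theta with repertoire size
#'
#' Fits `log(theta) ~ b * log(n_TF) + a` by ordinary least squares. The
#' exponent is an empirical description over the observed range only —
#' theta is bounded by 1, so the power law cannot extrapolate.
#'
#' @param species_fits data frame with columns `species`, `n_tf`, `theta`
#'   (and optionally `p_value` carried through).
#' @return A `species_scaling` object: `table` (per-species input, with any
#'   non-positive theta rows excluded), `exponent`, `se`, `fit` (the `lm`).
#' @examples
#' fit_theta_scaling(data.frame(
#'   species = c("a", "b"), n_tf = c(100, 1000),
#'   theta = c(0.2, 0.2 * 10^0.85))) # exponent exactly 0.85
#' @export
fit_theta_scaling <- function(species_fits) {
  stopifnot(is.data.frame(species_fits),
            all(c("species", "n_tf", "theta") %in% names(species_fits)))
  bad <- !is.finite(species_fits$theta) | species_fits$theta <= 0
  if (any(bad)) {
    warning(sprintf("excluding %d species with invalid theta", sum(bad)),
            call. = FALSE)
    species_fits <- species_fits[!bad, ]
  }
  if (nrow(species_fits) < 2L) {
    stop("need at least two species with valid theta", call. = FALSE)
  }
  fit <- stats::lm(log(theta) ~ log(n_tf), data = species_fits)
  cf <- suppressWarnings(summary(fit))$coefficients
  se <- if (nrow(species_fits) > 2L) cf["log(n_tf)", "Std. Error"] else NA_real_
  structure(
    list(table = species_fits,
         exponent = unname(stats::coef(fit)[["log(n_tf)"]]),
         se = se, fit = fit),
    class = "species_scaling"
  )
}

#' @export
print.species_scaling <- function(x, ...) {
  cat(sprintf(
    "theta ~ (# TFs)^b over %d species: b = %.4f (se %.4f)\n",
    nrow(x$table), x$exponent, x$se))
  invisible(x)
}
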