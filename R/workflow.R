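#' Full repertoire analysis: families, size law, theta fit
#'
#' Convenience wrapper chaining the pipeline on one species' TF records:
#' bipartite network, TF projection, motif families, size distribution and
#' the maximum-likelihood theta fit with bootstrap goodness of fit.
#'
#' @param records a `tf_dataset` (e.g. from [read_tf_table()]).
#' @param n_boot bootstrap replicates for the fit p-value (0 skips the
#'   bootstrap and reports only the point estimate).
#' @param seed integer seed for the bootstrap.
#' @return A `repertoire_summary` list: `n_tf` (PWM-carrying TFs),
#'   `n_pwm` (distinct motif IDs), `n_fam`, `largest` (largest family
#'   size), `kbar`, `theta`, `p_value` (NA when `n_boot = 0`), plus the
#'   intermediate `partition`, `sizes` and `graph`.
#' @export
repertoire_summary <- function(records, n_boot = 1000L, seed = 1L) {
  net <- tf_bipartite(records)
  g <- project_tf_network(net)
  dbd <- stats::setNames(net$tf_meta$dbd_class, net$tf_meta$tf_id)
  fam <- motif_families(g, dbd = dbd)
  s <- size_distribution(fam)
  th <- theta_mle(s)
  pval <- NA_real_
  if (n_boot > 0) {
    pval <- gof_pvalue(s, n_boot = n_boot, seed = seed)$p_value
  }
  structure(
    list(n_tf = length(net$tf_nodes), n_pwm = length(net$pwm_nodes),
         n_fam = s$F, largest = s$M, kbar = s$kbar, theta = th,
         p_value = pval, partition = fam, sizes = s, graph = g,
         network = net),
    class = "repertoire_summary"
  )
}

#' @export
print.repertoire_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Repertoire: %d TFs, %d PWMs -> %d motif families ",
           "(largest %d)\n  theta = %.4f (kbar = %.4f)%s\n"),
    x$n_tf, x$n_pwm, x$n_fam, x$largest, x$theta, x$kbar,
    if (is.na(x$p_value)) "" else sprintf(", GoF p = %.4g", x$p_value)))
  invisible(x)
}
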