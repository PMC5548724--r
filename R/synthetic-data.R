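#' Specification for a synthetic CIS-BP-like dataset
#'
#' Describes the ground truth of a generated TF repertoire: background
#' motif-family sizes drawn from the stationary BDI law at `theta`, an
#' optional set of planted over-expanded families (`spikes`), an optional
#' excess of size-1 families beyond what the law predicts
#' (`extra_singletons`), DBD-class labels spread over `n_dbd_classes`
#' classes, and optional per-class theta overrides (e.g. a low-theta,
#' fast-diversifying zinc-finger-like class).
#'
#' The defaults emulate the human-repertoire regime: theta = 0.74 over 424
#' background families, three planted spikes of sizes 41, 34 and 25, and
#' 50 excess singletons — so the generated totals approximate 900-odd TFs
#' while every family's origin stays known.
#'
#' @param theta background redundancy parameter in (0, 1).
#' @param n_families number of background families to draw.
#' @param spikes sizes of planted over-expanded families.
#' @param extra_singletons number of excess size-1 families.
#' @param pwms_per_family PWMs shared by every member of a family (each
#'   family's pool is unique, so planted families are exactly the
#'   connected components, and cliques).
#' @param n_dbd_classes number of DBD class labels for background families.
#' @param class_theta optional named numeric vector: DBD classes drawn at
#'   their own theta instead of the background one, each contributing
#'   `n_families / n_dbd_classes` families.
#' @param M truncation for the background size draw.
#' @param seed integer seed (fixtures are reproducible byte-for-byte).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(theta = 0.74, n_families = 424L,
                           spikes = c(41L, 34L, 25L),
                           extra_singletons = 50L,
                           pwms_per_family = 2L, n_dbd_classes = 8L,
                           class_theta = NULL, M = 2000L, seed = 1L) {
  check_theta(theta)
  stopifnot(n_families >= 1, extra_singletons >= 0, pwms_per_family >= 1,
            n_dbd_classes >= 1, all(spikes >= 1))
  if (!is.null(class_theta)) {
    stopifnot(!is.null(names(class_theta)), all(class_theta > 0),
              all(class_theta < 1))
  }
  structure(
    list(theta = theta, n_families = as.integer(n_families),
         spikes = as.integer(spikes),
         extra_singletons = as.integer(extra_singletons),
         pwms_per_family = as.integer(pwms_per_family),
         n_dbd_classes = as.integer(n_dbd_classes),
         class_theta = class_theta, M = as.integer(M),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# sharpened random profile: one dominant base per position plus noise
random_pwm <- function(motif_id, L = sample(6:10, 1)) {
  dom <- sample.int(4L, L, replace = TRUE)
  probs <- matrix(stats::runif(L * 4, 0.01, 0.05), nrow = L)
  probs[cbind(seq_len(L), dom)] <- 1
  probs <- probs / rowSums(probs)
  pwm_matrix(motif_id, probs)
}

#' Generate a CIS-BP-like dataset with known ground truth
#'
#' Draws family sizes per the spec, assigns each family a unique pool of
#' PWMs shared by all members (so the shared-ID projection recovers the
#' planted partition exactly, as cliques), attaches DBD labels, and builds
#' sharpened random PWM matrices of length 6-10. The ground-truth table
#' records every family's size, origin (background / spike /
#' singleton_excess), DBD class and the theta it was drawn at.
#'
#' @param spec a [synthetic_spec()].
#' @return A `synthetic_dataset`: `records` (a `tf_dataset`), `pwms`
#'   (named list of `pwm_matrix`), `truth` (data frame family_id, size,
#'   origin, dbd_class, theta, member tf ids as comma string), `spec`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  classes <- sprintf("DBD_%02d", seq_len(spec$n_dbd_classes))
  override <- names(spec$class_theta)
  if (length(setdiff(override, classes)) > 0L) {
    stop("class_theta names must be among the generated DBD classes",
         call. = FALSE)
  }
  per_class <- rep(spec$n_families %/% spec$n_dbd_classes,
                   spec$n_dbd_classes)
  per_class[seq_len(spec$n_families %% spec$n_dbd_classes)] <-
    per_class[seq_len(spec$n_families %% spec$n_dbd_classes)] + 1L
  names(per_class) <- classes
  fam_sizes <- integer(0); fam_dbd <- character(0); fam_theta <- numeric(0)
  for (cl in classes) {
    th <- if (cl %in% override) spec$class_theta[[cl]] else spec$theta
    if (per_class[[cl]] == 0L) next
    fam_sizes <- c(fam_sizes, bdi_sample_sizes(per_class[[cl]], th,
                                               M = spec$M))
    fam_dbd <- c(fam_dbd, rep(cl, per_class[[cl]]))
    fam_theta <- c(fam_theta, rep(th, per_class[[cl]]))
  }
  origin <- rep("background", length(fam_sizes))
  if (length(spec$spikes) > 0L) {
    fam_sizes <- c(fam_sizes, spec$spikes)
    fam_dbd <- c(fam_dbd, rep_len(classes, length(spec$spikes)))
    fam_theta <- c(fam_theta, rep(NA_real_, length(spec$spikes)))
    origin <- c(origin, rep("spike", length(spec$spikes)))
  }
  if (spec$extra_singletons > 0L) {
    fam_sizes <- c(fam_sizes, rep(1L, spec$extra_singletons))
    fam_dbd <- c(fam_dbd, sample(classes, spec$extra_singletons,
                                 replace = TRUE))
    fam_theta <- c(fam_theta, rep(NA_real_, spec$extra_singletons))
    origin <- c(origin, rep("singleton_excess", spec$extra_singletons))
  }
  n_fam <- length(fam_sizes)
  fam_ids <- sprintf("FAM%04d", seq_len(n_fam))
  tf_counter <- 0L; pwm_counter <- 0L
  records <- list(); pwms <- list(); members <- character(n_fam)
  for (k in seq_len(n_fam)) {
    pool <- sprintf("M%05d", pwm_counter + seq_len(spec$pwms_per_family))
    pwm_counter <- pwm_counter + spec$pwms_per_family
    for (mid in pool) pwms[[mid]] <- random_pwm(mid)
    tfs <- sprintf("T%04d", tf_counter + seq_len(fam_sizes[k]))
    tf_counter <- tf_counter + fam_sizes[k]
    members[k] <- paste(tfs, collapse = ",")
    for (tf in tfs) {
      records[[tf]] <- list(
        tf_id = tf, tf_name = paste0("tf_", tolower(tf)),
        species = "Synthetica_exemplaris", dbd_class = fam_dbd[k],
        pwm_ids = pool,
        provenance = stats::setNames(
          rep(c("direct", "inferred"),
              c(1L, length(pool) - 1L)), pool))
    }
  }
  truth <- data.frame(family_id = fam_ids, size = fam_sizes,
                      origin = origin, dbd_class = fam_dbd,
                      theta = fam_theta, members = members)
  structure(
    list(records = structure(unname(records), class = "tf_dataset"),
         pwms = pwms, truth = truth, spec = spec),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic dataset: %d TFs in %d families (%d spikes, %d excess singletons)\n",
    sum(x$truth$size), nrow(x$truth), sum(x$truth$origin == "spike"),
    sum(x$truth$origin == "singleton_excess")))
  invisible(x)
}

#' Structurally perturb a synthetic dataset
#'
#' Supported operations: `add_spike` (plant one new family of
#' `params$size` members), `add_singletons` (plant `params$n` new size-1
#' families), `merge_families` (give two families a shared PWM so they
#' become one connected component; `params$families` = two family ids).
#' Ground truth is updated alongside.
#'
#' @param dataset a `synthetic_dataset`.
#' @param op one of `"add_spike"`, `"add_singletons"`, `"merge_families"`.
#' @param params operation parameters, see above.
#' @param seed integer seed for the new PWM matrices.
#' @return The perturbed `synthetic_dataset`.
#' @export
perturb_dataset <- function(dataset, op, params = list(), seed = 1L) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  set.seed(seed)
  next_id <- function(prefix, existing, width) {
    n <- max(0L, as.integer(sub(prefix, "", existing)))
    sprintf(paste0(prefix, "%0", width, "d"), max(n) + 1L)
  }
  tf_ids <- vapply(dataset$records, `[[`, character(1), "tf_id")
  add_family <- function(ds, size, origin) {
    mid <- sprintf("M%05d",
                   max(as.integer(sub("M", "", names(ds$pwms)))) + 1L)
    ds$pwms[[mid]] <- random_pwm(mid)
    base <- max(as.integer(sub("T", "", tf_ids)))
    tfs <- sprintf("T%04d", base + seq_len(size))
    tf_ids <<- c(tf_ids, tfs)
    for (tf in tfs) {
      ds$records[[length(ds$records) + 1L]] <- list(
        tf_id = tf, tf_name = paste0("tf_", tolower(tf)),
        species = "Synthetica_exemplaris", dbd_class = "DBD_01",
        pwm_ids = mid,
        provenance = stats::setNames("direct", mid))
    }
    class(ds$records) <- "tf_dataset"
    ds$truth <- rbind(ds$truth, data.frame(
      family_id = sprintf("FAM%04d", nrow(ds$truth) + 1L),
      size = size, origin = origin, dbd_class = "DBD_01",
      theta = NA_real_, members = paste(tfs, collapse = ",")))
    ds
  }
  out <- switch(
    op,
    add_spike = add_family(dataset, as.integer(params$size), "spike"),
    add_singletons = {
      ds <- dataset
      for (i in seq_len(as.integer(params$n))) {
        ds <- add_family(ds, 1L, "singleton_excess")
      }
      ds
    },
    merge_families = {
      ds <- dataset
      fams <- params$families
      stopifnot(length(fams) == 2L, all(fams %in% ds$truth$family_id))
      mid <- sprintf("M%05d",
                     max(as.integer(sub("M", "", names(ds$pwms)))) + 1L)
      ds$pwms[[mid]] <- random_pwm(mid)
      touched <- unlist(strsplit(
        ds$truth$members[ds$truth$family_id %in% fams], ","))
      ds$records <- structure(lapply(ds$records, function(r) {
        if (r$tf_id %in% touched) {
          r$pwm_ids <- c(r$pwm_ids, mid)
          r$provenance <- c(r$provenance,
                            stats::setNames("inferred", mid))
        }
        r
      }), class = "tf_dataset")
      i <- which(ds$truth$family_id %in% fams)
      merged <- data.frame(
        family_id = ds$truth$family_id[i[1]],
        size = sum(ds$truth$size[i]), origin = "merged",
        dbd_class = ds$truth$dbd_class[i[1]], theta = NA_real_,
        members = paste(ds$truth$members[i], collapse = ","))
      ds$truth <- rbind(ds$truth[-i, ], merged)
      ds
    },
    stop(sprintf("unknown perturbation '%s'", op), call. = FALSE)
  )
  out
}

#' Write a synthetic dataset to disk in the CIS-BP dialect
#'
#' @param dataset a `synthetic_dataset`.
#' @param out_dir output directory; the ground-truth table is written
#'   alongside as `ground_truth.tsv`.
#' @return Invisibly, the written paths.
#' @export
write_synthetic <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  paths <- write_cisbp_like(dataset$records, dataset$pwms, out_dir)
  gt <- file.path(out_dir, "ground_truth.tsv")
  utils::write.table(dataset$truth, gt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, gt))
}
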