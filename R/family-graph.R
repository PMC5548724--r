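#' Build the TF-PWM bipartite association network
#'
#' Two node classes — TFs and PWM identifiers — with an edge wherever the
#' annotation associates a TF to a motif ID. TFs without any PWM are
#' excluded by default (they cannot join a family and the reference
#' repertoires count only PWM-carrying TFs); pass `keep_empty = TRUE` to
#' retain them as isolated TF nodes.
#'
#' @param records a `tf_dataset` (see [read_tf_table()]).
#' @param keep_empty keep TFs whose PWM set is empty.
#' @return A `tf_bipartite` object: `tf_nodes`, `pwm_nodes`, `edges` (data
#'   frame tf_id, motif_id), and `tf_meta` (tf_id, dbd_class, species).
#' @export
tf_bipartite <- function(records, keep_empty = FALSE) {
  stopifnot(inherits(records, "tf_dataset") || is.list(records))
  keep <- vapply(records, function(r) keep_empty || length(r$pwm_ids) > 0,
                 logical(1))
  records <- records[keep]
  tf_ids <- vapply(records, `[[`, character(1), "tf_id")
  if (anyDuplicated(tf_ids)) {
    stop("duplicate TF ids in dataset", call. = FALSE)
  }
  edges <- do.call(rbind, lapply(records, function(r) {
    if (length(r$pwm_ids) == 0L) return(NULL)
    data.frame(tf_id = r$tf_id, motif_id = r$pwm_ids)
  }))
  if (is.null(edges)) {
    edges <- data.frame(tf_id = character(0), motif_id = character(0))
  }
  meta <- data.frame(
    tf_id = tf_ids,
    dbd_class = vapply(records, `[[`, character(1), "dbd_class"),
    species = vapply(records, `[[`, character(1), "species"))
  structure(
    list(tf_nodes = tf_ids, pwm_nodes = unique(edges$motif_id),
         edges = edges, tf_meta = meta),
    class = "tf_bipartite"
  )
}

#' @export
print.tf_bipartite <- function(x, ...) {
  cat(sprintf("TF-PWM bipartite network: %d TFs, %d PWMs, %d associations\n",
              length(x$tf_nodes), length(x$pwm_nodes), nrow(x$edges)))
  invisible(x)
}

#' Project the bipartite network onto its TF nodes
#'
#' Two TFs are linked iff they share at least one PWM identifier (identity
#' of motif IDs, not similarity of matrices). TFs sharing no PWM with
#' anyone remain as isolated vertices.
#'
#' @param net a `tf_bipartite` object.
#' @return An undirected simple [igraph::graph] on the TF nodes.
#' @export
project_tf_network <- function(net) {
  stopifnot(inherits(net, "tf_bipartite"))
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(net$tf_nodes), name = net$tf_nodes)
  if (nrow(net$edges) > 0L) {
    by_pwm <- split(net$edges$tf_id, net$edges$motif_id)
    pair_list <- lapply(by_pwm, function(tfs) {
      tfs <- unique(tfs)
      if (length(tfs) < 2L) return(NULL)
      t(utils::combn(sort(tfs), 2L))
    })
    pairs <- do.call(rbind, pair_list)
    if (!is.null(pairs) && nrow(pairs) > 0L) {
      pairs <- unique(as.data.frame(pairs))
      g <- igraph::add_edges(g, as.vector(t(as.matrix(pairs))))
    }
  }
  igraph::simplify(g)
}

#' Extract motif families as connected components
#'
#' A motif family is a connected component of the TF projection: TFs that
#' share at least one PWM directly or through intermediaries. Isolated TFs
#' form size-1 families.
#'
#' @param tf_graph undirected TF graph from [project_tf_network()].
#' @param dbd optional named character vector (tf_id -> DBD class) used to
#'   record each family's majority DBD class.
#' @return A `motif_partition`: `families` (list of character member
#'   vectors, largest first), `sizes`, `membership` (named family index per
#'   TF), and `family_dbd` (majority DBD per family, if `dbd` given).
#' @export
motif_families <- function(tf_graph, dbd = NULL) {
  stopifnot(inherits(tf_graph, "igraph"))
  if (igraph::vcount(tf_graph) == 0L) {
    return(structure(list(families = list(), sizes = integer(0),
                          membership = integer(0), family_dbd = NULL),
                     class = "motif_partition"))
  }
  comp <- igraph::components(tf_graph)
  names_v <- igraph::V(tf_graph)$name
  fams <- split(names_v, comp$membership)
  ord <- order(lengths(fams), decreasing = TRUE)
  fams <- unname(fams[ord])
  membership <- stats::setNames(rep(NA_integer_, length(names_v)), names_v)
  for (i in seq_along(fams)) membership[fams[[i]]] <- i
  fam_dbd <- NULL
  if (!is.null(dbd)) {
    fam_dbd <- vapply(fams, function(m) {
      cls <- dbd[m]
      names(sort(table(cls), decreasing = TRUE))[1]
    }, character(1))
  }
  structure(
    list(families = fams, sizes = lengths(fams), membership = membership,
         family_dbd = fam_dbd),
    class = "motif_partition"
  )
}

#' @export
print.motif_partition <- function(x, ...) {
  cat(sprintf(
    "Motif family partition: %d TFs in %d families (largest %d)\n",
    sum(x$sizes), length(x$families),
    if (length(x$sizes)) max(x$sizes) else 0L))
  invisible(x)
}

#' Family-size distribution of a partition
#'
#' @param partition a `motif_partition` (or vector of sizes).
#' @return A [size_sample()] object.
#' @export
size_distribution <- function(partition) {
  if (inherits(partition, "motif_partition")) {
    return(size_sample(partition$sizes))
  }
  size_sample(partition)
}

#' Per-DBD-class element and family counts
#'
#' Restricts the projection to each DBD class in turn and counts its TFs
#' (`N`) and motif families (`F`) — the inputs of the per-class neutral
#' comparison. Families are recomputed within the class subgraph, mirroring
#' the view of each DBD class as an independent instance of the process.
#'
#' @param tf_graph TF projection graph.
#' @param dbd named character vector tf_id -> DBD class.
#' @return Data frame with `dbd_class`, `N`, `F`.
#' @export
dbd_class_counts <- function(tf_graph, dbd) {
  stopifnot(inherits(tf_graph, "igraph"))
  v <- igraph::V(tf_graph)$name
  dbd <- dbd[v]
  out <- lapply(split(v, dbd), function(members) {
    sub <- igraph::induced_subgraph(tf_graph, members)
    data.frame(N = length(members),
               F = igraph::components(sub)$no)
  })
  df <- do.call(rbind, out)
  df <- cbind(dbd_class = names(out), df)
  rownames(df) <- NULL
  df
}

# per-position log-probability score columns with pseudocount on zeros
pwm_log_scores <- function(probs, pseudocount = 1e-3) {
  p <- probs
  p[p == 0] <- pseudocount
  log(p)
}

# enumerate scores of all 4^L words for an L x 4 log-score matrix;
# word index encodes bases most-significant-first (A=0, C=1, G=2, T=3)
enumerate_word_scores <- function(logs) {
  L <- nrow(logs)
  if (L > 12) stop("word enumeration capped at L = 12", call. = FALSE)
  scores <- 0
  for (i in seq_len(L)) {
    scores <- rep(scores, each = 4) + rep(logs[i, ], times = 4^(i - 1))
  }
  scores
}

# word set: indices of words at or above min + frac * (max - min)
threshold_word_set <- function(logs, frac) {
  sc <- enumerate_word_scores(logs)
  lo <- sum(apply(logs, 1, min))
  hi <- sum(apply(logs, 1, max))
  which(sc >= lo + frac * (hi - lo))
}

revcomp_pwm <- function(probs) {
  # reverse positions and complement bases (A<->T, C<->G)
  probs[rev(seq_len(nrow(probs))), c("T", "G", "C", "A"), drop = FALSE]
}

#' Jaccard similarity between two PWMs via exhaustive word sets
#'
#' For each relative offset of the shorter matrix along the longer one, the
#' set of words recognized by each matrix on the shared window is
#' enumerated exhaustively (all `4^L` words of the overlap length; `L <= 12`
#' enforced). A word is recognized when its log-probability score is at or
#' above `word_threshold` of the way from the window's minimum to its
#' maximum attainable score (the convention of `Biostrings::matchPWM`'s
#' `min.score`), with a pseudocount of 1e-3 on zero entries. The reported
#' similarity is the maximum Jaccard index `|W_a n W_b| / |W_a u W_b|`
#' over offsets, and over the reverse complement of `b` when
#' `include_revcomp` is on (strand and register are not identifiable from
#' the data model).
#'
#' @param a,b `pwm_matrix` objects.
#' @param word_threshold fraction in (0, 1] of the score range.
#' @param include_revcomp also try the reverse complement of `b`.
#' @param pseudocount value substituted for zero probabilities before logs.
#' @return Similarity in `[0, 1]`; symmetric in its arguments. Returns 0
#'   with a warning if both word sets are empty at every offset.
#' @export
pwm_jaccard <- function(a, b, word_threshold = 0.8, include_revcomp = TRUE,
                        pseudocount = 1e-3) {
  stopifnot(inherits(a, "pwm_matrix"), inherits(b, "pwm_matrix"))
  if (!is.numeric(word_threshold) || word_threshold <= 0 ||
      word_threshold > 1) {
    stop("word_threshold must lie in (0, 1]", call. = FALSE)
  }
  orients <- list(b$probs)
  if (include_revcomp) orients <- c(orients, list(revcomp_pwm(b$probs)))
  best <- NA_real_
  any_words <- FALSE
  for (bp in orients) {
    # slide the shorter matrix over the longer; compare on the overlap
    if (a$L <= nrow(bp)) { short <- a$probs; long <- bp }
    else { short <- bp; long <- a$probs }
    Ls <- nrow(short); Ll <- nrow(long)
    for (off in 0:(Ll - Ls)) {
      wa <- threshold_word_set(
        pwm_log_scores(short, pseudocount), word_threshold)
      wb <- threshold_word_set(
        pwm_log_scores(long[off + seq_len(Ls), , drop = FALSE], pseudocount),
        word_threshold)
      un <- length(union(wa, wb))
      if (un > 0L) {
        any_words <- TRUE
        j <- length(intersect(wa, wb)) / un
        if (is.na(best) || j > best) best <- j
      }
    }
  }
  if (!any_words) {
    warning("both word sets empty at every offset; similarity defined as 0",
            call. = FALSE)
    return(0)
  }
  best
}

#' Pairwise PWM similarity matrix
#'
#' @param pwms named list of `pwm_matrix` objects.
#' @param ... passed to [pwm_jaccard()].
#' @return Symmetric matrix of Jaccard similarities (diagonal 1).
#' @export
pwm_similarity_matrix <- function(pwms, ...) {
  n <- length(pwms)
  ids <- vapply(pwms, `[[`, character(1), "motif_id")
  S <- diag(1, n)
  dimnames(S) <- list(ids, ids)
  if (n < 2L) return(S)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      S[i, j] <- S[j, i] <- pwm_jaccard(pwms[[i]], pwms[[j]], ...)
    }
  }
  S
}

#' Robustness sweep: augment the TF network by PWM similarity
#'
#' Lowers a similarity threshold and, at each level, adds a TF-TF link
#' wherever some pair of their PWMs has Jaccard similarity at or above the
#' threshold. New links are classified as internal (both TFs already in the
#' same motif family) or cross-family; the family organization is robust
#' when cross-family links appear only at very low thresholds.
#'
#' @param net a `tf_bipartite` network.
#' @param partition the `motif_partition` built from shared PWM ids.
#' @param pwms named list of `pwm_matrix` for (at least some of) the motif
#'   ids in `net`; pairs with missing matrices are skipped and coverage is
#'   reported.
#' @param thresholds descending vector of similarity thresholds.
#' @param ... passed to [pwm_jaccard()].
#' @return An `augmentation_report`: data frame with one row per threshold
#'   (`threshold`, `new_links`, `internal_links`, `cross_family_links`)
#'   plus attributes `coverage` (fraction of PWM pairs with matrices) and
#'   `pair_details`.
#' @export
augment_by_similarity <- function(net, partition, pwms, thresholds, ...) {
  stopifnot(inherits(net, "tf_bipartite"),
            inherits(partition, "motif_partition"))
  thresholds <- sort(thresholds, decreasing = TRUE)
  have <- intersect(net$pwm_nodes,
                    vapply(pwms, `[[`, character(1), "motif_id"))
  n_pairs_total <- choose(length(net$pwm_nodes), 2)
  coverage <- if (n_pairs_total > 0) choose(length(have), 2) / n_pairs_total
              else 1
  if (length(have) < length(net$pwm_nodes)) {
    warning(sprintf(
      "matrices available for %d of %d PWMs; uncovered pairs skipped",
      length(have), length(net$pwm_nodes)), call. = FALSE)
  }
  pwms <- pwms[match(have, vapply(pwms, `[[`, character(1), "motif_id"))]
  S <- pwm_similarity_matrix(pwms, ...)
  tf_of <- split(net$edges$tf_id, net$edges$motif_id)
  existing <- paste_pairs(project_edge_pairs(net))
  fam <- partition$membership
  rows <- lapply(thresholds, function(th) {
    hit <- which(S >= th & upper.tri(S), arr.ind = TRUE)
    links <- unique(do.call(rbind, lapply(seq_len(nrow(hit)), function(k) {
      tfs_a <- unique(tf_of[[rownames(S)[hit[k, 1]]]])
      tfs_b <- unique(tf_of[[colnames(S)[hit[k, 2]]]])
      eg <- expand.grid(a = tfs_a, b = tfs_b, stringsAsFactors = FALSE)
      eg <- eg[eg$a != eg$b, , drop = FALSE]
      if (nrow(eg) == 0L) return(NULL)
      t(apply(as.matrix(eg), 1, sort))
    })))
    if (is.null(links) || nrow(links) == 0L) {
      return(data.frame(threshold = th, new_links = 0L,
                        internal_links = 0L, cross_family_links = 0L))
    }
    keys <- paste(links[, 1], links[, 2], sep = "\r")
    new <- links[!(keys %in% existing), , drop = FALSE]
    cross <- if (nrow(new) > 0L) {
      sum(fam[new[, 1]] != fam[new[, 2]], na.rm = TRUE)
    } else 0L
    data.frame(threshold = th, new_links = nrow(new),
               internal_links = nrow(new) - cross,
               cross_family_links = cross)
  })
  out <- do.call(rbind, rows)
  attr(out, "coverage") <- coverage
  class(out) <- c("augmentation_report", class(out))
  out
}

# helper: edge pairs of the shared-ID projection, sorted within pair
project_edge_pairs <- function(net) {
  g <- project_tf_network(net)
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0L) return(el)
  t(apply(el, 1, sort))
}

paste_pairs <- function(el) {
  if (is.null(el) || nrow(el) == 0L) return(character(0))
  paste(el[, 1], el[, 2], sep = "\r")
}
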