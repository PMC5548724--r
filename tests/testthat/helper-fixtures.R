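# small in-code fixtures and independent oracles shared across test files

tf_rec <- function(id, motifs = character(0), dbd = "DBD_X",
                   species = "Synthetica_exemplaris") {
  prov <- if (length(motifs)) {
    stats::setNames(rep("direct", length(motifs)), motifs)
  } else character(0)
  list(tf_id = id, tf_name = tolower(id), species = species,
       dbd_class = dbd, pwm_ids = motifs, provenance = prov)
}

tf_ds <- function(...) structure(list(...), class = "tf_dataset")

# brute-force union-find over TF pairs sharing a PWM: independent oracle
# for the projection + connected-components pipeline
uf_families <- function(records) {
  ids <- vapply(records, `[[`, character(1), "tf_id")
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  n <- length(records)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (length(intersect(records[[i]]$pwm_ids,
                           records[[j]]$pwm_ids)) > 0) {
        parent[find(ids[i])] <- find(ids[j])
      }
    }
  }
  roots <- vapply(ids, find, character(1))
  unname(lapply(split(ids, roots), sort))
}

# independent naive Jaccard oracle: explicit loops, explicit word strings
naive_pwm_jaccard <- function(a, b, frac = 0.8, revcomp = TRUE,
                              pseudo = 1e-3) {
  word_set <- function(probs) {
    p <- probs
    p[p == 0] <- pseudo
    lg <- log(p)
    L <- nrow(lg)
    words <- do.call(expand.grid, rep(list(1:4), L))
    sc <- apply(words, 1, function(w) sum(lg[cbind(seq_len(L), as.integer(w))]))
    lo <- sum(apply(lg, 1, min)); hi <- sum(apply(lg, 1, max))
    keep <- sc >= lo + frac * (hi - lo)
    apply(words[keep, , drop = FALSE], 1, paste, collapse = "")
  }
  rc <- function(probs) probs[rev(seq_len(nrow(probs))), c(4, 3, 2, 1)]
  best <- NA_real_
  orients <- list(b$probs)
  if (revcomp) orients <- c(orients, list(rc(b$probs)))
  for (bp in orients) {
    if (a$L <= nrow(bp)) { short <- a$probs; long <- bp }
    else { short <- bp; long <- a$probs }
    for (off in 0:(nrow(long) - nrow(short))) {
      wa <- word_set(short)
      wb <- word_set(long[off + seq_len(nrow(short)), , drop = FALSE])
      un <- length(union(wa, wb))
      if (un > 0) {
        j <- length(intersect(wa, wb)) / un
        if (is.na(best) || j > best) best <- j
      }
    }
  }
  if (is.na(best)) 0 else best
}

# independent line-by-line transcription of the master equation used as an
# oracle for bdi_master_rhs
naive_master_rhs <- function(f, lambda, delta, mu, nu, N) {
  M <- length(f)
  d <- numeric(M)
  d[1] <- -(lambda + delta + mu) * f[1] + 2 * (delta + mu) * f[2] +
    mu * N + nu
  if (M > 2) {
    for (i in 2:(M - 1)) {
      d[i] <- (i - 1) * lambda * f[i - 1] -
        i * (lambda + delta + mu) * f[i] +
        (i + 1) * (delta + mu) * f[i + 1]
    }
  }
  d[M] <- (M - 1) * lambda * f[M - 1] - M * (delta + mu) * f[M]
  d
}

# strict consensus PWM for a base string like "ACGT"
consensus_pwm <- function(id, word) {
  bases <- strsplit(word, "")[[1]]
  idx <- match(bases, c("A", "C", "G", "T"))
  probs <- matrix(0, nrow = length(bases), ncol = 4)
  probs[cbind(seq_along(idx), idx)] <- 1
  pwm_matrix(id, probs)
}

# quantile-matched sample: counts round(F * CDF(i)) - round(F * CDF(i-1)),
# so the ECDF tracks the model CDF within 0.5/F everywhere
design_sample <- function(theta, F, imax = 200) {
  cdf <- bdi_cdf(seq_len(imax), theta)
  counts <- diff(c(0, round(F * cdf)))
  rep(seq_len(imax), counts)
}
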