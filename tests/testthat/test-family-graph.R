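test_that("TF projection links exactly the PWM-sharing pairs", {
  ds <- tf_ds(tf_rec("A", "m1"), tf_rec("B", "m1"), tf_rec("C", "m2"))
  g <- project_tf_network(tf_bipartite(ds))
  expect_equal(igraph::ecount(g), 1)
  expect_true(igraph::are_adjacent(g, "A", "B"))
  expect_equal(igraph::degree(g)[["C"]], 0)
  # projection is not transitive
  ds2 <- tf_ds(tf_rec("A", "m1"), tf_rec("B", c("m1", "m2")),
               tf_rec("C", "m2"))
  g2 <- project_tf_network(tf_bipartite(ds2))
  expect_true(igraph::are_adjacent(g2, "A", "B"))
  expect_true(igraph::are_adjacent(g2, "B", "C"))
  expect_false(igraph::are_adjacent(g2, "A", "C"))
  expect_equal(sum(igraph::which_loop(g2)), 0)
  # but components close transitively into one family of 3
  fam <- motif_families(g2)
  expect_equal(length(fam$families), 1)
  expect_setequal(fam$families[[1]], c("A", "B", "C"))
})

test_that("isolated TFs form size-1 families; empty graphs empty partitions", {
  ds <- tf_ds(tf_rec("A", "m1"), tf_rec("B", "m2"), tf_rec("C", "m3"))
  fam <- motif_families(project_tf_network(tf_bipartite(ds)))
  expect_equal(fam$sizes, rep(1L, 3))
  empty <- motif_families(igraph::make_empty_graph(directed = FALSE))
  expect_equal(length(empty$families), 0)
})

test_that("components agree with brute-force union-find on random graphs", {
  set.seed(41)
  for (rep in 1:15) {
    n_tf <- sample(4:12, 1)
    n_pwm <- sample(2:8, 1)
    recs <- lapply(seq_len(n_tf), function(i) {
      k <- sample(0:min(3, n_pwm), 1)
      tf_rec(sprintf("T%02d", i),
             if (k > 0) sample(sprintf("m%d", seq_len(n_pwm)), k)
             else character(0))
    })
    ds <- structure(recs, class = "tf_dataset")
    fam <- motif_families(project_tf_network(tf_bipartite(ds,
                                                          keep_empty = TRUE)))
    got <- lapply(fam$families, sort)
    want <- uf_families(recs)
    expect_setequal(vapply(got, paste, character(1), collapse = ","),
                    vapply(want, paste, character(1), collapse = ","))
  }
})

test_that("size distributions summarize partitions correctly", {
  s <- size_distribution(c(3, 1))
  expect_equal(s$N, 4); expect_equal(s$F, 2); expect_equal(s$kbar, 2)
  expect_equal(unname(s$f[c("1", "3")]), c(1L, 1L))
  # partition invariants: sum i f_i = N, sum f_i = F, M <= N
  set.seed(2)
  sizes <- bdi_sample_sizes(100, 0.7, M = 1000)
  ss <- size_sample(sizes)
  expect_equal(sum(as.integer(names(ss$f)) * ss$f), ss$N)
  expect_equal(sum(ss$f), ss$F)
  expect_lte(ss$M, ss$N)
})

test_that("family majority DBD class is recorded", {
  ds <- tf_ds(tf_rec("A", "m1", dbd = "Fork"), tf_rec("B", "m1", dbd = "Fork"),
              tf_rec("C", "m1", dbd = "Zn"), tf_rec("D", "m9", dbd = "Zn"))
  net <- tf_bipartite(ds)
  dbd <- setNames(net$tf_meta$dbd_class, net$tf_meta$tf_id)
  fam <- motif_families(project_tf_network(net), dbd = dbd)
  expect_equal(fam$family_dbd[[1]], "Fork")
  counts <- dbd_class_counts(project_tf_network(net), dbd)
  expect_equal(counts$N[counts$dbd_class == "Zn"], 2)
  expect_equal(counts$F[counts$dbd_class == "Zn"], 2)
  expect_equal(counts$F[counts$dbd_class == "Fork"], 1)
})

test_that("PWM Jaccard is symmetric, 1 on identity, 0 on disjoint consensi", {
  a <- consensus_pwm("a", "AAAA")
  b <- consensus_pwm("b", "CCCC")
  expect_equal(pwm_jaccard(a, a), 1)
  expect_equal(pwm_jaccard(a, b, include_revcomp = FALSE), 0)
  set.seed(50)
  for (rep in 1:5) {
    p1 <- pwm_matrix("p1", t(rmultinom(5, 60, rep(0.25, 4))) / 60)
    p2 <- pwm_matrix("p2", t(rmultinom(5, 60, rep(0.25, 4))) / 60)
    expect_equal(pwm_jaccard(p1, p2, 0.7), pwm_jaccard(p2, p1, 0.7))
  }
  expect_error(pwm_jaccard(a, b, word_threshold = 0), "threshold")
})

test_that("PWM Jaccard matches exhaustive word enumeration", {
  # two 6-mers differing in one strict position, plus soft random profiles
  a <- consensus_pwm("a", "ACGTAC")
  b <- consensus_pwm("b", "ACGTAT")
  expect_equal(pwm_jaccard(a, b, 0.8), naive_pwm_jaccard(a, b, 0.8))
  set.seed(51)
  for (rep in 1:4) {
    La <- sample(4:6, 1); Lb <- sample(4:6, 1)
    pa <- pwm_matrix("a", t(rmultinom(La, 40, c(0.5, 0.2, 0.2, 0.1))) / 40)
    pb <- pwm_matrix("b", t(rmultinom(Lb, 40, c(0.5, 0.2, 0.2, 0.1))) / 40)
    for (fr in c(0.6, 0.9)) {
      expect_equal(pwm_jaccard(pa, pb, fr), naive_pwm_jaccard(pa, pb, fr))
    }
  }
  # reverse-complement orientation is detected
  fwd <- consensus_pwm("f", "AACGTT")
  rc <- consensus_pwm("r", "AACGTT") # palindrome: rc identical
  expect_equal(pwm_jaccard(fwd, rc, include_revcomp = TRUE), 1)
})

test_that("similarity augmentation separates internal from cross links", {
  # two families: identical PWMs within the first, a weakly similar
  # motif in the second (pairwise Jaccard known from the enumeration oracle)
  ds <- tf_ds(tf_rec("A", "mA1"), tf_rec("B", c("mA1", "mA2")),
              tf_rec("C", "mC1"), tf_rec("D", "mC1"))
  pwms <- list(mA1 = consensus_pwm("mA1", "AAAAAA"),
               mA2 = consensus_pwm("mA2", "AAAAAA"),
               mC1 = consensus_pwm("mC1", "AAACCC"))
  net <- tf_bipartite(ds)
  fam <- motif_families(project_tf_network(net))
  rep_hi <- augment_by_similarity(net, fam, pwms, thresholds = c(1.0, 0.9),
                                  word_threshold = 0.5,
                                  include_revcomp = FALSE)
  # duplicate-PWM family: all added links internal, none cross-family
  expect_true(all(rep_hi$cross_family_links == 0))
  # once the threshold drops below the known cross-pool similarity the
  # two families get bridged
  j_cross <- naive_pwm_jaccard(pwms$mA1, pwms$mC1, 0.5, revcomp = FALSE)
  expect_gt(j_cross, 0)
  rep_all <- augment_by_similarity(net, fam, pwms,
                                   thresholds = c(1.0, 0.9 * j_cross),
                                   word_threshold = 0.5,
                                   include_revcomp = FALSE)
  expect_equal(rep_all$cross_family_links[rep_all$threshold == 1.0], 0)
  expect_gt(rep_all$cross_family_links[2], 0)
  # counts are monotone as the threshold decreases
  expect_true(all(diff(rep_all$new_links) >= 0))
  # missing matrices are skipped with a coverage warning
  expect_warning(
    cov <- augment_by_similarity(net, fam, pwms["mA1"],
                                 thresholds = 1.0,
                                 include_revcomp = FALSE),
    "matrices available")
  expect_lt(attr(cov, "coverage"), 1)
})
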