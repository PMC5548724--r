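test_that("a written dataset reads back record for record", {
  ds <- tf_ds(tf_rec("TF1", c("M1", "M2")), tf_rec("TF2", "M1"),
              tf_rec("TF3", "M3", dbd = "Homeodomain"))
  pwms <- lapply(c("M1", "M2", "M3"), function(id) {
    consensus_pwm(id, "ACGTAC")
  })
  dir <- withr::local_tempdir()
  paths <- write_cisbp_like(ds, pwms, dir)
  expect_equal(length(paths), 4) # table + three matrices
  back <- read_cisbp_dir(dir, quiet = TRUE)
  expect_equal(length(back$records), 3)
  got <- back$records[[which(vapply(back$records, `[[`, character(1),
                                    "tf_id") == "TF1")]]
  expect_setequal(got$pwm_ids, c("M1", "M2"))
  expect_equal(got$dbd_class, "DBD_X")
  expect_equal(sort(names(back$pwms)), c("M1", "M2", "M3"))
  expect_equal(back$pwms$M2$L, 6)
  # writing the read-back dataset reproduces the files byte for byte
  dir2 <- withr::local_tempdir()
  write_cisbp_like(back$records, unname(back$pwms), dir2)
  f1 <- file.path(dir, "TF_Information.txt")
  f2 <- file.path(dir2, "TF_Information.txt")
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(file.path(dir, "pwms", "M1.txt")),
                   readLines(file.path(dir2, "pwms", "M1.txt")))
})

test_that("writing the same dataset twice is byte-identical", {
  ds <- tf_ds(tf_rec("TF1", "M1"))
  p <- list(consensus_pwm("M1", "AAAA"))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cisbp_like(ds, p, d1)
  write_cisbp_like(ds, p, d2)
  expect_identical(readLines(file.path(d1, "TF_Information.txt")),
                   readLines(file.path(d2, "TF_Information.txt")))
})

test_that("single-row tables and empty datasets are handled", {
  d <- withr::local_tempdir()
  write_cisbp_like(tf_ds(tf_rec("TF1", "M1")), list(), d, id_only = "M1")
  one <- read_tf_table(file.path(d, "TF_Information.txt"), quiet = TRUE)
  expect_equal(length(one), 1)
  expect_equal(one[[1]]$pwm_ids, "M1")
  d2 <- withr::local_tempdir()
  write_cisbp_like(tf_ds(), list(), d2)
  expect_warning(empty <- read_tf_table(file.path(d2, "TF_Information.txt"),
                                        quiet = TRUE), "empty")
  expect_equal(length(empty), 0)
})

test_that("null motif token gives an empty PWM set, kept but not projected", {
  d <- withr::local_tempdir()
  write_cisbp_like(tf_ds(tf_rec("TF1", "M1"), tf_rec("TF2")),
                   list(), d, id_only = "M1")
  ds <- read_tf_table(file.path(d, "TF_Information.txt"), quiet = TRUE)
  tf2 <- ds[[which(vapply(ds, `[[`, character(1), "tf_id") == "TF2")]]
  expect_equal(length(tf2$pwm_ids), 0)
  net <- tf_bipartite(ds)
  expect_equal(net$tf_nodes, "TF1")
  net_all <- tf_bipartite(ds, keep_empty = TRUE)
  expect_setequal(net_all$tf_nodes, c("TF1", "TF2"))
})

test_that("ingest counts match a brute-force tally of the raw rows", {
  gen <- generate_dataset(synthetic_spec(n_families = 25, spikes = 8,
                                         extra_singletons = 5, seed = 42))
  d <- withr::local_tempdir()
  write_synthetic(gen, d)
  raw <- read.delim(file.path(d, "TF_Information.txt"),
                    colClasses = "character")
  msg <- capture_messages(
    ds <- read_tf_table(file.path(d, "TF_Information.txt")))
  expect_match(msg, sprintf("read %d TFs", length(unique(raw$TF_ID))))
  expect_match(msg, sprintf("%d distinct PWM IDs",
                            length(unique(raw$Motif_ID[raw$Motif_ID != "."]))))
  expect_equal(length(ds), length(unique(raw$TF_ID)))
})

test_that("missing required columns are named in the error", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("TF_ID\tTF_Name", "a\tb"), f)
  expect_error(read_tf_table(f), "Motif_ID")
})

test_that("PWM files parse, validate and renormalize", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Pos\tA\tC\tG\tT",
               "1\t1\t0\t0\t0", "2\t1\t0\t0\t0",
               "3\t1\t0\t0\t0", "4\t1\t0\t0\t0"), f)
  p <- read_pwm(f, motif_id = "strictA")
  expect_equal(p$L, 4)
  expect_equal(unname(p$probs[, "A"]), rep(1, 4))
  # uniform matrix: maximum entropy
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Pos\tA\tC\tG\tT",
               paste(1:3, 0.25, 0.25, 0.25, 0.25, sep = "\t")), f2)
  u <- read_pwm(f2)
  expect_true(all(u$probs == 0.25))
  # a row summing to 0.8 is rejected
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Pos\tA\tC\tG\tT", "1\t0.2\t0.2\t0.2\t0.2"), f3)
  expect_error(read_pwm(f3), "sums to 0.8")
  # non-numeric cells are a format error
  f4 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Pos\tA\tC\tG\tT", "1\tx\t0.2\t0.2\t0.2"), f4)
  expect_error(read_pwm(f4), "non-numeric")
  # mild rounding is renormalized to machine precision
  f5 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Pos\tA\tC\tG\tT", "1\t0.333\t0.333\t0.333\t0"), f5)
  r <- read_pwm(f5)
  expect_lt(abs(sum(r$probs[1, ]) - 1), 1e-6)
})

test_that("referencing a motif without a matrix fails the write", {
  expect_error(
    write_cisbp_like(tf_ds(tf_rec("TF1", "M9")), list(),
                     withr::local_tempdir()),
    "M9")
})
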