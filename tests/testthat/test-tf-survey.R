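test_that("primary NLS selection takes the top score, earliest on ties", {
  one <- data.frame(start = 10, end = 17, score = 5)
  expect_equal(select_primary_nls(one), one)
  two <- data.frame(start = c(10, 100), end = c(17, 108), score = c(5, 9))
  expect_equal(select_primary_nls(two)$start, 100)
  # enumerate all orderings of a tied pair: earliest start must always win
  tie <- data.frame(start = c(40, 12), end = c(47, 19), score = c(7, 7))
  for (perm in list(1:2, 2:1)) {
    expect_equal(select_primary_nls(tie[perm, ])$start, 12)
  }
  expect_error(select_primary_nls(NULL), "excluded")
})

test_that("terminal region follows the midpoint 50 percent rule", {
  rec <- function(L, s, e) tf_record("x", L, c(s, e), rep(0.5, L))
  r1 <- terminal_region(rec(100, 10, 20))
  expect_equal(r1$side, "N"); expect_equal(r1$range, c(1, 20))
  r2 <- terminal_region(rec(100, 80, 88))
  expect_equal(r2$side, "C"); expect_equal(r2$range, c(80, 100))
  # midpoint exactly at half length counts as N-side
  r3 <- terminal_region(rec(100, 46, 54))
  expect_equal(r3$side, "N"); expect_equal(r3$range, c(1, 54))
})

test_that("disorder means cover the stated ranges exactly", {
  const <- tf_record("c", 50, c(5, 12), rep(0.4, 50))
  expect_equal(disorder_means(const),
               c(full_mean = 0.4, region_mean = 0.4))
  prof <- c(rep(1, 20), rep(0, 80))
  rec <- tf_record("r", 100, c(14, 20), prof)   # region = [1, 20]
  expect_equal(disorder_means(rec),
               c(full_mean = 0.2, region_mean = 1.0))
  # region mean ignores scores outside the region
  prof2 <- prof; prof2[60:100] <- 0.9
  rec2 <- tf_record("r2", 100, c(14, 20), prof2)
  expect_equal(disorder_means(rec2)[["region_mean"]], 1.0)
})

test_that("planted elevation obeys the closed-form mean difference", {
  spec <- tf_sim_spec(n_proteins = 6, baseline_disorder_sd = 0,
                      region_disorder_delta = 0.2, noise_sd = 0, seed = 8)
  for (rec in gen_tf_dataset(spec)) {
    tr <- attr(rec, "truth")
    span <- tr$region[2] - tr$region[1] + 1
    m <- disorder_means(rec)
    expect_equal(terminal_region(rec)$range, tr$region)
    expect_equal(m[["region_mean"]] - m[["full_mean"]],
                 0.2 * (1 - span / rec$length), tolerance = 1e-12)
  }
})

test_that("isoform dedup keeps the longest, lexicographic on ties", {
  mk <- function(id, L) tf_record(id, L, c(1, 7), rep(0.5, L))
  recs <- list(mk("A1", 400), mk("A2", 350), mk("B9", 200))
  kept <- dedup_isoforms(recs, c("A", "A", "B"))
  expect_equal(vapply(kept, function(r) r$id, ""), c("A1", "B9"))
  eq <- list(mk("zz", 300), mk("aa", 300), mk("mm", 300))
  expect_equal(dedup_isoforms(eq, rep("g", 3))[[1]]$id, "aa")
  expect_length(dedup_isoforms(recs, c("x", "y", "z")), 3)
})

test_that("survey recovers the planted direction and is order-invariant", {
  recs <- gen_tf_dataset(tf_sim_spec(n_proteins = 60, noise_sd = 0,
                                     baseline_disorder_sd = 0, seed = 15))
  s <- run_survey(recs)
  expect_true(all(s$rows$region_mean > s$rows$full_mean))
  expect_lt(s$test$p.value, 0.01)
  s2 <- run_survey(rev(recs))
  expect_equal(s2$test$p.value, s$test$p.value)
  expect_equal(sort(s2$rows$id), sort(s$rows$id))
  # two identical flat records: maximal attainable P
  flat <- list(tf_record("f1", 100, c(10, 17), rep(0.5, 100)),
               tf_record("f2", 100, c(10, 17), rep(0.5, 100)))
  expect_equal(run_survey(flat)$test$p.value, 1)
  expect_error(run_survey(flat[1]), "at least 2")
})

test_that("paired signed-rank variant is calibrated under the null", {
  rej <- mean(sapply(1:300, function(r) {
    recs <- gen_tf_dataset(tf_sim_spec(n_proteins = 80,
                                       region_disorder_delta = 0,
                                       seed = 3000 + r))
    run_survey(recs, test = "wilcoxon-paired")$test$p.value < 0.05
  }))
  # 3 sigma band around 0.05 at 300 replicates
  expect_gt(rej, 0.012)
  expect_lt(rej, 0.088)
})

test_that("records without NLS are excluded with bookkeeping", {
  recs <- gen_tf_dataset(tf_sim_spec(n_proteins = 10, seed = 4))
  recs[[3]]$nls <- NULL
  s <- run_survey(recs)
  expect_equal(s$n, 9)
  expect_equal(s$n_excluded, 1)
})

test_that("datasets roundtrip through FASTA and predictor TSVs", {
  dir <- withr::local_tempdir()
  recs <- gen_tf_dataset(tf_sim_spec(n_proteins = 5, with_sequence = TRUE,
                                     seed = 77))
  write_tf_dataset(recs, dir)
  back <- read_tf_dataset(file.path(dir, "tf.fasta"),
                          file.path(dir, "disorder.tsv"),
                          file.path(dir, "nls.tsv"))
  expect_length(back, 5)
  for (i in seq_along(recs)) {
    expect_equal(back[[i]]$nls, recs[[i]]$nls)
    expect_equal(back[[i]]$length, recs[[i]]$length)
    expect_equal(back[[i]]$disorder, recs[[i]]$disorder, tolerance = 1e-6)
    expect_equal(toupper(back[[i]]$sequence), recs[[i]]$sequence)
  }
  expect_equal(run_survey(back)$rows$region_mean,
               run_survey(recs)$rows$region_mean, tolerance = 1e-6)
})

test_that("TF generation is seed-deterministic", {
  a <- gen_tf_dataset(tf_sim_spec(n_proteins = 8, seed = 99))
  b <- gen_tf_dataset(tf_sim_spec(n_proteins = 8, seed = 99))
  expect_identical(lapply(a, unclass), lapply(b, unclass))
})
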