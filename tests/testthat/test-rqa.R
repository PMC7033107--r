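test_that("pairwise distances are Euclidean and match the naive oracle", {
  pts <- rbind(c(0, 0), c(3, 4))
  d <- pairwise_distance_matrix(pts)
  expect_equal(d, rbind(c(0, 5), c(5, 0)))
  expect_equal(pairwise_distance_matrix(rbind(c(1, 2), c(1, 2)))[1, 2], 0)
  set.seed(2)
  pts2 <- matrix(rnorm(50 * 3), 50)
  expect_identical(pairwise_distance_matrix(pts2), naive_dist_matrix(pts2))
})

test_that("recurrence matrix honors radius and Theiler conventions", {
  set.seed(3)
  att <- delay_embed(sin(2 * pi * (0:149) / 30) + rnorm(150, 0, 0.1), 7, 3)
  d <- pairwise_distance_matrix(att)
  rm_all <- recurrence_matrix(d, radius_fraction = 1.0, theiler = 10)
  m_all <- rqa_metrics(rm_all)
  expect_equal(m_all$rec, 100)
  expect_error(recurrence_matrix(d, theiler = nrow(d)),
               class = "coordrqa_degenerate_input")
  expect_error(recurrence_matrix(matrix(0, 5, 5)),
               class = "coordrqa_degenerate_input")
  # band is excluded
  rm10 <- recurrence_matrix(d, theiler = 10)
  band <- abs(row(d) - col(d)) < 10
  expect_true(!any(rm10$entries[band]))
})

test_that("recurrence matrix equals the brute-force oracle bit for bit", {
  set.seed(9)
  x <- sin(2 * pi * (0:99) / 25) + rnorm(100, 0, 0.15)
  att <- delay_embed(x, 5, 3)
  d <- pairwise_distance_matrix(att)
  rm_ <- recurrence_matrix(d)
  oracle <- naive_rqa(unclass(att))
  expect_identical(unname(rm_$entries), unname(oracle$recurrence))
})

test_that("diagonal histogram counts hand-drawn runs {3, 10, 11}", {
  n <- 12
  ent <- matrix(FALSE, n, n)
  put_run <- function(k, rows) {
    for (i in rows) {
      ent[i, i + k] <<- TRUE
      ent[i + k, i] <<- TRUE
    }
  }
  put_run(1, 1:11)  # run of 11
  put_run(2, 1:10)  # run of 10
  put_run(3, 1:3)   # run of 3
  rm_ <- structure(list(entries = ent, radius = 1, radius_fraction = 0.15,
                        theiler = 1L, n = n),
                   class = "recurrence_matrix")
  h <- diagonal_line_histogram(rm_, min_line = 10)
  expect_equal(h$length, c(3L, 10L, 11L))
  expect_equal(h$count, c(1L, 1L, 1L))
  expect_equal(h$qualifies, c(FALSE, TRUE, TRUE))
  empty <- structure(list(entries = matrix(FALSE, n, n), radius = 1,
                          radius_fraction = 0.15, theiler = 1L, n = n),
                     class = "recurrence_matrix")
  expect_equal(nrow(diagonal_line_histogram(empty)), 0)
})

test_that("a periodic signal is nearly fully deterministic under paper parameters", {
  att <- delay_embed(sin(2 * pi * (0:2499) / 100), 25, 6)
  m <- rqa_analyze(att, 0.15, 10, 10)
  expect_gte(m$det, 99)
  expect_gt(m$rec, 0)
  expect_gt(m$maxline, 50)
})

test_that("an isolated recurrent pair yields zero %DET and %MAXLINE", {
  pts <- matrix(c(0, 10, 20, 30, 40, 0.1), ncol = 1)
  m <- rqa_analyze(pts, radius_fraction = 0.15, theiler = 2, min_line = 10)
  expect_gt(m$rec, 0)
  expect_equal(m$det, 0)
  expect_equal(m$maxline, 0)
})

test_that("shuffling a sine destroys its deterministic structure", {
  x <- sin(2 * pi * (0:299) / 30)
  att <- delay_embed(x, 7, 3)
  det0 <- rqa_analyze(att, 0.15, 5, 5)$det
  for (s in 1:5) {
    set.seed(s)
    atts <- delay_embed(sample(x), 7, 3)
    ms <- rqa_analyze(atts, 0.15, 5, 5)
    expect_lt(ifelse(is.na(ms$det), 0, ms$det), det0)
  }
})

test_that("streaming and matrix routes agree exactly", {
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(120) + sin(2 * pi * (0:119) / 20)
    att <- delay_embed(x, 4, 3)
    m1 <- rqa_analyze(att)
    m2 <- rqa_metrics(recurrence_matrix(pairwise_distance_matrix(att)))
    expect_identical(c(m1$rec, m1$det, m1$maxline),
                     c(m2$rec, m2$det, m2$maxline))
  }
})

test_that("%REC grows with radius and %DET shrinks with minimum line length", {
  set.seed(6)
  att <- delay_embed(sin(2 * pi * (0:199) / 40) + rnorm(200, 0, 0.1), 10, 3)
  recs <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(rf)
    rqa_analyze(att, rf, 10, 10)$rec, numeric(1))
  expect_true(all(diff(recs) >= 0))
  dets <- vapply(c(2, 5, 10, 20), function(ml)
    rqa_analyze(att, 0.15, 10, ml)$det, numeric(1))
  expect_true(all(diff(dets) <= 0))
})

test_that("metrics are invariant to amplitude scaling of the source signal", {
  set.seed(13)
  x <- sin(2 * pi * (0:299) / 30) + rnorm(300, 0, 0.05)
  a1 <- delay_embed(x, 7, 4)
  a2 <- delay_embed(42.7 * x, 7, 4)
  m1 <- rqa_analyze(a1); m2 <- rqa_analyze(a2)
  expect_equal(m1$rec, m2$rec, tolerance = 1e-10)
  expect_equal(m1$det, m2$det, tolerance = 1e-10)
  expect_equal(m1$maxline, m2$maxline, tolerance = 1e-10)
})

test_that("hand averaging propagates undefined determinism with a warning", {
  pts <- matrix(c(0, 10, 20, 30, 40, 0.1), ncol = 1)
  m <- rqa_analyze(pts, theiler = 2)
  avg <- participant_rqa(m, m)
  expect_equal(avg$rec, m$rec)
  none <- rqa_analyze(matrix(c(0, 100, 200, 300, 400, 500), ncol = 1),
                      radius_fraction = 0.01, theiler = 2)
  expect_equal(none$rec, 0)
  expect_true(is.na(none$det))
  expect_warning(both <- participant_rqa(m, none))
  expect_true(is.na(both$det))
})
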