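test_that("overlap score matches its definition on worked cases", {
  # sizes 14 and 10 sharing 4 proteins: 16/140, printed 0.11
  a <- sprintf("a%02d", 1:10)
  b <- c(a[1:4], sprintf("b%02d", 1:10))
  expect_equal(overlap_score(a, b), 16 / 140)
  expect_equal(round(overlap_score(a, b), 2), 0.11)

  expect_equal(overlap_score(letters[1:5], letters[1:5]), 1)
  expect_equal(overlap_score(letters[1:3], letters[4:6]), 0)
  expect_error(overlap_score(character(), "a"), "non-empty")
})

test_that("overlap score is symmetric and 1 only on identical sets", {
  set.seed(13)
  for (rep in 1:30) {
    a <- sample(letters, sample(2:10, 1))
    b <- sample(letters, sample(2:10, 1))
    os <- overlap_score(a, b)
    expect_equal(os, overlap_score(b, a))
    expect_gte(os, 0)
    expect_lte(os, 1)
    expect_equal(os == 1, setequal(a, b))
    expect_equal(os > 0, length(intersect(a, b)) > 0)
  }
})

test_that("confusion counts implement the inclusive-threshold definitions", {
  ref <- complex_set(list(c("a", "b", "c"), c("d", "e", "f"),
                          c("g", "h"), c("i", "j")))
  # p1 matches ref1 exactly, p2 overlaps ref2 (OS = 4/6), p3 is disjoint
  pred <- complex_set(list(c("a", "b", "c"), c("d", "e"), c("x", "y")))
  cc <- confusion_counts(pred, ref, os_threshold = 0.2)
  expect_equal(cc, tibble::tibble(tp = 2L, fp = 1L, fn = 2L))

  # pred == ref: perfect counts
  cc2 <- confusion_counts(ref, ref, os_threshold = 0.2)
  expect_equal(cc2, tibble::tibble(tp = 4L, fp = 0L, fn = 0L))

  # no predictions at all
  cc3 <- confusion_counts(complex_set(), ref, os_threshold = 0.2)
  expect_equal(cc3, tibble::tibble(tp = 0L, fp = 0L, fn = 4L))

  expect_error(confusion_counts(pred, complex_set()), "empty")
})

test_that("precision, recall and F-measure follow the harmonic-mean formula", {
  expect_equal(
    precision_recall_f(list(tp = 2, fp = 1, fn = 2)),
    tibble::tibble(recall = 0.5, precision = 2 / 3, f_measure = 4 / 7)
  )
  expect_equal(
    precision_recall_f(list(tp = 5, fp = 0, fn = 0)),
    tibble::tibble(recall = 1, precision = 1, f_measure = 1)
  )
  expect_equal(
    precision_recall_f(list(tp = 0, fp = 0, fn = 0)),
    tibble::tibble(recall = 0, precision = 0, f_measure = 0)
  )
})

test_that("F-measure sits between precision and recall when both positive", {
  set.seed(17)
  for (rep in 1:30) {
    counts <- list(tp = sample(1:50, 1), fp = sample(0:50, 1),
                   fn = sample(0:50, 1))
    prf <- precision_recall_f(counts)
    expect_gte(prf$f_measure, min(prf$precision, prf$recall))
    expect_lte(prf$f_measure, max(prf$precision, prf$recall))
  }
})

test_that("MMR reproduces the worked bipartite example", {
  # two references, three predictions; matched pairs score 0.8 and 0.75,
  # and the competing edge to the first reference is weaker
  # p1 vs r1: i=8, g=10, h=8 -> 64/80 = 0.8
  r1 <- sprintf("r%02d", 1:8)
  p1 <- c(r1, "x1", "x2")
  # p2 vs r1: i=3, g=6, h=8 -> 9/48 ~ 0.19 (weaker competitor)
  p2 <- c(r1[1:3], "y1", "y2", "y3")
  # p3 vs r2: i=6, g=8, h=6 -> 36/48 = 0.75
  r2 <- sprintf("s%02d", 1:6)
  p3 <- c(r2, "z1", "z2")
  pred <- complex_set(list(p1, p2, p3))
  ref <- complex_set(list(r1, r2))
  expect_equal(overlap_score(p1, r1), 0.8)
  expect_equal(overlap_score(p3, r2), 0.75)
  expect_equal(max_matching_ratio(pred, ref), (0.8 + 0.75) / 2)

  expect_equal(max_matching_ratio(ref, ref), 1)
  expect_equal(max_matching_ratio(complex_set(list(c("q", "w"))), ref), 0)
  expect_error(max_matching_ratio(pred, complex_set()), "empty")
})

test_that("MMR equals brute-force enumeration of one-to-one mappings", {
  set.seed(19)
  for (rep in 1:25) {
    pred <- rand_complex_set(sample(1:6, 1))
    ref <- rand_complex_set(sample(1:6, 1))
    expect_equal(max_matching_ratio(pred, ref), mmr_oracle(pred, ref),
                 tolerance = 1e-10)
  }
})

test_that("match count tables are anchored at t = 0 and monotone", {
  pred <- rand_complex_set(5)
  ref <- rand_complex_set(4)
  tab <- match_count_table(pred, ref)
  expect_equal(tab$os_threshold, seq(0, 1, 0.1))
  expect_equal(tab$n_pred_matched[1], 5L)
  expect_equal(tab$n_ref_matched[1], 4L)
  expect_true(all(diff(tab$n_pred_matched) <= 0))
  expect_true(all(diff(tab$n_ref_matched) <= 0))

  # identical sets: every row equals the set sizes
  tab2 <- match_count_table(ref, ref)
  expect_true(all(tab2$n_pred_matched == 4L))
  expect_true(all(tab2$n_ref_matched == 4L))

  # hand-checkable 3x2 instance verified against exhaustive pairwise OS
  pred3 <- complex_set(list(c("a", "b"), c("c", "d", "e"), c("x", "y")))
  ref2 <- complex_set(list(c("a", "b"), c("c", "d")))
  tab3 <- match_count_table(pred3, ref2)
  os <- outer(seq_len(3), seq_len(2), Vectorize(function(i, j) {
    overlap_score(pred3$members[[i]], ref2$members[[j]])
  }))
  for (k in seq_len(nrow(tab3))) {
    t <- tab3$os_threshold[k]
    expect_equal(tab3$n_pred_matched[k], sum(apply(os, 1, max) >= t))
    expect_equal(tab3$n_ref_matched[k], sum(apply(os, 2, max) >= t))
  }
})

test_that("the evaluation report assembles all metrics coherently", {
  pred <- complex_set(list(c("a", "b", "c"), c("d", "e"), c("z", "w")))
  ref <- complex_set(list(c("a", "b", "c"), c("d", "e", "f"), c("s")))
  ev <- evaluate_complexes(pred, ref, os_threshold = 0.2)
  # the singleton reference is filtered before any metric
  expect_equal(ev$n_ref, 2)
  expect_equal(glance(ev)$tp, 2L)
  expect_equal(glance(ev)$f_measure,
               precision_recall_f(ev$counts)$f_measure)
  expect_equal(tidy(ev), match_count_table(pred, complex_set(ref$members[1:2])))
  expect_s3_class(autoplot(ev), "ggplot")

  # self-evaluation of a singleton-free catalogue is perfect
  multi <- complex_set(ref$members[1:2])
  self <- evaluate_complexes(multi, multi)
  expect_equal(self$f_measure, 1)
  expect_equal(self$mmr, 1)
})
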