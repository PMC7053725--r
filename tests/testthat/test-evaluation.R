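test_that("metrics follow the confusion-matrix formulas and conventions", {
  r <- metrics(1, 0, 1, 0)
  expect_equal(c(r$recall, r$specificity, r$precision, r$accuracy, r$f1),
               rep(100, 5))

  # all-positive prediction over the curated pair counts
  r2 <- metrics(tp = 2931, fp = 2631, tn = 0, fn = 0)
  expect_equal(round1(r2$precision), 52.7)
  expect_equal(round1(r2$f1), 69.0)
  expect_equal(r2$recall, 100)
  expect_equal(r2$specificity, 0)
  expect_equal(r2$precision, r2$accuracy)   # no negatives predicted

  r3 <- metrics(50, 50, 50, 50)
  expect_equal(c(r3$recall, r3$specificity, r3$precision, r3$accuracy,
                 r3$f1), rep(50, 5))

  # undefined ratios are absent, not zero
  expect_true(is.na(metrics(0, 0, 5, 5)$precision))
  expect_true(is.na(metrics(0, 5, 5, 0)$recall))
  # count conservation
  r4 <- metrics(3, 4, 5, 6)
  expect_equal(r4$tp + r4$fp + r4$tn + r4$fn, 18)
  expect_error(metrics(0, 0, 0, 0))
})

test_that("co-occurrence baseline reproduces the curated-corpus figures", {
  b <- baseline_cooccurrence(2931, 2631)
  expect_equal(round1(b$precision), 52.7)
  expect_equal(round1(b$f1), 69.0)
  expect_equal(b$recall, 100); expect_equal(b$specificity, 0)

  b_iv <- baseline_cooccurrence(1598, 1269)
  expect_equal(round1(b_iv$precision), 55.7)
  expect_equal(round1(b_iv$f1), 71.6)

  b_niv <- baseline_cooccurrence(1333, 1362)
  expect_equal(round1(b_niv$precision), 49.5)
  expect_equal(round1(b_niv$f1), 66.2)

  b1 <- baseline_cooccurrence(1, 1)
  expect_equal(round1(b1$precision), 50.0)
  expect_equal(round1(b1$f1), 66.7)
})

test_that("auc equals brute-force pair enumeration", {
  expect_equal(auc(c(1, 1, -1, -1), c(0.9, 0.8, 0.2, 0.1)), 100)
  expect_equal(auc(c(1, 1, -1, -1), rep(1, 4)), 50)
  expect_equal(auc(c(1, 1, -1, -1), c(0.9, 0.4, 0.6, 0.1)), 75)
  expect_true(is.na(auc(c(1, 1), c(0.5, 0.2))))

  set.seed(17)
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    y <- sample(c(-1, 1), n, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n), 1)    # rounding forces ties
    expect_equal(auc(y, s), brute_auc(y, s))
  }
})

test_that("document folds partition documents deterministically", {
  x <- generate_corpus(synth_config(n_docs = 10, sentences_per_doc = 1,
                                    seed = 2))
  sp <- document_folds(x, 10, seed = 5)
  expect_equal(sort(unname(sp$assignment)), 1:10)    # one doc per fold

  expect_identical(document_folds(x, 10, seed = 5)$assignment,
                   sp$assignment)

  x25 <- generate_corpus(synth_config(n_docs = 25, sentences_per_doc = 1,
                                      seed = 2))
  sizes <- table(document_folds(x25, 10, seed = 1)$assignment)
  expect_true(all(sizes %in% c(2, 3)))
  expect_lte(max(sizes) - min(sizes), 1)

  expect_error(document_folds(x, 20, 1), "at least k")
})

test_that("cross-validation scores every labeled pair exactly once", {
  x <- generate_corpus(synth_config(n_docs = 8, sentences_per_doc = 2,
                                    seed = 6, p_verb_given_pos = 0.9,
                                    p_verb_given_neg = 0.1))
  sp <- document_folds(x, 4, 1)
  res <- cross_validate(x, "sl", sl_params(1, 1), split = sp,
                        verbs = default_verb_list())
  ct <- corpus_counts(x)
  expect_equal(nrow(res), ct$pairs)
  expect_false(anyDuplicated(res$pair_id) > 0)
  # each document's pairs scored in its own fold only
  expect_true(all(tapply(res$fold, res$doc_id,
                         function(f) length(unique(f))) == 1))

  # 2-document corpus, k = 2: each document scored by the other's model
  x2 <- generate_corpus(synth_config(n_docs = 2, sentences_per_doc = 3,
                                     seed = 3))
  sp2 <- document_folds(x2, 2, 1)
  res2 <- cross_validate(x2, "apg", apg_params(), split = sp2)
  expect_equal(sort(unique(res2$fold)), 1:2)
  expect_equal(nrow(res2), corpus_counts(x2)$pairs)

  xu <- make_simple_corpus(label = "unknown")
  expect_error(cross_validate(xu, "sl", sl_params(), split = sp),
               "fully labeled")
})

test_that("nested CV with a singleton grid equals plain CV", {
  x <- generate_corpus(synth_config(n_docs = 8, sentences_per_doc = 2,
                                    seed = 10, p_verb_given_pos = 0.9,
                                    p_verb_given_neg = 0.1))
  sp <- document_folds(x, 4, 2)
  plain <- cross_validate(x, "apg", apg_params(c = 0.5), split = sp)
  nested <- nested_cv(x, "apg", list(apg_params(c = 0.5)), split = sp)
  o1 <- plain[order(plain$pair_id), ]
  o2 <- nested$results[order(nested$results$pair_id), ]
  expect_equal(o1$score, o2$score)
  expect_equal(nrow(nested$chosen), 4)     # params recorded per fold
  expect_true(all(nested$chosen$grid_index == 1))
})

test_that("nested CV picks a planted dominant grid point in every fold", {
  # a grid where one SL configuration sees the signal and the other is
  # crippled (w beyond sentence ends adds nothing; use n contrast instead)
  x <- generate_corpus(synth_config(n_docs = 12, sentences_per_doc = 2,
                                    seed = 4, p_verb_given_pos = 1,
                                    p_verb_given_neg = 0,
                                    p_marker_given_pos = 1))
  sp <- document_folds(x, 3, 7)
  nested <- nested_cv(x, "apg",
                      list(apg_params(c = 0.25), apg_params(c = 0.25)),
                      split = sp)
  # identical grid points: tie broken to the first, in every fold
  expect_true(all(nested$chosen$grid_index == 1))
})

test_that("verb stratification recomputes metrics on flag subsets", {
  res <- data.frame(
    pair_id = paste0("p", 1:8),
    label = c(1, 1, 1, 1, -1, -1, -1, -1),
    score = c(1, 1, -1, 1, -1, 1, -1, -1),
    encloses_verb = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  st <- stratify_by_verb(res)
  expect_equal(st$iv$tp + st$iv$fp + st$iv$tn + st$iv$fn, 4)
  expect_equal(st$niv$tp + st$niv$fp + st$niv$tn + st$niv$fn, 4)
  expect_equal(st$iv$tp, 2); expect_equal(st$iv$fn, 1)

  all_iv <- res; all_iv$encloses_verb <- TRUE
  st2 <- stratify_by_verb(all_iv)
  expect_null(st2$niv)
  overall <- evaluate_results(res)
  expect_equal(st2$iv$f1, overall$f1)
})

test_that("chi-squared independence matches closed form and stats oracle", {
  cs <- chi_squared_independence(5, 5, 5, 5)
  expect_equal(cs$statistic, 0)
  expect_equal(cs$p_value, 1)

  cs2 <- chi_squared_independence(10, 0, 0, 10)
  expect_equal(cs2$statistic, 20)

  # transposition invariance
  a <- chi_squared_independence(12, 5, 7, 20)
  b <- chi_squared_independence(12, 7, 5, 20)
  expect_equal(a$statistic, b$statistic)

  # independent oracle: stats::chisq.test without continuity correction
  tab <- matrix(c(12, 5, 7, 20), 2, 2, byrow = TRUE)
  ref <- chisq.test(tab, correct = FALSE)
  expect_equal(a$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(a$p_value, unname(ref$p.value), tolerance = 1e-12)

  expect_error(chi_squared_independence(0, 0, 3, 4), "marginal")
})

test_that("conjunction combination obeys its recall/specificity bounds", {
  expect_equal(combine_and(c(1, 1, -1), c(1, -1, -1)), c(1L, -1L, -1L))
  expect_error(combine_and(c(1, 1), c(1, 1, 1)), "length")
  expect_error(combine_and(setNames(1, "a"), setNames(1, "b")), "aligned")

  # exhaustive check over all outcome patterns of 2 pairs x 2 models
  evalm <- function(pred, y) {
    tp <- sum(pred > 0 & y > 0); fp <- sum(pred > 0 & y < 0)
    tn <- sum(pred < 0 & y < 0); fn <- sum(pred < 0 & y > 0)
    c(rec = if (tp + fn > 0) tp / (tp + fn) else NA,
      spec = if (tn + fp > 0) tn / (tn + fp) else NA)
  }
  grid <- expand.grid(a1 = c(-1, 1), a2 = c(-1, 1), b1 = c(-1, 1),
                      b2 = c(-1, 1))
  y <- c(1, -1)
  for (i in seq_len(nrow(grid))) {
    A <- c(grid$a1[i], grid$a2[i]); B <- c(grid$b1[i], grid$b2[i])
    Cc <- combine_and(A, B)
    mA <- evalm(A, y); mB <- evalm(B, y); mC <- evalm(Cc, y)
    if (!is.na(mC["rec"])) expect_lte(mC["rec"], min(mA["rec"], mB["rec"]))
    if (!is.na(mC["spec"]) && !is.na(mA["spec"]) && !is.na(mB["spec"])) {
      expect_gte(mC["spec"], max(mA["spec"], mB["spec"]))
    }
  }

  # random label sets
  set.seed(23)
  for (rep in 1:10) {
    y <- sample(c(-1, 1), 40, replace = TRUE)
    A <- sample(c(-1, 1), 40, replace = TRUE)
    B <- sample(c(-1, 1), 40, replace = TRUE)
    if (!any(y > 0) || !any(y < 0)) next
    Cc <- combine_and(A, B)
    rec <- function(p) sum(p > 0 & y > 0) / sum(y > 0)
    spec <- function(p) sum(p < 0 & y < 0) / sum(y < 0)
    expect_lte(rec(Cc), min(rec(A), rec(B)) + 1e-12)
    expect_gte(spec(Cc), max(spec(A), spec(B)) - 1e-12)
  }
})

test_that("matched-precision threshold maximizes coverage at the target", {
  scores <- c(0.9, 0.8, 0.7)
  labels <- c(1, -1, 1)
  t100 <- matched_precision_threshold(scores, labels, 100)
  expect_gt(t100, 0.8); expect_lt(t100, 0.9)
  pred <- threshold_labels(scores, t100)
  expect_equal(sum(pred > 0 & labels > 0) / sum(pred > 0), 1)
  expect_equal(sum(pred > 0 & labels > 0) / sum(labels > 0), 0.5)

  expect_equal(matched_precision_threshold(scores, labels, 0), -Inf)
  # target equal to the all-positive precision: -Inf (largest count) wins
  expect_equal(matched_precision_threshold(scores, labels, 100 * 2 / 3),
               -Inf)
  expect_warning(
    t_imp <- matched_precision_threshold(c(0.5, 0.6), c(1, -1), 100),
    "no threshold")
  expect_equal(t_imp, Inf)
})
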