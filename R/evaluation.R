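# Evaluation machinery: confusion-matrix metrics, co-occurrence baseline,
# Mann-Whitney AUC, document-wise and nested cross-validation,
# interaction-verb stratification, chi-squared independence, conjunction of
# two kernels' predictions, and matched-precision threshold calibration.

#' Round half-up to one decimal (presentation only)
#' @param x numeric.
#' @return numeric rounded half-up to 1 decimal.
#' @export
round1 <- function(x) floor(x * 10 + 0.5) / 10

#' Confusion-matrix metrics
#'
#' Percentages are kept at full precision; round with [round1()] at
#' presentation time. Ratios with a zero denominator are `NA` (absent),
#' never 0 by convention.
#'
#' @param tp,fp,tn,fn non-negative integer counts, total > 0.
#' @return list of class `cpi_report`: `tp`, `fp`, `tn`, `fn`, `recall`,
#'   `specificity`, `precision`, `accuracy`, `f1` (percent), `auc`
#'   (percent or `NA`).
#' @export
metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  rec <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  acc <- 100 * (tp + tn) / (tp + fp + tn + fn)
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 recall = rec, specificity = spec, precision = prec,
                 accuracy = acc, f1 = f1, auc = NA_real_),
            class = "cpi_report")
}

#' @export
print.cpi_report <- function(x, ...) {
  cat(sprintf(
    "Rec. %s  Spec. %s  Prec. %s  Acc. %s  F1 %s%s   (tp %d fp %d tn %d fn %d)\n",
    fmt1(x$recall), fmt1(x$specificity), fmt1(x$precision), fmt1(x$accuracy),
    fmt1(x$f1), if (is.na(x$auc)) "" else paste0("  AUC ", fmt1(x$auc)),
    x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

fmt1 <- function(x) if (is.na(x)) "-" else sprintf("%.1f", round1(x))

#' Co-occurrence baseline report
#'
#' Every candidate pair is classified functional: recall 100%, specificity
#' 0%, precision = positive fraction.
#'
#' @param n_pos,n_neg labeled positive/negative pair counts (sum > 0).
#' @return a `cpi_report`.
#' @export
baseline_cooccurrence <- function(n_pos, n_neg) {
  stopifnot(n_pos + n_neg > 0)
  metrics(tp = n_pos, fp = n_neg, tn = 0, fn = 0)
}

#' Area under the ROC curve (Mann-Whitney statistic), in percent
#'
#' Equals the fraction of (positive, negative) score pairs ranked
#' correctly, counting ties as 1/2; computed via midranks.
#'
#' @param labels vector in \{-1, +1\} (or coercible via the usual rules).
#' @param scores numeric decision scores.
#' @return AUC in percent, or `NA` if only one class present.
#' @export
auc <- function(labels, scores) {
  y <- as_pm1(labels)
  n_pos <- sum(y > 0); n_neg <- sum(y < 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  100 * (sum(r[y > 0]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Assign documents to cross-validation folds
#'
#' Documents are shuffled by a seeded pseudo-random permutation and
#' assigned round-robin to `k` folds, so fold sizes differ by at most one.
#' Deterministic for a fixed (document order, k, seed); the caller's RNG
#' state is untouched.
#'
#' @param x a `cpi_corpus`.
#' @param k fold count (documents >= k required).
#' @param seed integer seed.
#' @return list of class `cpi_cvsplit`: `k`, `seed`, `assignment` (named
#'   integer vector doc_id -> fold in 1..k).
#' @export
document_folds <- function(x, k = 10L, seed = 1L) {
  doc_ids <- vapply(x$documents, `[[`, "", "doc_id")
  n <- length(doc_ids)
  if (n < k) stop("need at least k = ", k, " documents, have ", n)
  perm <- with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep_len(seq_len(k), n)
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 assignment = setNames(fold, doc_ids)),
            class = "cpi_cvsplit")
}

# ---- instance preparation ---------------------------------------------------

#' Build blinded instances (and metadata) for every pair of a corpus
#'
#' Parses each sentence, blinds each candidate pair, and recomputes the
#' enclosed-interaction-verb flag from the tokens. Degenerate instances
#' (overlapping candidates) are kept in the output but flagged; kernel
#' routines exclude them.
#'
#' @param x a `cpi_corpus`.
#' @param verbs interaction-verb lemma set.
#' @param backend parser backend name (default `"fixture"`).
#' @param blind_others blind non-candidate entities (default `TRUE`).
#' @return list with `instances` (list of `cpi_instance`) and `meta`
#'   (data.frame: `pair_id`, `doc_id`, `sent_id`, `label`,
#'   `encloses_verb`, `degenerate`).
#' @export
build_instances <- function(x, verbs = default_verb_list(),
                            backend = "fixture", blind_others = TRUE) {
  instances <- list()
  meta <- list()
  for (doc in x$documents) {
    for (s in doc$sentences) {
      if (!length(s$pairs)) next
      parsed <- parse_sentence(s, verbs, backend)
      for (p in s$pairs) {
        inst <- blind_entities(parsed, p, blind_others)
        ev <- detect_enclosed_interaction_verb(parsed, p, verbs)
        inst$encloses_verb <- ev
        instances[[length(instances) + 1L]] <- inst
        meta[[length(meta) + 1L]] <- data.frame(
          pair_id = p$pair_id, doc_id = doc$doc_id, sent_id = s$sent_id,
          label = p$label, encloses_verb = ev,
          degenerate = inst$degenerate, stringsAsFactors = FALSE)
      }
    }
  }
  list(instances = instances, meta = do.call(rbind, meta))
}

# Gram matrix for a kernel kind over prepared instances.
compute_kernel_matrix <- function(instances, kernel_kind, kernel_params) {
  switch(kernel_kind,
         sl = sl_kernel_matrix(instances, kernel_params),
         apg = apg_kernel_matrix(instances, kernel_params),
         stop("unknown kernel kind '", kernel_kind, "'"))
}

train_on_kernel <- function(kernel_kind, K, y, clf_params) {
  if (kernel_kind == "sl") {
    svc_train(K, y, C = clf_params$C %||0% 1)
  } else {
    rls_train(K, y, c = clf_params$c %||0% 0.25)
  }
}

#' Document-wise cross-validation of one kernel/classifier configuration
#'
#' The Gram matrix over all labeled, non-degenerate instances is computed
#' once (the kernel does not depend on the split); for each fold a model is
#' trained on the pairs of all non-fold documents and scores the fold's
#' pairs, so every labeled pair is scored exactly once. The SL kernel is
#' paired with the support-vector classifier, the APG kernel with
#' regularized least squares.
#'
#' @param x a `cpi_corpus` with fully labeled pairs (no `"unknown"`).
#' @param kernel_kind `"sl"` or `"apg"`.
#' @param kernel_params [sl_params()] or [apg_params()].
#' @param clf_params list: `C` for svc (default 1), `c` for rls (default
#'   from `kernel_params$c` when present).
#' @param split a `cpi_cvsplit` from [document_folds()].
#' @param verbs,backend,blind_others passed to [build_instances()].
#' @param prepared optionally, a precomputed list with `instances`, `meta`
#'   and (optionally) `K` to reuse across configurations.
#' @return data.frame of pooled results: `pair_id`, `doc_id`, `label`
#'   (+1/-1), `encloses_verb`, `score`, `fold`.
#' @export
cross_validate <- function(x, kernel_kind, kernel_params, clf_params = list(),
                           split, verbs = default_verb_list(),
                           backend = "fixture", blind_others = TRUE,
                           prepared = NULL) {
  if (is.null(prepared)) {
    prepared <- build_instances(x, verbs, backend, blind_others)
  }
  meta <- prepared$meta
  if (any(meta$label == "unknown")) {
    stop("cross_validate requires fully labeled pairs")
  }
  keep <- !meta$degenerate
  instances <- prepared$instances[keep]
  meta <- meta[keep, , drop = FALSE]
  if (kernel_kind == "apg" && is.null(clf_params$c)) {
    clf_params$c <- kernel_params$c
  }
  K <- prepared$K %||0% compute_kernel_matrix(instances, kernel_kind,
                                              kernel_params)
  y <- ifelse(meta$label == "functional", 1, -1)
  folds <- split$assignment[meta$doc_id]
  out <- list()
  for (f in sort(unique(folds))) {
    test <- which(folds == f)
    train <- which(folds != f)
    if (length(unique(y[train])) < 2L) {
      warning("fold ", f, " has single-class training data; pairs unscored")
      next
    }
    model <- train_on_kernel(kernel_kind,
                             K[train, train, drop = FALSE], y[train],
                             clf_params)
    sc <- predict_scores(model, K[train, test, drop = FALSE])
    out[[length(out) + 1L]] <- data.frame(
      pair_id = meta$pair_id[test], doc_id = meta$doc_id[test],
      label = y[test], encloses_verb = meta$encloses_verb[test],
      score = sc, fold = f, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize pooled cross-validation results at a decision threshold
#' @param results data.frame from [cross_validate()].
#' @param threshold decision cutoff (default 0; strict `>`).
#' @return a `cpi_report` including pooled AUC.
#' @export
evaluate_results <- function(results, threshold = 0) {
  pred <- threshold_labels(results$score, threshold)
  rep <- metrics(tp = sum(pred > 0 & results$label > 0),
                 fp = sum(pred > 0 & results$label < 0),
                 tn = sum(pred < 0 & results$label < 0),
                 fn = sum(pred < 0 & results$label > 0))
  rep$auc <- auc(results$label, results$score)
  rep
}

#' Nested document-wise cross-validation with inner-loop model selection
#'
#' For each outer fold, an inner (k-1)-fold document-wise CV on the
#' training documents evaluates every grid point; the point with the
#' highest inner pooled AUC (ties: first in grid order) is used to score
#' the outer fold. Outer scores are pooled into one result set.
#'
#' @param x labeled `cpi_corpus`.
#' @param kernel_kind `"sl"` or `"apg"`.
#' @param param_grid non-empty list of kernel parameter objects.
#' @param split outer `cpi_cvsplit`.
#' @param clf_params,verbs,backend passed through.
#' @return list with `results` (pooled data.frame as [cross_validate()])
#'   and `chosen` (data.frame `fold`, `grid_index`).
#' @export
nested_cv <- function(x, kernel_kind, param_grid, split, clf_params = list(),
                      verbs = default_verb_list(), backend = "fixture") {
  stopifnot(length(param_grid) >= 1L)
  prepared <- build_instances(x, verbs, backend)
  keep <- !prepared$meta$degenerate
  prepared$instances <- prepared$instances[keep]
  prepared$meta <- prepared$meta[keep, , drop = FALSE]
  Ks <- lapply(param_grid, function(p)
    compute_kernel_matrix(prepared$instances, kernel_kind, p))
  meta <- prepared$meta
  y <- ifelse(meta$label == "functional", 1, -1)
  folds <- split$assignment[meta$doc_id]
  doc_fold <- split$assignment

  out <- list(); chosen <- list()
  for (f in sort(unique(doc_fold))) {
    train_docs <- names(doc_fold)[doc_fold != f]
    inner_k <- max(2L, split$k - 1L)
    if (length(train_docs) < inner_k) inner_k <- length(train_docs)
    inner_corpus_docs <- train_docs
    inner_fold_of_doc <- local({
      perm <- with_seed(split$seed + f, sample.int(length(inner_corpus_docs)))
      fl <- integer(length(inner_corpus_docs))
      fl[perm] <- rep_len(seq_len(inner_k), length(inner_corpus_docs))
      setNames(fl, inner_corpus_docs)
    })
    inner_auc <- vapply(seq_along(param_grid), function(g) {
      K <- Ks[[g]]
      idx_train_all <- which(meta$doc_id %in% train_docs)
      scores <- rep(NA_real_, length(idx_train_all))
      ifold <- inner_fold_of_doc[meta$doc_id[idx_train_all]]
      for (ff in seq_len(inner_k)) {
        te <- idx_train_all[ifold == ff]
        tr <- idx_train_all[ifold != ff]
        if (!length(te) || length(unique(y[tr])) < 2L) next
        m <- train_on_kernel(kernel_kind, K[tr, tr, drop = FALSE], y[tr],
                             if (kernel_kind == "apg")
                               list(c = param_grid[[g]]$c) else clf_params)
        scores[match(te, idx_train_all)] <-
          predict_scores(m, K[tr, te, drop = FALSE])
      }
      ok <- !is.na(scores)
      if (!any(ok)) return(-Inf)
      auc(y[idx_train_all][ok], scores[ok])
    }, 0)
    g_best <- which.max(inner_auc)   # ties: first in grid order
    chosen[[length(chosen) + 1L]] <- data.frame(fold = f,
                                                grid_index = g_best)
    K <- Ks[[g_best]]
    test <- which(folds == f)
    train <- which(folds != f)
    m <- train_on_kernel(kernel_kind, K[train, train, drop = FALSE],
                         y[train],
                         if (kernel_kind == "apg")
                           list(c = param_grid[[g_best]]$c) else clf_params)
    sc <- predict_scores(m, K[train, test, drop = FALSE])
    out[[length(out) + 1L]] <- data.frame(
      pair_id = meta$pair_id[test], doc_id = meta$doc_id[test],
      label = y[test], encloses_verb = meta$encloses_verb[test],
      score = sc, fold = f, stringsAsFactors = FALSE)
  }
  list(results = do.call(rbind, out), chosen = do.call(rbind, chosen))
}

#' Stratify pooled results by the enclosed-interaction-verb flag
#'
#' Recomputes the evaluation separately on the pairs whose sentence
#' encloses an interaction verb between the candidates (IV) and those
#' whose does not (NIV), from the *same* pooled cross-validation scores.
#'
#' @param results pooled data.frame with `encloses_verb` flags.
#' @param threshold decision cutoff.
#' @return list with `iv` and `niv` reports (`NULL` for an empty subset).
#' @export
stratify_by_verb <- function(results, threshold = 0) {
  stopifnot(!anyNA(results$encloses_verb))
  sub <- function(flag) {
    r <- results[results$encloses_verb == flag, , drop = FALSE]
    if (!nrow(r)) return(NULL)
    evaluate_results(r, threshold)
  }
  list(iv = sub(TRUE), niv = sub(FALSE))
}

#' Pearson chi-squared test of independence for a 2x2 table
#'
#' Without continuity correction:
#' `X2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, 1 df.
#'
#' @param a,b,c,d non-negative integer cells (rows: label, columns: verb
#'   presence).
#' @return list `statistic`, `p_value`, `df = 1`.
#' @export
chi_squared_independence <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n <- a + b + c + d
  stopifnot(n > 0)
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) stop("chi-squared statistic undefined: zero marginal")
  stat <- n * (a * d - b * c)^2 / prod(marg)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1,
                                                 lower.tail = FALSE),
       df = 1L)
}

#' Conjunction of two aligned hard-label vectors
#'
#' Positive iff both inputs are positive (the "majority voting" of two
#' kernels): combined recall never exceeds either input's recall, combined
#' specificity never falls below either input's.
#'
#' @param labelsA,labelsB vectors in \{-1, +1\}, aligned by pair;
#'   optionally named by pair_id, in which case names must match.
#' @return integer vector in \{-1, +1\}.
#' @export
combine_and <- function(labelsA, labelsB) {
  if (length(labelsA) != length(labelsB)) {
    stop("label vectors have different lengths")
  }
  if (!is.null(names(labelsA)) && !is.null(names(labelsB)) &&
      !identical(names(labelsA), names(labelsB))) {
    stop("label vectors are not aligned by pair_id")
  }
  ifelse(labelsA > 0 & labelsB > 0, 1L, -1L)
}

#' Threshold achieving a target precision with maximal coverage
#'
#' Scans candidate thresholds (midpoints between consecutive distinct
#' sorted scores, plus -Inf and +Inf) and returns the one with the largest
#' number of positive predictions whose precision is at least
#' `target_precision`. If no threshold achieves the target, `+Inf` is
#' returned with a warning.
#'
#' @param scores numeric decision scores.
#' @param labels vector in \{-1, +1\}.
#' @param target_precision target precision in percent.
#' @return numeric threshold.
#' @export
matched_precision_threshold <- function(scores, labels, target_precision) {
  y <- as_pm1(labels)
  stopifnot(any(y > 0), any(y < 0))
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (head(s, -1) + tail(s, -1)) / 2, Inf)
  best_t <- Inf; best_n <- -1L
  for (t in cand) {
    pos <- scores > t
    npos <- sum(pos)
    if (npos == 0) next
    prec <- 100 * sum(pos & y > 0) / npos
    if (prec >= target_precision && npos > best_n) {
      best_n <- npos; best_t <- t
    }
  }
  if (best_n < 0L) {
    warning("no threshold reaches precision ", target_precision,
            "; returning +Inf")
  }
  best_t
}
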