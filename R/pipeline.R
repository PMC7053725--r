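# End-user workflow commands: cross-validation grids, final-model training,
# prediction on new corpora, and combination of two kernels' predictions.
# Each command is an ordinary R function; inst/cli/cpi_pipeline.R exposes
# them as shell subcommands.

#' Cross-kernel matrix between two instance sets
#'
#' Computes `k(a_i, b_j)` for all pairs by evaluating the Gram matrix over
#' the concatenated instance list and slicing the off-diagonal block, which
#' guarantees bit-identical values to the training kernel.
#'
#' @param instances_a,instances_b lists of non-degenerate `cpi_instance`.
#' @param kernel_kind `"sl"` or `"apg"`.
#' @param kernel_params kernel parameter object.
#' @return matrix with `length(instances_a)` rows, `length(instances_b)`
#'   columns.
#' @export
kernel_cross <- function(instances_a, instances_b, kernel_kind,
                         kernel_params) {
  na <- length(instances_a)
  K <- compute_kernel_matrix(c(instances_a, instances_b), kernel_kind,
                             kernel_params)
  K[seq_len(na), na + seq_len(length(instances_b)), drop = FALSE]
}

default_grid <- function(kernel_kind) {
  if (kernel_kind == "sl") {
    gr <- expand.grid(n = 1:3, w = 1:3)
    lapply(seq_len(nrow(gr)), function(i) sl_params(gr$n[i], gr$w[i]))
  } else {
    lapply(c(0.25, 0.5, 1, 2), function(cc) apg_params(c = cc))
  }
}

report_row <- function(rep, extra = list()) {
  cbind(as.data.frame(extra, stringsAsFactors = FALSE), data.frame(
    recall = round1(rep$recall), specificity = round1(rep$specificity),
    precision = round1(rep$precision), f1 = round1(rep$f1),
    auc = round1(rep$auc), stringsAsFactors = FALSE))
}

write_manifest <- function(out_dir, config) {
  lines <- c(paste0("cpirex\t", as.character(utils::packageVersion("cpirex"))),
             paste0("date\t", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             vapply(names(config), function(k)
               paste0(k, "\t", paste(format(config[[k]]), collapse = " ")),
               ""))
  writeLines(lines, file.path(out_dir, "manifest.tsv"))
}

#' Run a cross-validation grid and write report tables
#'
#' Runs document-wise k-fold cross-validation for every grid point of the
#' chosen kernel(s) (SL: n x w in \{1..3\}^2; APG: c in \{0.25, 0.5, 1,
#' 2\}), writing per-kernel result tables (recall / specificity /
#' precision / F1 / AUC, one row per grid point), the pooled per-pair
#' scores of the best-AUC configuration, interaction-verb stratified
#' tables, and a reproducibility manifest.
#'
#' @param corpus_path path to a unified-XML corpus with labeled pairs.
#' @param out_dir output directory (created if missing).
#' @param kernels character subset of `c("sl", "apg")`.
#' @param k fold count. @param seed fold-assignment seed.
#' @param verb_path optional interaction-verb list path (default: shipped
#'   list).
#' @param backend parser backend name.
#' @return invisibly, a named list of per-kernel grid result data.frames.
#' @export
cmd_crossval <- function(corpus_path, out_dir, kernels = c("sl", "apg"),
                         k = 10L, seed = 1L, verb_path = NULL,
                         backend = "fixture") {
  x <- parse_unified_xml(corpus_path)
  ct <- corpus_counts(x)
  if (ct$unknowns > 0) stop("corpus contains unlabeled pairs; aborting")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  verbs <- if (is.null(verb_path)) default_verb_list() else
    read_verb_list(verb_path)
  split <- document_folds(x, k, seed)
  prepared <- build_instances(x, verbs, backend)

  out <- list()
  for (kind in kernels) {
    grid <- default_grid(kind)
    rows <- list(); best <- NULL; best_auc <- -Inf
    for (gp in grid) {
      res <- cross_validate(x, kind, gp, split = split, verbs = verbs,
                            backend = backend, prepared = prepared)
      rep <- evaluate_results(res)
      extra <- if (kind == "sl") list(n = gp$n, w = gp$w) else list(c = gp$c)
      rows[[length(rows) + 1L]] <- report_row(rep, extra)
      if (!is.na(rep$auc) && rep$auc > best_auc) {
        best_auc <- rep$auc; best <- res
      }
    }
    tab <- do.call(rbind, rows)
    utils::write.table(tab, file.path(out_dir, paste0(kind, "_grid.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(best, file.path(out_dir, paste0(kind, "_scores.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    strat <- stratify_by_verb(best)
    srows <- list()
    if (!is.null(strat$iv)) {
      srows[[length(srows) + 1L]] <- report_row(strat$iv,
                                                list(subset = "IV"))
    }
    if (!is.null(strat$niv)) {
      srows[[length(srows) + 1L]] <- report_row(strat$niv,
                                                list(subset = "NIV"))
    }
    utils::write.table(do.call(rbind, srows),
                       file.path(out_dir, paste0(kind, "_stratified.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out[[kind]] <- tab
  }
  write_manifest(out_dir, list(
    command = "crossval", corpus = corpus_path,
    corpus_hash = fnv1a_hash(readLines(corpus_path, warn = FALSE)),
    kernels = kernels, k = k, seed = seed, backend = backend))
  invisible(out)
}

model_fingerprint <- function(verbs, backend, kernel_kind, kernel_params,
                              corpus_hash) {
  c(verb_hash = fnv1a_hash(verbs), backend = backend,
    kernel = kernel_kind,
    kernel_params = paste(names(kernel_params),
                          vapply(kernel_params, function(v)
                            paste(format(v), collapse = ","), ""),
                          sep = "=", collapse = ";"),
    corpus_hash = corpus_hash)
}

#' Train a final model on all labeled pairs of a corpus
#'
#' @param corpus_path labeled unified-XML corpus.
#' @param model_path output model file.
#' @param kernel_kind `"sl"` or `"apg"`.
#' @param kernel_params kernel parameters (defaults: the best grid points,
#'   SL n=3 w=1, APG c=0.25).
#' @param clf_params list (`C` for svc).
#' @param verb_path,backend preprocessing configuration.
#' @return invisibly, the trained `cpi_model`.
#' @export
cmd_train <- function(corpus_path, model_path, kernel_kind = "apg",
                      kernel_params = NULL, clf_params = list(),
                      verb_path = NULL, backend = "fixture") {
  x <- parse_unified_xml(corpus_path)
  if (corpus_counts(x)$unknowns > 0) stop("corpus contains unlabeled pairs")
  verbs <- if (is.null(verb_path)) default_verb_list() else
    read_verb_list(verb_path)
  if (is.null(kernel_params)) {
    kernel_params <- if (kernel_kind == "sl") sl_params(3, 1) else
      apg_params(c = 0.25)
  }
  prepared <- build_instances(x, verbs, backend)
  keep <- !prepared$meta$degenerate
  inst <- prepared$instances[keep]
  meta <- prepared$meta[keep, , drop = FALSE]
  K <- compute_kernel_matrix(inst, kernel_kind, kernel_params)
  y <- ifelse(meta$label == "functional", 1, -1)
  if (kernel_kind == "apg" && is.null(clf_params$c)) {
    clf_params$c <- kernel_params$c
  }
  model <- train_on_kernel(kernel_kind, K, y, clf_params)
  fp <- model_fingerprint(verbs, backend, kernel_kind, kernel_params,
                          fnv1a_hash(readLines(corpus_path, warn = FALSE)))
  write_model(model, model_path, fingerprint = fp)
  invisible(model)
}

#' Score candidate pairs of a corpus with a trained model
#'
#' Unknown labels are allowed (prediction-time corpora). The model's
#' preprocessing fingerprint (verb-list hash, backend, kernel parameters,
#' training-corpus hash) must match the supplied configuration; a mismatch
#' is a hard error. The fixture parser is refused in predict mode unless
#' `allow_fixture = TRUE` (testing), so silently degraded graph-kernel
#' predictions cannot occur.
#'
#' @param model_path model file from [cmd_train()].
#' @param train_corpus_path the corpus the model was trained on.
#' @param corpus_path corpus to score (unified XML).
#' @param out_path output TSV of prediction records.
#' @param kernel_kind,kernel_params must match the training configuration.
#' @param verb_path,backend preprocessing configuration.
#' @param allow_fixture permit the fixture parser backend (default FALSE).
#' @param threshold decision cutoff (default: the model's stored one).
#' @return invisibly, the prediction data.frame.
#' @export
cmd_predict <- function(model_path, train_corpus_path, corpus_path, out_path,
                        kernel_kind = "apg", kernel_params = NULL,
                        verb_path = NULL, backend = "fixture",
                        allow_fixture = FALSE, threshold = NULL) {
  if (backend == "fixture" && !allow_fixture) {
    stop("fixture parser refused in predict mode; pass allow_fixture = TRUE",
         " explicitly for testing")
  }
  loaded <- read_model(model_path)
  model <- loaded$model
  verbs <- if (is.null(verb_path)) default_verb_list() else
    read_verb_list(verb_path)
  if (is.null(kernel_params)) {
    kernel_params <- if (kernel_kind == "sl") sl_params(3, 1) else
      apg_params(c = 0.25)
  }
  fp <- model_fingerprint(verbs, backend, kernel_kind, kernel_params,
                          fnv1a_hash(readLines(train_corpus_path,
                                               warn = FALSE)))
  stored <- loaded$fingerprint
  for (f in names(fp)) {
    if (!identical(unname(stored[f]), unname(fp[f]))) {
      stop("fingerprint mismatch for '", f, "': model was trained with ",
           stored[f], ", current configuration gives ", fp[f])
    }
  }

  train_x <- parse_unified_xml(train_corpus_path)
  new_x <- parse_unified_xml(corpus_path)
  tr <- build_instances(train_x, verbs, backend)
  te <- build_instances(new_x, verbs, backend)
  tr_keep <- !tr$meta$degenerate
  te_keep <- !te$meta$degenerate
  if (any(!te_keep)) {
    message(sum(!te_keep), " degenerate pair(s) skipped: ",
            paste(te$meta$pair_id[!te_keep], collapse = ", "))
  }
  K_cross <- kernel_cross(tr$instances[tr_keep], te$instances[te_keep],
                          kernel_kind, kernel_params)
  sc <- predict_scores(model, K_cross)
  thr <- threshold %||0% model$threshold
  pred <- threshold_labels(sc, thr)

  # entity metadata per pair
  lookup <- list()
  for (doc in new_x$documents) for (s in doc$sentences) {
    emap <- setNames(s$entities, vapply(s$entities, `[[`, "", "ent_id"))
    for (p in s$pairs) {
      lookup[[p$pair_id]] <- list(
        doc_id = doc$doc_id, sent_id = s$sent_id,
        compound = emap[[p$compound_ref]], protein = emap[[p$protein_ref]])
    }
  }
  m <- te$meta[te_keep, , drop = FALSE]
  recs <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    info <- lookup[[m$pair_id[i]]]
    data.frame(doc_id = info$doc_id, sent_id = info$sent_id,
               pair_id = m$pair_id[i],
               compound = info$compound$surface,
               compound_id = info$compound$norm_id,
               protein = info$protein$surface,
               protein_id = info$protein$norm_id,
               score = sc[i],
               predicted = ifelse(pred[i] > 0, "functional",
                                  "non_functional"),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(recs, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message(sprintf("%d pairs scored; %.1f%% predicted functional",
                  nrow(recs), 100 * mean(pred > 0)))
  invisible(recs)
}

#' Combine two prediction TSVs by conjunction
#'
#' Both files must cover the same pair_id universe. A pair is labeled
#' functional iff both inputs predict functional; the agreement fraction
#' (identical predictions / total) is reported.
#'
#' @param path_a,path_b prediction TSVs from [cmd_predict()].
#' @param out_path combined output TSV.
#' @return invisibly, list with `combined` data.frame and `agreement`
#'   fraction.
#' @export
cmd_combine <- function(path_a, path_b, out_path) {
  a <- utils::read.delim(path_a, stringsAsFactors = FALSE)
  b <- utils::read.delim(path_b, stringsAsFactors = FALSE)
  missing_a <- setdiff(b$pair_id, a$pair_id)
  missing_b <- setdiff(a$pair_id, b$pair_id)
  if (length(missing_a) || length(missing_b)) {
    stop("pair_id mismatch; missing from A: ",
         paste(missing_a, collapse = ", "), "; missing from B: ",
         paste(missing_b, collapse = ", "))
  }
  b <- b[match(a$pair_id, b$pair_id), , drop = FALSE]
  la <- ifelse(a$predicted == "functional", 1L, -1L)
  lb <- ifelse(b$predicted == "functional", 1L, -1L)
  comb <- combine_and(la, lb)
  agreement <- mean(la == lb)
  out <- data.frame(pair_id = a$pair_id,
                    predicted_a = a$predicted, predicted_b = b$predicted,
                    combined = ifelse(comb > 0, "functional",
                                      "non_functional"),
                    stringsAsFactors = FALSE)
  utils::write.table(out, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message(sprintf("agreement: %.1f%%; %d combined functional predictions",
                  100 * agreement, sum(comb > 0)))
  invisible(list(combined = out, agreement = agreement))
}

#' Generate a synthetic corpus file (shell entry point)
#' @param out_path output XML path.
#' @param ... passed to [synth_config()].
#' @return invisibly, the corpus.
#' @export
cmd_synth <- function(out_path, ...) {
  x <- generate_corpus(synth_config(...))
  write_unified_xml(x, out_path)
  invisible(x)
}

#' Evaluate a pooled-scores TSV at a threshold
#' @param scores_path TSV with columns `label`, `score` (and optionally
#'   `encloses_verb`).
#' @param threshold decision cutoff.
#' @return the overall `cpi_report` (printed), invisibly.
#' @export
cmd_evaluate <- function(scores_path, threshold = 0) {
  res <- utils::read.delim(scores_path, stringsAsFactors = FALSE)
  rep <- evaluate_results(res, threshold)
  print(rep)
  if (!is.null(res$encloses_verb)) {
    strat <- stratify_by_verb(res, threshold)
    if (!is.null(strat$iv)) { cat("IV:  "); print(strat$iv) }
    if (!is.null(strat$niv)) { cat("NIV: "); print(strat$niv) }
  }
  invisible(rep)
}
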