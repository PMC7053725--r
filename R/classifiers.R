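# Binary classifiers on precomputed kernel matrices. The support-vector
# classifier solves the soft-margin dual by sequential minimal optimization
# (maximal-violating-pair working-set selection, LIBSVM-style stopping
# rule); the regularized least-squares classifier is the direct linear
# solve a = (K + lambda I)^{-1} y with lambda = 1/c.

#' Train a soft-margin support-vector classifier on a precomputed kernel
#'
#' Solves `min 1/2 a'Qa - 1'a` subject to `0 <= a_i <= C`,
#' `sum(a_i y_i) = 0` with `Q = (y y') * K` by SMO with maximal-violating-
#' pair selection. Iterates until the KKT violation gap falls below `tol`.
#' The bias is the mean of `y_i - f(x_i)` over free support vectors
#' (`0 < a < C`), falling back to the midpoint of the violation bounds.
#'
#' @param K symmetric PSD (within tolerance) Gram matrix.
#' @param y labels in \{-1, +1\} (or a factor/logical coerced to that).
#' @param C box constraint (cost), > 0.
#' @param tol KKT violation tolerance (default 1e-8).
#' @param max_iter iteration cap; a warning is raised if reached.
#' @return object of class `cpi_model` with fields `kind = "svc"`,
#'   `dual_coefficients` (= a_i y_i), `bias`, `training_instance_ids`,
#'   `params`, `threshold`, `training_scores`.
#' @export
svc_train <- function(K, y, C = 1, tol = 1e-8, max_iter = 500000L) {
  y <- as_pm1(y)
  n <- length(y)
  stopifnot(is.matrix(K), nrow(K) == n, ncol(K) == n, C > 0)
  if (max(abs(K - t(K))) > 1e-8) stop("kernel matrix is not symmetric")
  if (length(unique(y)) < 2L) stop("svc_train requires both classes")

  alpha <- numeric(n)
  Fv <- numeric(n)                  # F_i = sum_j alpha_j y_j K_ij
  it <- 0L
  repeat {
    it <- it + 1L
    grad <- y - Fv                  # -y_i * dObj_i
    up <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
    lo <- (y < 0 & alpha < C - 1e-12) | (y > 0 & alpha > 1e-12)
    if (!any(up) || !any(lo)) break
    i <- which(up)[which.max(grad[up])]
    j <- which(lo)[which.min(grad[lo])]
    if (grad[i] - grad[j] < tol) break
    if (it > max_iter) {
      warning("svc_train reached max_iter before tol; gap = ",
              format(grad[i] - grad[j]))
      break
    }
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (eta < 1e-12) eta <- 1e-12
    aj_new <- alpha[j] - y[j] * (grad[i] - grad[j]) / eta
    if (y[i] != y[j]) {
      L <- max(0, alpha[j] - alpha[i]); H <- min(C, C + alpha[j] - alpha[i])
    } else {
      L <- max(0, alpha[i] + alpha[j] - C); H <- min(C, alpha[i] + alpha[j])
    }
    aj_new <- min(max(aj_new, L), H)
    ai_new <- alpha[i] + y[i] * y[j] * (alpha[j] - aj_new)
    dFi <- y[i] * (ai_new - alpha[i])
    dFj <- y[j] * (aj_new - alpha[j])
    if (abs(dFi) < 1e-16 && abs(dFj) < 1e-16) break
    Fv <- Fv + dFi * K[, i] + dFj * K[, j]
    alpha[i] <- ai_new
    alpha[j] <- aj_new
  }

  free <- alpha > 1e-8 & alpha < C - 1e-8
  bias <- if (any(free)) mean(y[free] - Fv[free]) else {
    grad <- y - Fv
    up <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
    lo <- (y < 0 & alpha < C - 1e-12) | (y > 0 & alpha > 1e-12)
    hi <- if (any(up)) max(grad[up]) else 0
    lw <- if (any(lo)) min(grad[lo]) else 0
    (hi + lw) / 2
  }
  ids <- rownames(K) %||0% as.character(seq_len(n))
  structure(list(
    kind = "svc",
    dual_coefficients = alpha * y,
    bias = bias,
    training_instance_ids = ids,
    params = list(C = C, tol = tol),
    threshold = 0,
    # recomputed from the final coefficients (not the incremental Fv) so
    # that predict on the training kernel reproduces them bit-identically
    training_scores = as.numeric(crossprod(K, alpha * y)) + bias,
    alpha = alpha, y = y
  ), class = "cpi_model")
}

#' Train a regularized least-squares classifier on a precomputed kernel
#'
#' Dual coefficients `a = (K + lambda I)^{-1} y` with `lambda = 1/c`, so a
#' larger `c` means weaker regularization (the grid direction used for the
#' kernel evaluation). Decision score of instance x: `sum_i a_i K(x_i, x)`.
#'
#' @param K symmetric PSD (within tolerance) Gram matrix.
#' @param y labels in \{-1, +1\}.
#' @param c regularization parameter (> 0); ridge `lambda = 1/c`.
#' @return object of class `cpi_model` with `kind = "rls"`, `bias = 0`.
#' @export
rls_train <- function(K, y, c = 0.25) {
  y <- as_pm1(y)
  n <- length(y)
  stopifnot(is.matrix(K), nrow(K) == n, ncol(K) == n, c > 0)
  if (max(abs(K - t(K))) > 1e-8) stop("kernel matrix is not symmetric")
  if (length(unique(y)) < 2L) warning("rls_train with single-class labels")
  lambda <- 1 / c
  a <- solve(K + diag(lambda, n), y)
  ids <- rownames(K) %||0% as.character(seq_len(n))
  structure(list(
    kind = "rls",
    dual_coefficients = as.numeric(a),
    bias = 0,
    training_instance_ids = ids,
    params = list(c = c, lambda = lambda),
    threshold = 0,
    training_scores = as.numeric(crossprod(K, as.numeric(a)))
  ), class = "cpi_model")
}

as_pm1 <- function(y) {
  if (is.logical(y)) return(ifelse(y, 1, -1))
  if (is.character(y)) return(ifelse(y == "functional", 1, -1))
  y <- as.numeric(y)
  stopifnot(all(y %in% c(-1, 1)))
  y
}

#' Decision scores for new instances from a trained model
#'
#' @param model a `cpi_model`.
#' @param K_cross matrix of kernel values `k(train_i, test_j)` with one row
#'   per training instance (in training order) and one column per test
#'   instance.
#' @return numeric vector of decision scores (one per test instance).
#' @export
predict_scores <- function(model, K_cross) {
  stopifnot(inherits(model, "cpi_model"))
  if (is.vector(K_cross)) K_cross <- matrix(K_cross, ncol = 1L)
  if (nrow(K_cross) != length(model$dual_coefficients)) {
    stop("K_cross must have one row per training instance (",
         length(model$dual_coefficients), "), got ", nrow(K_cross))
  }
  as.numeric(crossprod(K_cross, model$dual_coefficients)) + model$bias
}

#' @export
predict.cpi_model <- function(object, K_cross, ...) {
  predict_scores(object, K_cross)
}

#' Threshold decision scores into hard labels
#'
#' Strictly greater than: a score exactly equal to the threshold is
#' classified negative, which keeps precision maximization at high
#' thresholds well-defined.
#'
#' @param scores numeric decision scores.
#' @param t threshold (default 0; `-Inf` labels everything positive).
#' @return integer vector in \{-1, +1\}.
#' @export
threshold_labels <- function(scores, t = 0) {
  ifelse(scores > t, 1L, -1L)
}

# ---- model serialization ----------------------------------------------------

#' Write a trained model to a portable structured-text file
#' @param model a `cpi_model`.
#' @param path output file path.
#' @param fingerprint optional named character vector recording the
#'   preprocessing configuration (verb-list hash, parser backend, kernel
#'   parameters); checked at predict time by the pipeline commands.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, fingerprint = character()) {
  stopifnot(inherits(model, "cpi_model"))
  lines <- c(
    "cpirex-model 1",
    paste0("kind\t", model$kind),
    paste0("bias\t", format(model$bias, digits = 17)),
    paste0("threshold\t", format(model$threshold, digits = 17)),
    paste0("params\t", paste(names(model$params),
                             vapply(model$params, format, "", digits = 17),
                             sep = "=", collapse = " ")),
    paste0("fingerprint\t", paste(names(fingerprint), fingerprint,
                                  sep = "=", collapse = " ")),
    paste0("n\t", length(model$dual_coefficients)),
    paste(model$training_instance_ids,
          vapply(model$dual_coefficients, format, "", digits = 17),
          sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a model written by [write_model()]
#' @param path file path.
#' @return list with `model` (a `cpi_model`) and `fingerprint`.
#' @export
read_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!identical(lines[1], "cpirex-model 1")) {
    stop("not a cpirex model file (bad magic line)")
  }
  field <- function(name) {
    ln <- grep(paste0("^", name, "\t"), lines, value = TRUE)[1]
    sub(paste0("^", name, "\t"), "", ln)
  }
  parse_kv <- function(s) {
    if (!nzchar(s)) return(character())
    items <- strsplit(s, " ", fixed = TRUE)[[1]]   # values contain no spaces
    setNames(sub("^[^=]*=", "", items), sub("=.*$", "", items))
  }
  n <- as.integer(field("n"))
  coef_lines <- tail(lines, n)
  parts <- strsplit(coef_lines, "\t", fixed = TRUE)
  params_chr <- parse_kv(field("params"))
  model <- structure(list(
    kind = field("kind"),
    dual_coefficients = vapply(parts, function(p) as.numeric(p[2]), 0),
    bias = as.numeric(field("bias")),
    training_instance_ids = vapply(parts, `[`, "", 1),
    params = lapply(as.list(params_chr), as.numeric),
    threshold = as.numeric(field("threshold"))
  ), class = "cpi_model")
  list(model = model, fingerprint = parse_kv(field("fingerprint")))
}
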