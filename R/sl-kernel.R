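# Shallow linguistic kernel: sum of a global context kernel (bag-of-n-grams
# over fore-between / between / between-after token patterns, candidate
# placeholders excluded) and a local context kernel (position-indexed
# orthographic/POS indicator features in windows around each candidate).
# Every sub-kernel is the cosine-normalized dot product of explicit sparse
# feature vectors; empty patterns contribute 0.

SEP <- "\x1f"  # joins gram members / feature key fields

#' Shallow linguistic kernel parameters
#' @param n maximum n-gram length for the global context kernel (the
#'   evaluated grid is 1..3).
#' @param w window size for the local context kernel (grid 1..3).
#' @return list of class `sl_params`.
#' @export
sl_params <- function(n = 3L, w = 1L) {
  n <- as.integer(n); w <- as.integer(w)
  stopifnot(n >= 1L, w >= 1L)
  if (n > 3L || w > 3L) {
    warning("sl_params outside the evaluated 1..3 grid (n=", n, ", w=", w, ")")
  }
  structure(list(n = n, w = w), class = "sl_params")
}

#' Extract the three global context token patterns of a blinded instance
#'
#' fb = tokens before the first candidate placeholder plus tokens between
#' the placeholders; b = tokens between; ba = tokens between plus tokens
#' after the second placeholder. The candidate placeholders themselves are
#' excluded from all three patterns; "first"/"second" is by surface
#' position, not entity type. Other-entity placeholders participate as
#' ordinary tokens.
#'
#' @param inst a `cpi_instance` from [blind_entities()].
#' @return list with character vectors `fb`, `b`, `ba`.
#' @export
extract_global_contexts <- function(inst) {
  stopifnot(inherits(inst, "cpi_instance"), !inst$degenerate)
  s <- inst$tokens$surface
  i1 <- inst$e1_index + 1L     # 1-based
  i2 <- inst$e2_index + 1L
  fore <- if (i1 > 1L) s[seq_len(i1 - 1L)] else character()
  between <- if (i2 - i1 > 1L) s[(i1 + 1L):(i2 - 1L)] else character()
  after <- if (i2 < length(s)) s[(i2 + 1L):length(s)] else character()
  list(fb = c(fore, between), b = between, ba = c(between, after))
}

#' Bag of contiguous k-grams, k = 1..n, over lowercased surfaces
#'
#' The bag (multiset) of grams is unordered, but token order *within* a
#' gram is preserved (standard n-gram semantics).
#'
#' @param tokens character vector of token surfaces.
#' @param n maximum gram length.
#' @return named numeric vector of counts (empty for an empty sequence).
#' @export
ngram_vector <- function(tokens, n) {
  stopifnot(n >= 1L)
  m <- length(tokens)
  if (!m) return(setNames(numeric(0), character(0)))
  tokens <- tolower(tokens)
  keys <- character(0)
  for (k in seq_len(min(n, m))) {
    if (k == 1L) {
      keys <- c(keys, tokens)
    } else {
      starts <- seq_len(m - k + 1L)
      keys <- c(keys, vapply(starts, function(i)
        paste(tokens[i:(i + k - 1L)], collapse = SEP), ""))
    }
  }
  tab <- table(keys)
  setNames(as.numeric(tab), names(tab))
}

# cosine-normalized sparse dot product; 0 if either vector is empty
normdot <- function(x, y) {
  if (!length(x) || !length(y)) return(0)
  shared <- intersect(names(x), names(y))
  num <- if (length(shared)) sum(x[shared] * y[shared]) else 0
  num / sqrt(sum(x^2) * sum(y^2))
}

#' Global context kernel between two instances' patterns
#'
#' Sum over the three patterns (fb, b, ba) of the cosine-normalized n-gram
#' vector dot products; bounded by \[0, 3\].
#'
#' @param g1,g2 outputs of [extract_global_contexts()].
#' @param n maximum gram length.
#' @return numeric in \[0, 3\].
#' @export
global_kernel <- function(g1, g2, n) {
  sum(vapply(c("fb", "b", "ba"), function(p)
    normdot(ngram_vector(g1[[p]], n), ngram_vector(g2[[p]], n)), 0))
}

#' Local context indicator features of a blinded instance
#'
#' For each candidate placeholder (entity 1 = first by position, entity 2 =
#' second) and each in-bounds window offset -w..-1 (left) and +1..+w
#' (right), indicator features are emitted for the neighbor token's
#' lowercased surface, POS tag, and the three orthographic flags. Feature
#' keys encode (side, entity, relative position, kind, value), so the same
#' word at different offsets yields different features.
#'
#' @param inst a `cpi_instance`.
#' @param w window size.
#' @return list with named numeric indicator vectors `left` and `right`.
#' @export
extract_local_contexts <- function(inst, w) {
  stopifnot(inherits(inst, "cpi_instance"), !inst$degenerate, w >= 1L)
  tok <- inst$tokens
  m <- nrow(tok)
  feats <- list(left = character(0), right = character(0))
  anchors <- c(e1 = inst$e1_index, e2 = inst$e2_index)
  for (ent in names(anchors)) {
    a <- anchors[[ent]]
    for (d in seq_len(w)) {
      for (side in c("left", "right")) {
        j <- if (side == "left") a - d else a + d   # 0-based neighbor
        if (j < 0L || j >= m) next
        row <- j + 1L
        rel <- if (side == "left") -d else d
        key <- function(kind, val)
          paste(ent, rel, kind, val, sep = SEP)
        feats[[side]] <- c(feats[[side]],
          key("surface", tolower(tok$surface[row])),
          key("pos", tok$pos[row]),
          key("cap", tok$is_capitalized[row]),
          key("punct", tok$is_punct[row]),
          key("num", tok$is_numeral[row]))
      }
    }
  }
  lapply(feats, function(k) setNames(rep(1, length(k)), k))
}

#' Local context kernel between two instances
#'
#' Sum of the cosine-normalized dot products of the left-side and
#' right-side indicator vectors; bounded by \[0, 2\].
#'
#' @param l1,l2 outputs of [extract_local_contexts()] (same `w`).
#' @return numeric in \[0, 2\].
#' @export
local_kernel <- function(l1, l2) {
  normdot(l1$left, l2$left) + normdot(l1$right, l2$right)
}

#' Shallow linguistic kernel value for one instance pair
#' @param i1,i2 `cpi_instance` objects.
#' @param params an [sl_params()] object.
#' @return numeric in \[0, 5\].
#' @export
sl_kernel_value <- function(i1, i2, params = sl_params()) {
  global_kernel(extract_global_contexts(i1), extract_global_contexts(i2),
                params$n) +
    local_kernel(extract_local_contexts(i1, params$w),
                 extract_local_contexts(i2, params$w))
}

# Sparse row-normalized feature matrix over a list of named numeric vectors.
# Zero rows (empty vectors) stay zero, so empty patterns contribute 0.
sparse_feature_matrix <- function(vecs) {
  keys <- unique(unlist(lapply(vecs, names), use.names = FALSE))
  n <- length(vecs)
  if (!length(keys)) return(Matrix::sparseMatrix(i = integer(), j = integer(),
                                                 x = numeric(),
                                                 dims = c(n, 0L)))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (r in seq_len(n)) {
    v <- vecs[[r]]
    if (!length(v)) next
    ii <- c(ii, rep(r, length(v)))
    jj <- c(jj, match(names(v), keys))
    xx <- c(xx, unname(v))
  }
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(n, length(keys)))
  nrm <- sqrt(Matrix::rowSums(X^2))
  nrm[nrm == 0] <- 1
  Matrix::Diagonal(x = 1 / nrm) %*% X
}

#' Shallow linguistic kernel Gram matrix
#'
#' `K[i, j]` is the sum of the three normalized global-pattern kernels and
#' the two normalized local-window kernels, computed via sparse feature
#' matrices. Symmetric and positive semidefinite (a sum of cosine kernels);
#' the diagonal equals 5 for instances with all patterns non-empty.
#'
#' @param instances list of `cpi_instance` (non-degenerate).
#' @param params an [sl_params()] object.
#' @return dense symmetric numeric matrix with instance `pair_id` dimnames.
#' @export
sl_kernel_matrix <- function(instances, params = sl_params()) {
  stopifnot(length(instances) >= 1L)
  if (any(vapply(instances, `[[`, TRUE, "degenerate"))) {
    stop("degenerate instances must be excluded before kernel computation")
  }
  g <- lapply(instances, extract_global_contexts)
  l <- lapply(instances, extract_local_contexts, w = params$w)
  parts <- list(
    lapply(g, function(x) ngram_vector(x$fb, params$n)),
    lapply(g, function(x) ngram_vector(x$b, params$n)),
    lapply(g, function(x) ngram_vector(x$ba, params$n)),
    lapply(l, `[[`, "left"),
    lapply(l, `[[`, "right"))
  n <- length(instances)
  K <- matrix(0, n, n)
  for (vecs in parts) {
    X <- sparse_feature_matrix(vecs)
    K <- K + as.matrix(Matrix::tcrossprod(X))
  }
  ids <- vapply(instances, `[[`, "", "pair_id")
  dimnames(K) <- list(ids, ids)
  (K + t(K)) / 2
}
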