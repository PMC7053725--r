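# All-paths graph kernel over weighted dependency graphs. Tokens are
# vertices carrying label sets (surface/placeholder, POS, incoming
# dependency type); each dependency edge is inserted in both orientations,
# weighted w_sp if it lies on a shortest path between the candidate
# entities, else w_other. Summing the adjacency powers (Neumann series,
# identity subtracted) gives total path weights between all vertex pairs;
# the label allocation matrix projects these onto label pairs; two
# instances are compared by the Frobenius inner product of their
# label-pair matrices, cosine-normalized.

#' All-paths graph kernel parameters
#'
#' @param c regularization parameter of the downstream RLS classifier
#'   (evaluated grid 0.25, 0.5, 1, 2); mapped to ridge `lambda = 1/c`.
#' @param w_sp weight of edges on a shortest path between the candidate
#'   entities (highest emphasis).
#' @param w_other weight of all other edges.
#' @param d_max truncation length for the series fallback when the Neumann
#'   series diverges; `NULL` means `2 * n_vertices` at call time.
#' @param use_dep_labels attach `dep:TYPE` vertex labels (default `TRUE`).
#' @return list of class `apg_params`.
#' @export
apg_params <- function(c = 0.25, w_sp = 0.9, w_other = 0.3, d_max = NULL,
                       use_dep_labels = TRUE) {
  stopifnot(c > 0, w_other > 0, w_other <= w_sp, w_sp < 1,
            is.null(d_max) || d_max >= 1)
  structure(list(c = c, w_sp = w_sp, w_other = w_other, d_max = d_max,
                 use_dep_labels = use_dep_labels),
            class = "apg_params")
}

#' Edges on any shortest path between two token spans
#'
#' Edges are treated as undirected and unit-length. Returns the union of
#' edges lying on *any* path of minimal length between any token of
#' `span1` and any token of `span2`; empty if the spans are disconnected.
#'
#' @param edges data.frame `head`, `dependent` (0-based indices).
#' @param span1,span2 integer vectors of 0-based token indices.
#' @param n_vertices vertex count.
#' @return character vector of undirected edge keys `"u-v"` with `u < v`.
#' @export
shortest_path_edges <- function(edges, span1, span2, n_vertices) {
  if (!nrow(edges)) return(character(0))
  adj <- vector("list", n_vertices)
  for (r in seq_len(nrow(edges))) {
    u <- edges$head[r] + 1L; v <- edges$dependent[r] + 1L
    adj[[u]] <- c(adj[[u]], v - 1L)
    adj[[v]] <- c(adj[[v]], u - 1L)
  }
  bfs <- function(sources) {
    dist <- rep(Inf, n_vertices)
    dist[sources + 1L] <- 0
    frontier <- sources
    d <- 0
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        for (v in adj[[u + 1L]]) {
          if (is.infinite(dist[v + 1L])) {
            dist[v + 1L] <- d + 1
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- unique(nxt)
      d <- d + 1
    }
    dist
  }
  d1 <- bfs(unique(span1))
  d2 <- bfs(unique(span2))
  D <- min(d1[span2 + 1L])
  if (is.infinite(D)) return(character(0))
  keys <- character(0)
  for (r in seq_len(nrow(edges))) {
    u <- edges$head[r]; v <- edges$dependent[r]
    on_path <- (d1[u + 1L] + 1 + d2[v + 1L] == D) ||
               (d1[v + 1L] + 1 + d2[u + 1L] == D)
    if (isTRUE(on_path)) {
      keys <- c(keys, paste(min(u, v), max(u, v), sep = "-"))
    }
  }
  unique(keys)
}

#' Build the weighted graph and label allocation of a blinded instance
#'
#' One vertex per blinded token. Vertex labels: the lowercased surface (or
#' placeholder), `pos:POS`, and `dep:TYPE` for the token's incoming
#' dependency if present and enabled. Each dependency edge is inserted in
#' both orientations; weight `w_sp` if its undirected edge lies on a
#' shortest path between the candidate placeholders, else `w_other`.
#'
#' @param inst a non-degenerate `cpi_instance` with >= 2 tokens.
#' @param params an [apg_params()] object.
#' @return list with `W` (adjacency matrix), `L` (binary vertex x label
#'   matrix with label colnames), `connected` (logical: candidate spans
#'   connected).
#' @export
build_weighted_graph <- function(inst, params = apg_params()) {
  stopifnot(inherits(inst, "cpi_instance"))
  if (inst$degenerate || nrow(inst$tokens) < 2L) {
    stop("degenerate instance '", inst$pair_id, "' (needs >= 2 vertices)")
  }
  tok <- inst$tokens
  m <- nrow(tok)
  sp <- shortest_path_edges(inst$edges, inst$e1_index, inst$e2_index, m)
  W <- matrix(0, m, m)
  ed <- inst$edges
  for (r in seq_len(nrow(ed))) {
    u <- ed$head[r]; v <- ed$dependent[r]
    key <- paste(min(u, v), max(u, v), sep = "-")
    w <- if (key %in% sp) params$w_sp else params$w_other
    W[u + 1L, v + 1L] <- w
    W[v + 1L, u + 1L] <- w
  }

  labs_per_vertex <- vector("list", m)
  placeholders <- c("COMPOUND_C", "PROTEIN_C", "COMPOUND_O", "PROTEIN_O")
  for (i in seq_len(m)) {
    surf <- tok$surface[i]
    l <- c(if (surf %in% placeholders) surf else tolower(surf),
           paste0("pos:", tok$pos[i]))
    if (params$use_dep_labels && nrow(ed)) {
      inc <- ed$dep_type[ed$dependent == i - 1L]
      if (length(inc)) l <- c(l, paste0("dep:", inc[1]))
    }
    labs_per_vertex[[i]] <- unique(l)
  }
  alphabet <- unique(unlist(labs_per_vertex))
  L <- matrix(0, m, length(alphabet), dimnames = list(NULL, alphabet))
  for (i in seq_len(m)) L[i, labs_per_vertex[[i]]] <- 1

  list(W = W, L = L, connected = length(sp) > 0)
}

#' Sum of all positive-length weighted path (walk) matrices
#'
#' If the spectral radius of `W` is below `1 - 1e-6`, the closed-form
#' Neumann sum `(I - W)^-1 - I` is returned. Otherwise the truncated series
#' `W + W^2 + ... + W^d_max` is returned and the attribute `truncated` is
#' set to `TRUE`.
#'
#' @param W square non-negative adjacency matrix.
#' @param d_max truncation length for the fallback.
#' @return matrix of summed path weights with attribute `truncated`.
#' @export
all_paths_matrix <- function(W, d_max = 2L * nrow(W)) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W), all(W >= 0))
  n <- nrow(W)
  rho <- if (n) max(Mod(eigen(W, only.values = TRUE)$values)) else 0
  if (rho <= 1 - 1e-6) {
    M <- solve(diag(n) - W) - diag(n)
    attr(M, "truncated") <- FALSE
  } else {
    M <- matrix(0, n, n)
    P <- diag(n)
    for (k in seq_len(max(1L, d_max))) {
      P <- P %*% W
      M <- M + P
    }
    attr(M, "truncated") <- TRUE
  }
  M[M < 0] <- 0      # guard tiny negative round-off from the inverse
  M
}

#' Project path weights onto label pairs: G = t(L) M L
#'
#' `G[a, b]` is the total weight of paths from any vertex labeled `a` to
#' any vertex labeled `b`.
#'
#' @param L binary vertex x label allocation matrix (label colnames).
#' @param M all-paths matrix over the same vertices.
#' @return labels x labels matrix with label dimnames.
#' @export
feature_matrix <- function(L, M) {
  stopifnot(nrow(L) == nrow(M), ncol(M) == nrow(M))
  G <- t(L) %*% M %*% L
  dimnames(G) <- list(colnames(L), colnames(L))
  G
}

#' Frobenius inner product of two label-pair feature matrices
#'
#' The matrices are aligned on the union label alphabet (absent labels are
#' zero rows/columns), then multiplied entrywise and summed.
#'
#' @param G1,G2 outputs of [feature_matrix()].
#' @return numeric scalar.
#' @export
apg_kernel_value <- function(G1, G2) {
  shared <- intersect(rownames(G1), rownames(G2))
  if (!length(shared)) return(0)
  sum(G1[shared, shared, drop = FALSE] * G2[shared, shared, drop = FALSE])
}

# Per-instance label-pair feature matrix as a named sparse vector
# keyed "labelA\x1flabelB".
apg_feature_vector <- function(inst, params) {
  g <- build_weighted_graph(inst, params)
  d_max <- if (is.null(params$d_max)) 2L * nrow(g$W) else params$d_max
  M <- all_paths_matrix(g$W, d_max)
  G <- feature_matrix(g$L, M)
  nz <- which(G != 0, arr.ind = TRUE)
  if (!nrow(nz)) return(setNames(numeric(0), character(0)))
  setNames(G[nz],
           paste(rownames(G)[nz[, 1]], colnames(G)[nz[, 2]], sep = SEP))
}

#' All-paths graph kernel Gram matrix
#'
#' `K[i, j]` is the cosine-normalized Frobenius inner product of the two
#' instances' label-pair feature matrices (unit diagonal). Degenerate
#' instances must be excluded beforehand.
#'
#' @param instances list of non-degenerate `cpi_instance`.
#' @param params an [apg_params()] object.
#' @return dense symmetric matrix with unit diagonal and `pair_id`
#'   dimnames.
#' @export
apg_kernel_matrix <- function(instances, params = apg_params()) {
  stopifnot(length(instances) >= 1L)
  if (any(vapply(instances, `[[`, TRUE, "degenerate"))) {
    stop("degenerate instances must be excluded before kernel computation")
  }
  vecs <- lapply(instances, apg_feature_vector, params = params)
  X <- sparse_feature_matrix(vecs)   # row-normalized
  K <- as.matrix(Matrix::tcrossprod(X))
  ids <- vapply(instances, `[[`, "", "pair_id")
  dimnames(K) <- list(ids, ids)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  K
}
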