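chain_edges <- function(m) {
  data.frame(head = 0:(m - 2L), dependent = 1:(m - 1L), dep_type = "next",
             stringsAsFactors = FALSE)
}

test_that("shortest path edges cover all minimal paths", {
  # unique path on a chain
  expect_setequal(shortest_path_edges(chain_edges(4), 0L, 3L, 4L),
                  c("0-1", "1-2", "2-3"))

  # diamond: two equal shortest paths -> all four edges
  dia <- data.frame(head = c(0L, 0L, 1L, 2L), dependent = c(1L, 2L, 3L, 3L),
                    dep_type = "d", stringsAsFactors = FALSE)
  expect_setequal(shortest_path_edges(dia, 0L, 3L, 4L),
                  c("0-1", "0-2", "1-3", "2-3"))
  # brute-force cross-check: enumerate all simple paths 0 -> 3
  # (0-1-3 and 0-2-3, both length 2; edge 1-2 absent)
  expect_false("1-2" %in% shortest_path_edges(dia, 0L, 3L, 4L))

  # disconnected components -> empty set
  dis <- data.frame(head = c(0L, 2L), dependent = c(1L, 3L), dep_type = "d",
                    stringsAsFactors = FALSE)
  expect_length(shortest_path_edges(dis, 0L, 3L, 4L), 0L)

  # multi-token spans: minimal overall distance wins
  expect_setequal(shortest_path_edges(chain_edges(5), c(0L, 1L), 4L, 5L),
                  c("1-2", "2-3", "3-4"))
})

test_that("weighted graph gives shortest-path edges the higher weight", {
  # pair at the ends of a 3-token chain: whole chain is shortest path
  inst <- make_instance(c("CmpX", "inhibits", "ProtY"), 0L, 2L)
  g <- build_weighted_graph(inst, apg_params(w_sp = 0.9, w_other = 0.3))
  expect_equal(sum(g$W == 0.9), 4L)   # both orientations of both edges
  expect_equal(sum(g$W == 0.3), 0L)

  # pair at tokens 0 and 2 of a 4-token chain: last edge is off-path
  inst2 <- make_instance(c("CmpX", "binds", "ProtY", "."), 0L, 2L)
  g2 <- build_weighted_graph(inst2, apg_params(w_sp = 0.9, w_other = 0.3))
  expect_equal(g2$W[1, 2], 0.9)
  expect_equal(g2$W[2, 3], 0.9)
  expect_equal(g2$W[3, 4], 0.3)
  expect_equal(g2$W, t(g2$W))

  # vertex label set: surface, POS, incoming dependency type
  labs <- colnames(g$L)[g$L[2, ] == 1]
  expect_setequal(labs, c("inhibits", "pos:VBZ", "dep:next"))
  expect_true("COMPOUND_C" %in% colnames(g$L)[g$L[1, ] == 1])

  bad <- make_instance(c("CmpX", "x", "ProtY"), 0L, 2L)
  bad$degenerate <- TRUE
  expect_error(build_weighted_graph(bad, apg_params()), "degenerate")
})

test_that("all_paths_matrix matches the Neumann series and truncated sums", {
  W <- matrix(c(0, 0.5, 0, 0), 2, 2, byrow = TRUE)
  M <- all_paths_matrix(W)
  expect_equal(unname(M), W, ignore_attr = TRUE)
  expect_false(attr(M, "truncated"))

  # 3-chain, both directions, weight 0.3: closed form vs truncated series
  W3 <- matrix(0, 3, 3)
  W3[1, 2] <- W3[2, 1] <- W3[2, 3] <- W3[3, 2] <- 0.3
  M3 <- all_paths_matrix(W3)
  expect_gte(M3[1, 3], 0.09)              # includes the length-2 path
  expect_equal(unname(M3), brute_walk_sum(W3, 200), tolerance = 1e-9,
               ignore_attr = TRUE)

  # random graphs with spectral radius < 0.9: closed form == series
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    W <- matrix(runif(n * n) * (runif(n * n) < 0.4), n, n)
    diag(W) <- 0
    rho <- max(Mod(eigen(W, only.values = TRUE)$values))
    if (rho >= 0.9) W <- W * (0.8 / rho)
    M <- all_paths_matrix(W)
    expect_false(attr(M, "truncated"))
    expect_equal(unname(M), brute_walk_sum(W, 400), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }

  # divergent series: self-loop of weight 1 -> truncated branch
  Wd <- matrix(c(1, 0, 0, 0), 2, 2)
  Md <- all_paths_matrix(Wd, d_max = 5)
  expect_true(attr(Md, "truncated"))
  expect_equal(Md[1, 1], 5)               # 1 + 1 + ... five times

  expect_error(all_paths_matrix(matrix(-1, 1, 1)), "W >= 0|non-negative")
})

test_that("feature matrix G = t(L) M L sums path weight by label pairs", {
  # L = identity -> G = M
  M <- matrix(c(0, 0.4, 0, 0), 2, 2, byrow = TRUE)
  L <- diag(2); colnames(L) <- c("x", "y")
  expect_equal(unname(feature_matrix(L, M)), M)

  # single edge u->v weight 0.5 with labels x, y
  G <- feature_matrix(L, matrix(c(0, 0.5, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(G["x", "y"], 0.5)
  expect_equal(sum(G), 0.5)

  # a vertex with two labels contributes to both rows/columns
  L2 <- matrix(c(1, 1, 0, 0, 0, 1), 2, 3,
               dimnames = list(NULL, c("x", "x2", "y")), byrow = TRUE)
  G2 <- feature_matrix(L2, matrix(c(0, 0.5, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(G2["x", "y"], 0.5)
  expect_equal(G2["x2", "y"], 0.5)
  # column sums of L explain the totals
  expect_equal(sum(G2), 0.5 * sum(L2[1, ]) * sum(L2[2, ]))

  expect_error(feature_matrix(diag(3), M), "nrow")
})

test_that("feature matrix equals brute-force path enumeration on a DAG", {
  # 5-vertex DAG with distinct labels; walks = paths here (acyclic)
  W <- matrix(0, 5, 5)
  W[1, 2] <- 0.9; W[2, 3] <- 0.3; W[1, 4] <- 0.3; W[4, 3] <- 0.3
  W[3, 5] <- 0.9
  L <- diag(5); colnames(L) <- letters[1:5]
  M <- all_paths_matrix(W)
  G <- feature_matrix(L, M)
  enum <- brute_walk_enum(W, 10)   # longest path length 3 < 10
  expect_equal(unname(G), enum, tolerance = 1e-12)
  # spot values: a->c via b (0.27) and via d (0.09)
  expect_equal(G["a", "c"], 0.9 * 0.3 + 0.3 * 0.3, tolerance = 1e-12)
  expect_equal(G["a", "e"], (0.27 + 0.09) * 0.9, tolerance = 1e-12)
})

test_that("apg kernel values follow the Frobenius inner product", {
  G1 <- diag(2); dimnames(G1) <- list(c("x", "y"), c("x", "y"))
  expect_equal(apg_kernel_value(G1, G1), 2.0)

  G2 <- diag(2); dimnames(G2) <- list(c("p", "q"), c("p", "q"))
  expect_equal(apg_kernel_value(G1, G2), 0.0)

  A <- matrix(1:4, 2, 2, byrow = TRUE, dimnames = list(c("x", "y"),
                                                       c("x", "y")))
  B <- matrix(1, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(apg_kernel_value(A, B), 10.0)
})

test_that("apg kernel matrix is unit-diagonal, symmetric, PSD", {
  i1 <- make_instance(c("CmpX", "inhibits", "ProtY"), 0L, 2L)
  expect_equal(unname(apg_kernel_matrix(list(i1))), matrix(1, 1, 1))

  K2 <- apg_kernel_matrix(list(i1, i1))
  expect_equal(unname(K2[1, 2]), 1.0, tolerance = 1e-12)

  insts <- random_instances(8, seed = 13)
  K <- apg_kernel_matrix(insts, apg_params())
  expect_equal(K, t(K))
  expect_equal(unname(diag(K)), rep(1, 8))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
})

test_that("raising w_sp does not decrease shortest-path label-pair weights", {
  # weights kept inside the convergent regime (undirected 3-chain has
  # spectral radius w_sp * sqrt(2)), so all comparisons use the closed form
  inst <- make_instance(c("CmpX", "inhibits", "ProtY"), 0L, 2L)
  for (wsp in c(0.35, 0.5, 0.65)) {
    g <- build_weighted_graph(inst, apg_params(w_sp = wsp, w_other = 0.3))
    M <- all_paths_matrix(g$W)
    expect_false(attr(M, "truncated"))
    G <- feature_matrix(g$L, M)
    if (wsp > 0.35) {
      expect_true(all(G[c("COMPOUND_C"), c("PROTEIN_C")] >=
                        prevG[c("COMPOUND_C"), c("PROTEIN_C")]))
    }
    prevG <- G
  }
})
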