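# Shared fixture builders. Everything is constructed in code; no files.

TEST_VERBS <- c("inhibit", "increase", "activate", "bind", "mediate")

# A one-sentence document with a compound, a protein, and one labeled pair.
make_simple_sentence <- function(text = "Aspirin inhibits COX-2.",
                                 comp = "Aspirin", prot = "COX-2",
                                 sent_id = "s1", label = "functional") {
  cs <- regexpr(comp, text, fixed = TRUE)
  ps <- regexpr(prot, text, fixed = TRUE)
  e1 <- entity(paste0(sent_id, ".e1"), "compound",
               cs - 1L, cs - 1L + nchar(comp), comp)
  e2 <- entity(paste0(sent_id, ".e2"), "protein",
               ps - 1L, ps - 1L + nchar(prot), prot)
  s <- sentence(sent_id, text, list(e1, e2))
  s$pairs <- list(candidate_pair(paste0(sent_id, ".p1"), e1$ent_id,
                                 e2$ent_id, label))
  s
}

make_simple_corpus <- function(label = "functional") {
  corpus(list(document("d1", list(make_simple_sentence(label = label)))))
}

# Blinded instance straight from surfaces: entities are single tokens
# named COMP/PROT placed at given 0-based positions in `words`.
make_instance <- function(words, comp_pos, prot_pos, sent_id = "t1",
                          label = "functional", verbs = TEST_VERBS) {
  text <- paste(words, collapse = " ")
  starts <- cumsum(c(0L, nchar(words) + 1L))[seq_along(words)]
  e1 <- entity(paste0(sent_id, ".e1"), "compound", starts[comp_pos + 1L],
               starts[comp_pos + 1L] + nchar(words[comp_pos + 1L]),
               words[comp_pos + 1L])
  e2 <- entity(paste0(sent_id, ".e2"), "protein", starts[prot_pos + 1L],
               starts[prot_pos + 1L] + nchar(words[prot_pos + 1L]),
               words[prot_pos + 1L])
  s <- sentence(sent_id, text, list(e1, e2))
  p <- candidate_pair(paste0(sent_id, ".p1"), e1$ent_id, e2$ent_id, label)
  s$pairs <- list(p)
  parsed <- parse_sentence(s, verbs, "fixture")
  blind_entities(parsed, p)
}

# Random small instances for property tests (seeded by caller).
random_instances <- function(n, seed = 1) {
  cfg <- synth_config(n_docs = n, sentences_per_doc = 1L, seed = seed,
                      p_verb_given_pos = 0.9, p_verb_given_neg = 0.1)
  x <- generate_corpus(cfg)
  b <- build_instances(x)
  b$instances[!b$meta$degenerate]
}

# Brute-force n-gram bag (independent of ngram_vector's implementation).
brute_ngram_bag <- function(tokens, n) {
  tokens <- tolower(tokens)
  out <- character(0)
  for (k in seq_len(n)) {
    if (length(tokens) < k) break
    for (i in seq_len(length(tokens) - k + 1L)) {
      out <- c(out, paste(tokens[i:(i + k - 1L)], collapse = "\x1f"))
    }
  }
  out
}

brute_cosine <- function(bag1, bag2) {
  if (!length(bag1) || !length(bag2)) return(0)
  t1 <- table(bag1); t2 <- table(bag2)
  shared <- intersect(names(t1), names(t2))
  num <- sum(as.numeric(t1[shared]) * as.numeric(t2[shared]))
  num / sqrt(sum(as.numeric(t1)^2) * sum(as.numeric(t2)^2))
}

# Cosine of two named numeric vectors, computed by explicit densification.
normdot_oracle <- function(x, y) {
  keys <- union(names(x), names(y))
  if (!length(keys) || !length(x) || !length(y)) return(0)
  xv <- setNames(numeric(length(keys)), keys); xv[names(x)] <- x
  yv <- setNames(numeric(length(keys)), keys); yv[names(y)] <- y
  sum(xv * yv) / sqrt(sum(xv^2) * sum(yv^2))
}

# Brute-force AUC by pair enumeration.
brute_auc <- function(labels, scores) {
  pos <- scores[labels > 0]; neg <- scores[labels < 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  100 * total / (length(pos) * length(neg))
}

# Brute-force sum over all directed paths (no repeated vertices needed:
# walks) up to length kmax via explicit power accumulation, entrywise.
brute_walk_sum <- function(W, kmax) {
  M <- matrix(0, nrow(W), ncol(W))
  P <- diag(nrow(W))
  for (k in seq_len(kmax)) {
    P <- P %*% W
    M <- M + P
  }
  M
}

# Enumerate all directed walks up to length kmax by DFS, summing weight
# products by (start, end) vertex; equivalent to brute_walk_sum but built
# from path enumeration rather than matrix algebra.
brute_walk_enum <- function(W, kmax) {
  n <- nrow(W)
  M <- matrix(0, n, n)
  recurse <- function(v, w, depth, start) {
    if (depth > kmax) return()
    for (u in seq_len(n)) {
      if (W[v, u] > 0) {
        M[start, u] <<- M[start, u] + w * W[v, u]
        recurse(u, w * W[v, u], depth + 1L, start)
      }
    }
  }
  for (s in seq_len(n)) recurse(s, 1, 1L, s)
  M
}
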