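#' @importFrom Matrix sparseMatrix tcrossprod Diagonal rowSums
#' @importFrom stats pchisq runif setNames
#' @importFrom utils head tail
NULL

# ---- constructors -----------------------------------------------------------

#' Create an annotated entity
#'
#' An entity is a contiguous character span of a sentence annotated as a
#' chemical compound or a protein. Offsets are 0-based, end-exclusive,
#' relative to the sentence text.
#'
#' @param ent_id unique id within the sentence.
#' @param ent_type `"compound"` or `"protein"`.
#' @param char_start,char_end 0-based, end-exclusive character offsets.
#' @param surface the covered text; must equal the slice of the sentence.
#' @param norm_id optional database identifier (e.g. PubChem CID, UniProt).
#' @return an object of class `cpi_entity`.
#' @export
entity <- function(ent_id, ent_type, char_start, char_end, surface,
                   norm_id = NA_character_) {
  stopifnot(is.character(ent_id), nzchar(ent_id))
  ent_type <- match.arg(ent_type, c("compound", "protein"))
  char_start <- as.integer(char_start)
  char_end <- as.integer(char_end)
  if (char_start >= char_end) {
    stop("entity '", ent_id, "': char_start must be < char_end")
  }
  structure(
    list(ent_id = ent_id, ent_type = ent_type,
         char_start = char_start, char_end = char_end,
         surface = surface, norm_id = norm_id),
    class = "cpi_entity"
  )
}

#' Create a candidate compound-protein pair
#'
#' @param pair_id unique id within the sentence.
#' @param compound_ref,protein_ref entity ids of the candidate members.
#' @param label `"functional"`, `"non_functional"` or `"unknown"`.
#' @param encloses_verb optional logical: does an interaction verb occur
#'   strictly between the two entities (token order)?
#' @return an object of class `cpi_pair`.
#' @export
candidate_pair <- function(pair_id, compound_ref, protein_ref,
                           label = "unknown", encloses_verb = NA) {
  label <- match.arg(label, c("functional", "non_functional", "unknown"))
  structure(
    list(pair_id = pair_id, compound_ref = compound_ref,
         protein_ref = protein_ref, label = label,
         encloses_verb = as.logical(encloses_verb)),
    class = "cpi_pair"
  )
}

#' Create a sentence
#'
#' @param sent_id unique id within the document.
#' @param text the sentence text.
#' @param entities list of [entity()] objects.
#' @param pairs list of [candidate_pair()] objects.
#' @return an object of class `cpi_sentence`.
#' @export
sentence <- function(sent_id, text, entities = list(), pairs = list()) {
  structure(
    list(sent_id = sent_id, text = text, entities = entities, pairs = pairs),
    class = "cpi_sentence"
  )
}

#' Create a document (one abstract / PubMed record)
#' @param doc_id document id, e.g. a PubMed ID. Must be non-empty.
#' @param sentences list of [sentence()] objects.
#' @return an object of class `cpi_document`.
#' @export
document <- function(doc_id, sentences = list()) {
  stopifnot(is.character(doc_id), nzchar(doc_id))
  structure(list(doc_id = doc_id, sentences = sentences),
            class = "cpi_document")
}

#' Create a corpus and validate its internal consistency
#'
#' @param documents list of [document()] objects.
#' @param source free-text provenance tag stored on serialization.
#' @param validate run full invariant checks (default `TRUE`).
#' @return an object of class `cpi_corpus`.
#' @export
corpus <- function(documents = list(), source = "cpirex", validate = TRUE) {
  x <- structure(list(documents = documents, source = source),
                 class = "cpi_corpus")
  if (validate) validate_corpus(x)
  x
}

# ---- validation -------------------------------------------------------------

#' Validate corpus invariants
#'
#' Checks id uniqueness, entity offsets against sentence text, surface
#' agreement, and pair references (compound_ref resolves to a compound
#' entity of the same sentence, protein_ref to a protein).
#'
#' @param x a `cpi_corpus`.
#' @return `x`, invisibly; stops with an informative error on violation.
#' @export
validate_corpus <- function(x) {
  stopifnot(inherits(x, "cpi_corpus"))
  doc_ids <- vapply(x$documents, `[[`, "", "doc_id")
  if (anyDuplicated(doc_ids)) {
    stop("duplicate doc_id: ", doc_ids[duplicated(doc_ids)][1])
  }
  for (doc in x$documents) {
    sent_ids <- vapply(doc$sentences, `[[`, "", "sent_id")
    if (anyDuplicated(sent_ids)) {
      stop("document '", doc$doc_id, "': duplicate sent_id")
    }
    for (s in doc$sentences) {
      n <- nchar(s$text)
      emap <- list()
      for (e in s$entities) {
        if (e$char_start < 0L || e$char_end > n) {
          stop("sentence '", s$sent_id, "': entity '", e$ent_id,
               "' offsets outside text")
        }
        got <- substr(s$text, e$char_start + 1L, e$char_end)
        if (!identical(got, e$surface)) {
          stop("sentence '", s$sent_id, "': entity '", e$ent_id,
               "' surface mismatch ('", e$surface, "' vs '", got, "')")
        }
        emap[[e$ent_id]] <- e$ent_type
      }
      for (p in s$pairs) {
        ct <- emap[[p$compound_ref]]
        pt <- emap[[p$protein_ref]]
        if (is.null(ct) || ct != "compound") {
          stop("sentence '", s$sent_id, "': pair '", p$pair_id,
               "' compound_ref '", p$compound_ref,
               "' does not resolve to a compound entity")
        }
        if (is.null(pt) || pt != "protein") {
          stop("sentence '", s$sent_id, "': pair '", p$pair_id,
               "' protein_ref '", p$protein_ref,
               "' does not resolve to a protein entity")
        }
      }
    }
  }
  invisible(x)
}

#' Corpus summary counts
#'
#' @param x a `cpi_corpus`.
#' @return list with `documents`, `sentences`, `pairs`, `positives`,
#'   `negatives`, `unknowns`. Always satisfies
#'   `positives + negatives + unknowns == pairs`.
#' @export
corpus_counts <- function(x) {
  stopifnot(inherits(x, "cpi_corpus"))
  n_sent <- 0L; n_pos <- 0L; n_neg <- 0L; n_unk <- 0L
  for (doc in x$documents) {
    n_sent <- n_sent + length(doc$sentences)
    for (s in doc$sentences) {
      for (p in s$pairs) {
        switch(p$label,
               functional = { n_pos <- n_pos + 1L },
               non_functional = { n_neg <- n_neg + 1L },
               unknown = { n_unk <- n_unk + 1L })
      }
    }
  }
  list(documents = length(x$documents), sentences = n_sent,
       pairs = n_pos + n_neg + n_unk,
       positives = n_pos, negatives = n_neg, unknowns = n_unk)
}

#' @export
print.cpi_corpus <- function(x, ...) {
  ct <- corpus_counts(x)
  cat("<cpi_corpus>", ct$documents, "documents,", ct$sentences, "sentences,",
      ct$pairs, "pairs (", ct$positives, "functional /", ct$negatives,
      "non-functional /", ct$unknowns, "unknown )\n")
  invisible(x)
}

# ---- pair enumeration -------------------------------------------------------

#' Enumerate candidate compound-protein pairs of a sentence
#'
#' Every compound entity is paired with every protein entity co-occurring in
#' the sentence (Cartesian product). Long-form and abbreviation mentions are
#' distinct entities and therefore distinct pair members. Order is
#' deterministic: by compound `char_start`, then protein `char_start`.
#'
#' @param s a `cpi_sentence`.
#' @param label label assigned to the generated pairs (default `"unknown"`).
#' @return list of `cpi_pair` objects (empty if either entity type absent).
#' @export
generate_candidate_pairs <- function(s, label = "unknown") {
  stopifnot(inherits(s, "cpi_sentence"))
  comps <- Filter(function(e) e$ent_type == "compound", s$entities)
  prots <- Filter(function(e) e$ent_type == "protein", s$entities)
  if (!length(comps) || !length(prots)) return(list())
  comps <- comps[order(vapply(comps, `[[`, 0L, "char_start"))]
  prots <- prots[order(vapply(prots, `[[`, 0L, "char_start"))]
  out <- vector("list", length(comps) * length(prots))
  k <- 0L
  for (ce in comps) {
    for (pe in prots) {
      k <- k + 1L
      out[[k]] <- candidate_pair(
        pair_id = paste0(s$sent_id, ".p", k),
        compound_ref = ce$ent_id, protein_ref = pe$ent_id, label = label)
    }
  }
  out
}

# ---- small shared helpers ---------------------------------------------------

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# FNV-1a 32-bit hash over the bytes of a character vector; returns hex string.
# Arithmetic kept below 2^53 so plain doubles are exact.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
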