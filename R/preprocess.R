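# Linguistic preprocessing: tokenization, sentence splitting, entity-token
# alignment, candidate blinding, enclosed-interaction-verb detection, and the
# pluggable dependency-parser contract.

PUNCT_RE <- "^[[:punct:]]+$"
NUM_RE <- "^[0-9]+([.,][0-9]+)?$"

#' Tokenize a sentence
#'
#' Whitespace-delimited tokenization with punctuation split off as separate
#' tokens. Word-internal hyphens, periods and commas are kept inside the
#' token (so "7-ketocholesterol", "COX-2" and "0.5" are single tokens while
#' a sentence-final "." is its own token). Character offsets into the input
#' are recorded so that entity spans can be aligned.
#'
#' Orthographic flags: `is_capitalized` (first char uppercase alphabetic),
#' `is_punct` (all chars punctuation), `is_numeral` (integer or decimal).
#' A part-of-speech tag is attached by a small rule set (see [tag_pos()]).
#'
#' @param text sentence text (non-empty string).
#' @param verbs optional interaction-verb lemma set, used by the rule-based
#'   tagger to assign verbal tags.
#' @return data.frame with columns `index` (0-based), `surface`,
#'   `char_start`, `char_end` (0-based end-exclusive), `pos`,
#'   `is_capitalized`, `is_punct`, `is_numeral`.
#' @export
tokenize <- function(text, verbs = character()) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  # a word runs alnum..alnum with internal [-._',/] ; anything else is a
  # single-character token
  pat <- "[[:alnum:]](?:[-._',/[:alnum:]]*[[:alnum:]])?|[^[:space:]]"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  surf <- substring(text, starts + 1L, starts + lens)
  tok <- data.frame(
    index = seq_along(surf) - 1L,
    surface = surf,
    char_start = starts,
    char_end = starts + lens,
    stringsAsFactors = FALSE
  )
  tok$is_capitalized <- grepl("^[A-Z]", surf)
  tok$is_punct <- grepl(PUNCT_RE, surf)
  tok$is_numeral <- grepl(NUM_RE, surf)
  tok$pos <- tag_pos(tok, verbs)
  tok[, c("index", "surface", "char_start", "char_end", "pos",
          "is_capitalized", "is_punct", "is_numeral")]
}

#' Rule-based part-of-speech tagging
#'
#' A deliberately small fixture-grade tagger (Penn-style tags) sufficient
#' for the kernels' feature spaces: punctuation -> its own surface class
#' ".", numerals -> "CD", tokens whose rudimentary lemma is in the
#' interaction-verb set -> "VBZ", "-ly" adverbs -> "RB", capitalized tokens
#' -> "NNP", everything else -> "NN". Real deployments plug in an external
#' tagger/parser through the backend contract instead.
#'
#' @param tok token data.frame (needs `surface`, `is_punct`, `is_numeral`).
#' @param verbs lowercased verb lemma set.
#' @return character vector of tags.
#' @export
tag_pos <- function(tok, verbs = character()) {
  s <- tok$surface
  tag <- rep("NN", nrow(tok))
  tag[grepl("^[A-Z]", s)] <- "NNP"
  tag[grepl("ly$", s)] <- "RB"
  if (length(verbs)) {
    tag[vapply(s, lemma_in_set, TRUE, verbs = verbs)] <- "VBZ"
  }
  tag[tok$is_numeral] <- "CD"
  tag[tok$is_punct] <- "."
  tag
}

#' Rudimentary lemmatization by suffix stripping
#'
#' Lowercases and strips the inflection suffixes `s`, `es`, `ed`, `ing`
#' (longest applicable first), restoring a dropped `e` for `-ing`/`-ed`
#' forms when that recovers a known shape is NOT attempted: the rule is the
#' documented fallback only.
#'
#' @param x character vector of surfaces.
#' @return lowercased candidate lemmas.
#' @export
rudimentary_lemma <- function(x) {
  x <- tolower(x)
  vapply(x, function(w) {
    if (grepl("ing$", w) && nchar(w) > 4) return(sub("ing$", "", w))
    if (grepl("ed$", w) && nchar(w) > 3) return(sub("ed$", "", w))
    if (grepl("es$", w) && nchar(w) > 3) return(sub("es$", "", w))
    if (grepl("s$", w) && nchar(w) > 2) return(sub("s$", "", w))
    w
  }, "", USE.NAMES = FALSE)
}

# Matches a lowercased surface against a lemma set, trying the surface
# itself and the suffix-stripped variants (an "-es" strip and an "-e"
# restoration for "-ed"/"-ing" forms, e.g. "increased" -> "increase").
lemma_in_set <- function(surface, verbs) {
  s <- tolower(surface)
  cand <- unique(c(
    s,
    sub("s$", "", s), sub("es$", "", s), sub("ed$", "", s),
    sub("ing$", "", s),
    sub("ed$", "e", s), sub("ing$", "e", s)
  ))
  any(cand %in% verbs)
}

#' Split text into sentences with character offsets
#'
#' Rule-based: a boundary is sentence-final punctuation (`.`, `!`, `?`)
#' followed by whitespace and an uppercase letter or digit, unless the
#' preceding word is a known abbreviation. Offsets are 0-based,
#' end-exclusive into the input.
#'
#' @param text input string.
#' @return data.frame with columns `start`, `end`, `text`.
#' @export
split_sentences <- function(text) {
  abbrev <- c("e.g", "i.e", "al", "fig", "figs", "dr", "prof", "vs", "etc",
              "no", "ref", "ca", "approx", "cf")
  n <- nchar(text)
  cand <- gregexpr("[.!?](?=\\s+[A-Z0-9])", text, perl = TRUE)[[1]]
  bounds <- integer()
  if (cand[1] != -1L) {
    for (pos in as.integer(cand)) {
      before <- substr(text, max(1L, pos - 12L), pos - 1L)
      lastword <- tolower(sub("^.*?([[:alnum:].]+)$", "\\1", before))
      lastword <- sub("\\.$", "", lastword)
      if (lastword %in% abbrev) next
      bounds <- c(bounds, pos)               # 1-based index of the punct char
    }
  }
  starts0 <- c(0L, bounds)                   # 0-based starts (pre-trim)
  ends0 <- c(bounds, n)                      # 0-based exclusive ends
  out <- data.frame(start = integer(), end = integer(), text = character(),
                    stringsAsFactors = FALSE)
  for (i in seq_along(starts0)) {
    s <- starts0[i]; e <- ends0[i]
    seg <- substr(text, s + 1L, e)
    lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    s <- s + lead; e <- e - trail
    if (e > s) {
      out <- rbind(out, data.frame(start = s, end = e,
                                   text = substr(text, s + 1L, e),
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

# ---- entity-token alignment -------------------------------------------------

#' Align entity character spans to token index spans
#'
#' Each entity maps to the minimal contiguous token range whose character
#' spans overlap the entity's character span.
#'
#' @param entities list of `cpi_entity`.
#' @param tokens token data.frame from [tokenize()].
#' @return data.frame `ent_id`, `first_token`, `last_token` (0-based,
#'   inclusive).
#' @export
align_entities <- function(entities, tokens) {
  out <- data.frame(ent_id = character(), first_token = integer(),
                    last_token = integer(), stringsAsFactors = FALSE)
  for (e in entities) {
    hit <- which(tokens$char_start < e$char_end & tokens$char_end > e$char_start)
    if (!length(hit)) {
      stop("entity '", e$ent_id, "' overlaps no token")
    }
    out <- rbind(out, data.frame(ent_id = e$ent_id,
                                 first_token = min(hit) - 1L,
                                 last_token = max(hit) - 1L,
                                 stringsAsFactors = FALSE))
  }
  out
}

# ---- dependency parsing contract -------------------------------------------

#' Dependency-parse a token sequence through a named backend
#'
#' The package defines a parser *contract*: a backend returns typed
#' head->dependent edges over the given token indices. The built-in
#' `"fixture"` backend deterministically returns the linear chain
#' `i -> i+1` typed `"next"`; adapters for real parsers register themselves
#' with [register_parser_backend()].
#'
#' @param tokens token data.frame.
#' @param backend backend name (default `"fixture"`).
#' @return data.frame `head`, `dependent` (0-based token indices),
#'   `dep_type`.
#' @export
dependency_parse <- function(tokens, backend = "fixture") {
  stopifnot(nrow(tokens) >= 1L)
  fn <- parser_backends[[backend]]
  if (is.null(fn)) stop("unknown parser backend '", backend, "'")
  edges <- fn(tokens)
  if (nrow(edges)) {
    stopifnot(all(edges$head != edges$dependent),
              all(edges$head >= 0L), all(edges$dependent >= 0L),
              all(edges$head < nrow(tokens)),
              all(edges$dependent < nrow(tokens)))
  }
  edges
}

parser_backends <- new.env(parent = emptyenv())

#' Register a dependency-parser backend
#' @param name backend name used in configs.
#' @param fn function(tokens) -> edge data.frame (`head`, `dependent`,
#'   `dep_type`).
#' @export
register_parser_backend <- function(name, fn) {
  assign(name, fn, envir = parser_backends)
  invisible(name)
}

fixture_parser <- function(tokens) {
  m <- nrow(tokens)
  if (m < 2L) {
    return(data.frame(head = integer(), dependent = integer(),
                      dep_type = character(), stringsAsFactors = FALSE))
  }
  data.frame(head = 0:(m - 2L), dependent = 1:(m - 1L),
             dep_type = "next", stringsAsFactors = FALSE)
}

register_parser_backend("fixture", fixture_parser)

#' Parse a sentence: tokens, entity alignment, dependency edges
#'
#' @param s a `cpi_sentence`.
#' @param verbs interaction-verb lemmas for the tagger.
#' @param backend parser backend name.
#' @return list of class `cpi_parsed` with `sentence`, `tokens`,
#'   `entity_spans`, `edges`.
#' @export
parse_sentence <- function(s, verbs = character(), backend = "fixture") {
  tok <- tokenize(s$text, verbs)
  spans <- align_entities(s$entities, tok)
  edges <- dependency_parse(tok, backend)
  structure(list(sentence = s, tokens = tok, entity_spans = spans,
                 edges = edges),
            class = "cpi_parsed")
}

# ---- candidate blinding -----------------------------------------------------

entity_span <- function(parsed, ent_id) {
  i <- match(ent_id, parsed$entity_spans$ent_id)
  if (is.na(i)) stop("entity '", ent_id, "' not aligned")
  c(parsed$entity_spans$first_token[i], parsed$entity_spans$last_token[i])
}

#' Blind the candidate (and optionally other) entities of an instance
#'
#' The candidate compound's tokens are collapsed into a single placeholder
#' token `COMPOUND_C`, the candidate protein's into `PROTEIN_C`. With
#' `blind_others = TRUE` (default) every other annotated entity is collapsed
#' to `COMPOUND_O` / `PROTEIN_O`. The placeholder inherits the POS tag of
#' the entity's head (last) token. Dependency edges are re-indexed onto the
#' collapsed token sequence; edges internal to a collapsed span are dropped,
#' duplicates merged.
#'
#' Instances whose candidate entities share tokens are flagged
#' `degenerate = TRUE` and excluded from kernel computation downstream.
#'
#' @param parsed a `cpi_parsed` sentence.
#' @param pair a `cpi_pair` of that sentence.
#' @param blind_others blind non-candidate entities too? Default `TRUE`.
#' @return list of class `cpi_instance`: `pair_id`, `label`,
#'   `encloses_verb`, `tokens`, `edges`, `e1_index`, `e2_index` (0-based
#'   indices of the first/second candidate placeholder by surface order),
#'   `degenerate`.
#' @export
blind_entities <- function(parsed, pair, blind_others = TRUE) {
  tok <- parsed$tokens
  m <- nrow(tok)
  cs <- entity_span(parsed, pair$compound_ref)
  ps <- entity_span(parsed, pair$protein_ref)

  degenerate <- max(cs[1], ps[1]) <= min(cs[2], ps[2])
  if (degenerate) {
    warning("pair '", pair$pair_id,
            "' has overlapping candidate entities; instance degenerate")
  }

  # group id per original token: 0 = keep as-is, otherwise collapse group
  group <- integer(m)                     # 0 means singleton
  glabel <- character(0)
  gpos <- character(0)
  add_group <- function(span, label) {
    gid <- length(glabel) + 1L
    glabel[[gid]] <<- label
    gpos[[gid]] <<- tok$pos[span[2] + 1L]  # head = last token of the span
    group[(span[1]:span[2]) + 1L] <<- gid
  }
  add_group(cs, "COMPOUND_C")
  if (!degenerate) add_group(ps, "PROTEIN_C")
  if (blind_others) {
    cand_ids <- c(pair$compound_ref, pair$protein_ref)
    for (e in parsed$sentence$entities) {
      if (e$ent_id %in% cand_ids) next
      sp <- entity_span(parsed, e$ent_id)
      # skip entities overlapping a candidate span (keep candidates intact)
      covered <- group[(sp[1]:sp[2]) + 1L]
      if (any(covered != 0L)) next
      add_group(sp, if (e$ent_type == "compound") "COMPOUND_O" else "PROTEIN_O")
    }
  }

  # build collapsed token sequence, preserving order
  new_surface <- character(0); new_pos <- character(0)
  new_of_old <- integer(m)               # new 0-based index per old token
  last_gid <- -1L
  for (i in seq_len(m)) {
    gid <- group[i]
    if (gid == 0L) {
      new_surface <- c(new_surface, tok$surface[i])
      new_pos <- c(new_pos, tok$pos[i])
      last_gid <- -1L
    } else if (gid != last_gid) {
      new_surface <- c(new_surface, glabel[gid])
      new_pos <- c(new_pos, gpos[gid])
      last_gid <- gid
    }
    new_of_old[i] <- length(new_surface) - 1L
  }
  ntok <- data.frame(
    index = seq_along(new_surface) - 1L,
    surface = new_surface, pos = new_pos,
    stringsAsFactors = FALSE)
  ntok$is_capitalized <- grepl("^[A-Z]", ntok$surface)
  ntok$is_punct <- grepl(PUNCT_RE, ntok$surface)
  ntok$is_numeral <- grepl(NUM_RE, ntok$surface)

  ed <- parsed$edges
  if (nrow(ed)) {
    nh <- new_of_old[ed$head + 1L]
    nd <- new_of_old[ed$dependent + 1L]
    keep <- nh != nd
    ed <- data.frame(head = nh[keep], dependent = nd[keep],
                     dep_type = ed$dep_type[keep], stringsAsFactors = FALSE)
    ed <- ed[!duplicated(ed[, c("head", "dependent", "dep_type")]), ,
             drop = FALSE]
    rownames(ed) <- NULL
  }

  c_new <- new_of_old[cs[1] + 1L]
  p_new <- if (degenerate) c_new else new_of_old[ps[1] + 1L]
  structure(list(
    pair_id = pair$pair_id, label = pair$label,
    encloses_verb = pair$encloses_verb,
    tokens = ntok, edges = ed,
    e1_index = min(c_new, p_new), e2_index = max(c_new, p_new),
    compound_index = c_new, protein_index = p_new,
    degenerate = degenerate
  ), class = "cpi_instance")
}

# ---- enclosed interaction verbs --------------------------------------------

#' Detect an interaction verb enclosed by a candidate pair
#'
#' `TRUE` iff at least one token strictly between the two candidate entity
#' token spans (in surface order, exclusive on both sides) has a verbal POS
#' tag and a lemma in the verb set. Lemma matching lowercases the surface
#' and falls back to rudimentary suffix stripping (`s`/`es`/`ed`/`ing`,
#' plus `-e` restoration). Symmetric in entity order.
#'
#' @param parsed a `cpi_parsed` sentence.
#' @param pair a `cpi_pair` of that sentence.
#' @param verbs lowercased interaction-verb lemma set.
#' @return logical scalar.
#' @export
detect_enclosed_interaction_verb <- function(parsed, pair, verbs) {
  cs <- entity_span(parsed, pair$compound_ref)
  ps <- entity_span(parsed, pair$protein_ref)
  lo <- min(cs[2], ps[2])                  # last token of the left span
  hi <- max(cs[1], ps[1])                  # first token of the right span
  if (hi - lo < 2L) return(FALSE)          # nothing strictly between
  between <- (lo + 1L):(hi - 1L)
  for (i in between) {
    row <- i + 1L
    if (!startsWith(parsed$tokens$pos[row], "V")) next
    if (lemma_in_set(parsed$tokens$surface[row], verbs)) return(TRUE)
  }
  FALSE
}
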