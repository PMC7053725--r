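# Unified interaction-corpus XML dialect:
#   <corpus source="..."><document id="..."><sentence id="..." text="...">
#     <entity id="..." type="compound|protein" charOffset="s-e" text="..."
#             normId="..."/>
#     <pair id="..." e1="COMPOUND_ID" e2="PROTEIN_ID" interaction="True|False"/>
#   </sentence></document></corpus>
# charOffset is printed inclusive-inclusive (the common PPI-corpus
# convention); internally offsets are 0-based end-exclusive.

#' Parse a unified interaction-corpus XML string
#'
#' @param xml_text XML as a single character string, or a file path.
#' @return a validated `cpi_corpus`.
#' @export
parse_unified_xml <- function(xml_text) {
  doc <- xml2::read_xml(xml_text)
  if (xml2::xml_name(doc) != "corpus") stop("root element must be <corpus>")
  docs <- lapply(xml2::xml_find_all(doc, "./document"), function(dn) {
    sents <- lapply(xml2::xml_find_all(dn, "./sentence"), function(sn) {
      sid <- xml2::xml_attr(sn, "id")
      text <- xml2::xml_attr(sn, "text")
      ents <- lapply(xml2::xml_find_all(sn, "./entity"), function(en) {
        off <- xml2::xml_attr(en, "charOffset")
        se <- as.integer(strsplit(off, "-", fixed = TRUE)[[1]])
        if (length(se) != 2L || anyNA(se)) {
          stop("sentence '", sid, "': malformed charOffset '", off, "'")
        }
        cs <- se[1]                     # inclusive start
        ce <- se[2] + 1L                # inclusive end -> exclusive
        if (cs < 0L || ce > nchar(text)) {
          stop("sentence '", sid, "': entity offset ", off,
               " outside sentence text")
        }
        norm <- xml2::xml_attr(en, "normId")
        entity(xml2::xml_attr(en, "id"), xml2::xml_attr(en, "type"),
               cs, ce, substr(text, cs + 1L, ce),
               norm_id = if (is.na(norm)) NA_character_ else norm)
      })
      prs <- lapply(xml2::xml_find_all(sn, "./pair"), function(pn) {
        inter <- xml2::xml_attr(pn, "interaction")
        label <- if (is.na(inter) || identical(inter, "unknown")) "unknown"
                 else if (identical(inter, "True")) "functional"
                 else if (identical(inter, "False")) "non_functional"
                 else stop("sentence '", sid, "': bad interaction attribute '",
                           inter, "'")
        candidate_pair(xml2::xml_attr(pn, "id"),
                       xml2::xml_attr(pn, "e1"), xml2::xml_attr(pn, "e2"),
                       label = label)
      })
      sentence(sid, text, ents, prs)
    })
    document(xml2::xml_attr(dn, "id"), sents)
  })
  corpus(docs, source = xml2::xml_attr(doc, "source") %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Serialize a corpus to the unified XML dialect
#'
#' Round-trip identity holds: `parse_unified_xml(write_unified_xml(x))`
#' equals `x` field-for-field, and serialization is byte-stable.
#'
#' @param x a `cpi_corpus`.
#' @param path optional file path; if given, the XML is also written there.
#' @return the XML as a single character string (invisibly if `path` given).
#' @export
write_unified_xml <- function(x, path = NULL) {
  validate_corpus(x)
  root <- xml2::xml_new_root("corpus", source = x$source)
  for (doc in x$documents) {
    dn <- xml2::xml_add_child(root, "document", id = doc$doc_id)
    for (s in doc$sentences) {
      sn <- xml2::xml_add_child(dn, "sentence", id = s$sent_id, text = s$text)
      for (e in s$entities) {
        en <- xml2::xml_add_child(
          sn, "entity", id = e$ent_id, type = e$ent_type,
          charOffset = paste0(e$char_start, "-", e$char_end - 1L),
          text = e$surface)
        if (!is.na(e$norm_id)) xml2::xml_set_attr(en, "normId", e$norm_id)
      }
      for (p in s$pairs) {
        pn <- xml2::xml_add_child(sn, "pair", id = p$pair_id,
                                  e1 = p$compound_ref, e2 = p$protein_ref)
        if (p$label != "unknown") {
          xml2::xml_set_attr(pn, "interaction",
                             if (p$label == "functional") "True" else "False")
        }
      }
    }
  }
  out <- as.character(root)
  if (!is.null(path)) {
    writeLines(out, path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

# ---- PubTator ---------------------------------------------------------------

#' Parse PubTator pipe/tab-delimited abstracts into a corpus
#'
#' Expects blocks of the form `PMID|t|title`, `PMID|a|abstract`, followed by
#' annotation lines `PMID<TAB>start<TAB>end<TAB>mention<TAB>type<TAB>id`.
#' Title and abstract are joined with a single space; the joined text is
#' sentence-split with [split_sentences()]; document-relative annotation
#' offsets are remapped to sentence-relative ones. Only `Chemical`
#' annotations (-> compound) and `Gene`/`Protein` annotations (-> protein)
#' are kept. Annotations whose span crosses a sentence boundary or falls
#' outside the text are dropped with a warning. Candidate pairs are
#' enumerated per sentence with label `"unknown"`.
#'
#' @param text PubTator content as one string or a character vector of lines.
#' @return a `cpi_corpus`.
#' @export
parse_pubtator <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else text
  lines <- lines[nzchar(lines)]

  titles <- list(); abstracts <- list(); anns <- list(); order_seen <- character()
  for (ln in lines) {
    if (grepl("^[^\t|]+\\|t\\|", ln)) {
      pmid <- sub("\\|.*$", "", ln)
      titles[[pmid]] <- sub("^[^|]+\\|t\\|", "", ln)
      if (!pmid %in% order_seen) order_seen <- c(order_seen, pmid)
    } else if (grepl("^[^\t|]+\\|a\\|", ln)) {
      pmid <- sub("\\|.*$", "", ln)
      abstracts[[pmid]] <- sub("^[^|]+\\|a\\|", "", ln)
      if (!pmid %in% order_seen) order_seen <- c(order_seen, pmid)
    } else if (grepl("\t", ln, fixed = TRUE)) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) >= 5L) {
        pmid <- f[1]
        anns[[pmid]] <- c(anns[[pmid]], list(list(
          start = as.integer(f[2]), end = as.integer(f[3]),
          mention = f[4], type = f[5],
          norm = if (length(f) >= 6L) f[6] else NA_character_)))
        if (!pmid %in% order_seen) order_seen <- c(order_seen, pmid)
      }
    }
  }

  docs <- list()
  for (pmid in order_seen) {
    if (is.null(titles[[pmid]])) {
      warning("PubTator document ", pmid, " has no title line; skipped")
      next
    }
    full <- if (is.null(abstracts[[pmid]])) titles[[pmid]] else
      paste(titles[[pmid]], abstracts[[pmid]])
    sent_spans <- split_sentences(full)
    sents <- vector("list", nrow(sent_spans))
    for (i in seq_len(nrow(sent_spans))) {
      sents[[i]] <- sentence(paste0(pmid, ".s", i), sent_spans$text[i])
    }
    eid <- 0L
    for (a in anns[[pmid]] %||0% list()) {
      etype <- switch(a$type, Chemical = "compound",
                      Gene = "protein", Protein = "protein", NULL)
      if (is.null(etype)) next
      if (is.na(a$start) || is.na(a$end) || a$start < 0L ||
          a$end > nchar(full) || a$start >= a$end) {
        warning("PubTator ", pmid, ": annotation offsets ", a$start, "-",
                a$end, " outside text; skipped")
        next
      }
      hit <- which(sent_spans$start <= a$start & a$end <= sent_spans$end)
      if (!length(hit)) {
        warning("PubTator ", pmid, ": annotation '", a$mention,
                "' crosses a sentence boundary; dropped")
        next
      }
      i <- hit[1]
      cs <- a$start - sent_spans$start[i]
      ce <- a$end - sent_spans$start[i]
      surf <- substr(sent_spans$text[i], cs + 1L, ce)
      if (!identical(surf, a$mention)) {
        warning("PubTator ", pmid, ": mention '", a$mention,
                "' does not match text slice '", surf, "'; dropped")
        next
      }
      eid <- eid + 1L
      sents[[i]]$entities <- c(sents[[i]]$entities, list(
        entity(paste0(pmid, ".e", eid), etype, cs, ce, surf,
               norm_id = a$norm)))
    }
    for (i in seq_along(sents)) {
      # same-type entities with identical span are duplicates
      key <- vapply(sents[[i]]$entities, function(e)
        paste(e$ent_type, e$char_start, e$char_end), "")
      sents[[i]]$entities <- sents[[i]]$entities[!duplicated(key)]
      sents[[i]]$pairs <- generate_candidate_pairs(sents[[i]])
    }
    docs <- c(docs, list(document(pmid, sents)))
  }
  corpus(docs, source = "pubtator")
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

#' Read an interaction-verb list
#'
#' One lemma per line; `#` starts a comment; blank lines ignored.
#'
#' @param path file path (UTF-8).
#' @return character vector of lowercased lemmas.
#' @export
read_verb_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  tolower(lines[nzchar(lines)])
}

#' Default interaction-verb list shipped with the package
#' @return character vector of lemmas.
#' @export
default_verb_list <- function() {
  read_verb_list(system.file("extdata", "interaction_verbs.txt",
                             package = "cpirex", mustWork = TRUE))
}
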