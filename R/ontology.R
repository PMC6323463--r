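#' @title Domain ontology for laboratory-medicine concept detection
#' @description
#' The engine's ontology is a deliberately simple, database-friendly schema:
#' four classes (Test, Specimen, Category, Disease), instances with one
#' representative term plus a multilingual synonym lexicon, typed properties
#' between instances, and optional cross-links to external vocabularies
#' (e.g. a UMLS code). Every lexicon surface form resolves to exactly one
#' instance, which is what makes translation ("local-language surface in,
#' representative English term out") a plain lookup.
#' @name cds_ontology
NULL

.cds_classes <- c("Test", "Specimen", "Category", "Disease")

# canonical surface form used as a lexicon key: tokenize and re-join, so
# matching is insensitive to case/punctuation/whitespace
canon_surface <- function(s) {
  vapply(s, function(x) paste(tokenize(x), collapse = " "), character(1),
         USE.NAMES = FALSE)
}

#' Construct an ontology from instance records
#'
#' @param instances A list of instance records, each a list with fields
#'   `id`, `class` (one of Test/Specimen/Category/Disease),
#'   `representative`, `synonyms` (character, possibly multilingual),
#'   and optional `external_ids` (named list).
#' @param properties Optional data.frame with columns `type`, `from`, `to`
#'   (instance ids) for typed relations such as test-disease.
#' @return An object of class `cds_ontology` with a case-folded lexicon
#'   mapping every surface form to its instance id.
#' @export
cds_ontology <- function(instances, properties = NULL) {
  if (is.null(properties))
    properties <- data.frame(type = character(0), from = character(0),
                             to = character(0), stringsAsFactors = FALSE)
  ids <- vapply(instances, function(i) as.character(i$id), character(1))
  if (anyDuplicated(ids))
    stop("duplicate instance id: ", ids[duplicated(ids)][1])
  names(instances) <- ids
  lex <- new.env(parent = emptyenv(), hash = TRUE)
  max_ng <- 1L
  for (inst in instances) {
    if (!is.character(inst$class) || !(inst$class %in% .cds_classes))
      stop("instance '", inst$id, "': class '", inst$class,
           "' is not one of ", paste(.cds_classes, collapse = "/"))
    if (is.null(inst$representative) || !nzchar(inst$representative))
      stop("instance '", inst$id, "': missing representative term")
    syn <- unique(canon_surface(as.character(inst$synonyms %||% character(0))))
    rep_c <- canon_surface(inst$representative)
    syn <- setdiff(syn, rep_c)
    if (!is.null(inst$external_ids)) {
      bad <- !nzchar(unlist(inst$external_ids, use.names = FALSE))
      if (any(bad))
        stop("instance '", inst$id, "': empty external identifier")
    }
    for (s in c(rep_c, syn)) {
      if (!nzchar(s)) next
      prev <- get0(s, envir = lex, inherits = FALSE)
      if (!is.null(prev) && prev != inst$id)
        stop("surface term '", s, "' maps to both '", prev, "' and '",
             inst$id, "'")
      assign(s, as.character(inst$id), envir = lex)
      max_ng <- max(max_ng, length(strsplit(s, " ", fixed = TRUE)[[1]]))
    }
  }
  structure(list(classes = .cds_classes, instances = instances,
                 lexicon = lex, properties = properties,
                 max_ngram = max_ng),
            class = "cds_ontology")
}

#' @export
print.cds_ontology <- function(x, ...) {
  cat("<cds_ontology> ", length(x$instances), " instances, ",
      length(ls(x$lexicon)), " lexicon surface forms, ",
      nrow(x$properties), " properties\n", sep = "")
  invisible(x)
}

#' Number of lexicon surface forms in an ontology
#' @param ontology A `cds_ontology`.
#' @return Integer count of distinct case-folded surface forms.
#' @export
lexicon_size <- function(ontology) length(ls(ontology$lexicon))

#' Load an ontology from its JSON serialization
#'
#' The on-disk format is a JSON object
#' `{"instances": [...], "properties": [...]}` where each instance record has
#' `id`, `class`, `representative`, `synonyms`, and optionally
#' `external_ids`. All invariants (closed class set, single-instance surface
#' mapping, non-empty external ids) are checked on load.
#'
#' @param path Path to the JSON file.
#' @return A validated `cds_ontology`.
#' @export
load_ontology <- function(path) {
  if (!file.exists(path)) stop("ontology file not found: ", path)
  raw <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("ontology parse failure in '",
                                           path, "': ", conditionMessage(e)))
  if (is.null(raw$instances)) stop("ontology file '", path,
                                   "' has no 'instances' array")
  insts <- lapply(raw$instances, function(r) {
    list(id = r$id, class = r$class, representative = r$representative,
         synonyms = unlist(r$synonyms, use.names = FALSE) %||% character(0),
         external_ids = r$external_ids)
  })
  props <- NULL
  if (!is.null(raw$properties) && length(raw$properties)) {
    props <- data.frame(
      type = vapply(raw$properties, function(p) as.character(p$type), ""),
      from = vapply(raw$properties, function(p) as.character(p$from), ""),
      to   = vapply(raw$properties, function(p) as.character(p$to), ""),
      stringsAsFactors = FALSE)
  }
  cds_ontology(insts, props)
}

#' Save an ontology to JSON
#'
#' Inverse of [load_ontology()]: `load_ontology(save_ontology(o, f))` is the
#' identity on the canonical form.
#'
#' @param ontology A `cds_ontology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_ontology <- function(ontology, path) {
  insts <- lapply(unname(ontology$instances), function(i) {
    out <- list(id = i$id, class = i$class,
                representative = i$representative,
                synonyms = as.list(i$synonyms %||% character(0)))
    if (!is.null(i$external_ids)) out$external_ids <- i$external_ids
    out
  })
  props <- lapply(seq_len(nrow(ontology$properties)), function(k)
    as.list(ontology$properties[k, c("type", "from", "to")]))
  jsonlite::write_json(list(instances = insts, properties = props), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Detect ontology concepts in a token sequence and translate them
#'
#' Scans contiguous token n-grams (longest match first, then leftmost)
#' against the ontology lexicon. Each hit becomes a concept mention carrying
#' the instance's representative English term; tokens matching no lexicon
#' entry yield nothing, which is how local-language terms without an English
#' counterpart are discarded.
#'
#' @param tokens Character vector of (case-folded) tokens.
#' @param ontology A `cds_ontology`.
#' @param max_len Maximum n-gram length scanned (default 4, clamped to the
#'   longest surface form actually present).
#' @return A data.frame with one row per mention: `instance_id`, `surface`,
#'   `representative`, `start`, `end` (0-based, half-open token offsets),
#'   `polarity` (`"unassessed"` until [detect_polarity()] runs).
#' @export
detect_and_translate <- function(tokens, ontology, max_len = 4L) {
  empty <- data.frame(instance_id = character(0), surface = character(0),
                      representative = character(0), start = integer(0),
                      end = integer(0), polarity = character(0),
                      stringsAsFactors = FALSE)
  if (!length(tokens)) return(empty)
  tokens <- tolower(tokens)
  max_len <- min(as.integer(max_len), ontology$max_ngram, length(tokens))
  out <- vector("list", length(tokens))
  nhit <- 0L
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    hit <- NULL
    for (len in seq(min(max_len, n - i + 1L), 1L)) {
      key <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      id <- get0(key, envir = ontology$lexicon, inherits = FALSE)
      if (!is.null(id)) {
        hit <- list(id = id, surface = key, len = len)
        break
      }
    }
    if (is.null(hit)) {
      i <- i + 1L
    } else {
      nhit <- nhit + 1L
      out[[nhit]] <- data.frame(
        instance_id = hit$id, surface = hit$surface,
        representative = ontology$instances[[hit$id]]$representative,
        start = i - 1L, end = i - 1L + hit$len, polarity = "unassessed",
        stringsAsFactors = FALSE)
      i <- i + hit$len
    }
  }
  if (!nhit) return(empty)
  do.call(rbind, out[seq_len(nhit)])
}

#' Synonym provider backed by the ontology lexicon
#'
#' Returns a function mapping a representative term to the set of its other
#' surface forms, which is the default provider for [expand_synonyms()]. A
#' caller can substitute any function with the same signature (for instance
#' one backed by an external terminology service).
#'
#' @param ontology A `cds_ontology`.
#' @return `function(representative_term) -> character vector`.
#' @export
ontology_synonym_provider <- function(ontology) {
  by_rep <- new.env(parent = emptyenv())
  for (inst in ontology$instances) {
    assign(canon_surface(inst$representative),
           unique(canon_surface(inst$synonyms %||% character(0))),
           envir = by_rep)
  }
  function(representative_term) {
    get0(canon_surface(representative_term), envir = by_rep,
         inherits = FALSE) %||% character(0)
  }
}

#' Expand concept mentions with weighted synonyms
#'
#' Original representative terms keep weight 1; each synonym the provider
#' returns enters with `weight` (default 0.5). Synonyms identical to an
#' original term are not re-added. A failing provider degrades gracefully:
#' the original terms are returned unchanged with a warning.
#'
#' @param mentions Mention data.frame from [detect_and_translate()].
#' @param provider A synonym provider function (see
#'   [ontology_synonym_provider()]).
#' @param weight Weight assigned to synonym terms (default 0.5).
#' @return A weighted-query data.frame (see [weighted_query()]): columns
#'   `term`, `weight`, `origin`, `neg_prefixed`, `source_concept`.
#' @export
expand_synonyms <- function(mentions, provider, weight = 0.5) {
  orig <- weighted_query(term = unique(mentions$representative),
                         weight = 1, origin = "original")
  if (!nrow(mentions)) return(orig)
  orig$source_concept <- mentions$instance_id[
    match(orig$term, mentions$representative)]
  syn_rows <- lapply(seq_len(nrow(mentions)), function(k) {
    syns <- tryCatch(provider(mentions$representative[k]),
                     error = function(e) {
                       warning("synonym provider failed for '",
                               mentions$representative[k], "': ",
                               conditionMessage(e), call. = FALSE)
                       character(0)
                     })
    syns <- setdiff(canon_surface(syns), canon_surface(orig$term))
    if (!length(syns)) return(NULL)
    weighted_query(term = syns, weight = weight, origin = "synonym",
                   source_concept = mentions$instance_id[k])
  })
  out <- rbind(orig, do.call(rbind, syn_rows))
  out[!duplicated(out$term), , drop = FALSE]
}
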