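#' Construct a weighted query
#'
#' The query representation that flows through the whole engine: a table of
#' terms with non-negative weights, each tagged with its origin
#' (`original`, `synonym`, or `prf`), whether it carries the "no-" negation
#' prefix, and — for synonym terms — the concept instance it was expanded
#' from.
#'
#' @param term Character vector of terms.
#' @param weight Numeric weights (recycled), all finite and >= 0.
#' @param origin One of `"original"`, `"synonym"`, `"prf"` (recycled).
#' @param neg_prefixed Logical flag (recycled), `TRUE` once a term has been
#'   rewritten to its `"no-"` form.
#' @param source_concept Instance id the term derives from, or `NA`.
#' @return A data.frame of class `cds_query`.
#' @export
weighted_query <- function(term, weight = 1, origin = "original",
                           neg_prefixed = FALSE, source_concept = NA_character_) {
  term <- as.character(term)
  stopifnot(all(is.finite(weight)), all(weight >= 0),
            all(origin %in% c("original", "synonym", "prf")))
  out <- data.frame(term = term,
                    weight = rep_len(as.numeric(weight), length(term)),
                    origin = rep_len(as.character(origin), length(term)),
                    neg_prefixed = rep_len(as.logical(neg_prefixed), length(term)),
                    source_concept = rep_len(as.character(source_concept), length(term)),
                    stringsAsFactors = FALSE)
  class(out) <- c("cds_query", "data.frame")
  out
}

#' @export
print.cds_query <- function(x, ...) {
  cat("<cds_query> ", nrow(x), " terms\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

# rbind of cds_query data.frames keeps the class via data.frame methods;
# this helper normalizes after arbitrary manipulation.
as_cds_query <- function(df) {
  class(df) <- c("cds_query", "data.frame")
  rownames(df) <- NULL
  df
}
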