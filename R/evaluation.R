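#' Read TREC-format relevance judgments
#'
#' Lines of `qid 0 pid grade` with integer grades 0 (not relevant),
#' 1 (possibly relevant), 2 (definitely relevant). For evaluation the two
#' positive grades are conflated into a single relevant set; unjudged pairs
#' count as not relevant.
#'
#' @param path qrels file path.
#' @return data.frame of class `cds_qrels`: `query_id`, `passage_id`,
#'   `grade`.
#' @export
read_qrels <- function(path) {
  df <- utils::read.table(path, col.names = c("query_id", "iter",
                                              "passage_id", "grade"),
                          colClasses = c("character", "character",
                                         "character", "integer"))
  qrels(df$query_id, df$passage_id, df$grade)
}

#' Construct a judgments table
#'
#' @param query_id,passage_id,grade Parallel vectors; grade in 0/1/2.
#' @return data.frame of class `cds_qrels`.
#' @export
qrels <- function(query_id, passage_id, grade) {
  stopifnot(all(grade %in% 0:2))
  out <- data.frame(query_id = as.character(query_id),
                    passage_id = as.character(passage_id),
                    grade = as.integer(grade), stringsAsFactors = FALSE)
  class(out) <- c("cds_qrels", "data.frame")
  out
}

#' Write TREC-format qrels
#' @param qr A `cds_qrels`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qrels <- function(qr, path) {
  writeLines(sprintf("%s 0 %s %d", qr$query_id, qr$passage_id, qr$grade),
             path)
  invisible(path)
}

#' Read a TREC run file
#'
#' Lines of `qid Q0 pid rank score tag`.
#'
#' @param path Run file path.
#' @return data.frame `query_id`, `passage_id`, `rank`, `score`, `tag`.
#' @export
read_run <- function(path) {
  utils::read.table(path, col.names = c("query_id", "q0", "passage_id",
                                        "rank", "score", "tag"),
                    colClasses = c("character", "character", "character",
                                   "integer", "numeric", "character"))[
    , c("query_id", "passage_id", "rank", "score", "tag")]
}

#' Write a TREC run file
#'
#' @param run data.frame with `query_id`, `passage_id`, `rank`, `score`,
#'   `tag`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  writeLines(sprintf("%s Q0 %s %d %.6f %s", run$query_id, run$passage_id,
                     run$rank, run$score, run$tag), path)
  invisible(path)
}

# relevant passage ids for one query (grade >= 1)
relevant_set <- function(qr, qid) {
  unique(qr$passage_id[qr$query_id == qid & qr$grade >= 1])
}

# ranked passage ids for one query
ranked_ids <- function(run, qid) {
  sub <- run[run$query_id == qid, , drop = FALSE]
  sub$passage_id[order(sub$rank)]
}

#' Precision at N
#'
#' Fraction of the top `n` ranked passages that are relevant; a run shorter
#' than `n` is padded conceptually with non-relevant passages.
#'
#' @param ranked Character vector of passage ids in rank order.
#' @param relevant Character vector of relevant passage ids.
#' @param n Cutoff (>= 1).
#' @return Fraction in `[0, 1]`.
#' @export
precision_at_n <- function(ranked, relevant, n) {
  stopifnot(n >= 1)
  if (!length(ranked)) return(0)
  sum(ranked[seq_len(min(n, length(ranked)))] %in% relevant) / n
}

#' R-precision
#'
#' Precision at rank `R`, where `R` is the number of relevant passages for
#' the query. Undefined (NA, with a warning) when `R = 0`.
#'
#' @inheritParams precision_at_n
#' @return Fraction, or `NA` when the query has no relevant passages.
#' @export
r_precision <- function(ranked, relevant) {
  R <- length(unique(relevant))
  if (R == 0) {
    warning("query has no relevant passages; R-precision undefined")
    return(NA_real_)
  }
  sum(ranked[seq_len(min(R, length(ranked)))] %in% relevant) / R
}

#' Normalized discounted cumulative gain at N
#'
#' Binary gains (1 if relevant). The rank-1 gain is undiscounted; gains at
#' rank `p >= 2` are divided by `log2(p)`. DCG is normalized by the ideal
#' DCG attainable at the cutoff; 0 when the query has no relevant passages.
#'
#' @inheritParams precision_at_n
#' @return Fraction in `[0, 1]`.
#' @export
ndcg_at_n <- function(ranked, relevant, n) {
  stopifnot(n >= 1)
  R <- length(unique(relevant))
  if (R == 0) return(0)
  disc <- function(p) ifelse(p == 1, 1, 1 / log2(p))
  top <- ranked[seq_len(min(n, length(ranked)))]
  gains <- as.numeric(top %in% relevant)
  dcg <- sum(gains * disc(seq_along(top)))
  ideal_n <- min(n, R)
  idcg <- sum(disc(seq_len(ideal_n)))
  dcg / idcg
}

#' Reciprocal rank of the first relevant passage
#'
#' @inheritParams precision_at_n
#' @return `1 / rank` of the first relevant passage, or 0 when none is
#'   retrieved.
#' @export
reciprocal_rank <- function(ranked, relevant) {
  pos <- which(ranked %in% relevant)
  if (!length(pos)) return(0)
  1 / pos[1]
}

#' Mean reciprocal rank over a run
#'
#' @param run Run data.frame (see [read_run()]).
#' @param qr A `cds_qrels`.
#' @param query_ids Queries to average over (default: all in the run).
#' @return Mean over queries of the reciprocal rank; queries retrieving no
#'   relevant passage contribute 0.
#' @export
mrr <- function(run, qr, query_ids = unique(run$query_id)) {
  stopifnot(length(query_ids) >= 1)
  mean(vapply(query_ids, function(q)
    reciprocal_rank(ranked_ids(run, q), relevant_set(qr, q)), numeric(1)))
}

#' Evaluate a run against judgments
#'
#' @param run Run data.frame.
#' @param qr A `cds_qrels`.
#' @param metrics Character vector among `"P5"`, `"P10"`, `"Rprec"`,
#'   `"nDCG5"`, `"nDCG10"`, `"RR"` (per-query reciprocal rank, averaged to
#'   MRR).
#' @return List with `per_query` (data.frame, one row per query) and
#'   `mean` (named numeric vector).
#' @export
evaluate_run <- function(run, qr,
                         metrics = c("P5", "Rprec", "nDCG10", "RR")) {
  qids <- sort(unique(run$query_id))
  orphans <- setdiff(qids, unique(qr$query_id))
  if (length(orphans))
    warning("queries missing from qrels: ", paste(orphans, collapse = ", "))
  one <- function(q) {
    rk <- ranked_ids(run, q)
    rel <- relevant_set(qr, q)
    vals <- c(P5 = precision_at_n(rk, rel, 5),
              P10 = precision_at_n(rk, rel, 10),
              Rprec = if (length(rel)) r_precision(rk, rel) else NA_real_,
              nDCG5 = ndcg_at_n(rk, rel, 5),
              nDCG10 = ndcg_at_n(rk, rel, 10),
              RR = reciprocal_rank(rk, rel))
    vals[metrics]
  }
  per <- vapply(qids, one, numeric(length(metrics)))
  per <- if (length(metrics) == 1L) matrix(per, ncol = 1L) else t(per)
  per_query <- data.frame(query_id = qids, per, stringsAsFactors = FALSE,
                          row.names = NULL)
  names(per_query)[-1] <- metrics
  list(per_query = per_query,
       mean = colMeans(per_query[, metrics, drop = FALSE], na.rm = TRUE))
}

#' Paired comparison of two runs
#'
#' Computes the chosen metric per query for both runs and applies a paired
#' t-test to the differences. When the differences are (numerically)
#' constant the t statistic degenerates: the reported p is 0 for a nonzero
#' constant shift and 1 for identical runs.
#'
#' @param run_a,run_b Run data.frames over the same query set.
#' @param qr A `cds_qrels`.
#' @param metric One metric name as in [evaluate_run()].
#' @return List `mean_diff` (mean of a - b), `p_value`, `per_query`
#'   (data.frame of paired values).
#' @export
paired_comparison <- function(run_a, run_b, qr, metric = "P5") {
  qids <- sort(intersect(unique(run_a$query_id), unique(run_b$query_id)))
  if (length(qids) < 2) stop("paired comparison needs at least 2 queries")
  ea <- evaluate_run(run_a, qr, metrics = metric)$per_query
  eb <- evaluate_run(run_b, qr, metrics = metric)$per_query
  a <- ea[[metric]][match(qids, ea$query_id)]
  b <- eb[[metric]][match(qids, eb$query_id)]
  d <- a - b
  d <- d[!is.na(d)]
  md <- mean(d)
  sdd <- stats::sd(d)
  if (!is.finite(sdd) || sdd < 1e-12) {
    p <- if (abs(md) < 1e-12) 1 else 0
  } else {
    p <- stats::t.test(d)$p.value
  }
  list(mean_diff = md, p_value = p,
       per_query = data.frame(query_id = qids, a = a, b = b,
                              stringsAsFactors = FALSE))
}
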