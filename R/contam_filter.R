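# Assembly contamination screen: per-query interval-union coverage by taxon
# class from tabular (outfmt-6-style) alignment hits; queries whose
# non-target coverage exceeds 50% are flagged for removal.

OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Read tabular alignment hits with taxon classes
#'
#' Expects the 12 standard tabular alignment columns plus a `taxon_class`
#' column (`target` / `non_target`) and a sidecar table of query lengths.
#' Query coordinates are normalised so `qstart <= qend` and validated
#' against the query length.
#'
#' @param hits data.frame or TSV path (header with outfmt-6 column names
#'   plus `taxon_class`).
#' @param query_lens data.frame or TSV path with `query_id`, `query_len`.
#' @return data.frame `query_id`, `query_len`, `q_start`, `q_end`,
#'   `taxon_class`.
#' @export
read_blast_hits <- function(hits, query_lens) {
  if (is.character(hits)) hits <- utils::read.delim(hits, stringsAsFactors = FALSE)
  if (is.character(query_lens)) {
    query_lens <- utils::read.delim(query_lens, stringsAsFactors = FALSE)
  }
  need <- c("qseqid", "qstart", "qend", "taxon_class")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("hit table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(c("query_id", "query_len") %in% names(query_lens))) {
    stop("query length table needs columns query_id, query_len")
  }
  bad_class <- setdiff(unique(hits$taxon_class), c("target", "non_target"))
  if (length(bad_class)) stop("unknown taxon_class: ", bad_class[1L])
  len <- stats::setNames(as.integer(query_lens$query_len),
                         as.character(query_lens$query_id))
  qid <- as.character(hits$qseqid)
  no_len <- setdiff(unique(qid), names(len))
  if (length(no_len)) stop("no query length for ", no_len[1L])
  q_start <- pmin(hits$qstart, hits$qend)
  q_end <- pmax(hits$qstart, hits$qend)
  out <- data.frame(
    query_id = qid, query_len = unname(len[qid]),
    q_start = as.integer(q_start), q_end = as.integer(q_end),
    taxon_class = as.character(hits$taxon_class),
    stringsAsFactors = FALSE
  )
  bad <- out$q_start < 1L | out$q_end > out$query_len
  if (any(bad)) {
    stop("hit interval outside [1, query_len] for query ",
         out$query_id[which(bad)[1L]])
  }
  out
}

#' Interval-union coverage of one query by a taxon class
#'
#' The covered fraction is the length of the union of the `[q_start,
#' q_end]` intervals of hits in `class_filter`, divided by the query
#' length; overlapping hits count once. Positions covered by both classes
#' count fully toward each class (no subtraction).
#'
#' @param hits normalised hit table (see [read_blast_hits()]) for a single
#'   query.
#' @param class_filter `"target"` or `"non_target"`.
#' @return fraction in `[0, 1]`.
#' @export
union_coverage <- function(hits, class_filter = c("non_target", "target")) {
  class_filter <- match.arg(class_filter)
  if (!nrow(hits)) return(0)
  if (length(unique(hits$query_id)) != 1L) stop("hits must come from one query")
  qlen <- hits$query_len[1L]
  if (any(hits$q_start < 1L) || any(hits$q_end > qlen)) {
    stop("hit interval outside [1, query_len]")
  }
  h <- hits[hits$taxon_class == class_filter, , drop = FALSE]
  if (!nrow(h)) return(0)
  covered <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(h$q_start, h$q_end)
  )))
  covered / qlen
}

#' Screen queries for contamination by non-target coverage
#'
#' A query is removed when its non-target interval-union coverage strictly
#' exceeds 0.5 ("non-target coverage greater than 50%"); coverage of
#' exactly 0.5 keeps the query. Queries listed in `all_queries` but absent
#' from the hit table are kept with zero coverage.
#'
#' @param hits normalised hit table from [read_blast_hits()].
#' @param all_queries optional data.frame `query_id`, `query_len` (or id
#'   vector) enumerating every query, hit or not.
#' @return data.frame `query_id`, `target_coverage`,
#'   `non_target_coverage`, `verdict` (`keep` / `remove`).
#' @export
screen_queries <- function(hits, all_queries = NULL) {
  ids <- unique(hits$query_id)
  if (!is.null(all_queries)) {
    extra <- if (is.data.frame(all_queries)) as.character(all_queries$query_id)
             else as.character(all_queries)
    ids <- unique(c(ids, extra))
  }
  res <- do.call(rbind, lapply(ids, function(q) {
    h <- hits[hits$query_id == q, , drop = FALSE]
    tc <- union_coverage(h, "target")
    nc <- union_coverage(h, "non_target")
    data.frame(query_id = q, target_coverage = tc, non_target_coverage = nc,
               verdict = if (nc > 0.5) "remove" else "keep",
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}
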