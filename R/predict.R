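# Query ranking: score every network drug's signature in a query log2
# fold-change profile, aggregate scores per MoA, and rank at both levels
# in similar or reverse mode.

#' Mean direction-adjusted expression of a drug signature in a query
#'
#' `score = mean over matched signature genes of direction * query value`.
#' Genes absent from the query are skipped; a drug whose signature shares
#' no gene with the query has an undefined score (`NA`).
#'
#' @param query named numeric vector of log2 fold changes.
#' @param signature a [drug_signature()].
#' @return mean expression score, or `NA` when no signature gene matches.
#' @export
drug_query_score <- function(query, signature) {
  genes <- signature$entries$gene_id
  present <- genes %in% names(query)
  if (!any(present)) return(NA_real_)
  mean(signature$entries$direction[present] * query[genes[present]])
}

#' Rank MoAs and drugs against a query profile
#'
#' Each network drug gets a mean-expression score from
#' [drug_query_score()]; a MoA's score aggregates its member drug scores
#' (mean by default). In `similar` mode MoAs are ranked by descending MoA
#' score and drugs within each MoA by descending score; in `reverse` mode
#' both orders are ascending, so the drugs most opposed to the query come
#' first. Global ranks run 1..N down the MoA-grouped list. Ties are broken
#' by MoA id / drug name ascending, making `reverse` ranking of a query
#' identical to `similar` ranking of its negation. Drugs (and MoAs) with
#' undefined scores are placed at the bottom with a reason code rather
#' than dropped.
#'
#' @param query named numeric vector of log2 fold changes; must cover at
#'   least half of the network's signature genes.
#' @param network a [moa_network()].
#' @param signatures named list of [drug_signature()] objects covering the
#'   network drugs.
#' @param mode `"similar"` or `"reverse"`.
#' @param aggregate MoA-level aggregation of drug scores, `"mean"`
#'   (default) or `"max"` (`"max"` means the most extreme score in the
#'   ranking direction).
#' @return object of class `prediction_result` with `mode`, `rows`
#'   (rank, drug_name, score, moa_id, reason) and `moa_order`
#'   (moa_id, moa_score).
#' @export
rank_predictions <- function(query, network, signatures,
                             mode = c("similar", "reverse"),
                             aggregate = c("mean", "max")) {
  mode <- match.arg(mode)
  aggregate <- match.arg(aggregate)
  if (!length(network$drugs)) stop("empty network")
  sig_genes <- unique(unlist(lapply(network$drugs, function(d)
    signatures[[d]]$entries$gene_id)))
  coverage <- mean(sig_genes %in% names(query))
  if (coverage < 0.5)
    stop(sprintf("query covers only %.0f%% of network signature genes (>= 50%% required)",
                 100 * coverage))
  scores <- vapply(network$drugs, function(d) {
    s <- signatures[[d]]
    if (is.null(s)) NA_real_ else drug_query_score(query, s)
  }, numeric(1))
  asc <- mode == "reverse"
  key <- function(x) if (asc) x else -x   # ascending sort key
  moa_score <- vapply(names(network$moa_members), function(m) {
    ms <- scores[network$moa_members[[m]]]
    ms <- ms[!is.na(ms)]
    if (!length(ms)) return(NA_real_)
    if (aggregate == "mean") mean(ms) else if (asc) min(ms) else max(ms)
  }, numeric(1))
  moa_ids <- names(moa_score)
  moa_ord <- moa_ids[order(is.na(moa_score), key(moa_score), moa_ids)]
  rows <- do.call(rbind, lapply(moa_ord, function(m) {
    mem <- network$moa_members[[m]]
    s <- scores[mem]
    mem <- mem[order(is.na(s), key(s), mem)]
    data.frame(drug_name = mem, score = unname(scores[mem]), moa_id = m,
               reason = ifelse(is.na(scores[mem]), "no_signature_gene_in_query", ""),
               stringsAsFactors = FALSE)
  }))
  # drugs with undefined scores sink to the bottom of the whole report
  rows <- rows[order(is.na(rows$score) & rows$reason != ""), ]
  rows <- data.frame(rank = seq_len(nrow(rows)), rows, row.names = NULL)
  structure(list(mode = mode,
                 rows = rows,
                 moa_order = data.frame(moa_id = moa_ord,
                                        moa_score = unname(moa_score[moa_ord]),
                                        stringsAsFactors = FALSE)),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, n = 10, ...) {
  cat(sprintf("%s-mode prediction: %d drugs in %d MoAs\n", x$mode,
              nrow(x$rows), nrow(x$moa_order)))
  print(head(x$rows[, c("rank", "drug_name", "score", "moa_id")], n))
  invisible(x)
}
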