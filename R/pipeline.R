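#' Run the full MoA-network pipeline on a fold-change dataset
#'
#' Chains the stages on a log2 fold-change matrix: empirical null
#' construction, per-drug signature selection, replicate quality control,
#' drug consensus profiles, signature distance matrix, background
#' threshold calibration, MoA clustering and network construction.
#'
#' @param fc_matrix log2 fold-change matrix (genes x treated samples).
#' @param metadata sample metadata (see [read_metadata()]).
#' @param alpha signature selection level (default 0.001).
#' @param n_null_draws draws for the empirical null (default 1e5).
#' @param seed seed for the null sampling.
#' @param min_agreement QC pairwise agreement floor (default 2).
#' @param p_level background significance level for the clustering
#'   threshold (default 0.01).
#' @param background_method background estimation method (default
#'   `"reflected"`, robust to corpora where same-MoA pairs are a sizable
#'   fraction of all drug pairs; see [background_threshold()]).
#' @param linkage hierarchical clustering linkage (default `"average"`).
#' @param run_qc apply replicate QC before profiling (default TRUE).
#' @return list with components `null`, `signatures`, `qc_reports`,
#'   `profiles`, `dist`, `background`, `moa_of`, `network`, and
#'   `removed_drugs` (drugs dropped with the reason).
#' @export
run_moa_pipeline <- function(fc_matrix, metadata, alpha = 0.001,
                             n_null_draws = 1e5, seed = 1, min_agreement = 2,
                             p_level = 0.01, background_method = "reflected",
                             linkage = "average", run_qc = TRUE) {
  metadata <- validate_metadata(metadata)
  null <- build_null(fc_matrix, metadata, n_draws = n_null_draws, seed = seed)
  signatures <- select_all_signatures(fc_matrix, metadata, null, alpha)
  qc_reports <- if (run_qc)
    qc_all_drugs(fc_matrix, metadata, null, alpha, min_agreement)
  else NULL
  # signatures of QC'd drugs are re-selected from the kept samples only
  if (run_qc) {
    for (d in names(qc_reports)) {
      rep <- qc_reports[[d]]
      if (rep$drug_removed || !length(rep$removed_sample_ids)) next
      signatures[[d]] <- select_drug_signature(fc_matrix, rep$kept_sample_ids,
                                               null, alpha, drug_name = d)
    }
  }
  removed <- vapply(signatures, function(s) s$status, character(1))
  removed <- removed[removed != "ok"]
  if (!is.null(qc_reports)) {
    gone <- names(qc_reports)[vapply(qc_reports, function(r) r$drug_removed,
                                     logical(1))]
    gone <- setdiff(gone, names(removed))
    removed <- c(removed, setNames(rep("qc_removed", length(gone)), gone))
  }
  profiles <- build_drug_profiles(fc_matrix, metadata, signatures, qc_reports)
  if (length(profiles) < 2)
    stop("fewer than 2 drugs with usable signatures; cannot build a network")
  dm <- distance_matrix(profiles)
  bg <- background_threshold(dm, p_level, method = background_method)
  moa_of <- cluster_moas(dm, bg$threshold, linkage)
  network <- build_network(moa_of, dm, bg$threshold)
  list(null = null, signatures = signatures, qc_reports = qc_reports,
       profiles = profiles, dist = dm, background = bg, moa_of = moa_of,
       network = network, removed_drugs = removed)
}
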