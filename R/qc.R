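# Second-round quality control: among the replicate samples of one drug,
# remove samples that are not consistently expressed with the others.
# Agreement between two replicates is measured by how many genes their
# pairwise signature selects, relative to the count expected by chance.

#' Agreement score between two replicate samples
#'
#' The number of genes selected by [select_pair_signature()] at `alpha`,
#' divided by the chance expectation `n_genes * alpha`. A value near 1
#' means the pair shares no more consistently regulated genes than two
#' unrelated samples; large values indicate true replication.
#'
#' @param sample_a,sample_b named fold-change vectors over the same genes.
#' @param null a `null_distribution` from [build_null()].
#' @param alpha selection level (default 0.001).
#' @return non-negative agreement score.
#' @export
sample_agreement <- function(sample_a, sample_b, null, alpha = 0.001) {
  n_sel <- nrow(select_pair_signature(sample_a, sample_b, null, alpha))
  n_sel / (length(sample_a) * alpha)
}

#' Filter inconsistent replicate samples of one drug
#'
#' Applied only to drugs with more than 3 samples; smaller drugs pass
#' through untouched. While any pair among the remaining samples has
#' agreement below `min_agreement`, the sample with the lowest mean
#' agreement to the others is removed (ties broken by removing the
#' lexicographically larger sample id), stopping when all pairs pass or
#' only two samples remain. If the final pair still fails, the whole drug
#' is flagged as removed.
#'
#' @param fc_matrix log2 fold-change matrix containing the drug's samples.
#' @param sample_ids the drug's replicate sample ids.
#' @param null a `null_distribution`.
#' @param alpha selection level (default 0.001).
#' @param min_agreement minimum pairwise agreement, in multiples of the
#'   chance expectation (default 2, i.e. a replicate pair must share at
#'   least twice as many consistently regulated genes as expected by
#'   chance; outlier pairs score about 1 regardless of geometry).
#' @param drug_name name recorded in the report.
#' @return a `qc_report`: kept/removed sample ids, the initial pairwise
#'   agreement matrix, a text trace of removal decisions, and a
#'   `drug_removed` flag.
#' @export
filter_drug_samples <- function(fc_matrix, sample_ids, null, alpha = 0.001,
                                min_agreement = 2, drug_name = "drug") {
  sample_ids <- as.character(sample_ids)
  n <- length(sample_ids)
  report <- function(kept, removed, agreement, trace, drug_removed) {
    structure(list(drug_name = drug_name, kept_sample_ids = kept,
                   removed_sample_ids = removed, agreement_matrix = agreement,
                   rule_trace = trace, drug_removed = drug_removed),
              class = "qc_report")
  }
  if (n <= 3) {
    return(report(sample_ids, character(0), NULL,
                  sprintf("%d sample(s) <= 3: pass-through, no removal attempted", n),
                  drug_removed = FALSE))
  }
  A <- matrix(NA_real_, n, n, dimnames = list(sample_ids, sample_ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      A[i, j] <- A[j, i] <- sample_agreement(fc_matrix[, sample_ids[i]],
                                             fc_matrix[, sample_ids[j]],
                                             null, alpha)
    }
  }
  kept <- sample_ids
  removed <- character(0)
  trace <- character(0)
  repeat {
    sub <- A[kept, kept, drop = FALSE]
    fails <- sub < min_agreement
    diag(fails) <- FALSE
    if (!any(fails)) {
      trace <- c(trace, sprintf("all %d remaining pairs pass (min_agreement = %g)",
                                choose(length(kept), 2), min_agreement))
      break
    }
    if (length(kept) == 2) {
      trace <- c(trace, sprintf("final pair agreement %.3g < %g: drug removed entirely",
                                sub[1, 2], min_agreement))
      return(report(character(0), sample_ids, A, trace, drug_removed = TRUE))
    }
    mean_agree <- rowMeans(sub, na.rm = TRUE)
    worst <- min(mean_agree)
    cand <- sort(names(mean_agree)[mean_agree == worst])
    victim <- cand[length(cand)]   # tie: lexicographically larger id
    trace <- c(trace, sprintf("removed %s (mean agreement %.3g, lowest of %d)",
                              victim, worst, length(kept)))
    removed <- c(removed, victim)
    kept <- setdiff(kept, victim)
  }
  report(kept, removed, A, trace, drug_removed = FALSE)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report for %s: kept %d, removed %d%s\n", x$drug_name,
              length(x$kept_sample_ids), length(x$removed_sample_ids),
              if (x$drug_removed) " (drug removed entirely)" else ""))
  for (line in x$rule_trace) cat(" -", line, "\n")
  invisible(x)
}

#' Run QC on every drug in a dataset
#'
#' @param fc_matrix log2 fold-change matrix.
#' @param metadata sample metadata.
#' @param null a `null_distribution`.
#' @param alpha selection level.
#' @param min_agreement see [filter_drug_samples()].
#' @return named list of `qc_report` objects, one per drug.
#' @export
qc_all_drugs <- function(fc_matrix, metadata, null, alpha = 0.001,
                         min_agreement = 2) {
  metadata <- validate_metadata(metadata)
  md <- metadata[metadata$role == "treated" &
                   metadata$sample_id %in% colnames(fc_matrix), ]
  drugs <- unique(md$drug_name)
  reports <- lapply(drugs, function(d) {
    filter_drug_samples(fc_matrix, md$sample_id[md$drug_name == d],
                        null, alpha, min_agreement, drug_name = d)
  })
  setNames(reports, drugs)
}
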