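# Signature-based drug-drug distance, empirical background threshold,
# hierarchical clustering into modes of action, and network construction.

#' Drug-level consensus profiles
#'
#' For each drug with a non-empty signature, builds the per-gene median
#' log2 fold change over its QC-passed replicate samples, together with
#' the variance of that consensus across genes (the denominator of the
#' signature distance).
#'
#' @param fc_matrix log2 fold-change matrix.
#' @param metadata sample metadata.
#' @param signatures named list of [drug_signature()] objects.
#' @param qc_reports optional named list of `qc_report`s from
#'   [qc_all_drugs()]; when given, only kept samples enter the consensus
#'   and drugs removed by QC are dropped.
#' @return named list of `drug_profile` objects
#'   (`drug_name`, `consensus_values`, `variance`, `signature`).
#' @export
build_drug_profiles <- function(fc_matrix, metadata, signatures,
                                qc_reports = NULL) {
  metadata <- validate_metadata(metadata)
  md <- metadata[metadata$role == "treated" &
                   metadata$sample_id %in% colnames(fc_matrix), ]
  profiles <- list()
  for (d in unique(md$drug_name)) {
    sig <- signatures[[d]]
    if (is.null(sig) || sig$status != "ok" || nrow(sig$entries) == 0) next
    ids <- md$sample_id[md$drug_name == d]
    if (!is.null(qc_reports) && !is.null(qc_reports[[d]])) {
      if (qc_reports[[d]]$drug_removed) next
      ids <- intersect(ids, qc_reports[[d]]$kept_sample_ids)
    }
    if (!length(ids)) next
    consensus <- apply(fc_matrix[, ids, drop = FALSE], 1, median)
    v <- var(consensus)
    if (!is.finite(v) || v <= 0) next
    profiles[[d]] <- structure(list(drug_name = d, consensus_values = consensus,
                                    variance = v, signature = sig,
                                    sample_ids = ids),
                               class = "drug_profile")
  }
  profiles
}

#' Signature-based similarity between two drugs
#'
#' `S_ab = 1/2 * [ mean over a's signature genes of dir_i * b_i / var(b)
#'               + mean over b's signature genes of dir_j * a_j / var(a) ]`
#' where `b_i` is drug b's consensus fold change at gene i and `var(b)` is
#' the variance of b's consensus across genes. Each drug's signature is
#' read out, direction-adjusted, in the other drug's profile, so the score
#' is positive when the two drugs regulate each other's signature genes
#' the same way. Set `signed = FALSE` for the unsigned variant that sums
#' raw fold changes without direction adjustment.
#'
#' @param profile_a,profile_b `drug_profile` objects sharing gene ids.
#' @param signed adjust each gene by its signature direction (default TRUE).
#' @return symmetric similarity score.
#' @export
pairwise_similarity <- function(profile_a, profile_b, signed = TRUE) {
  read_out <- function(sig, other) {
    genes <- sig$entries$gene_id
    present <- genes %in% names(other$consensus_values)
    if (!any(present))
      stop(sprintf("no signature gene of %s present in profile of %s",
                   sig$drug_name, other$drug_name))
    if (!all(present))
      message(sprintf("%d signature gene(s) of %s absent from profile of %s; skipped",
                      sum(!present), sig$drug_name, other$drug_name))
    dir <- if (signed) sig$entries$direction[present] else 1
    mean(dir * other$consensus_values[genes[present]]) / other$variance
  }
  0.5 * (read_out(profile_a$signature, profile_b) +
           read_out(profile_b$signature, profile_a))
}

#' Pairwise drug distance matrix
#'
#' Computes all pairwise similarities, sets `D_max` to the maximum
#' off-diagonal similarity, and reports distances `D = D_max - S` so the
#' most similar drug pair has distance 0. The diagonal of D is 0 by
#' convention.
#'
#' @param profiles named list of `drug_profile` objects (>= 2).
#' @param signed see [pairwise_similarity()].
#' @return object of class `distance_matrix`: `drugs`, `S`, `D`, `D_max`.
#' @export
distance_matrix <- function(profiles, signed = TRUE) {
  drugs <- names(profiles)
  n <- length(drugs)
  if (n < 2) stop("need at least 2 drug profiles")
  S <- matrix(0, n, n, dimnames = list(drugs, drugs))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      S[i, j] <- S[j, i] <- pairwise_similarity(profiles[[i]], profiles[[j]], signed)
    }
  }
  diag(S) <- NA_real_
  d_max <- max(S, na.rm = TRUE)
  D <- d_max - S
  diag(D) <- 0
  diag(S) <- d_max          # self-similarity stored at the maximum
  structure(list(drugs = drugs, S = S, D = D, D_max = d_max),
            class = "distance_matrix")
}

#' Empirical background distribution and clustering threshold
#'
#' Under the null hypothesis that two drugs do not share a mode of action,
#' their distance follows the population distance distribution, estimated
#' empirically from all off-diagonal pairwise distances. The threshold is
#' the lower-tail `p_level` quantile (linear interpolation between order
#' statistics): only pairs closer than expected for 1 pair in
#' `1/p_level` are called same-MoA.
#'
#' The `"pooled"` method takes the quantile of the pooled distances
#' directly; it is accurate when truly related pairs are a small fraction
#' (at most about `p_level`) of all pairs, as in a large compound corpus.
#' The `"reflected"` method estimates the null component of the pooled
#' distribution by reflecting its upper half around the median (related
#' pairs contaminate only the lower tail, and the null distance of two
#' unrelated drugs is approximately symmetric); use it when the corpus is
#' small enough that same-MoA pairs are a sizable fraction of all pairs.
#'
#' @param dm a [distance_matrix()].
#' @param p_level significance level (default 0.01).
#' @param method `"pooled"` (default) or `"reflected"`; see Details.
#' @return object of class `background_distribution`:
#'   sorted pooled distances, `threshold`, `p_level`, `method`.
#' @export
background_threshold <- function(dm, p_level = 0.01,
                                 method = c("pooled", "reflected")) {
  method <- match.arg(method)
  pooled <- sort(dm$D[upper.tri(dm$D)])
  if (length(pooled) < 10)
    stop("need at least 10 off-diagonal distances to estimate the background")
  if (max(pooled) == min(pooled)) {
    warning("degenerate background: all pairwise distances equal")
    thr <- pooled[1]
  } else if (method == "pooled") {
    thr <- unname(quantile(pooled, p_level, type = 7))
  } else {
    med <- median(pooled)
    upper <- pooled[pooled >= med]
    null_sample <- c(upper, 2 * med - upper)
    thr <- unname(quantile(null_sample, p_level, type = 7))
  }
  structure(list(distances = pooled, threshold = thr, p_level = p_level,
                 method = method),
            class = "background_distribution")
}

#' Cluster drugs into modes of action
#'
#' Agglomerative hierarchical clustering on the distance matrix, cut at
#' the background threshold: every resulting cluster is one MoA. Singleton
#' MoAs are expected, since some compounds share their treatment effect
#' with no other. MoA ids are assigned in order of each MoA's
#' alphabetically first member, making the labels invariant to drug input
#' order.
#'
#' @param dm a [distance_matrix()].
#' @param threshold cut height (typically
#'   `background_threshold(dm)$threshold`).
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return named character vector mapping drug -> MoA id.
#' @export
cluster_moas <- function(dm, threshold, linkage = "average") {
  hc <- stats::hclust(stats::as.dist(dm$D), method = linkage)
  raw <- stats::cutree(hc, h = threshold)
  relabel_partition(raw)
}

# deterministic MoA ids: order clusters by their alphabetically smallest
# member drug
relabel_partition <- function(raw) {
  firsts <- vapply(split(names(raw), raw), function(m) min(sort(m)), character(1))
  new_id <- setNames(paste0("MoA", seq_along(firsts)), names(firsts)[order(firsts)])
  setNames(unname(new_id[as.character(raw)]), names(raw))
}

#' Build the MoA network
#'
#' Intra-MoA edges connect same-MoA drug pairs with distance below the
#' threshold; each MoA's center is the drug with the largest betweenness
#' centrality on its intra-edge subgraph (ties broken alphabetically;
#' singletons are their own center); two MoAs are linked when the distance
#' of their closest member pair is below the threshold.
#'
#' @param moa_of named drug -> MoA id vector from [cluster_moas()].
#' @param dm a [distance_matrix()].
#' @param threshold the clustering threshold.
#' @return a [moa_network()].
#' @export
build_network <- function(moa_of, dm, threshold) {
  drugs <- names(moa_of)
  members <- split(drugs, moa_of)
  intra <- data.frame(drug_a = character(), drug_b = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  centers <- character(0)
  for (m in names(members)) {
    mem <- sort(members[[m]])
    if (length(mem) == 1) {
      centers[m] <- mem
      next
    }
    sub <- dm$D[mem, mem, drop = FALSE]
    idx <- which(upper.tri(sub) & sub < threshold, arr.ind = TRUE)
    edges <- data.frame(drug_a = mem[idx[, 1]], drug_b = mem[idx[, 2]],
                        distance = sub[idx], stringsAsFactors = FALSE)
    intra <- rbind(intra, edges)
    g <- igraph::graph_from_data_frame(edges[, c("drug_a", "drug_b")],
                                       directed = FALSE,
                                       vertices = data.frame(name = mem))
    btw <- igraph::betweenness(g, weights = NA)
    best <- sort(names(btw)[btw == max(btw)])[1]
    centers[m] <- best
  }
  moas <- names(members)
  inter <- data.frame(moa_a = character(), moa_b = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (length(moas) > 1) {
    for (i in seq_len(length(moas) - 1)) {
      for (j in seq(i + 1, length(moas))) {
        dmin <- min(dm$D[members[[moas[i]]], members[[moas[j]]]])
        if (dmin < threshold)
          inter <- rbind(inter, data.frame(moa_a = moas[i], moa_b = moas[j],
                                           distance = dmin,
                                           stringsAsFactors = FALSE))
      }
    }
  }
  moa_network(moa_of, centers, intra, inter, threshold)
}
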