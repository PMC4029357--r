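# Per-drug signature gene-set selection. Replicate fold-change profiles
# are standardized by their own standard deviation; a per-gene consistency
# statistic rewards genes strongly and concordantly regulated in a pair of
# replicates; significance comes from an empirical null sampled from
# cross-drug sample pairs, at a raw p < 0.1% cutoff; a drug's signature is
# the intersection of its pairwise signatures.

#' Standardize a fold-change profile by its own standard deviation
#'
#' Divides every gene's fold change by the standard deviation of the whole
#' profile, so that replicate samples of different overall noise levels
#' become comparable. No centering is applied.
#'
#' @param x numeric vector of per-gene log2 fold changes.
#' @return the standardized vector.
#' @export
z_scale <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s <= 0) stop("zero-variance sample cannot be standardized")
  x / s
}

#' Replicate-consistency statistic
#'
#' `R = z_x * z_y - |z_x - z_y|` for standardized fold changes of the same
#' gene in two replicate samples. R is large when both values are large,
#' share a sign, and are close in magnitude; discordant pairs are penalized
#' twice (negative product plus the magnitude of the gap).
#'
#' @param z_x,z_y standardized fold changes (vectors are accepted and
#'   handled elementwise).
#' @return numeric vector of R values.
#' @export
consistency_statistic <- function(z_x, z_y) {
  z_x * z_y - abs(z_x - z_y)
}

#' Build the empirical null distribution of the consistency statistic
#'
#' The null models "not consistently differentially expressed": sample
#' pairs are drawn at random from *different* drugs (so shared true drug
#' effects cannot contribute), a random gene is read from each pair, and
#' the consistency statistic is pooled over `n_draws` draws. A
#' `pairing = "within_drug"` alternative draws both samples from the same
#' drug; it is provided for sensitivity analysis but retains true signal
#' and therefore yields a conservative null.
#'
#' @param fc_matrix log2 fold-change matrix (genes x samples).
#' @param metadata sample metadata; only rows with role `"treated"` and a
#'   column present in `fc_matrix` are used.
#' @param n_draws number of null draws (default 1e5).
#' @param seed integer seed; the null records it for provenance.
#' @param pairing `"cross_drug"` (default) or `"within_drug"`.
#' @return object of class `null_distribution`: sorted R values plus
#'   provenance.
#' @export
build_null <- function(fc_matrix, metadata, n_draws = 1e5, seed = 1,
                       pairing = c("cross_drug", "within_drug")) {
  pairing <- match.arg(pairing)
  metadata <- validate_metadata(metadata)
  md <- metadata[metadata$role == "treated" &
                   metadata$sample_id %in% colnames(fc_matrix), ]
  drugs <- md$drug_name
  if (length(unique(drugs)) < 2)
    stop("null construction needs samples from at least 2 distinct drugs")
  Z <- apply(fc_matrix[, md$sample_id, drop = FALSE], 2, z_scale)
  n_genes <- nrow(Z); n_samp <- ncol(Z)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  i <- sample.int(n_samp, n_draws, replace = TRUE)
  j <- sample.int(n_samp, n_draws, replace = TRUE)
  bad <- if (pairing == "cross_drug") drugs[i] == drugs[j] else i == j
  while (any(bad)) {
    j[bad] <- sample.int(n_samp, sum(bad), replace = TRUE)
    bad <- if (pairing == "cross_drug") drugs[i] == drugs[j] else i == j
  }
  g <- sample.int(n_genes, n_draws, replace = TRUE)
  r <- consistency_statistic(Z[cbind(g, i)], Z[cbind(g, j)])
  structure(list(values = sort(r), n_draws = n_draws,
                 seed = seed, pairing = pairing),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Empirical null of the consistency statistic: %d draws (%s pairing, seed %d)\n",
              x$n_draws, x$pairing, x$seed))
  print(quantile(x$values, c(.5, .9, .99, .999)))
  invisible(x)
}

#' Upper-tail empirical p-values against a null distribution
#'
#' `p = (1 + #null >= R) / (n_draws + 1)`, the add-one continuity
#' correction that keeps p-values strictly positive.
#'
#' @param null a `null_distribution` from [build_null()].
#' @param r observed R value(s).
#' @return p-values in (0, 1].
#' @export
null_pvalue <- function(null, r) {
  n <- length(null$values)
  n_lt <- findInterval(r, null$values, left.open = TRUE)
  (1 + (n - n_lt)) / (n + 1)
}

#' Signature gene set of one replicate pair
#'
#' Standardizes both samples, computes the per-gene consistency statistic,
#' and keeps genes with empirical `p < alpha` whose standardized values
#' agree in sign. Direction is the sign of `z_a + z_b`.
#'
#' @param sample_a,sample_b named fold-change vectors over the same genes.
#' @param null a `null_distribution`.
#' @param alpha selection level (default 0.001, i.e. p < 0.1%).
#' @return data.frame `gene_id`, `direction`, `p_value`, `z_a`, `z_b`.
#' @export
select_pair_signature <- function(sample_a, sample_b, null, alpha = 0.001) {
  if (!identical(names(sample_a), names(sample_b)))
    stop("samples must share gene ids in the same order")
  empty <- data.frame(gene_id = character(), direction = integer(),
                      p_value = numeric(), z_a = numeric(), z_b = numeric(),
                      stringsAsFactors = FALSE)
  # a flat profile carries no differential signal at all
  if (sd(sample_a) == 0 || sd(sample_b) == 0) return(empty)
  za <- z_scale(sample_a)
  zb <- z_scale(sample_b)
  r <- consistency_statistic(za, zb)
  p <- null_pvalue(null, r)
  keep <- p < alpha & sign(za) == sign(zb) & za != 0
  data.frame(gene_id = names(sample_a)[keep],
             direction = as.integer(sign(za + zb))[keep],
             p_value = p[keep], z_a = unname(za[keep]), z_b = unname(zb[keep]),
             stringsAsFactors = FALSE)
}

#' Signature gene set of a drug from all its replicate samples
#'
#' Every replicate pair contributes a pairwise signature; the drug
#' signature is the intersection over all pairs. The gene direction comes
#' from the mean standardized value across samples, and the reported
#' p-value is the largest (least significant) pairwise p among pairs.
#' Drugs with a single sample are flagged `single_sample` and drugs whose
#' intersection is empty are flagged `no_signature`; both are removed
#' downstream.
#'
#' @param fc_matrix log2 fold-change matrix containing the drug's samples.
#' @param sample_ids ids of the drug's replicate samples (>= 1).
#' @param null a `null_distribution`.
#' @param alpha selection level (default 0.001).
#' @param drug_name compound name recorded in the signature.
#' @return a [drug_signature()].
#' @export
select_drug_signature <- function(fc_matrix, sample_ids, null, alpha = 0.001,
                                  drug_name = "drug") {
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) < 2)
    return(drug_signature(drug_name, empty_signature_entries(),
                          n_samples_used = length(sample_ids),
                          status = "single_sample"))
  Z <- apply(fc_matrix[, sample_ids, drop = FALSE], 2, function(x) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else x / s
  })
  rownames(Z) <- rownames(fc_matrix)
  pairs <- utils::combn(length(sample_ids), 2)
  common <- NULL
  pmax_of <- NULL
  for (k in seq_len(ncol(pairs))) {
    a <- sample_ids[pairs[1, k]]; b <- sample_ids[pairs[2, k]]
    sig <- select_pair_signature(fc_matrix[, a], fc_matrix[, b], null, alpha)
    pk <- setNames(sig$p_value, sig$gene_id)
    if (is.null(common)) {
      common <- sig$gene_id
      pmax_of <- pk
    } else {
      common <- intersect(common, sig$gene_id)
      pmax_of <- pmax(pmax_of[common], pk[common])
      names(pmax_of) <- common
    }
    if (!length(common)) break
  }
  if (!length(common))
    return(drug_signature(drug_name, empty_signature_entries(),
                          n_samples_used = length(sample_ids),
                          status = "no_signature"))
  mean_z <- rowMeans(Z[common, , drop = FALSE])
  keep <- mean_z != 0
  entries <- data.frame(gene_id = common[keep],
                        direction = as.integer(sign(mean_z[keep])),
                        p_value = unname(pmax_of[common[keep]]),
                        mean_z = unname(mean_z[keep]),
                        stringsAsFactors = FALSE)
  entries <- entries[order(entries$p_value, entries$gene_id), ]
  rownames(entries) <- NULL
  drug_signature(drug_name, entries, n_samples_used = length(sample_ids),
                 status = "ok")
}

#' Signatures for every drug in a dataset
#'
#' @param fc_matrix log2 fold-change matrix.
#' @param metadata sample metadata (treated rows are grouped by drug).
#' @param null a `null_distribution`.
#' @param alpha selection level.
#' @return named list of [drug_signature()] objects, one per drug.
#' @export
select_all_signatures <- function(fc_matrix, metadata, null, alpha = 0.001) {
  metadata <- validate_metadata(metadata)
  md <- metadata[metadata$role == "treated" &
                   metadata$sample_id %in% colnames(fc_matrix), ]
  drugs <- unique(md$drug_name)
  sigs <- lapply(drugs, function(d) {
    select_drug_signature(fc_matrix, md$sample_id[md$drug_name == d],
                          null, alpha, drug_name = d)
  })
  setNames(sigs, drugs)
}

# save/restore the RNG state so seeded internals do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
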