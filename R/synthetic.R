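# Synthetic fold-change datasets with planted MoA structure, replicate
# samples, outliers and (optionally) probe-level data with vehicle
# controls, so every pipeline stage is testable without external data.

#' Simulation configuration
#'
#' Defaults describe a compact connectivity-map-like study: 10,000 genes,
#' 6 MoAs of 5 drugs each, 3 replicate samples per drug, 50-gene planted
#' signatures at 5 noise-SD effect size, unit log2 noise, 10% outlier
#' samples and disjoint MoA signatures.
#'
#' @param n_genes number of genes.
#' @param n_moas number of planted modes of action.
#' @param drugs_per_moa drugs per MoA.
#' @param samples_per_drug replicate treated samples per drug.
#' @param signature_size planted signature genes per MoA.
#' @param effect_size planted effect in units of the noise SD.
#' @param noise_sd standard deviation of the i.i.d. log2 noise.
#' @param outlier_rate probability that a sample is replaced by pure noise.
#' @param overlap_fraction fraction of signature genes shared between
#'   consecutive MoAs.
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 10000, n_moas = 6, drugs_per_moa = 5,
                       samples_per_drug = 3, signature_size = 50,
                       effect_size = 5, noise_sd = 1, outlier_rate = 0.1,
                       overlap_fraction = 0, seed = 1) {
  cfg <- list(n_genes = n_genes, n_moas = n_moas, drugs_per_moa = drugs_per_moa,
              samples_per_drug = samples_per_drug, signature_size = signature_size,
              effect_size = effect_size, noise_sd = noise_sd,
              outlier_rate = outlier_rate, overlap_fraction = overlap_fraction,
              seed = seed)
  counts <- c("n_genes", "n_moas", "drugs_per_moa", "samples_per_drug",
              "signature_size")
  if (any(unlist(cfg[counts]) < 1)) stop("all counts must be positive")
  if (effect_size < 0 || noise_sd <= 0) stop("invalid effect_size/noise_sd")
  if (outlier_rate < 0 || outlier_rate > 1) stop("outlier_rate must be in [0,1]")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0,1)")
  if (overlap_fraction == 0 && signature_size * n_moas > n_genes)
    stop("disjoint signatures need signature_size * n_moas <= n_genes")
  structure(cfg, class = "sim_config")
}

#' Generate a fold-change dataset with planted MoA structure
#'
#' Every MoA gets a signature gene set with random up/down directions;
#' every replicate sample of a drug in that MoA is
#' `direction * effect_size * noise_sd` at the signature genes plus
#' i.i.d. `N(0, noise_sd^2)` noise everywhere. With probability
#' `outlier_rate` a sample is replaced by pure noise and recorded as a
#' planted outlier. Output is deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (log2 fold-change expression matrix),
#'   `metadata` (sample table), and `truth`
#'   (`moa_of_drug`, `signature_genes` per MoA with directions,
#'   `outlier_sample_ids`, `config`).
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  moas <- sprintf("planted%02d", seq_len(config$n_moas))
  n_drugs <- config$n_moas * config$drugs_per_moa
  drugs <- sprintf("drug%03d", seq_len(n_drugs))
  moa_of_drug <- setNames(rep(moas, each = config$drugs_per_moa), drugs)

  # MoA signatures: consecutive MoAs share overlap_fraction of their genes
  n_shared <- round(config$overlap_fraction * config$signature_size)
  n_own <- config$signature_size - n_shared
  pool <- sample(genes)
  signature_genes <- list()
  take <- 0
  prev_genes <- character(0)
  for (m in seq_along(moas)) {
    shared <- if (m > 1 && n_shared > 0) prev_genes[seq_len(n_shared)] else character(0)
    n_new <- config$signature_size - length(shared)
    own <- pool[take + seq_len(n_new)]
    take <- take + n_new
    sel <- c(shared, own)
    signature_genes[[moas[m]]] <- data.frame(
      gene_id = sel,
      direction = sample(c(-1L, 1L), length(sel), replace = TRUE),
      stringsAsFactors = FALSE)
    prev_genes <- own
  }

  n_samples <- n_drugs * config$samples_per_drug
  sample_ids <- sprintf("s%04d", seq_len(n_samples))
  sample_drug <- rep(drugs, each = config$samples_per_drug)
  mat <- matrix(rnorm(config$n_genes * n_samples, 0, config$noise_sd),
                config$n_genes, n_samples, dimnames = list(genes, sample_ids))
  outliers <- character(0)
  for (k in seq_len(n_samples)) {
    if (runif(1) < config$outlier_rate) {
      outliers <- c(outliers, sample_ids[k])   # pure-noise column stays as drawn
      next
    }
    sig <- signature_genes[[moa_of_drug[[sample_drug[k]]]]]
    mat[sig$gene_id, k] <- mat[sig$gene_id, k] +
      sig$direction * config$effect_size * config$noise_sd
  }
  metadata <- data.frame(sample_id = sample_ids, drug_name = sample_drug,
                         cell_line = "MCF7", dose = "10 uM", batch = "b1",
                         role = "treated", stringsAsFactors = FALSE)
  list(matrix = expression_matrix(mat, scale_tag = "log2_fold_change"),
       metadata = metadata,
       truth = list(moa_of_drug = moa_of_drug,
                    signature_genes = signature_genes,
                    outlier_sample_ids = outliers,
                    config = config))
}

#' Generate a query profile aligned with (or opposing) a planted MoA
#'
#' The query is the planted MoA signature pattern
#' (`direction * effect_size * noise_sd` at signature genes, 0 elsewhere),
#' negated for `polarity = "reverse"`, plus i.i.d. `N(0, noise_sd^2)`
#' noise. At `noise_sd = 0` the similar-polarity query equals the MoA
#' consensus pattern exactly.
#'
#' @param truth the `truth` component of [generate_dataset()] output.
#' @param moa_id one of the planted MoA ids.
#' @param polarity `"similar"` or `"reverse"`.
#' @param noise_sd query noise SD (default 1).
#' @param seed integer RNG seed.
#' @return named numeric vector of log2 fold changes over all genes.
#' @export
generate_query <- function(truth, moa_id, polarity = c("similar", "reverse"),
                           noise_sd = 1, seed = 1) {
  polarity <- match.arg(polarity)
  if (!moa_id %in% names(truth$signature_genes))
    stop("unknown MoA id: ", moa_id)
  cfg <- truth$config
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  q <- setNames(numeric(cfg$n_genes), genes)
  sig <- truth$signature_genes[[moa_id]]
  q[sig$gene_id] <- sig$direction * cfg$effect_size * cfg$noise_sd
  if (polarity == "reverse") q <- -q
  if (noise_sd > 0) q <- q + rnorm(cfg$n_genes, 0, noise_sd)
  q
}

#' Generate a probe-level dataset with vehicle controls
#'
#' Exercises the normalization chain: absolute log2 intensities with
#' per-gene baselines, per-probe affinities, vehicle samples, and treated
#' samples that add the planted fold-change structure of
#' [generate_dataset()] on top of the baseline.
#'
#' @param config a [sim_config()] (kept small; probe-level data is
#'   `n_genes * probes_per_gene` rows).
#' @param probes_per_gene probes per gene (default 4).
#' @param n_vehicles number of vehicle samples (default 3).
#' @param baseline_mean mean absolute log2 intensity (default 7).
#' @return list with `treated` and `vehicle` probe-level matrices,
#'   `probe_map` (probe_id, gene_id), `metadata` covering all samples,
#'   `truth` as in [generate_dataset()].
#' @export
generate_probe_dataset <- function(config = sim_config(n_genes = 500, n_moas = 2,
                                                       drugs_per_moa = 2,
                                                       samples_per_drug = 2,
                                                       signature_size = 20,
                                                       outlier_rate = 0),
                                   probes_per_gene = 4, n_vehicles = 3,
                                   baseline_mean = 7) {
  ds <- generate_dataset(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  genes <- rownames(ds$matrix)
  probe_map <- data.frame(
    probe_id = sprintf("%s_p%02d", rep(genes, each = probes_per_gene),
                       rep(seq_len(probes_per_gene), length(genes))),
    gene_id = rep(genes, each = probes_per_gene), stringsAsFactors = FALSE)
  gene_base <- setNames(rnorm(length(genes), baseline_mean, 1), genes)
  probe_aff <- rnorm(nrow(probe_map), 0, 0.5)
  probe_noise_sd <- 0.1
  base_probe <- gene_base[probe_map$gene_id] + probe_aff
  treated <- sapply(colnames(ds$matrix), function(s)
    base_probe + ds$matrix[probe_map$gene_id, s] +
      rnorm(nrow(probe_map), 0, probe_noise_sd))
  rownames(treated) <- probe_map$probe_id
  veh_ids <- sprintf("veh%02d", seq_len(n_vehicles))
  vehicle <- sapply(veh_ids, function(s)
    base_probe + rnorm(nrow(probe_map), 0, probe_noise_sd))
  rownames(vehicle) <- probe_map$probe_id
  metadata <- rbind(ds$metadata,
                    data.frame(sample_id = veh_ids, drug_name = "",
                               cell_line = "MCF7", dose = "",
                               batch = "b1", role = "vehicle",
                               stringsAsFactors = FALSE))
  list(treated = expression_matrix(treated, scale_tag = "absolute_log2"),
       vehicle = expression_matrix(vehicle, scale_tag = "absolute_log2"),
       probe_map = probe_map, metadata = metadata, truth = ds$truth)
}
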