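# Small in-code fixtures shared across tests.

# Pure-noise fold-change dataset: `n_drugs` drugs x `reps` samples.
noise_dataset <- function(n_genes = 2000, n_drugs = 6, reps = 2, seed = 1,
                          noise_sd = 1) {
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  ids <- sprintf("s%03d", seq_len(n_drugs * reps))
  m <- matrix(rnorm(n_genes * length(ids), 0, noise_sd), n_genes,
              dimnames = list(genes, ids))
  md <- data.frame(sample_id = ids,
                   drug_name = rep(sprintf("drug%02d", seq_len(n_drugs)), each = reps),
                   cell_line = "MCF7", dose = "1 uM", batch = "b1",
                   role = "treated", stringsAsFactors = FALSE)
  list(matrix = expression_matrix(m, scale_tag = "log2_fold_change"),
       metadata = md)
}

# Null distribution from a small pure-noise dataset (cached per session).
small_null <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- noise_dataset(seed = 99)
      cache <<- build_null(ds$matrix, ds$metadata, n_draws = 1e5, seed = 99)
    }
    cache
  }
})

# Drug profile built directly from parts (unit-test shortcut).
make_profile <- function(drug, consensus, signature_entries, n_samples = 2,
                         variance = NULL) {
  sig <- drug_signature(drug, signature_entries, n_samples_used = n_samples)
  if (is.null(variance)) variance <- var(consensus)
  structure(list(drug_name = drug, consensus_values = consensus,
                 variance = variance, signature = sig),
            class = "drug_profile")
}

sig_entries <- function(genes, directions, p = 1e-4) {
  data.frame(gene_id = genes, direction = as.integer(directions),
             p_value = rep(p, length.out = length(genes)),
             mean_z = as.numeric(directions), stringsAsFactors = FALSE)
}

# Minimal two-MoA network used by IO and prediction tests.
toy_network <- function() {
  moa_of <- c(a1 = "MoA1", a2 = "MoA1", b1 = "MoA2", b2 = "MoA2")
  centers <- c(MoA1 = "a1", MoA2 = "b1")
  intra <- data.frame(drug_a = c("a1", "b1"), drug_b = c("a2", "b2"),
                      distance = c(0.1, 0.2), stringsAsFactors = FALSE)
  inter <- data.frame(moa_a = "MoA1", moa_b = "MoA2", distance = 0.4,
                      stringsAsFactors = FALSE)
  moa_network(moa_of, centers, intra, inter, threshold = 0.5)
}
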