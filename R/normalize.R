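# Preprocessing chain: quantile normalization of untreated samples,
# rank-invariant normalization of each treated sample against the vehicle
# baseline, median-polish probe summarization, and fold-change assembly.

#' Quantile-normalize the columns of an expression matrix
#'
#' After normalization every column has the identical sorted value vector:
#' the cross-column mean of the order statistics. Ties within a column
#' receive the mean of their reference positions. A single-column matrix is
#' returned unchanged with a warning.
#'
#' @param x expression matrix on the absolute log2 scale.
#' @return normalized matrix with the same dimnames and scale tag.
#' @export
quantile_normalize <- function(x) {
  if (ncol(x) < 2) {
    warning("quantile normalization needs >=2 samples; returning input unchanged")
    return(x)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  attr(out, "scale_tag") <- scale_tag(x)
  out
}

#' Vehicle baseline for normalization
#'
#' The normalization baseline is the per-gene median of the untreated
#' vehicle samples.
#'
#' @param vehicle_matrix absolute-log2 matrix of vehicle samples.
#' @return named numeric vector of per-gene baseline values.
#' @export
vehicle_baseline <- function(vehicle_matrix) {
  apply(vehicle_matrix, 1, median)
}

#' Rank-invariant normalization of one sample against a baseline
#'
#' Selects genes whose rank differs between sample and baseline by at most
#' `rank_tolerance * n_genes` (excluding the extreme 5% of the baseline
#' distribution at each tail), fits a monotone piecewise-linear mapping
#' sample -> baseline on that rank-invariant set (isotonic regression
#' followed by linear interpolation, with linear extrapolation beyond the
#' fitted range), and applies the mapping to every gene. If fewer than 50
#' rank-invariant genes are found the function falls back to a
#' median-shift normalization with a warning.
#'
#' @param sample_values named numeric vector (one sample, log2 scale).
#' @param baseline named numeric vector from [vehicle_baseline()]; must
#'   cover the same genes.
#' @param rank_tolerance allowed rank difference as a fraction of the
#'   number of genes (default 0.05).
#' @param tail_exclusion fraction of genes excluded at each extreme of the
#'   baseline distribution before selecting the invariant set (default 0.05).
#' @return normalized sample vector, same names and order as the input.
#' @export
rank_invariant_normalize <- function(sample_values, baseline,
                                     rank_tolerance = 0.05,
                                     tail_exclusion = 0.05) {
  if (!identical(names(sample_values), names(baseline)))
    stop("sample and baseline must share gene ids in the same order")
  n <- length(sample_values)
  rs <- rank(sample_values, ties.method = "average")
  rb <- rank(baseline, ties.method = "average")
  in_core <- rb > tail_exclusion * n & rb <= (1 - tail_exclusion) * n
  invariant <- in_core & abs(rs - rb) <= rank_tolerance * n
  if (sum(invariant) < 50) {
    warning(sprintf("rank-invariant set too small (%d genes); using median-shift normalization",
                    sum(invariant)))
    return(sample_values - median(sample_values) + median(baseline))
  }
  sx <- sample_values[invariant]
  sy <- baseline[invariant]
  o <- order(sx, sy)
  sx <- sx[o]; sy <- sy[o]
  fit <- stats::isoreg(sx, sy)           # monotone non-decreasing map
  knots_x <- sx
  knots_y <- fit$yf
  keep <- !duplicated(knots_x)
  knots_x <- knots_x[keep]; knots_y <- knots_y[keep]
  out <- approx(knots_x, knots_y, xout = sample_values, rule = 2, ties = "ordered")$y
  # linear extrapolation from the outer 10% of knots for out-of-range genes
  m <- length(knots_x)
  k <- max(2L, ceiling(0.1 * m))
  lo <- sample_values < knots_x[1]
  hi <- sample_values > knots_x[m]
  if (any(lo)) {
    sl <- edge_slope(knots_x[seq_len(k)], knots_y[seq_len(k)])
    out[lo] <- knots_y[1] + sl * (sample_values[lo] - knots_x[1])
  }
  if (any(hi)) {
    idx <- seq(m - k + 1L, m)
    sl <- edge_slope(knots_x[idx], knots_y[idx])
    out[hi] <- knots_y[m] + sl * (sample_values[hi] - knots_x[m])
  }
  names(out) <- names(sample_values)
  out
}

# least-squares slope over a boundary window, clamped to be non-negative so
# the extrapolated map stays monotone
edge_slope <- function(x, y) {
  if (length(unique(x)) < 2) return(1)
  max(0, stats::cov(x, y) / stats::var(x))
}

#' Summarize probe-level values to gene level by median polish
#'
#' For each gene the probes-by-samples block is decomposed by two-way
#' median polish (iterative removal of row and column medians, at most 10
#' iterations or until the total absolute residual changes by less than
#' 1e-6); the per-sample summary is the overall effect plus the column
#' effect. A single-probe gene's summaries equal that probe's values.
#'
#' @param probe_matrix probes-by-samples numeric matrix with probe rownames.
#' @param probe_to_gene data.frame with columns `probe_id`, `gene_id`
#'   assigning each probe to exactly one gene.
#' @return expression matrix with one row per gene, same scale tag as the
#'   input.
#' @export
median_polish_summarize <- function(probe_matrix, probe_to_gene) {
  if (!all(c("probe_id", "gene_id") %in% colnames(probe_to_gene)))
    stop("probe_to_gene needs columns probe_id and gene_id")
  if (anyDuplicated(probe_to_gene$probe_id))
    stop("each probe must map to exactly one gene")
  map <- setNames(as.character(probe_to_gene$gene_id),
                  as.character(probe_to_gene$probe_id))
  probes <- rownames(probe_matrix)
  unknown <- setdiff(probes, names(map))
  if (length(unknown))
    stop("probe(s) missing from map: ", paste(head(unknown, 5), collapse = ", "))
  genes <- unique(unname(map[probes]))
  out <- matrix(NA_real_, length(genes), ncol(probe_matrix),
                dimnames = list(genes, colnames(probe_matrix)))
  for (g in genes) {
    block <- probe_matrix[probes[map[probes] == g], , drop = FALSE]
    if (nrow(block) == 1) {
      out[g, ] <- block[1, ]
    } else {
      # the 10-iteration cap is part of the contract; medpolish warns when
      # it stops there, which is expected behaviour here
      mp <- suppressWarnings(
        stats::medpolish(block, eps = 1e-6, maxiter = 10, trace.iter = FALSE))
      out[g, ] <- mp$overall + mp$col
    }
  }
  tag <- scale_tag(probe_matrix)
  expression_matrix(out, scale_tag = if (is.null(tag)) "absolute_log2" else tag)
}

#' Assemble per-treatment log2 fold-change profiles
#'
#' Each treated sample is matched to its vehicle group (same `batch` and
#' `cell_line`) and the per-gene median of that vehicle group is
#' subtracted. Treated samples without any matching vehicle are excluded
#' with a warning and listed in the `excluded` attribute of the result.
#'
#' @param treated_matrix absolute-log2 matrix of treated samples.
#' @param vehicle_matrix absolute-log2 matrix of vehicle samples, same genes.
#' @param metadata sample metadata covering both matrices
#'   (see [read_metadata()]).
#' @return expression matrix of log2 fold changes, one column per treated
#'   sample that had vehicles.
#' @export
assemble_fold_change <- function(treated_matrix, vehicle_matrix, metadata) {
  if (!identical(rownames(treated_matrix), rownames(vehicle_matrix)))
    stop("treated and vehicle matrices must share gene ids in the same order")
  metadata <- validate_metadata(metadata)
  md <- metadata[match(colnames(treated_matrix), metadata$sample_id), ]
  if (anyNA(md$sample_id))
    stop("treated sample(s) missing from metadata")
  vmd <- metadata[metadata$role == "vehicle" &
                    metadata$sample_id %in% colnames(vehicle_matrix), ]
  vkey <- paste(vmd$batch, vmd$cell_line, sep = "\r")
  tkey <- paste(md$batch, md$cell_line, sep = "\r")
  cols <- list(); excluded <- character(0)
  for (i in seq_along(tkey)) {
    vs <- vmd$sample_id[vkey == tkey[i]]
    if (!length(vs)) {
      excluded <- c(excluded, colnames(treated_matrix)[i])
      next
    }
    base <- apply(vehicle_matrix[, vs, drop = FALSE], 1, median)
    cols[[colnames(treated_matrix)[i]]] <- treated_matrix[, i] - base
  }
  if (length(excluded))
    warning("treated sample(s) without matching vehicles excluded: ",
            paste(excluded, collapse = ", "))
  if (!length(cols)) stop("no treated sample had a matching vehicle group")
  fc <- expression_matrix(do.call(cbind, cols), gene_ids = rownames(treated_matrix),
                          sample_ids = names(cols),
                          scale_tag = "log2_fold_change")
  attr(fc, "excluded") <- excluded
  fc
}
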