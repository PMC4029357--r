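#' @importFrom stats median sd var quantile approx rnorm runif setNames
#' @importFrom utils read.delim write.table head
NULL

# Expression matrices are plain numeric matrices with unique rownames
# (gene ids), unique colnames (sample ids) and a "scale_tag" attribute,
# one of "absolute_log2" or "log2_fold_change".

SCALE_TAGS <- c("absolute_log2", "log2_fold_change")

#' Construct and validate an expression matrix
#'
#' An expression matrix is a numeric genes-by-samples matrix on the log2
#' scale, carrying unique gene ids as rownames, unique sample ids as
#' colnames, and a `scale_tag` attribute distinguishing absolute log2
#' expression from log2 fold change over a vehicle baseline.
#'
#' @param values numeric matrix, rows = genes, columns = samples.
#' @param gene_ids character vector of unique gene/probe-set identifiers;
#'   defaults to `rownames(values)`.
#' @param sample_ids character vector of unique sample identifiers;
#'   defaults to `colnames(values)`.
#' @param scale_tag `"absolute_log2"` or `"log2_fold_change"`.
#' @return the validated matrix with ids attached and `scale_tag` set.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              scale_tag = "absolute_log2") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  scale_tag <- match.arg(scale_tag, SCALE_TAGS)
  gene_ids <- trimws(as.character(gene_ids))
  sample_ids <- trimws(as.character(sample_ids))
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length does not match number of rows")
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length does not match number of columns")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 gene_ids[bad[1]], sample_ids[bad[2]]))
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  attr(values, "scale_tag") <- scale_tag
  values
}

#' Scale tag of an expression matrix
#' @param x an expression matrix.
#' @return `"absolute_log2"`, `"log2_fold_change"`, or `NULL` if untagged.
#' @export
scale_tag <- function(x) attr(x, "scale_tag")

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' Row and column order are preserved exactly as in the file; duplicate
#' identifiers or non-numeric cells are load errors.
#'
#' @param path file path.
#' @param scale_tag scale of the stored values (see [expression_matrix()]).
#' @return an expression matrix.
#' @export
read_expression <- function(path, scale_tag = "absolute_log2") {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   check.names = FALSE, colClasses = "character",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression file needs a gene-id column plus >=1 sample")
  gene_ids <- trimws(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("non-numeric value '%s' at row %d (gene '%s'), column '%s'",
                   vals[bad[1, 1], bad[1, 2]], bad[1, 1], gene_ids[bad[1, 1]],
                   colnames(df)[-1][bad[1, 2]]))
    }
    stop("missing values in expression file; impute or remove them first")
  }
  expression_matrix(num, gene_ids = gene_ids,
                    sample_ids = trimws(colnames(df)[-1]),
                    scale_tag = scale_tag)
}

#' Write an expression matrix as tab-delimited text
#'
#' Values are written with 15 significant digits so that a
#' write-then-read round trip reproduces them to at least 12 significant
#' digits.
#'
#' @param x an expression matrix.
#' @param path output path.
#' @param id_column header of the gene-id column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, id_column = "gene_id") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c(id_column, colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1, function(r) paste(sprintf("%.15g", r), collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

SAMPLE_ROLES <- c("treated", "vehicle")
METADATA_COLUMNS <- c("sample_id", "drug_name", "cell_line", "dose", "batch", "role")

#' Read a sample-metadata table
#'
#' The table must be tab-delimited with columns `sample_id`, `drug_name`,
#' `cell_line`, `dose`, `batch`, `role`; `role` is `"treated"` or
#' `"vehicle"`, and every treated sample must name its drug.
#'
#' @param path file path.
#' @return a data.frame of validated sample records.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character", stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' Validate a sample-metadata data.frame
#' @param df data.frame with the columns listed under [read_metadata()].
#' @return the validated data.frame (character columns, trimmed).
#' @export
validate_metadata <- function(df) {
  missing_cols <- setdiff(METADATA_COLUMNS, colnames(df))
  if (length(missing_cols))
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, METADATA_COLUMNS, drop = FALSE]
  df[] <- lapply(df, function(v) trimws(as.character(v)))
  bad_role <- setdiff(unique(df$role), SAMPLE_ROLES)
  if (length(bad_role))
    stop("unknown role value(s): ", paste(bad_role, collapse = ", "),
         " (expected treated/vehicle)")
  no_drug <- df$role == "treated" & df$drug_name == ""
  if (any(no_drug))
    stop("treated sample(s) without a drug name: ",
         paste(df$sample_id[no_drug], collapse = ", "))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicate sample_id(s) in metadata: ", paste(unique(dup), collapse = ", "))
  rownames(df) <- NULL
  df
}

#' Write a sample-metadata table
#' @param df metadata data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(df, path) {
  write.table(df[, METADATA_COLUMNS, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a drug signature
#'
#' A drug signature is the set of genes consistently and strongly
#' differentially expressed across a drug's replicate treatment samples,
#' each with an up/down direction, the largest pairwise p-value that
#' supported it, and the mean standardized fold change.
#'
#' @param drug_name compound name.
#' @param entries data.frame with columns `gene_id`, `direction` (+1/-1),
#'   `p_value`, `mean_z`; may have zero rows.
#' @param n_samples_used number of replicate samples behind the signature.
#' @param status `"ok"`, `"no_signature"` (no gene consistent across all
#'   replicate pairs) or `"single_sample"` (fewer than 2 replicates, so the
#'   consistency statistic is unavailable).
#' @return an object of class `drug_signature`.
#' @export
drug_signature <- function(drug_name, entries, n_samples_used,
                           status = c("ok", "no_signature", "single_sample")) {
  status <- match.arg(status)
  if (nrow(entries)) {
    entries$gene_id <- trimws(as.character(entries$gene_id))
    entries$direction <- as.integer(entries$direction)
    if (anyDuplicated(entries$gene_id))
      stop("duplicate gene ids within signature of ", drug_name)
    if (!all(entries$direction %in% c(-1L, 1L)))
      stop("signature directions must be +1/-1")
    if (!all(entries$direction == sign(entries$mean_z)))
      stop("signature direction must equal sign(mean_z)")
  }
  structure(list(drug_name = drug_name,
                 entries = entries[, c("gene_id", "direction", "p_value", "mean_z")],
                 n_samples_used = as.integer(n_samples_used),
                 status = status),
            class = "drug_signature")
}

#' @export
print.drug_signature <- function(x, ...) {
  cat(sprintf("Drug signature: %s [%s], %d gene(s), %d sample(s)\n",
              x$drug_name, x$status, nrow(x$entries), x$n_samples_used))
  if (nrow(x$entries)) print(head(x$entries, 10))
  invisible(x)
}

empty_signature_entries <- function() {
  data.frame(gene_id = character(), direction = integer(),
             p_value = numeric(), mean_z = numeric(),
             stringsAsFactors = FALSE)
}

#' Write drug signatures as a TSV table
#'
#' One row per (drug, gene); the `n_samples_used` and `status` columns are
#' repeated per row so the file round-trips to identical signature objects.
#' Drugs with an empty signature are represented by a single row with an
#' empty `gene_id`.
#'
#' @param signatures list of [drug_signature()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signatures_tsv <- function(signatures, path) {
  rows <- lapply(signatures, function(s) {
    if (nrow(s$entries) == 0) {
      data.frame(drug_name = s$drug_name, gene_id = "", direction = NA_integer_,
                 p_value = NA_real_, mean_z = NA_real_,
                 n_samples_used = s$n_samples_used, status = s$status,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(drug_name = s$drug_name, s$entries,
                 n_samples_used = s$n_samples_used, status = s$status,
                 stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(tab))
    tab <- data.frame(drug_name = character(), gene_id = character(),
                      direction = integer(), p_value = numeric(),
                      mean_z = numeric(), n_samples_used = integer(),
                      status = character())
  num <- vapply(tab, is.numeric, logical(1)) & names(tab) %in% c("p_value", "mean_z")
  tab[num] <- lapply(tab[num], function(v) format(v, digits = 15, trim = TRUE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read drug signatures from a TSV written by [write_signatures_tsv()]
#' @param path file path.
#' @return named list of `drug_signature` objects.
#' @export
read_signatures_tsv <- function(path) {
  tab <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                    colClasses = c(drug_name = "character", gene_id = "character",
                                   status = "character"))
  sigs <- lapply(split(tab, factor(tab$drug_name, levels = unique(tab$drug_name))),
                 function(d) {
    entries <- d[d$gene_id != "", c("gene_id", "direction", "p_value", "mean_z")]
    rownames(entries) <- NULL
    if (!nrow(entries)) entries <- empty_signature_entries()
    drug_signature(d$drug_name[1], entries, d$n_samples_used[1], d$status[1])
  })
  names(sigs) <- vapply(sigs, function(s) s$drug_name, character(1))
  sigs[unique(tab$drug_name)]
}

#' Write drug signatures in GMT (Broad gene-set) format
#'
#' Emits one line per drug per direction with set names `<drug>_up` and
#' `<drug>_down`; the description field carries `n_samples_used`. Empty
#' directions produce no line.
#'
#' @param signatures list of [drug_signature()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signatures_gmt <- function(signatures, path) {
  lines <- character(0)
  for (s in signatures) {
    for (d in c(1L, -1L)) {
      genes <- s$entries$gene_id[s$entries$direction == d]
      if (!length(genes)) next
      set_name <- paste0(s$drug_name, if (d == 1L) "_up" else "_down")
      lines <- c(lines, paste(c(set_name, s$n_samples_used, genes), collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct a MoA network
#'
#' Drugs are partitioned into modes of action (MoAs); drug pairs of the
#' same MoA closer than the clustering threshold form intra-MoA edges; each
#' MoA is centered on its highest-betweenness drug; MoA pairs whose closest
#' member pair falls under the threshold are linked by an inter-MoA edge.
#'
#' @param moa_of named character vector mapping drug -> MoA id.
#' @param centers named character vector mapping MoA id -> center drug.
#' @param intra_edges data.frame `drug_a`, `drug_b`, `distance`.
#' @param inter_moa_edges data.frame `moa_a`, `moa_b`, `distance`.
#' @param threshold clustering/linking distance threshold.
#' @return an object of class `moa_network`.
#' @export
moa_network <- function(moa_of, centers, intra_edges, inter_moa_edges, threshold) {
  drugs <- names(moa_of)
  if (is.null(drugs) || anyDuplicated(drugs))
    stop("moa_of must be a named vector with unique drug names")
  members <- split(drugs, moa_of)
  if (!all(names(centers) %in% names(members)))
    stop("center listed for unknown MoA")
  ok <- vapply(names(centers), function(m) centers[[m]] %in% members[[m]], logical(1))
  if (!all(ok)) stop("every center must be a member of its MoA")
  if (nrow(intra_edges)) {
    same <- moa_of[intra_edges$drug_a] == moa_of[intra_edges$drug_b]
    if (!all(same)) stop("intra-MoA edge connecting different MoAs")
    if (!all(intra_edges$distance < threshold))
      stop("intra-MoA edge at or above threshold")
  }
  if (nrow(inter_moa_edges) && any(inter_moa_edges$moa_a == inter_moa_edges$moa_b))
    stop("inter-MoA edge must connect distinct MoAs")
  structure(list(drugs = drugs, moa_of = moa_of,
                 moa_members = members, centers = centers,
                 intra_edges = intra_edges, inter_moa_edges = inter_moa_edges,
                 threshold = threshold),
            class = "moa_network")
}

#' @export
print.moa_network <- function(x, ...) {
  cat(sprintf("MoA network: %d drugs in %d MoAs (threshold %.4g)\n",
              length(x$drugs), length(x$moa_members), x$threshold))
  cat(sprintf("  %d intra-MoA edges, %d inter-MoA links\n",
              nrow(x$intra_edges), nrow(x$inter_moa_edges)))
  invisible(x)
}

#' Write a MoA network as GraphML
#'
#' Nodes carry `moa_id` and `is_center` attributes; edges carry `kind`
#' (`intra` between drugs, `inter_moa` between the centers of linked MoAs)
#' and `distance`; the clustering threshold is stored as a graph attribute.
#'
#' @param network a [moa_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(network$drugs),
                            name = network$drugs,
                            moa_id = unname(network$moa_of[network$drugs]),
                            is_center = as.integer(
                              network$drugs %in% unname(network$centers)))
  add_edges <- function(g, a, b, kind, distance) {
    if (!length(a)) return(g)
    idx <- rbind(match(a, network$drugs), match(b, network$drugs))
    igraph::add_edges(g, as.vector(idx), kind = kind, distance = distance)
  }
  g <- add_edges(g, network$intra_edges$drug_a, network$intra_edges$drug_b,
                 "intra", network$intra_edges$distance)
  # inter-MoA links are materialized between the two MoA centers
  g <- add_edges(g, unname(network$centers[network$inter_moa_edges$moa_a]),
                 unname(network$centers[network$inter_moa_edges$moa_b]),
                 "inter_moa", network$inter_moa_edges$distance)
  g <- igraph::set_graph_attr(g, "threshold", network$threshold)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a MoA network from GraphML written by [write_network_graphml()]
#' @param path file path.
#' @return a [moa_network()].
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  drugs <- igraph::vertex_attr(g, "name")
  moa_of <- setNames(igraph::vertex_attr(g, "moa_id"), drugs)
  is_center <- igraph::vertex_attr(g, "is_center") != 0
  centers <- setNames(drugs[is_center], moa_of[is_center])
  ends <- igraph::as_edgelist(g)
  kind <- igraph::edge_attr(g, "kind")
  dist <- igraph::edge_attr(g, "distance")
  intra <- kind == "intra"
  intra_edges <- data.frame(drug_a = ends[intra, 1], drug_b = ends[intra, 2],
                            distance = dist[intra], stringsAsFactors = FALSE)
  inter_moa_edges <- data.frame(moa_a = unname(moa_of[ends[!intra, 1]]),
                                moa_b = unname(moa_of[ends[!intra, 2]]),
                                distance = dist[!intra], stringsAsFactors = FALSE)
  moa_network(moa_of, centers, intra_edges, inter_moa_edges,
              igraph::graph_attr(g, "threshold"))
}

#' Write a prediction report as TSV
#'
#' Mirrors the standard report layout with columns
#' `Rank`, `Drug`, `MeanExpression`, `MoA`.
#'
#' @param result a `prediction_result` from [rank_predictions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(result, path) {
  tab <- data.frame(Rank = result$rows$rank,
                    Drug = result$rows$drug_name,
                    MeanExpression = result$rows$score,
                    MoA = result$rows$moa_id)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
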