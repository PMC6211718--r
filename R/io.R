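# Readers/writers for the external formats (expression TSV, edge lists,
# sample annotations, GMT, RNK, SIF/GraphML) plus quantile normalization.
# Expression data are held as a plain numeric matrix (genes x samples) with
# unique dimnames; networks as an "relation_network" S3 object wrapping a
# two-column edge data frame.

#' Read a gene x sample expression table
#'
#' Expects a tab-separated file whose first column holds gene identifiers and
#' whose header row holds sample identifiers; all remaining cells must be
#' numeric (log2 scale by convention).  Duplicate gene rows are resolved by a
#' configurable rule; duplicate sample identifiers are an error.
#'
#' @param path Path to the TSV file.
#' @param duplicate_genes How to resolve duplicated gene identifiers:
#'   `"highest_mean"` (default) keeps the row with the highest mean value,
#'   `"first"` keeps the first occurrence, `"error"` aborts.
#' @param na_action `"error"` (default) rejects missing cells; `"drop_rows"`
#'   removes genes with any missing value (with a warning).
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_table <- function(path,
                                  duplicate_genes = c("highest_mean", "first", "error"),
                                  na_action = c("error", "drop_rows")) {
  duplicate_genes <- match.arg(duplicate_genes)
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop2("expression file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop2("expression table needs a gene column and >=1 sample column")
  genes <- as.character(tab[[1L]])
  sample_ids <- colnames(tab)[-1L]
  if (anyDuplicated(sample_ids))
    stop2("duplicate sample ids: ",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(tab[, -1L, drop = FALSE], 2L, as.numeric))) &
                   !is.na(as.matrix(tab[, -1L, drop = FALSE])), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop2("non-numeric cell at gene row ", bad[1L, 1L], ", sample column ", bad[1L, 2L])
    stop2("non-numeric values in expression table")
  }
  if (anyNA(vals)) {
    if (na_action == "error") {
      idx <- which(is.na(vals), arr.ind = TRUE)
      stop2("missing value at gene '", genes[idx[1L, 1L]], "', sample '",
            sample_ids[idx[1L, 2L]], "'")
    }
    keep <- rowSums(is.na(vals)) == 0L
    warn2(sum(!keep), " gene rows with missing values dropped")
    vals <- vals[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    if (duplicate_genes == "error")
      stop2("duplicate gene ids: ", paste(utils::head(dups, 5L), collapse = ", "))
    keep <- if (duplicate_genes == "first") {
      !duplicated(genes)
    } else {
      means <- rowMeans(vals)
      ord <- order(genes, -means)  # within gene, best row first
      first_best <- ord[!duplicated(genes[ord])]
      seq_along(genes) %in% first_best
    }
    warn2(length(dups), " duplicated gene id(s) resolved by rule '", duplicate_genes, "'")
    vals <- vals[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  dimnames(vals) <- list(genes, sample_ids)
  vals
}

#' Write an expression matrix as a TSV round-trippable by
#' [read_expression_table()]
#'
#' @param expr Numeric gene x sample matrix with dimnames.
#' @param path Output path.
#' @param gene_column Header for the gene-identifier column.
#' @export
write_expression_table <- function(expr, path, gene_column = "gene") {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  # 17 significant digits make the text representation round-trip doubles
  # bitwise
  chr <- matrix(sprintf("%.17g", expr), nrow = nrow(expr))
  df <- data.frame(rownames(expr), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(gene_column, colnames(expr))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a simple undirected relation network from an edge data frame
#'
#' Self-loops are dropped and duplicate (unordered) edges collapsed, each with
#' a warning.  The result is the package's container for a priori gene-gene
#' relations such as protein-protein interactions.
#'
#' @param edges Two-column data frame or matrix of node identifiers.
#' @return A `relation_network` object with elements `nodes` (character) and
#'   `edges` (two-column character data frame, lexicographically ordered
#'   within each row).
#' @export
relation_network <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) != 2L) stop2("edge table must have exactly two columns")
  a <- as.character(edges[[1L]]); b <- as.character(edges[[2L]])
  loops <- a == b
  if (any(loops)) {
    warn2(sum(loops), " self-loop(s) dropped")
    a <- a[!loops]; b <- b[!loops]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    warn2(sum(duplicated(key)), " duplicate edge(s) collapsed")
    keep <- !duplicated(key)
    lo <- lo[keep]; hi <- hi[keep]
  }
  structure(list(nodes = sort(unique(c(lo, hi))),
                 edges = data.frame(from = lo, to = hi,
                                    stringsAsFactors = FALSE)),
            class = "relation_network")
}

#' @export
print.relation_network <- function(x, ...) {
  cat("relation_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Read an undirected edge list (two-column TSV or SIF)
#'
#' SIF lines carry a relation type in the middle column (`A pp B`); plain TSV
#' lines carry two node tokens.  The format is auto-detected per file from the
#' token count of its lines.
#'
#' @param path Path to the edge-list file.
#' @return A [relation_network()] object.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop2("edge list not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop2("edge list is empty: ", path)
  toks <- strsplit(trimws(lines), "[\t ]+")
  n_tok <- lengths(toks)
  if (all(n_tok == 3L)) {            # SIF with a single relation type
    edges <- data.frame(from = vapply(toks, `[`, "", 1L),
                        to   = vapply(toks, `[`, "", 3L),
                        stringsAsFactors = FALSE)
  } else {
    bad <- which(n_tok != 2L)
    if (length(bad) > 0L)
      stop2("line ", bad[1L], ": expected 2 node tokens, found ", n_tok[bad[1L]])
    edges <- data.frame(from = vapply(toks, `[`, "", 1L),
                        to   = vapply(toks, `[`, "", 2L),
                        stringsAsFactors = FALSE)
  }
  relation_network(edges)
}

#' Write a relation network as a two-column TSV
#' @param network A [relation_network()].
#' @param path Output path.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "relation_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' @param path TSV path with a header row.
#' @param sample_col,group_col,stage_col,time_col,event_col Column names for
#'   sample id, group label, disease stage, survival time (months) and event
#'   indicator; stage/time/event columns are optional and `NA` by default.
#' @return Data frame with standardized column names `sample_id`, `group`,
#'   and optionally `stage`, `survival_time`, `event`.
#' @export
read_annotation <- function(path, sample_col = "sample_id", group_col = "group",
                            stage_col = NA, time_col = NA, event_col = NA) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(sample_col, group_col, stage_col, time_col, event_col)
  need <- need[!is.na(need)]
  missing_cols <- setdiff(need, colnames(tab))
  if (length(missing_cols) > 0L)
    stop2("annotation lacks column(s): ", paste(missing_cols, collapse = ", "))
  out <- data.frame(sample_id = as.character(tab[[sample_col]]),
                    group = as.character(tab[[group_col]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id)) stop2("duplicate sample ids in annotation")
  if (!is.na(stage_col)) out$stage <- as.character(tab[[stage_col]])
  if (!is.na(time_col)) {
    out$survival_time <- as.numeric(tab[[time_col]])
    if (any(out$survival_time < 0, na.rm = TRUE)) stop2("negative survival time")
  }
  if (!is.na(event_col)) {
    out$event <- as.integer(tab[[event_col]])
    if (!all(out$event %in% c(0L, 1L, NA))) stop2("event indicator must be 0/1")
  }
  out
}

#' Quantile-normalize the columns of a matrix
#'
#' Forces every column (sample) to share the same distribution: the mean of
#' the order statistics across columns.  Ties within a column receive the mean
#' of their target quantiles.  Delegates to [limma::normalizeQuantiles()].
#'
#' @param values Numeric matrix, samples in columns, all values finite.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(values) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(!is.finite(values))) stop2("quantile_normalize requires finite values")
  if (ncol(values) == 1L) {
    warn2("single-column matrix returned unchanged")
    return(values)
  }
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors (set name -> member genes).
#' @param path Output path.
#' @param description Single description string recycled per set.
#' @export
write_gmt <- function(sets, path, description = "subnetDE") {
  stopifnot(is.list(sets), !is.null(names(sets)), !anyDuplicated(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(toks, function(t) t[-(1:2)]),
                  vapply(toks, `[`, "", 1L))
}

#' Export a subnetwork with TOM/PPI edge and fold-change/leading-edge node
#' attributes
#'
#' Writes either a SIF file (edges only, relation `tom`) or a GraphML file
#' with edge attributes `tom_weight` and `is_ppi` and node attributes
#' `log2_fold_change` and `is_leading_edge`, suitable for Cytoscape-style
#' viewers.  Every within-subnetwork prior edge is included; non-prior pairs
#' are included when their TOM weight exceeds `tom_cut`.
#'
#' @param members Character vector of subnetwork gene ids (nonempty).
#' @param tom Symmetric TOM matrix with gene dimnames covering `members`.
#' @param prior A [relation_network()] (the a priori relations).
#' @param fold_changes Named numeric vector, log2 fold changes per gene.
#' @param leading_edge Character vector of leading-edge gene ids.
#' @param path Output path.
#' @param format `"graphml"` or `"sif"`.
#' @param tom_cut TOM threshold for drawing non-prior edges (default 0:
#'   all positive-TOM pairs).
#' @return The path, invisibly.
#' @export
export_subnetwork_graph <- function(members, tom, prior, fold_changes,
                                    leading_edge, path,
                                    format = c("graphml", "sif"),
                                    tom_cut = 0) {
  if (length(members) == 0L) stop2("empty subnetwork")
  if (!is.character(format) || !all(format %in% c("graphml", "sif")))
    stop2("unknown format; supported formats: graphml, sif")
  format <- match.arg(format)
  stopifnot(all(members %in% rownames(tom)))
  ppi <- prior_matrix(prior, members)
  tm <- tom[members, members, drop = FALSE]
  n <- length(members)
  from <- integer(0); to <- integer(0)
  if (n >= 2L) {
    idx <- which(upper.tri(tm), arr.ind = TRUE)
    keep <- ppi[idx] == 1 | tm[idx] > tom_cut
    from <- idx[keep, 1L]; to <- idx[keep, 2L]
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = members)
  g <- igraph::set_vertex_attr(g, "log2_fold_change",
                               value = as.numeric(fold_changes[members]))
  g <- igraph::set_vertex_attr(g, "is_leading_edge",
                               value = as.integer(members %in% leading_edge))
  if (length(from) > 0L) {
    g <- igraph::add_edges(g, rbind(from, to))
    g <- igraph::set_edge_attr(g, "tom_weight", value = tm[cbind(from, to)])
    g <- igraph::set_edge_attr(g, "is_ppi", value = as.integer(ppi[cbind(from, to)]))
  }
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    ed <- igraph::as_edgelist(g)
    writeLines(if (nrow(ed) > 0L) paste(ed[, 1L], "tom", ed[, 2L]) else character(0),
               path)
  }
  invisible(path)
}
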