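# Whole-pipeline orchestration: for each of the two phenotype groups as
# correlation source, build the prior-primed network, detect subnetworks and
# screen them with preranked GSEA against the SAM-ranked list, yielding four
# result lists (source group x enrichment sign).  Statistical confidence is
# whole-pipeline: the pipeline is re-run on permuted inputs (prior-label or
# gene-label shuffles) and observed NES values are compared with the pooled
# permuted NES population.

#' Pipeline configuration
#'
#' @param group_a,group_b Group labels in the annotation; `group_a` is the
#'   reference, so positive ranking scores mean up-regulation in `group_b`.
#' @param source_tags Two short tags naming the correlation sources in result
#'   list ids (default the first two characters of the labels, upper-cased).
#' @param beta Numeric length-2 vector of soft-threshold powers for the two
#'   sources; `NA` (default) selects each power by the scale-free criterion.
#' @param beta_grid,r2_target Soft-threshold search grid and fit target.
#' @param deep_split,min_size,max_size,cut_height Module detection and size
#'   filter settings (defaults 2, 10, 500, 0.99).
#' @param s0_method Fudge-factor rule for the SAM statistic.
#' @param gsea_n_perm Gene-permutation draws inside GSEA (default 1000).
#' @param n_perm Whole-pipeline permutation replicates (default 500).
#' @param jump_delta,fdr_ceiling FDR-jump selection parameters (defaults 0.2
#'   and 0.25).
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(group_a, group_b,
                            source_tags = NULL,
                            beta = c(NA, NA),
                            beta_grid = 1:20, r2_target = 0.8,
                            deep_split = 2, min_size = 10, max_size = 500,
                            cut_height = 0.99,
                            s0_method = c("median", "percentile_search"),
                            gsea_n_perm = 1000,
                            n_perm = 500,
                            jump_delta = 0.2, fdr_ceiling = 0.25,
                            seed = 1) {
  if (is.null(source_tags))
    source_tags <- toupper(substr(c(group_a, group_b), 1L, 2L))
  if (anyDuplicated(source_tags)) source_tags <- c("A", "B")
  structure(list(group_a = group_a, group_b = group_b,
                 source_tags = source_tags,
                 beta = rep_len(beta, 2L),
                 beta_grid = beta_grid, r2_target = r2_target,
                 deep_split = deep_split, min_size = min_size,
                 max_size = max_size, cut_height = cut_height,
                 s0_method = match.arg(s0_method),
                 gsea_n_perm = gsea_n_perm, n_perm = n_perm,
                 jump_delta = jump_delta, fdr_ceiling = fdr_ceiling,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# network construction + module detection + GSEA for one correlation source
run_one_source <- function(expr, samples, prior, ranked, config, source_idx) {
  sim <- suppressWarnings(abs_pearson_similarity(expr, samples))
  pm <- prior_matrix(prior, rownames(sim))
  deg <- rowSums(pm)
  use <- deg > 0                        # prior-isolated genes cannot join modules
  sim <- sim[use, use, drop = FALSE]
  pm <- pm[use, use, drop = FALSE]
  beta <- config$beta[source_idx]
  sft <- NULL
  if (is.na(beta)) {
    sft <- pick_soft_threshold(sim, pm, config$beta_grid, config$r2_target)
    beta <- sft$beta
  }
  adj <- combined_adjacency(sim, pm, beta)
  tom <- topological_overlap(adj)
  diss <- 1 - tom
  diag(diss) <- 0
  dend <- average_linkage_cluster(diss)
  labels <- dynamic_tree_cut(dend, diss, deep_split = config$deep_split,
                             min_size = config$min_size,
                             cut_height = config$cut_height)
  extracted <- extract_subnetworks(labels, tom, pm,
                                   min_size = config$min_size,
                                   max_size = config$max_size,
                                   id_prefix = config$source_tags[source_idx])
  enr <- run_enrichment(ranked, extracted$sets,
                        n_perm = config$gsea_n_perm,
                        seed = config$seed + 7919L * source_idx,
                        size_min = config$min_size,
                        size_max = config$max_size)
  list(beta = beta, scale_free = sft, labels = labels, tom = tom,
       sets = extracted$sets, subnetworks = extracted$subnetworks,
       enrichment = enr)
}

#' Run the full subnetwork-detection pipeline
#'
#' Ranks all genes with the SAM statistic (`group_a` vs `group_b`), then for
#' each group as correlation source builds the prior-primed adjacency at its
#' soft threshold, computes TOM, detects modules with the dynamic tree cut,
#' filters them to the admissible size range, and screens them with preranked
#' GSEA.  The scored subnetworks are split into four lists labeled source tag
#' + enriched-group tag (e.g. `PTME` = primary-tumor correlations, enriched in
#' metastases).
#'
#' @param expr Gene x sample expression matrix (log2 scale).
#' @param annotation Data frame with `sample_id` and `group`.
#' @param prior A [relation_network()] of a priori gene-gene relations.
#' @param config A [pipeline_config()].
#' @return A `subnet_pipeline` object: `lists` (four enrichment data frames),
#'   `sources` (per-source detection detail), `ranked`, `config`.
#' @export
run_pipeline <- function(expr, annotation, prior, config) {
  stopifnot(inherits(config, "pipeline_config"))
  samples_a <- annotation$sample_id[annotation$group == config$group_a]
  samples_b <- annotation$sample_id[annotation$group == config$group_b]
  if (length(samples_a) < 3L || length(samples_b) < 3L)
    stop2("each group needs >= 3 samples")
  if (length(intersect(prior$nodes, rownames(expr))) == 0L)
    stop2("prior network shares no genes with the expression matrix")

  sam <- sam_statistic(expr, samples_a, samples_b, s0 = 1)  # s/diff for s0 rule
  s0 <- estimate_s0(sam$s, method = config$s0_method, diff = sam$diff)
  sam <- sam_statistic(expr, samples_a, samples_b, s0 = s0)
  ranked <- rank_genes(sam$d)

  sources <- list()
  lists <- list()
  tags <- config$source_tags
  for (i in 1:2) {
    samples <- if (i == 1L) samples_a else samples_b
    res <- tryCatch(
      run_one_source(expr, samples, prior, ranked, config, i),
      error = function(e) stop2("source ", tags[i], ": ", conditionMessage(e)))
    sources[[tags[i]]] <- res
    signed <- split_by_sign(res$enrichment)
    lists[[paste0(tags[i], tags[1L])]] <- signed$negative  # up in group_a
    lists[[paste0(tags[i], tags[2L])]] <- signed$positive  # up in group_b
  }
  structure(list(lists = lists, sources = sources, ranked = ranked,
                 s0 = s0, config = config),
            class = "subnet_pipeline")
}

#' @export
print.subnet_pipeline <- function(x, ...) {
  cat("subnet_pipeline:",
      paste(names(x$lists), vapply(x$lists, nrow, 0L), sep = "=", collapse = " "),
      "\n")
  for (tag in names(x$sources))
    cat("  source", tag, ": beta =", x$sources[[tag]]$beta, ",",
        length(x$sources[[tag]]$sets), "subnetworks\n")
  invisible(x)
}

#' Shuffle gene labels on a fixed network topology
#'
#' The degree sequence, component structure and label multiset are preserved
#' exactly; only the assignment of labels to nodes is permuted.
#'
#' @param network A [relation_network()].
#' @param seed Integer seed.
#' @return A [relation_network()] with the same topology.
#' @export
permute_prior_labels <- function(network, seed = 1) {
  stopifnot(inherits(network, "relation_network"))
  nodes <- network$nodes
  new_labels <- with_seed(seed, sample(nodes))
  map <- stats::setNames(new_labels, nodes)
  relation_network(data.frame(from = unname(map[network$edges$from]),
                              to = unname(map[network$edges$to]),
                              stringsAsFactors = FALSE))
}

#' Shuffle gene labels over fixed expression rows
#'
#' The matrix of row values (and hence the gene-gene correlation structure) is
#' untouched; only the gene-id-to-row assignment is permuted.
#'
#' @param expr Gene x sample matrix with rownames.
#' @param seed Integer seed.
#' @return Matrix with permuted rownames.
#' @export
permute_expression_gene_labels <- function(expr, seed = 1) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  rownames(expr) <- with_seed(seed, sample(rownames(expr)))
  expr
}

#' Whole-pipeline permutation significance
#'
#' Re-runs the full pipeline `n_perm` times on input with one source permuted
#' — prior-network labels (`"ppi"`) or expression gene labels (`"gene"`) —
#' pooling every permuted subnetwork's NES by sign.  For an observed
#' subnetwork with score NES*: nominal p is the fraction of same-sign pooled
#' permuted NES at least as extreme, and FDR is the ratio of the permuted to
#' the observed same-sign tail fractions at |NES*|, clipped to `[0, 1]`.
#'
#' @param observed A `subnet_pipeline` from [run_pipeline()].
#' @param expr,annotation,prior The pipeline inputs.
#' @param scheme `"ppi"` (prior-label permutation) or `"gene"` (expression
#'   gene-label permutation).
#' @param n_perm Number of pipeline replicates (default `config$n_perm`).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param beta_mode `"fixed"` (default) re-uses the observed soft-threshold
#'   power per source in every replicate — cheaper and conservative;
#'   `"full"` re-optimizes the power per replicate.
#' @param progress Print a dot per replicate to stderr.
#' @return A `significance_table`: data frame with `list`, `set`, `size`,
#'   `es`, `nes`, `p`, `fdr`, ordered as in the observed lists, with
#'   attributes `scheme`, `n_perm` and `null_nes`.
#' @export
permutation_significance <- function(observed, expr, annotation, prior,
                                     scheme = c("ppi", "gene"),
                                     n_perm = NULL, seed = NULL,
                                     beta_mode = c("fixed", "full"),
                                     progress = FALSE) {
  scheme <- match.arg(scheme)
  beta_mode <- match.arg(beta_mode)
  config <- observed$config
  n_perm <- n_perm %||% config$n_perm
  seed <- seed %||% (config$seed + 100000L)
  if (n_perm < 1) stop2("n_perm must be >= 1")
  config_perm <- config
  if (beta_mode == "fixed")
    config_perm$beta <- vapply(observed$sources, `[[`, 0, "beta")
  null_nes <- numeric(0)
  for (r in seq_len(n_perm)) {
    res_r <- if (scheme == "ppi") {
      run_pipeline(expr, annotation, permute_prior_labels(prior, seed + r),
                   config_perm)
    } else {
      run_pipeline(permute_expression_gene_labels(expr, seed + r), annotation,
                   prior, config_perm)
    }
    null_nes <- c(null_nes,
                  unlist(lapply(res_r$lists, function(t) t$nes),
                         use.names = FALSE))
    if (progress) cat(".", file = stderr())
  }
  if (progress) cat("\n", file = stderr())
  score_against_null(observed, null_nes, scheme = scheme, n_perm = n_perm)
}

# shared estimator: observed lists vs a pooled permuted-NES population
score_against_null <- function(observed, null_nes, scheme, n_perm) {
  null_nes <- null_nes[is.finite(null_nes)]
  obs_nes <- unlist(lapply(observed$lists, function(t) t$nes), use.names = FALSE)
  rows <- list()
  for (nm in names(observed$lists)) {
    tab <- observed$lists[[nm]]
    if (nrow(tab) == 0L) next
    for (i in seq_len(nrow(tab))) {
      nes <- tab$nes[i]
      same_null <- if (nes >= 0) null_nes[null_nes >= 0] else null_nes[null_nes < 0]
      same_obs <- if (nes >= 0) obs_nes[obs_nes >= 0] else obs_nes[obs_nes < 0]
      if (length(same_null) == 0L) {
        warn2("no permuted NES with the sign of ", tab$set[i], ": p/FDR undefined")
        p <- NA_real_; fdr <- NA_real_
      } else {
        p <- mean(abs(same_null) >= abs(nes))
        fdr <- min(1, p / mean(abs(same_obs) >= abs(nes)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        list = nm, set = tab$set[i], size = tab$size[i], es = tab$es[i],
        nes = nes, p = p, fdr = fdr, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(list = character(0), set = character(0), size = integer(0),
               es = numeric(0), nes = numeric(0), p = numeric(0),
               fdr = numeric(0))
  rownames(out) <- NULL
  structure(out, scheme = scheme, n_perm = n_perm, null_nes = null_nes,
            class = c("significance_table", "data.frame"))
}

#' Select the significant prefix of a ranked FDR list
#'
#' Walks the list (already ranked by decreasing |NES|) and cuts before the
#' first rank whose FDR both jumps by more than `jump_delta` above the
#' previous rank and exceeds `fdr_ceiling`; the previous value at rank 1 is
#' taken as 0, so a list opening at a high FDR selects nothing.
#'
#' @param fdr Numeric FDR values in list order.
#' @param jump_delta Minimal jump size (default 0.2).
#' @param fdr_ceiling Minimal absolute FDR at the cut (default 0.25).
#' @return Integer vector of selected ranks (possibly empty).
#' @export
select_significant <- function(fdr, jump_delta = 0.2, fdr_ceiling = 0.25) {
  prev <- 0
  for (i in seq_along(fdr)) {
    if (!is.na(fdr[i]) && fdr[i] - prev > jump_delta && fdr[i] > fdr_ceiling)
      return(seq_len(i - 1L))
    prev <- fdr[i]
  }
  seq_along(fdr)
}
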