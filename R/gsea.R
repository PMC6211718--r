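# Preranked gene set enrichment: weighted running-sum enrichment score,
# size-matched gene-permutation nulls, NES, nominal p and the leading edge.
# Only gene-based permutation is provided — with a preranked list that is the
# only permutation scheme available.

#' Weighted running-sum enrichment score
#'
#' Walking down the ranked list, the running sum gains
#' `|score|^weight_exponent / N_R` at member genes (N_R the sum of those
#' weights) and loses `1 / (N - N_H)` at non-members.  The ES is the running
#' sum's maximal deviation from zero; on ties the earliest peak is taken.  The
#' leading edge is the member genes at or before a positive peak (at or after
#' a negative peak).
#'
#' @param ranked Data frame `gene`, `score` from [rank_genes()].
#' @param gene_set Character vector of member genes.
#' @param weight_exponent Score weighting p (default 1; 0 gives the classic
#'   Kolmogorov-Smirnov statistic).
#' @return List with `es`, `peak_index`, `leading_edge`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  genes <- ranked$gene
  hit <- genes %in% gene_set
  n <- length(genes)
  n_h <- sum(hit)
  if (n_h == 0L) stop2("gene set has empty intersection with the ranked list")
  if (n_h == n) stop2("gene set covers the whole ranked list")
  w <- abs(ranked$score)^weight_exponent
  n_r <- sum(w[hit])
  inc <- numeric(n)
  if (n_r > 0) {
    inc[hit] <- w[hit] / n_r
  } else {
    inc[hit] <- 1 / n_h          # all member scores zero: fall back to equal weights
  }
  inc[!hit] <- -1 / (n - n_h)
  running <- cumsum(inc)
  peak <- which.max(abs(running))           # earliest maximal deviation
  es <- running[peak]
  leading <- if (es >= 0) genes[hit & seq_len(n) <= peak]
             else genes[hit & seq_len(n) >= peak]
  list(es = es, peak_index = peak, leading_edge = leading)
}

#' Null enrichment-score distribution for one set size
#'
#' ES of `n_perm` uniform random gene subsets of the given size drawn without
#' replacement from the ranked universe (gene-based permutation).
#'
#' @param ranked Data frame `gene`, `score`.
#' @param set_size Size of the random sets (< universe size).
#' @param n_perm Number of draws (>= 100 recommended).
#' @param seed Integer seed; the draw is reproducible.
#' @param weight_exponent Passed to [enrichment_score()].
#' @return Numeric vector of `n_perm` ES values.
#' @export
null_es_distribution <- function(ranked, set_size, n_perm = 1000, seed = 1,
                                 weight_exponent = 1) {
  n <- nrow(ranked)
  if (set_size >= n) stop2("set_size must be smaller than the ranked universe")
  if (set_size < 1) stop2("set_size must be >= 1")
  with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, set_size)
      enrichment_score(ranked, ranked$gene[idx], weight_exponent)$es
    }, 0)
  })
}

#' Score a collection of gene sets and normalize against permutation nulls
#'
#' Sets outside `[size_min, size_max]` after intersection with the ranked
#' universe are excluded before scoring.  Null pools are computed once per
#' distinct set size and reused.  `NES = ES / mean(|null ES| of matching
#' sign)`; the nominal p-value is the fraction of same-sign null ES at least
#' as extreme (0 means "more extreme than every null", i.e. p < 1/n_perm).
#'
#' @param ranked Data frame `gene`, `score` from [rank_genes()].
#' @param sets Named list of gene-id vectors.
#' @param n_perm Gene-permutation draws per set size (default 1000).
#' @param seed Integer seed.
#' @param size_min,size_max Admissible set sizes (defaults 10 and 500).
#' @param weight_exponent Passed to [enrichment_score()].
#' @return Data frame with one row per scored set: `set`, `size`, `es`,
#'   `nes`, `p_nominal`, `peak_index`, `leading_edge` (list column), sorted by
#'   decreasing `|nes|`, plus attribute `excluded` (names of size-filtered
#'   sets).
#' @export
run_enrichment <- function(ranked, sets, n_perm = 1000, seed = 1,
                           size_min = 10, size_max = 500,
                           weight_exponent = 1) {
  stopifnot(is.list(sets), !is.null(names(sets)), !anyDuplicated(names(sets)))
  universe <- ranked$gene
  inter <- lapply(sets, intersect, x = universe)
  sizes <- lengths(inter)
  admissible <- sizes >= size_min & sizes <= size_max
  excluded <- names(sets)[!admissible]
  sets_use <- inter[admissible]
  if (length(sets_use) == 0L) {
    out <- data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p_nominal = numeric(0),
                      peak_index = integer(0))
    out$leading_edge <- list()
    attr(out, "excluded") <- excluded
    return(out)
  }
  scored <- lapply(sets_use, enrichment_score, ranked = ranked,
                   weight_exponent = weight_exponent)
  nulls <- list()
  for (sz in unique(lengths(sets_use))) {
    nulls[[as.character(sz)]] <- null_es_distribution(
      ranked, sz, n_perm = n_perm, seed = seed + sz,
      weight_exponent = weight_exponent)
  }
  rows <- lapply(names(sets_use), function(nm) {
    sc <- scored[[nm]]
    null <- nulls[[as.character(length(sets_use[[nm]]))]]
    ns <- normalize_es(sc$es, null)
    data.frame(set = nm, size = length(sets_use[[nm]]), es = sc$es,
               nes = ns$nes, p_nominal = ns$p, peak_index = sc$peak_index,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$leading_edge <- lapply(names(sets_use), function(nm) scored[[nm]]$leading_edge)
  out <- out[order(-abs(out$nes), out$set), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Normalize an enrichment score against its null distribution
#'
#' @param es Observed ES.
#' @param null_es Numeric vector of null ES values (same set size).
#' @return List with `nes` and nominal `p` (fraction of same-sign nulls at
#'   least as extreme; `NA` with a warning when no null shares the sign).
#' @export
normalize_es <- function(es, null_es) {
  same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  if (length(same) == 0L) {
    warn2("no same-sign null ES values: NES undefined")
    return(list(nes = NA_real_, p = NA_real_))
  }
  list(nes = es / mean(abs(same)),
       p = mean(abs(same) >= abs(es)))
}

#' Split an enrichment table into the two signed result lists
#'
#' @param enrichment Data frame from [run_enrichment()].
#' @return List with `positive` (ES > 0, enriched in group 2) and `negative`
#'   (ES < 0, enriched in group 1), each sorted by decreasing `|nes|`.
#' @export
split_by_sign <- function(enrichment) {
  list(positive = enrichment[enrichment$es > 0, , drop = FALSE],
       negative = enrichment[enrichment$es < 0, , drop = FALSE])
}
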