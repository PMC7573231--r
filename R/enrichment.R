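#' Call differentially expressed genes
#'
#' Applies the conventional DE filter: adjusted p strictly below `padj_cut`
#' and |log2 fold change| strictly above `lfc_cut` (a gene at exactly the
#' cut-off is excluded on both axes). Genes with missing `padj` (e.g.
#' independent-filtering NAs) are never called.
#'
#' @param table data.frame with columns `gene_id`, `log2fc`, `padj`
#'   (gene ids must be unique)
#' @param padj_cut adjusted-p threshold (default 0.05, strict)
#' @param lfc_cut log2 fold-change threshold (default 1, strict)
#' @return list with character vectors `up` and `down`
#' @export
filter_de <- function(table, padj_cut = 0.05, lfc_cut = 1) {
  need <- c("gene_id", "log2fc", "padj")
  if (!all(need %in% names(table)))
    smt_stop(paste0("DE table needs columns ", paste(need, collapse = ",")),
             "sealmito_invalid_input")
  if (anyDuplicated(table$gene_id))
    smt_stop("duplicate gene ids in DE table", "sealmito_invalid_input")
  p <- table$padj
  if (any(p < 0 | p > 1, na.rm = TRUE))
    smt_stop("padj must lie in [0, 1]", "sealmito_invalid_input")
  sig <- !is.na(p) & p < padj_cut
  list(up = table$gene_id[sig & table$log2fc > lfc_cut],
       down = table$gene_id[sig & table$log2fc < -lfc_cut])
}

#' One-sided Fisher exact enrichment test
#'
#' Tests over-representation of `target` in `query` against `background`
#' via the hypergeometric upper tail P(X >= overlap), the one-sided Fisher
#' exact p of the 2x2 table (overlap; query-only; target-only; rest).
#'
#' @param query,target,background character vectors of gene ids;
#'   `query` and `target` must be subsets of `background`
#' @return list: `overlap`, `odds_ratio` (sample odds ratio of the 2x2
#'   table), `p`
#' @export
fisher_enrich <- function(query, target, background) {
  background <- unique(background)
  N <- length(background)
  if (N == 0L) smt_stop("empty background", "sealmito_invalid_input")
  query <- unique(query); target <- unique(target)
  if (!all(query %in% background) || !all(target %in% background))
    smt_stop("query and target must be subsets of background",
             "sealmito_invalid_input")
  q <- length(query); m <- length(target)
  a <- length(intersect(query, target))
  p <- stats::phyper(a - 1, m, N - m, q, lower.tail = FALSE)
  b <- q - a; cc <- m - a; d <- N - q - m + a
  or <- (a * d) / (b * cc)   # may be Inf/NaN for degenerate margins
  list(overlap = a, odds_ratio = or, p = min(p, 1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR adjustment with monotonicity enforcement, returned in
#' the input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\]
#' @return adjusted p-values, same length and order
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    smt_stop("p-values must lie in [0, 1]", "sealmito_invalid_input")
  n <- length(pvals)
  o <- order(pvals, na.last = TRUE)
  ranked <- pvals[o] * n / seq_len(n)
  adj <- pmin(1, rev(cummin(rev(ranked))))
  out <- numeric(n)
  out[o] <- adj
  out[is.na(pvals)] <- NA_real_
  out
}

#' Rank-deviation z-scores for a gene-set collection
#'
#' For each set, the Fisher p-value rank among all sets (mean rank on ties)
#' is compared to the distribution of that rank under `n_permutations`
#' random queries of the same size drawn from the background:
#' `z = (observed_rank - expected_rank) / sd_rank`. A set more enriched
#' than expected ranks better (lower) than its permutation ranks, giving a
#' negative z — the convention under which `log(p) * z` (the combined
#' score) is positive for enriched sets.
#'
#' @param query character vector of query gene ids (subset of background)
#' @param collection named list of gene-id character vectors
#' @param background character vector, the gene universe
#' @param n_permutations number of random queries (>= 100)
#' @param seed optional integer seed for reproducibility
#' @return named numeric vector of z-scores (NA where undefined, e.g. a
#'   collection of size 1 or a degenerate rank distribution)
#' @export
rank_deviation_z <- function(query, collection, background,
                             n_permutations = 1000, seed = NULL) {
  if (n_permutations < 100)
    smt_stop("n_permutations must be >= 100", "sealmito_invalid_input")
  background <- unique(background)
  N <- length(background)
  nsets <- length(collection)
  if (nsets < 2L) {
    warning("collection has fewer than 2 sets: rank-deviation z undefined",
            call. = FALSE)
    return(stats::setNames(rep(NA_real_, nsets), names(collection)))
  }
  query <- unique(query)
  if (!all(query %in% background))
    smt_stop("query must be a subset of background", "sealmito_invalid_input")
  S <- vapply(collection, function(s) background %in% s, logical(N))  # N x nsets
  m <- colSums(S)
  qsize <- length(query)
  pv_for <- function(q_logical) {
    ov <- as.numeric(crossprod(S, q_logical))   # overlap per set
    stats::phyper(ov - 1, m, N - m, qsize, lower.tail = FALSE)
  }
  obs_rank <- rank(pv_for(background %in% query), ties.method = "average")
  ranks <- maybe_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      q <- logical(N)
      q[sample.int(N, qsize)] <- TRUE
      rank(pv_for(q), ties.method = "average")
    }, numeric(nsets))
  })
  if (nsets == 1L) ranks <- matrix(ranks, nrow = 1L)
  exp_rank <- rowMeans(ranks)
  sd_rank <- apply(ranks, 1L, stats::sd)
  z <- (obs_rank - exp_rank) / sd_rank
  z[!is.finite(z)] <- NA_real_
  stats::setNames(z, names(collection))
}

#' Enrichment combined score
#'
#' `score = log(p) * z` (natural log). With the z convention of
#' [rank_deviation_z()] (negative z = enriched beyond expectation), enriched
#' sets with small p get large positive scores; `p = 1` gives 0 for any z.
#' A p of exactly 0 is capped at the smallest positive double with a
#' warning.
#'
#' @param p Fisher exact p-value(s) in (0, 1]
#' @param z rank-deviation z-score(s)
#' @return numeric score(s)
#' @export
combined_score <- function(p, z) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    smt_stop("p must lie in [0, 1]", "sealmito_invalid_input")
  if (any(p == 0, na.rm = TRUE)) {
    warning("p = 0 capped at the smallest positive double", call. = FALSE)
    p[!is.na(p) & p == 0] <- .Machine$double.xmin
  }
  log(p) * z
}

#' Gene-set enrichment of a query against a collection
#'
#' Fisher exact p per set, BH adjustment across the collection, permutation
#' rank-deviation z and the combined score, sorted by combined score
#' (descending, NAs last).
#'
#' @param query character vector of gene ids
#' @param collection named list of gene sets (e.g. from [read_gmt()])
#' @param background gene universe; defaults to the union of the collection
#'   and the query (prefer passing the assayed universe explicitly, e.g. all
#'   genes in the DE table)
#' @param n_permutations permutations for the z-score (>= 100); set to 0 to
#'   skip the z/combined-score columns
#' @param seed optional integer seed
#' @return data.frame of class `enrichment_result`
#' @export
enrich <- function(query, collection, background = NULL,
                   n_permutations = 1000, seed = NULL) {
  if (is.null(names(collection)) || anyDuplicated(names(collection)))
    smt_stop("collection must have unique names", "sealmito_invalid_input")
  if (any(lengths(collection) == 0L))
    smt_stop("empty gene set in collection", "sealmito_invalid_input")
  background <- unique(background %||% union(unlist(collection), query))
  collection <- lapply(collection, function(s) intersect(unique(s), background))
  query <- intersect(unique(query), background)
  ft <- lapply(collection, function(s) fisher_enrich(query, s, background))
  p <- vapply(ft, `[[`, numeric(1), "p")
  res <- data.frame(
    set_name = names(collection),
    overlap_count = vapply(ft, `[[`, numeric(1), "overlap"),
    set_size = lengths(collection),
    query_size = length(query),
    background_size = length(background),
    odds_ratio = vapply(ft, `[[`, numeric(1), "odds_ratio"),
    p = p,
    padj = bh_adjust(p),
    stringsAsFactors = FALSE
  )
  if (n_permutations > 0) {
    res$z <- rank_deviation_z(query, collection, background,
                              n_permutations = n_permutations, seed = seed)
    res$combined_score <- combined_score(res$p, res$z)
    res <- res[order(-res$combined_score, res$p, na.last = TRUE), ]
  } else {
    res$z <- NA_real_
    res$combined_score <- NA_real_
    res <- res[order(res$p), ]
  }
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Read a GMT gene-set file
#'
#' Tab-delimited: set name, description, then member gene ids.
#'
#' @param path GMT path
#' @return named list of character vectors, with set descriptions in the
#'   `"descriptions"` attribute
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L))
    smt_stop(paste0(path, ": each GMT line needs name, description and >= 1 gene"),
             "sealmito_io_error")
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    smt_stop(paste0(path, ": duplicate set names"), "sealmito_io_error")
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[[`, character(1), 2L), nm)
  sets
}

#' Write a named list of gene sets as GMT
#'
#' @param sets named list of character vectors
#' @param path output path
#' @param descriptions optional character vector of set descriptions
#' @return `path`, invisibly
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a DE table TSV
#'
#' Columns: `gene_id`, `log2fc`, `pvalue`, `padj`.
#'
#' @param path TSV path
#' @return data.frame
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "padj")
  if (!all(need %in% names(df)))
    smt_stop(paste0(path, ": expected columns ", paste(need, collapse = ",")),
             "sealmito_io_error")
  df
}
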