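# Host-gene association screen: detection filter, Pearson r^2 screen against
# HERV-K env abundance, clinical fold-change filter, and hypergeometric term
# overrepresentation under Benjamini-Hochberg control.

#' Association screen parameters
#'
#' @param min_tags Detection threshold: a gene is kept when its count
#'   reaches `min_tags` in at least one sample (or in every sample with
#'   `per_sample = TRUE`, the strict conjunctive reading).
#' @param r2_threshold Squared Pearson correlation threshold against env
#'   abundance; both correlation signs pass, since the screen is on r^2.
#' @param fold_change_threshold Clinical fold-change threshold; see
#'   [fold_change_filter()] for the definition.
#' @param fdr_q BH-adjusted significance level used when reporting enriched
#'   terms.
#' @param per_sample Strict per-sample detection mode.
#' @param fc_mode `"symmetric"` scores `|case/control - 1|` (both 1.3x up
#'   and 0.7x down pass at 0.3); `"ratio"` scores the raw ratio's excess
#'   `case/control - 1` (up-regulation only).
#' @return Object of class `assoc_params`.
#' @export
assoc_params <- function(min_tags = 2L, r2_threshold = 0.5,
                         fold_change_threshold = 0.3, fdr_q = 0.05,
                         per_sample = FALSE,
                         fc_mode = c("symmetric", "ratio")) {
  min_tags <- as.integer(min_tags)
  if (is.na(min_tags) || min_tags < 0L) stop("min_tags must be >= 0")
  if (!is.numeric(r2_threshold) || r2_threshold < 0 || r2_threshold > 1)
    stop("r2_threshold must lie in [0, 1]")
  if (!is.numeric(fold_change_threshold) || fold_change_threshold < 0)
    stop("fold_change_threshold must be >= 0")
  if (!is.numeric(fdr_q) || fdr_q <= 0 || fdr_q > 1)
    stop("fdr_q must lie in (0, 1]")
  structure(list(min_tags = min_tags, r2_threshold = r2_threshold,
                 fold_change_threshold = fold_change_threshold,
                 fdr_q = fdr_q, per_sample = isTRUE(per_sample),
                 fc_mode = match.arg(fc_mode)),
            class = "assoc_params")
}

#' Detection filter on a count matrix
#'
#' Keeps genes detected with at least `min_tags` counts; by default a gene
#' passes when its maximum count across samples reaches the threshold, in
#' `per_sample` mode every sample must reach it.
#'
#' @param matrix Non-negative count matrix, genes in rows.
#' @param min_tags Detection threshold.
#' @param per_sample Require the threshold in every sample?
#' @return The filtered matrix, gene order preserved.
#' @export
detection_filter <- function(matrix, min_tags = 2L, per_sample = FALSE) {
  m <- as.matrix(matrix)
  if (any(m < 0)) stop("count matrix must be non-negative")
  keep <- if (per_sample) apply(m, 1L, min) >= min_tags
          else apply(m, 1L, max) >= min_tags
  m[keep, , drop = FALSE]
}

#' Correlate each gene with env abundance
#'
#' Pearson correlation of each gene's (normalized) counts with the
#' per-sample HERV-K env abundance vector. Genes with zero variance have an
#' undefined correlation: they are flagged and fail the screen.
#'
#' @param matrix Globally normalized count matrix, genes in rows; column
#'   names must match `names(env_abundance)`.
#' @param env_abundance Named per-sample env abundance (>= 2 distinct
#'   values, >= 3 samples).
#' @param params [assoc_params()].
#' @return Data frame `gene`, `r`, `r2`, `undefined`, `passes_r2`.
#' @export
correlate_with_env <- function(matrix, env_abundance,
                               params = assoc_params()) {
  m <- as.matrix(matrix)
  if (ncol(m) < 3L) stop("correlation screen needs >= 3 samples")
  if (is.null(colnames(m)) || is.null(names(env_abundance)) ||
      !identical(sort(colnames(m)), sort(names(env_abundance))))
    stop("sample-name mismatch between count matrix and env vector")
  env <- env_abundance[colnames(m)]
  if (length(unique(env)) < 2L)
    stop("env abundance must have >= 2 distinct values")
  sds <- apply(m, 1L, function(v) max(v) - min(v))
  r <- rep(NA_real_, nrow(m))
  ok <- sds > 0
  if (any(ok)) r[ok] <- as.numeric(cor(t(m[ok, , drop = FALSE]), env))
  r2 <- r^2
  data.frame(gene = rownames(m), r = r, r2 = r2,
             undefined = !ok,
             passes_r2 = !is.na(r2) & r2 >= params$r2_threshold,
             stringsAsFactors = FALSE)
}

#' Clinical fold-change filter
#'
#' The default symmetric definition scores
#' `|mean(case) / mean(control) - 1|`, so at threshold 0.3 both a 1.3-fold
#' induction and a 0.7-fold suppression pass. A zero control mean with a
#' positive case mean is an infinite change and passes.
#'
#' @param matrix (Normalized) count matrix, genes in rows.
#' @param group_labels Named per-sample group labels covering every column.
#' @param threshold Fold-change threshold.
#' @param case,control Group labels of the case and control samples.
#' @param fc_mode See [assoc_params()].
#' @return Data frame `gene`, `fold_change`, `passes_fc`.
#' @export
fold_change_filter <- function(matrix, group_labels, threshold = 0.3,
                               case = "HIVpos", control = "HIVneg",
                               fc_mode = "symmetric") {
  m <- as.matrix(matrix)
  if (is.null(colnames(m)) ||
      !all(colnames(m) %in% names(group_labels)))
    stop("missing group label for: ",
         paste(setdiff(colnames(m), names(group_labels)), collapse = ", "))
  g <- group_labels[colnames(m)]
  if (!any(g == case) || !any(g == control))
    stop("both groups need >= 1 sample")
  mc <- rowMeans(m[, g == case, drop = FALSE])
  m0 <- rowMeans(m[, g == control, drop = FALSE])
  ratio <- mc / m0
  fc <- if (fc_mode == "symmetric") abs(ratio - 1) else ratio - 1
  fc[m0 == 0 & mc > 0] <- Inf
  fc[m0 == 0 & mc == 0] <- 0
  data.frame(gene = rownames(m), fold_change = fc,
             passes_fc = fc >= threshold, stringsAsFactors = FALSE)
}

#' Hypergeometric term overrepresentation with BH control
#'
#' For each term, tests whether the selected gene set contains more of the
#' term's genes than expected under hypergeometric sampling from the
#' universe (`p = P[X >= k]`, the upper tail). P-values are BH-adjusted
#' across the tested terms.
#'
#' @param selected Character vector of selected genes (subset of
#'   `universe`).
#' @param universe Character vector: the gene universe.
#' @param term_map Data frame with columns `gene`, `term` (multiple rows
#'   per gene allowed); genes outside the universe are ignored.
#' @return Data frame `term`, `k` (overlap), `K` (term size in universe),
#'   `n` (selected size), `N` (universe size), `p`, `q`, sorted by `p` then
#'   term.
#' @export
enrich <- function(selected, universe, term_map) {
  universe <- unique(as.character(universe))
  selected <- unique(as.character(selected))
  outside <- setdiff(selected, universe)
  if (length(outside))
    stop("selected genes outside the universe: ",
         paste(outside, collapse = ", "))
  tm <- term_map[term_map$gene %in% universe, , drop = FALSE]
  terms <- sort(unique(as.character(tm$term)))
  N <- length(universe)
  n <- length(selected)
  res <- do.call(rbind, lapply(terms, function(t) {
    members <- unique(tm$gene[tm$term == t])
    K <- length(members)
    k <- length(intersect(members, selected))
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = t, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(res))
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric()))
  res$q <- p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$term, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Run the full host-gene association screen
#'
#' Pipeline: global normalization, detection filter, Pearson r^2 screen
#' against env abundance, the clinical fold-change filter when group labels
#' are supplied, then term overrepresentation of the selected genes against
#' the detection-passing universe. When `out_dir` is given every
#' intermediate is written as TSV together with a JSON run manifest
#' (parameters plus MD5 digests of the inputs).
#'
#' @param counts Raw genes-by-samples count matrix.
#' @param env_abundance Named per-sample env abundance vector.
#' @param group_labels Named per-sample group labels (`NULL` for the
#'   healthy-brain mode without the fold-change filter).
#' @param term_map Data frame `gene`, `term`.
#' @param params [assoc_params()].
#' @param out_dir Output directory, or `NULL` to keep results in memory.
#' @return List of class `association_run`: `results` (per-gene table with
#'   all screen columns and the final `selected` flag), `selected` (gene
#'   vector), `enrichment` ([enrich()] output), `universe`, `params`.
#' @export
run_association <- function(counts, env_abundance, group_labels = NULL,
                            term_map, params = assoc_params(),
                            out_dir = NULL) {
  stopifnot(inherits(params, "assoc_params"))
  counts <- as.matrix(counts)
  normed <- global_normalize(counts)
  detected <- detection_filter(normed, params$min_tags, params$per_sample)
  if (nrow(detected) == 0L) stop("no gene passes the detection filter")
  universe <- rownames(detected)

  corr <- correlate_with_env(detected, env_abundance, params)
  res <- data.frame(gene = rownames(normed),
                    passes_detection = rownames(normed) %in% universe,
                    stringsAsFactors = FALSE)
  res <- merge(res, corr, by = "gene", all.x = TRUE, sort = FALSE)

  if (!is.null(group_labels)) {
    fc <- fold_change_filter(detected, group_labels,
                             params$fold_change_threshold,
                             fc_mode = params$fc_mode)
    res <- merge(res, fc, by = "gene", all.x = TRUE, sort = FALSE)
    res$selected <- res$passes_detection &
      !is.na(res$passes_r2) & res$passes_r2 &
      !is.na(res$passes_fc) & res$passes_fc
  } else {
    res$selected <- res$passes_detection & !is.na(res$passes_r2) & res$passes_r2
  }
  res <- res[match(rownames(normed), res$gene), , drop = FALSE]
  rownames(res) <- NULL
  selected <- res$gene[res$selected]

  enrichment <- enrich(selected, universe, term_map)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_count_matrix(normed, file.path(out_dir, "normalized_counts.tsv"))
    write.table(res, file.path(out_dir, "association_results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(selected, file.path(out_dir, "selected_genes.txt"))
    write.table(enrichment, file.path(out_dir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(
      params = unclass(params),
      inputs = list(
        counts_md5 = matrix_digest(counts),
        env_md5 = matrix_digest(rbind(env_abundance)),
        n_genes = nrow(counts), n_samples = ncol(counts)),
      selected_n = length(selected))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA),
               file.path(out_dir, "manifest.json"))
  }

  structure(list(results = res, selected = selected, enrichment = enrichment,
                 universe = universe, params = params),
            class = "association_run")
}

# md5 of a matrix's serialized TSV image (stable across sessions)
matrix_digest <- function(m) {
  f <- tempfile()
  on.exit(unlink(f))
  write.table(m, f, sep = "\t", quote = FALSE)
  unname(tools::md5sum(f))
}

#' @export
print.association_run <- function(x, ...) {
  cat("association_run:", length(x$universe), "genes in universe,",
      length(x$selected), "selected\n")
  if (nrow(x$enrichment))
    cat("  top term:", x$enrichment$term[1L], " q =",
        signif(x$enrichment$q[1L], 3), "\n")
  invisible(x)
}
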