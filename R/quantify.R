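# Headline HERV quantities: per-family tag frequencies over unambiguously
# assigned tags, length-normalized env/gag-pol/LTR region frequencies,
# global normalization of count matrices, and exact/approximate Mann-Whitney
# group comparisons.

#' Per-family tag frequencies of a sample
#'
#' A family's tag frequency is its percent share of the sample's
#' HERV-assigned tags. Tags classified `HERV_AMBIGUOUS` are excluded from
#' the denominator by default, since frequencies are defined over
#' unambiguously assigned tags; set `include_ambiguous = TRUE` to count them
#' as their own `AMBIGUOUS` row inside the denominator.
#'
#' @param assignments Assignment table from [classify_sample()].
#' @param include_ambiguous Count ambiguous tags as their own category?
#' @return Data frame `family`, `count`, `freq` (percent, summing to 100)
#'   with attribute `total_herv_tags`.
#' @export
family_frequencies <- function(assignments, include_ambiguous = FALSE) {
  herv <- assignments[assignments$category == "HERV", , drop = FALSE]
  counts <- table(herv$family)
  out <- data.frame(family = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  if (include_ambiguous) {
    n_amb <- sum(assignments$category == "HERV_AMBIGUOUS")
    out <- rbind(out, data.frame(family = "AMBIGUOUS", count = n_amb))
  }
  total <- sum(out$count)
  if (total == 0L)
    stop("no HERV-assigned tags in this sample; family frequencies undefined")
  out$freq <- 100 * out$count / total
  out <- out[order(-out$count, out$family), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_herv_tags") <- total
  out
}

#' Length-normalized region frequencies for one HERV family
#'
#' Region tag counts are divided by the family's total annotated length per
#' label (tags per nt), then rescaled to percentages within the family, so
#' a long gag-pol region does not dominate purely by length.
#'
#' @inheritParams family_frequencies
#' @param ref The [reference_set()] the assignments were made against.
#' @param family HERV family name.
#' @return Data frame `label`, `count`, `length_nt`, `rate` (tags/nt),
#'   `freq` (percent, summing to 100 when any region tag exists). A family
#'   absent from the table yields zero counts, not an error.
#' @export
region_frequencies <- function(assignments, ref, family) {
  lens <- region_lengths(ref, family)
  rows <- assignments$category == "HERV" & !is.na(assignments$family) &
    assignments$family == family
  counts <- table(factor(assignments$region[rows], levels = names(lens)))
  out <- data.frame(label = names(lens), count = as.integer(counts),
                    length_nt = as.integer(lens), stringsAsFactors = FALSE)
  out$rate <- out$count / out$length_nt
  total_rate <- sum(out$rate)
  out$freq <- if (total_rate > 0) 100 * out$rate / total_rate else
    rep(NA_real_, nrow(out))
  rownames(out) <- NULL
  out
}

#' Family and region abundance profile of one sample
#'
#' @inheritParams region_frequencies
#' @param sample_id Sample label.
#' @return List of class `abundance_profile` with `sample_id`, `families`
#'   ([family_frequencies()] output), `regions` (named list of
#'   [region_frequencies()] outputs per family present), and
#'   `total_herv_tags`.
#' @export
abundance_profile <- function(assignments, ref, sample_id = "sample",
                              include_ambiguous = FALSE) {
  fams <- family_frequencies(assignments, include_ambiguous)
  present <- setdiff(fams$family, "AMBIGUOUS")
  regions <- lapply(setNames(present, present), function(f)
    region_frequencies(assignments, ref, f))
  structure(list(sample_id = sample_id, families = fams, regions = regions,
                 total_herv_tags = attr(fams, "total_herv_tags")),
            class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat("abundance_profile for", x$sample_id, "-", x$total_herv_tags,
      "HERV tags\n")
  print(x$families, ...)
  invisible(x)
}

#' Globally normalize a count matrix
#'
#' Rescales each sample's column so that every column total equals the mean
#' of the original column totals, under the assumption that the expression
#' distribution is similar across samples. Idempotent, and preserves the
#' overall scale of the data.
#'
#' @param matrix Non-negative numeric matrix, genes in rows, samples in
#'   columns (at least 2).
#' @return Matrix of the same shape with equal column sums.
#' @export
global_normalize <- function(matrix) {
  m <- as.matrix(matrix)
  if (ncol(m) < 2L) stop("global normalization needs >= 2 samples")
  if (any(m < 0)) stop("count matrix must be non-negative")
  totals <- colSums(m)
  zero <- totals == 0
  if (any(zero))
    stop("sample with zero total count: ",
         paste(colnames(m)[zero], collapse = ", "))
  sweep(m, 2L, mean(totals) / totals, "*")
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments;
# ties get the usual half credit in U
mw_enumerate <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  m <- n1 * length(y)
  u_of <- function(sel) {
    a <- pooled[sel]
    b <- pooled[-sel]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  sel <- combn(length(pooled), n1)
  us <- apply(sel, 2L, u_of)
  dev_obs <- abs(u_obs - m / 2)
  p <- mean(abs(us - m / 2) >= dev_obs - 1e-9)
  list(U = u_obs, p = p)
}

# tie-corrected normal approximation with continuity correction
mw_normal <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = u, p = 1))
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  list(U = u, p = min(1, 2 * pnorm(-max(z, 0))))
}

#' Mann-Whitney comparison of two groups
#'
#' Two-sided Mann-Whitney test on per-sample values. When both groups have
#' at most `exact_threshold` values the p-value is exact, by full
#' enumeration of all group assignments of the pooled values (ties handled
#' by half-credit in U; the two-sided p counts assignments whose U deviates
#' from its null mean at least as much as observed). Larger groups use the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param values_by_group Named list of two numeric vectors (>= 2 values
#'   each).
#' @param exact_threshold Largest per-group size for exact enumeration.
#' @param metric Optional metric name carried in the result.
#' @return List of class `group_comparison`: `metric`, `group_values`,
#'   `medians`, `U` (first group), `p_two_sided`, `method`.
#' @export
compare_groups <- function(values_by_group, exact_threshold = 8L,
                           metric = NULL) {
  if (!is.list(values_by_group) || length(values_by_group) != 2L)
    stop("values_by_group must be a named list of two numeric vectors")
  sizes <- lengths(values_by_group)
  if (any(sizes < 2L)) stop("each group needs >= 2 values")
  x <- as.numeric(values_by_group[[1L]])
  y <- as.numeric(values_by_group[[2L]])
  exact <- all(sizes <= exact_threshold)
  res <- if (exact) mw_enumerate(x, y) else mw_normal(x, y)
  structure(list(metric = metric,
                 group_values = values_by_group,
                 medians = vapply(values_by_group, median, numeric(1)),
                 U = res$U, p_two_sided = res$p,
                 method = if (exact) "exact enumeration"
                          else "normal approximation (tie-corrected)"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Mann-Whitney", if (!is.null(x$metric)) paste0("(", x$metric, ")"),
      "-", x$method, "\n")
  cat("  medians:", paste(names(x$medians), signif(x$medians, 4),
                          sep = "=", collapse = " "), "\n")
  cat("  U =", x$U, " two-sided p =", signif(x$p_two_sided, 4), "\n")
  invisible(x)
}

#' Read / write a genes-by-samples count matrix as TSV
#'
#' The TSV has a `gene` first column and one column per sample.
#'
#' @param path File path.
#' @return `read_count_matrix`: numeric matrix with gene rownames.
#' @export
read_count_matrix <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1L] != "gene") stop("count matrix TSV must start with a 'gene' column")
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d$gene
  storage.mode(m) <- "double"
  m
}

#' @rdname read_count_matrix
#' @param matrix Genes-by-samples matrix with dimnames.
#' @export
write_count_matrix <- function(matrix, path) {
  d <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
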