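test_that("family frequencies are plain shares of unambiguous HERV tags", {
  tab <- assignment_rows(c("HERV", "HERV", "HERV", "HERV_AMBIGUOUS", "RRNA"),
                         family = c("HERV-K", "HERV-H", "HERV-W", NA, NA),
                         n = c(31, 57, 12, 10, 40))
  ff <- family_frequencies(tab)
  expect_equal(setNames(ff$freq, ff$family),
               c(`HERV-H` = 57, `HERV-K` = 31, `HERV-W` = 12))
  expect_equal(attr(ff, "total_herv_tags"), 100L)
  expect_equal(sum(ff$freq), 100)
  # ambiguous tags never leak into a family, but can be their own category
  ffa <- family_frequencies(tab, include_ambiguous = TRUE)
  expect_equal(ffa$count[ffa$family == "AMBIGUOUS"], 10L)
  expect_equal(sum(ffa$freq), 100)
  expect_equal(ffa$count[ffa$family == "HERV-K"], 31L)
  # single family: 100%
  one <- assignment_rows("HERV", family = "HERV-K", n = 10)
  expect_equal(family_frequencies(one)$freq, 100)
  # no HERV tags at all: undefined
  expect_error(family_frequencies(assignment_rows("RRNA", n = 5)),
               "undefined")
})

test_that("family frequencies match an independent tally and scale invariance", {
  set.seed(31)
  for (i in 1:20) {
    fams <- paste0("F", 1:4)
    n <- sample(1:50, 4)
    tab <- assignment_rows(rep("HERV", 4), family = fams, n = n)
    tab <- tab[sample(nrow(tab)), ]
    ff <- family_frequencies(tab)
    # one-line independent tally
    oracle <- 100 * table(tab$family)[ff$family] / nrow(tab)
    expect_equal(setNames(ff$freq, ff$family), unlist(as.list(oracle)))
    # duplicating every tag leaves frequencies unchanged
    ff2 <- family_frequencies(rbind(tab, tab))
    expect_equal(ff2$freq, ff$freq)
  }
})

test_that("region frequencies are normalized by annotated length", {
  seqs <- c(`HERV-K` = rand_dna(2800))
  ann <- data.frame(ref_id = "HERV-K", start = c(0, 500, 2500),
                    end = c(500, 2500, 2800),
                    label = c("LTR", "GAG_POL", "ENV"))
  ref <- reference_set(seqs, "HERV", "HERV-K", ann)
  tab <- assignment_rows(rep("HERV", 3), family = "HERV-K",
                         region = c("ENV", "GAG_POL", "LTR"),
                         n = c(5, 20, 50))
  rf <- region_frequencies(tab, ref, "HERV-K")
  expect_equal(setNames(rf$rate, rf$label),
               c(ENV = 5 / 300, GAG_POL = 20 / 2000, LTR = 50 / 500))
  expect_equal(setNames(round(rf$freq, 2), rf$label),
               c(ENV = 13.16, GAG_POL = 7.89, LTR = 78.95))
  expect_equal(sum(rf$freq), 100)
  # all tags in one region
  ltr_only <- assignment_rows("HERV", family = "HERV-K", region = "LTR", n = 7)
  rl <- region_frequencies(ltr_only, ref, "HERV-K")
  expect_equal(rl$freq[rl$label == "LTR"], 100)
  # family absent from the table: zero counts, not an error
  empty <- region_frequencies(assignment_rows("RRNA", n = 3), ref, "HERV-K")
  expect_equal(sum(empty$count), 0L)
})

test_that("region frequencies are invariant to a uniform length rescaling", {
  tab <- assignment_rows(rep("HERV", 3), family = "HERV-K",
                         region = c("ENV", "GAG_POL", "LTR"), n = c(8, 30, 60))
  make_ref <- function(scale) {
    lens <- c(LTR = 200, GAG_POL = 800, ENV = 200) * scale
    cuts <- cumsum(c(0, lens))
    reference_set(setNames(rand_dna(sum(lens)), "HERV-K"), "HERV", "HERV-K",
                  data.frame(ref_id = "HERV-K", start = cuts[1:3],
                             end = cuts[2:4], label = names(lens)))
  }
  set.seed(2)
  r1 <- make_ref(1); r2 <- make_ref(3)
  f1 <- region_frequencies(tab, r1, "HERV-K")
  f2 <- region_frequencies(tab, r2, "HERV-K")
  expect_equal(f1$freq, f2$freq)
})

test_that("global normalization equalizes column totals and is idempotent", {
  set.seed(5)
  m <- matrix(rpois(300, 20), nrow = 50,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  m[, 2] <- m[, 2] * 3
  n1 <- global_normalize(m)
  expect_lt(diff(range(colSums(n1))) / mean(colSums(n1)), 1e-9)
  expect_equal(colSums(n1), setNames(rep(mean(colSums(m)), 6), colnames(m)))
  # idempotence
  expect_equal(global_normalize(n1), n1, tolerance = 1e-12)
  # equal totals: identity
  eq <- matrix(c(1, 2, 3, 3, 2, 1), nrow = 3)
  expect_equal(global_normalize(eq), eq)
  # doubling one sample is undone symmetrically
  two <- cbind(A = c(5, 5), B = c(10, 10))
  n2 <- global_normalize(two)
  expect_equal(unname(colSums(n2)), c(15, 15))
  # zero-total sample is named in the error
  bad <- cbind(A = c(1, 2), B = c(0, 0))
  expect_error(global_normalize(bad), "zero total.*B")
  expect_error(global_normalize(matrix(1:3, ncol = 1)), ">= 2 samples")
})

test_that("exact Mann-Whitney enumeration reproduces known and oracle p-values", {
  cmp <- compare_groups(list(A = c(1, 2, 3), B = c(4, 5, 6)))
  expect_equal(cmp$U, 0)
  expect_equal(cmp$p_two_sided, 0.1)   # 2 of the 20 arrangements as extreme
  expect_equal(unname(cmp$medians), c(2, 5))
  # identical groups: p = 1
  same <- compare_groups(list(A = c(2, 2, 2), B = c(2, 2, 2)))
  expect_equal(same$p_two_sided, 1)
  # tie-free random instances against wilcox.test's exact distribution
  set.seed(77)
  for (i in 1:100) {
    x <- sample(1:1000, 4); y <- sample(1001:2000, 5) - 1000.5
    ours <- compare_groups(list(x = x, y = y))$p_two_sided
    oracle <- suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value)
    expect_equal(ours, oracle, tolerance = 1e-12, label = paste("case", i))
  }
  expect_error(compare_groups(list(A = 1, B = c(1, 2))), ">= 2 values")
})

test_that("large groups fall back to the tie-corrected normal approximation", {
  set.seed(9)
  x <- rnorm(20); y <- rnorm(25, 1)
  cmp <- compare_groups(list(x = x, y = y))
  expect_match(cmp$method, "normal")
  oracle <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(cmp$p_two_sided, oracle, tolerance = 1e-9)
  # with heavy ties the tie-corrected variance still matches
  xt <- rep(1:3, c(4, 8, 3)); yt <- rep(2:4, c(5, 4, 6))
  cmp_t <- compare_groups(list(x = xt, y = yt), exact_threshold = 8)
  oracle_t <- suppressWarnings(wilcox.test(xt, yt, exact = FALSE,
                                           correct = TRUE)$p.value)
  expect_equal(cmp_t$p_two_sided, oracle_t, tolerance = 1e-9)
})

test_that("exact Mann-Whitney p-values are valid and well calibrated under the null", {
  set.seed(123)
  nrep <- 1500
  p <- replicate(nrep, compare_groups(list(rnorm(5), rnorm(5)))$p_two_sided)
  for (a in c(0.05, 0.1, 0.25, 0.5)) {
    frac <- mean(p <= a)
    expect_lte(frac, a + 3 * sqrt(a * (1 - a) / nrep))  # never anti-conservative
    expect_gte(frac, a - 0.09)   # close to nominal at the discrete resolution
  }
})

test_that("count matrices survive a TSV round trip", {
  m <- matrix(c(0, 3, 7.5, 2, 1, 9), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  f <- tempfile(fileext = ".tsv")
  write_count_matrix(m, f)
  expect_equal(read_count_matrix(f), m)
})
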