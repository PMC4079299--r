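test_that("an exact unique substring yields a single zero-mismatch hit", {
  ref <- tiny_reference()
  tag <- substr(ref$sequences[["GENE_A"]], 101, 136)
  hits <- align_tag(tag, ref)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$ref_id, "GENE_A")
  expect_equal(hits$position, 100L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0L)
  # and on the minus strand via its reverse complement
  hits_rc <- align_tag(oracle_revcomp(tag), ref)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$position, 100L)
})

test_that("tags matching nothing within the mismatch budget return no hits", {
  ref <- tiny_reference()
  set.seed(1)
  tag <- rand_dna(36)   # random 36-mer: astronomically unlikely to hit
  expect_equal(nrow(align_tag(tag, ref)), 0L)
  expect_error(align_tag("ACGT", ref), "shorter than seed_length")
})

test_that("seed-and-extend equals the exhaustive Hamming scan on random cases", {
  ref <- tiny_reference()
  scan <- oracle_scanner(ref, max_mm = 2)
  set.seed(42)
  src <- ref$sequences
  for (i in 1:150) {
    tag <- if (i %% 3 == 0) rand_dna(36) else {
      k <- sample(0:3, 1)    # up to one past the budget
      s <- src[[sample(length(src), 1)]]
      t <- mutated_substring(s, 36, k)
      if (runif(1) < 0.5) t else oracle_revcomp(t)
    }
    expect_identical(align_tag(tag, ref), scan(tag), label = paste("case", i))
  }
})

test_that("the ambiguity margin separates near-tied families as documented", {
  # HERV-K carries the tag at 1 mismatch, HERV-H at 2
  set.seed(7)
  tag <- rand_dna(36)
  near_k <- strsplit(tag, "")[[1]]
  near_k[5] <- setdiff(c("A", "C", "G", "T"), near_k[5])[1]
  near_h <- strsplit(tag, "")[[1]]
  near_h[10] <- setdiff(c("A", "C", "G", "T"), near_h[10])[1]
  near_h[20] <- setdiff(c("A", "C", "G", "T"), near_h[20])[1]
  seqs <- c(`HERV-K` = paste0(rand_dna(40), paste(near_k, collapse = ""),
                              rand_dna(40)),
            `HERV-H` = paste0(rand_dna(40), paste(near_h, collapse = ""),
                              rand_dna(40)))
  ann <- data.frame(ref_id = names(seqs), start = 0, end = 116, label = "LTR")
  ref <- reference_set(seqs, "HERV", c("HERV-K", "HERV-H"), ann)
  # verify the construction with the independent scanner
  scan <- oracle_scanner(ref, max_mm = 2)
  d <- scan(tag)
  expect_equal(min(d$mismatches[d$ref_id == "HERV-K"]), 1L)
  expect_equal(min(d$mismatches[d$ref_id == "HERV-H"]), 2L)
  a1 <- classify_tag(tag, ref, classifier_params(ambiguity_margin = 1))
  expect_equal(a1$category, "HERV")
  expect_equal(a1$family, "HERV-K")
  a2 <- classify_tag(tag, ref, classifier_params(ambiguity_margin = 2))
  expect_equal(a2$category, "HERV_AMBIGUOUS")
  expect_true(is.na(a2$family))
})

test_that("earlier triage tiers always win over later ones", {
  # plant the same 36-mer into an rRNA and a HERV reference
  set.seed(8)
  shared <- rand_dna(36)
  seqs <- c(RRNA_X = paste0(rand_dna(50), shared, rand_dna(50)),
            `HERV-K` = paste0(rand_dna(50), shared, rand_dna(50)),
            GENE_A = rand_dna(300))
  ann <- data.frame(ref_id = "HERV-K", start = 0, end = 136, label = "ENV")
  ref <- reference_set(seqs, c("RRNA", "HERV", "HOST_TX"),
                       c(NA, "HERV-K", NA), ann)
  a <- classify_tag(shared, ref)
  expect_equal(a$category, "RRNA")
  expect_equal(a$ref_id, "RRNA_X")
  # host transcriptome beats nuclear-genome-only within the host tier
  seqs2 <- c(GENE_A = paste0(rand_dna(30), shared, rand_dna(30)),
             NUC_1 = paste0(rand_dna(30), shared, rand_dna(30)),
             `HERV-K` = rand_dna(200))
  ann2 <- data.frame(ref_id = "HERV-K", start = 0, end = 200, label = "LTR")
  ref2 <- reference_set(seqs2, c("HOST_TX", "NUCLEAR", "HERV"),
                        c(NA, NA, "HERV-K"), ann2)
  expect_equal(classify_tag(shared, ref2)$category, "HOST_TX")
})

test_that("tags from a planted shared motif are ambiguous, with no family leakage", {
  cfg <- sim_config(seed = 17, n_tags = 3000,
                    class_mixture = c(RRNA = 0, HOST_TX = 0, NUCLEAR = 0,
                                      MTDNA = 0, MICROBIAL = 0, HERV = 1,
                                      JUNK = 0),
                    error_rate = 0)
  built <- build_reference(cfg)
  sim <- simulate_tags(built$ref, cfg, "m",
                       motif_interval = built$truth$motif_interval)
  cl <- retroscope:::classify_tags(sim$tags, built$ref)
  motif_tags <- sim$truth$tag_id[sim$truth$in_motif]
  expect_gt(length(motif_tags), 10)
  got <- cl[match(motif_tags, cl$tag_id), ]
  expect_true(all(got$category == "HERV_AMBIGUOUS"))
  expect_true(all(is.na(got$family)))
})

test_that("region is assigned by the midpoint of the aligned interval", {
  ref <- tiny_reference()               # LTR 0-120, GAG_POL 120-600, ENV 600-720
  s <- ref$sequences[["HERV-K"]]
  # tag straddling the LTR/GAG_POL boundary at position 100: midpoint 118 -> LTR
  a <- classify_tag(substr(s, 101, 136), ref)
  expect_equal(a$region, "LTR")
  # one base later the midpoint crosses into GAG_POL... at start 103, mid=121
  b <- classify_tag(substr(s, 104, 139), ref)
  expect_equal(b$region, "GAG_POL")
  c_ <- classify_tag(substr(s, 650, 685), ref)
  expect_equal(c_$region, "ENV")
})

test_that("classify_sample tabulates a pure-class FASTQ as 100% that class", {
  ref <- tiny_reference()
  set.seed(3)
  starts <- sample(600, 40)
  tags <- substring(ref$sequences[["RRNA_A"]], starts, starts + 35)
  fq <- tempfile(fileext = ".fastq")
  write_fastq_plain(tags, fq)
  cl <- classify_sample(fq, ref, sample_id = "pure")
  bd <- cl$breakdown
  expect_equal(bd$fraction[bd$category == "RRNA"], 100)
  expect_equal(sum(bd$count), 40L)
  expect_equal(sum(bd$fraction), 100)
})

test_that("breakdowns add over concatenated FASTQs and ignore record order", {
  cfg <- sim_config(seed = 23, n_tags = 400)
  built <- build_reference(cfg)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  simulate_tags(built$ref, cfg, "a", fastq_path = f1)
  simulate_tags(built$ref, cfg, "b", fastq_path = f2)
  cat12 <- tempfile(fileext = ".fastq")
  writeLines(c(readLines(f1), readLines(f2)), cat12)
  b1 <- classify_sample(f1, built$ref)$breakdown
  b2 <- classify_sample(f2, built$ref)$breakdown
  b12 <- classify_sample(cat12, built$ref)$breakdown
  expect_equal(b12$count, b1$count + b2$count)
  # permuted record order: identical breakdown, row-permuted assignments
  lines <- matrix(readLines(f1), nrow = 4)
  set.seed(1); perm <- sample(ncol(lines))
  fp <- tempfile(fileext = ".fastq")
  writeLines(as.vector(lines[, perm]), fp)
  cp <- classify_sample(fp, built$ref)
  c1 <- classify_sample(f1, built$ref)
  expect_equal(cp$breakdown$count, c1$breakdown$count)
  a1 <- c1$assignments[order(c1$assignments$tag_id), ]
  ap <- cp$assignments[order(cp$assignments$tag_id), ]
  rownames(a1) <- rownames(ap) <- NULL
  expect_identical(a1, ap)
})

test_that("empty or missing FASTQ input fails loudly", {
  ref <- tiny_reference()
  fq <- tempfile(fileext = ".fastq")
  file.create(fq)
  expect_error(classify_sample(fq, ref), "empty|malformed")
})
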