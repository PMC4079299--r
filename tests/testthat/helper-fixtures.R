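# Small fixtures built in code.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# minimal mixed-class reference set: 2 rRNA, 2 host, 1 mito, 1 microbial,
# 2 HERV families fully annotated
tiny_reference <- function(seed = 11, herv_len = c(LTR = 120, GAG_POL = 480,
                                                   ENV = 120)) {
  set.seed(seed)
  total <- sum(herv_len)
  seqs <- c(RRNA_A = rand_dna(700), RRNA_B = rand_dna(700),
            GENE_A = rand_dna(500), GENE_B = rand_dna(500),
            MT_1 = rand_dna(600), MICRO_1 = rand_dna(500),
            `HERV-K` = rand_dna(total), `HERV-H` = rand_dna(total))
  cls <- c("RRNA", "RRNA", "HOST_TX", "HOST_TX", "MTDNA", "MICROBIAL",
           "HERV", "HERV")
  fam <- c(rep(NA, 6), "HERV-K", "HERV-H")
  cuts <- cumsum(c(0, herv_len))
  ann <- data.frame(
    ref_id = rep(c("HERV-K", "HERV-H"), each = 3),
    start = rep(cuts[1:3], 2), end = rep(cuts[2:4], 2),
    label = rep(names(herv_len), 2))
  reference_set(seqs, cls, fam, ann)
}

write_fastq_plain <- function(tags, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("t%04d", seq_along(tags))
  writeLines(as.vector(rbind(paste0("@", ids), tags, "+",
                             strrep("I", nchar(tags)))), path)
  path
}

# assignment-table row builder for quantification tests
assignment_rows <- function(category, family = NA, region = NA, n = 1) {
  do.call(rbind, Map(function(cat, fam, reg, k) {
    data.frame(tag_id = replicate(k, paste0("t", sample.int(1e9, 1))),
               category = cat, family = fam, region = reg,
               ref_id = NA_character_, position = NA_integer_,
               strand = NA_character_, mismatches = NA_integer_,
               stringsAsFactors = FALSE)
  }, category, family, region, n))
}
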