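# Seeded synthetic-data generator: HERV family references diverged from a
# common ancestor with a verbatim shared LTR motif (the planted ambiguity),
# decoy references for the other source classes, fixed-length single-end tag
# FASTQs with substitution errors, and a two-group cohort with a planted
# env-tracking host-gene module. Everything is a pure function of the config
# seed so downstream stages can be tested against exact ground truth.

DNA_BASES <- c("A", "C", "G", "T")

random_seq <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# i.i.d. substitution at rate p; each substitution uniform over the 3 other bases
mutate_seq <- function(seq, p) {
  if (p <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(v)) < p)
  if (length(hit)) {
    for (i in hit) v[i] <- sample(setdiff(DNA_BASES, v[i]), 1L)
    seq <- paste(v, collapse = "")
  }
  seq
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# deterministic per-sample seed below 2^31
derive_seed <- function(seed, salt) {
  s <- sum(utf8ToInt(as.character(salt))) %% 100003L
  as.integer((as.numeric(seed) * 7919 + s * 104729 + 17) %% 2147483647)
}

#' Default two-group cohort design
#'
#' @param n_per_group Samples per clinical group.
#' @return Data frame `sample_id`, `group` with `HIVpos` and `HIVneg` arms.
#' @export
default_samples <- function(n_per_group = 4L) {
  data.frame(
    sample_id = c(sprintf("HIVpos_%d", seq_len(n_per_group)),
                  sprintf("HIVneg_%d", seq_len(n_per_group))),
    group = rep(c("HIVpos", "HIVneg"), each = n_per_group),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is exercised under: a
#' 36-nt single-end tag regime, a source-class mixture patterned on the
#' observed triage of a deep-sequenced brain library (rRNA-dominated, with a
#' substantial nuclear-genome and unmappable fraction and a small HERV
#' fraction), six HERV families at 10% per-site divergence from a common
#' ancestor sharing one verbatim LTR motif, and an eight-sample two-group
#' cohort (HIV+ vs HIV-) whose HERV-K env abundance is strongly induced in
#' the HIV+ group and drives a 20-gene planted host module.
#'
#' @param seed Integer seed; every downstream draw derives from it.
#' @param tag_length Tag length in nt.
#' @param n_tags Tags per sample.
#' @param class_mixture Named fractions over `RRNA`, `HOST_TX`, `NUCLEAR`,
#'   `MTDNA`, `MICROBIAL`, `HERV`, `JUNK`; must sum to 1. `JUNK` tags are
#'   i.i.d. random sequence (the unmappable fraction).
#' @param herv_family_mixture Named fractions over the HERV families; must
#'   sum to 1. Its names define the family set; length must equal
#'   `n_families`.
#' @param error_rate Per-base substitution probability, in `[0, 0.25]`.
#' @param n_families Number of HERV families.
#' @param family_divergence Per-site substitution rate from the common
#'   ancestor to each family.
#' @param region_lengths Named lengths (nt) of the `LTR`, `GAG_POL` and
#'   `ENV` regions of every HERV reference.
#' @param shared_ltr_motif_length Length of the motif copied verbatim into
#'   every family's LTR (the planted ambiguity); must fit inside the LTR and
#'   should exceed `tag_length` so whole tags can fall inside it.
#' @param rrna_length,mtdna_length,microbial_length,nuclear_length Decoy
#'   reference lengths.
#' @param n_genes,gene_length Host transcript universe (these references
#'   double as the association-stage genes).
#' @param gene_mean_meanlog,gene_mean_sdlog Log-normal hyper-parameters of
#'   the per-gene baseline mean counts.
#' @param gene_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 degenerates to deterministic means.
#' @param module_size Number of planted module genes.
#' @param module_effect Effect size: module gene means are
#'   `mu_g * (1 + module_effect * (env_s / mean(env) - 1))`, so 1 means
#'   exactly proportional to env abundance and 0 removes the module.
#' @param env_meanlog Named log-scale group means of the per-sample true
#'   HERV-K env abundance.
#' @param env_sdlog Log-scale spread of env abundance within group.
#' @param n_terms,term_size Number and size of decoy annotation terms.
#' @param planted_term_decoys Non-module genes added to the planted term.
#' @param samples Data frame `sample_id`, `group` (`HIVpos`/`HIVneg`).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       tag_length = 36L,
                       n_tags = 20000L,
                       class_mixture = c(RRNA = 0.3145, HOST_TX = 0.1179,
                                         NUCLEAR = 0.3260, MTDNA = 0.0767,
                                         MICROBIAL = 0.0010, HERV = 0.0200,
                                         JUNK = 0.1439),
                       herv_family_mixture = c("HERV-H" = 0.57,
                                               "HERV-K" = 0.31,
                                               "HERV-W" = 0.05,
                                               "HERV-R" = 0.04,
                                               "HERV-E" = 0.02,
                                               "HERV-FRD" = 0.01),
                       error_rate = 0.01,
                       n_families = length(herv_family_mixture),
                       family_divergence = 0.10,
                       region_lengths = c(LTR = 500L, GAG_POL = 2000L,
                                          ENV = 500L),
                       shared_ltr_motif_length = 80L,
                       rrna_length = 1500L, mtdna_length = 2000L,
                       microbial_length = 1000L, nuclear_length = 3000L,
                       n_genes = 200L, gene_length = 400L,
                       gene_mean_meanlog = log(100), gene_mean_sdlog = 0.6,
                       gene_dispersion = 0.1,
                       module_size = 20L, module_effect = 1,
                       env_meanlog = c(HIVneg = log(1), HIVpos = log(10)),
                       env_sdlog = 0.2,
                       n_terms = 10L, term_size = 15L,
                       planted_term_decoys = 5L,
                       samples = default_samples()) {
  cfg <- list(seed = as.integer(seed), tag_length = as.integer(tag_length),
              n_tags = as.integer(n_tags), class_mixture = class_mixture,
              herv_family_mixture = herv_family_mixture,
              error_rate = error_rate, n_families = as.integer(n_families),
              family_divergence = family_divergence,
              region_lengths = region_lengths,
              shared_ltr_motif_length = as.integer(shared_ltr_motif_length),
              rrna_length = as.integer(rrna_length),
              mtdna_length = as.integer(mtdna_length),
              microbial_length = as.integer(microbial_length),
              nuclear_length = as.integer(nuclear_length),
              n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              gene_mean_meanlog = gene_mean_meanlog,
              gene_mean_sdlog = gene_mean_sdlog,
              gene_dispersion = gene_dispersion,
              module_size = as.integer(module_size),
              module_effect = module_effect,
              env_meanlog = env_meanlog, env_sdlog = env_sdlog,
              n_terms = as.integer(n_terms), term_size = as.integer(term_size),
              planted_term_decoys = as.integer(planted_term_decoys),
              samples = as.data.frame(samples))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check_mixture <- function(m, what) {
    if (any(m < 0 | m > 1)) stop(what, " fractions must lie in [0, 1]")
    if (abs(sum(m) - 1) > 1e-9) stop(what, " must sum to 1 (got ", sum(m), ")")
  }
  if (!setequal(names(cfg$class_mixture), SIM_CLASSES))
    stop("class_mixture must name exactly: ",
         paste(SIM_CLASSES, collapse = ", "))
  check_mixture(cfg$class_mixture, "class_mixture")
  check_mixture(cfg$herv_family_mixture, "herv_family_mixture")
  if (cfg$n_families != length(cfg$herv_family_mixture))
    stop("n_families must match length(herv_family_mixture)")
  if (cfg$error_rate < 0 || cfg$error_rate > 0.25)
    stop("error_rate must lie in [0, 0.25]")
  if (cfg$n_tags < 1L) stop("n_tags must be positive")
  if (!setequal(names(cfg$region_lengths), REGION_LABELS))
    stop("region_lengths must name ", paste(REGION_LABELS, collapse = ", "))
  if (cfg$shared_ltr_motif_length > cfg$region_lengths[["LTR"]])
    stop("shared_ltr_motif_length exceeds the LTR length")
  shortest <- min(cfg$rrna_length, cfg$mtdna_length, cfg$microbial_length,
                  cfg$nuclear_length, cfg$gene_length,
                  sum(cfg$region_lengths))
  if (cfg$tag_length > shortest)
    stop("tag_length exceeds the shortest reference length")
  if (!all(c("sample_id", "group") %in% names(cfg$samples)))
    stop("samples needs columns sample_id, group")
  if (!all(cfg$samples$group %in% c("HIVpos", "HIVneg")))
    stop("sample group labels must be HIVpos or HIVneg")
  if (cfg$module_size > cfg$n_genes) stop("module_size exceeds n_genes")
  invisible(cfg)
}

#' Build the synthetic reference universe
#'
#' Emits one reference per HERV family, all derived from a single random
#' ancestor by i.i.d. substitution at `family_divergence`, each annotated
#' `LTR`/`GAG_POL`/`ENV`, with the shared LTR motif copied verbatim into
#' every family at the same offset (centered in the LTR). Decoy references
#' are added for the rRNA, host-transcript (the association-stage gene
#' universe), nuclear, mtDNA and microbial classes. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `ref` (a [reference_set()]) and `truth` (list with the
#'   planted motif sequence, its interval, the family ids and the gene ids).
#' @export
build_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "reference"))
  rl <- cfg$region_lengths
  herv_len <- sum(rl)
  ltr_len <- rl[["LTR"]]
  motif_len <- cfg$shared_ltr_motif_length
  motif_start <- (ltr_len - motif_len) %/% 2L
  families <- names(cfg$herv_family_mixture)

  ancestor <- random_seq(herv_len)
  motif <- if (motif_len > 0L) random_seq(motif_len) else ""
  herv_seqs <- vapply(families, function(f) {
    s <- mutate_seq(ancestor, cfg$family_divergence)
    if (motif_len > 0L)
      s <- paste0(substr(s, 1L, motif_start), motif,
                  substr(s, motif_start + motif_len + 1L, herv_len))
    s
  }, character(1))

  gene_ids <- sprintf("GENE_%03d", seq_len(cfg$n_genes))
  decoys <- c(
    setNames(replicate(2L, random_seq(cfg$rrna_length)), c("RRNA_1", "RRNA_2")),
    setNames(vapply(gene_ids, function(g) random_seq(cfg$gene_length),
                    character(1)), gene_ids),
    setNames(replicate(2L, random_seq(cfg$nuclear_length)),
             c("NUCLEAR_1", "NUCLEAR_2")),
    setNames(random_seq(cfg$mtdna_length), "MTDNA_1"),
    setNames(replicate(2L, random_seq(cfg$microbial_length)),
             c("MICROBIAL_1", "MICROBIAL_2")))
  classes <- c(rep("RRNA", 2L), rep("HOST_TX", cfg$n_genes),
               rep("NUCLEAR", 2L), "MTDNA", rep("MICROBIAL", 2L))

  sequences <- c(herv_seqs, decoys)
  source_class <- c(rep("HERV", length(families)), classes)
  family <- c(families, rep(NA_character_, length(decoys)))
  ann <- data.frame(
    ref_id = rep(families, each = 3L),
    start = rep(c(0L, ltr_len, ltr_len + rl[["GAG_POL"]]), length(families)),
    end = rep(c(ltr_len, ltr_len + rl[["GAG_POL"]], herv_len),
              length(families)),
    label = rep(c("LTR", "GAG_POL", "ENV"), length(families)),
    stringsAsFactors = FALSE)

  ref <- reference_set(sequences, source_class, family, ann)
  truth <- list(motif = motif,
                motif_interval = c(start = motif_start,
                                   end = motif_start + motif_len),
                families = families, gene_ids = gene_ids)
  list(ref = ref, truth = truth)
}

#' Simulate one sample's tag FASTQ with ground truth
#'
#' Each tag draws a source class from `class_mixture` (JUNK tags are i.i.d.
#' random sequence), a reference uniformly within the class (HERV family
#' from `herv_family_mixture`, host transcript optionally weighted), a
#' uniform start position and strand, then i.i.d. substitution errors at
#' `error_rate`. Qualities are written as a constant `I`.
#'
#' @param ref A [reference_set()] (normally from [build_reference()]).
#' @param cfg A [sim_config()].
#' @param sample_id Sample label; also salts the derived RNG seed.
#' @param fastq_path Where to write the FASTQ, or `NULL` to skip writing.
#' @param gene_weights Optional named sampling weights over the host
#'   transcripts (used by [simulate_cohort()] so FASTQ tag counts track the
#'   cohort count matrix).
#' @param family_mixture Optional per-sample override of the HERV family
#'   mixture.
#' @param motif_interval Optional `c(start, end)` of the planted LTR motif,
#'   used to flag tags lying wholly inside it.
#' @return List with `truth` (per-tag data frame: `tag_id`, `class`,
#'   `family`, `ref_id`, `start`, `strand`, `n_errors`, `in_motif`),
#'   `fastq_path`, and `tags` (named character vector of tag sequences).
#' @export
simulate_tags <- function(ref, cfg, sample_id, fastq_path = NULL,
                          gene_weights = NULL, family_mixture = NULL,
                          motif_interval = NULL) {
  stopifnot(inherits(ref, "reference_set"), inherits(cfg, "sim_config"))
  if (cfg$n_tags <= 0L) stop("n_tags must be positive")
  set.seed(derive_seed(cfg$seed, paste0("tags:", sample_id)))
  n <- cfg$n_tags
  L <- cfg$tag_length
  mix <- cfg$class_mixture[SIM_CLASSES]
  fam_mix <- if (is.null(family_mixture)) cfg$herv_family_mixture else
    family_mixture / sum(family_mixture)

  cls <- sample(SIM_CLASSES, n, replace = TRUE, prob = mix)
  meta <- ref$meta
  fam <- rep(NA_character_, n)
  ref_id <- rep(NA_character_, n)

  for (cl in setdiff(SIM_CLASSES, "JUNK")) {
    idx <- which(cls == cl)
    if (!length(idx)) next
    if (cl == "HERV") {
      fam[idx] <- sample(names(fam_mix), length(idx), replace = TRUE,
                         prob = fam_mix)
      for (f in unique(fam[idx])) {
        fi <- idx[fam[idx] == f]
        pool <- meta$id[meta$source_class == "HERV" & !is.na(meta$family) &
                          meta$family == f]
        ref_id[fi] <- pool[sample.int(length(pool), length(fi), replace = TRUE)]
      }
    } else if (cl == "HOST_TX" && !is.null(gene_weights)) {
      pool <- meta$id[meta$source_class == cl]
      w <- gene_weights[pool]
      w[is.na(w)] <- 0
      if (sum(w) <= 0) w <- rep(1, length(pool))
      ref_id[idx] <- pool[sample.int(length(pool), length(idx),
                                     replace = TRUE, prob = w)]
    } else {
      pool <- meta$id[meta$source_class == cl]
      ref_id[idx] <- pool[sample.int(length(pool), length(idx), replace = TRUE)]
    }
  }

  ref_len <- setNames(meta$length, meta$id)
  start <- rep(NA_integer_, n)
  mapped <- !is.na(ref_id)
  nvalid <- ref_len[ref_id[mapped]] - L + 1L
  start[mapped] <- as.integer(floor(runif(sum(mapped)) * nvalid))  # 0-based
  strand <- sample(c("+", "-"), n, replace = TRUE)

  seqs <- character(n)
  seqs[mapped] <- substring(ref$sequences[ref_id[mapped]],
                            start[mapped] + 1L, start[mapped] + L)
  minus <- mapped & strand == "-"
  if (any(minus)) seqs[minus] <- revcomp_chr(seqs[minus])
  junk <- which(!mapped)
  if (length(junk)) {
    mat <- matrix(sample(DNA_BASES, length(junk) * L, replace = TRUE),
                  nrow = length(junk))
    seqs[junk] <- apply(mat, 1L, paste, collapse = "")
  }

  n_errors <- rbinom(n, L, cfg$error_rate)
  for (i in which(n_errors > 0L)) {
    pos <- sample.int(L, n_errors[i])
    v <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    for (p in pos) v[p] <- sample(setdiff(DNA_BASES, v[p]), 1L)
    seqs[i] <- paste(v, collapse = "")
  }

  tag_id <- sprintf("%s_tag_%06d", sample_id, seq_len(n))
  in_motif <- rep(FALSE, n)
  if (!is.null(motif_interval)) {
    hv <- mapped & cls == "HERV"
    in_motif[hv] <- start[hv] >= motif_interval[["start"]] &
      (start[hv] + L) <= motif_interval[["end"]]
  }
  truth <- data.frame(tag_id = tag_id, class = cls, family = fam,
                      ref_id = ref_id, start = start, strand = strand,
                      n_errors = n_errors, in_motif = in_motif,
                      stringsAsFactors = FALSE)
  names(seqs) <- tag_id
  if (!is.null(fastq_path)) {
    dna <- Biostrings::DNAStringSet(seqs)
    qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(dna, fastq_path, format = "fastq",
                                qualities = qual)
  }
  list(truth = truth, fastq_path = fastq_path, tags = seqs)
}

#' Simulate a two-group cohort with a planted env-tracking gene module
#'
#' Assigns each sample a true HERV-K env abundance (log-normal within group,
#' higher in `HIVpos`), draws the host-gene count matrix as negative
#' binomial with module gene means scaling with env abundance, builds the
#' gene-to-term table (one planted term covering the module plus decoys,
#' and `n_terms` random decoy terms), and optionally writes per-sample tag
#' FASTQs in which the per-sample HERV-K share scales with env abundance and
#' host-transcript tags are drawn proportionally to the count matrix.
#'
#' @param cfg A [sim_config()] with at least 3 samples per group for the
#'   association stage.
#' @param out_dir Output directory for FASTQs and tables, or `NULL` to keep
#'   everything in memory.
#' @param write_fastq Set `FALSE` to skip tag simulation (the count matrix,
#'   env abundances and terms are enough for the association stage).
#' @return List with `ref`, `ref_truth`, `counts` (genes x samples matrix),
#'   `env` (named per-sample true env abundance), `samples`, `term_map`
#'   (data frame `gene`, `term`), `planted` (module genes and planted term),
#'   `tag_truth` (per-sample list, when FASTQs are simulated), `fastq_paths`,
#'   and `paths` of any files written.
#' @export
simulate_cohort <- function(cfg, out_dir = NULL, write_fastq = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  samples <- cfg$samples
  if (any(table(factor(samples$group, c("HIVpos", "HIVneg"))) < 3L) &&
      cfg$module_effect != 0)
    warning("fewer than 3 samples per group; association recovery is fragile")
  built <- build_reference(cfg)
  ref <- built$ref

  set.seed(derive_seed(cfg$seed, "cohort"))
  env <- setNames(rlnorm(nrow(samples),
                         meanlog = cfg$env_meanlog[samples$group],
                         sdlog = cfg$env_sdlog),
                  samples$sample_id)
  if (length(unique(signif(env, 12))) < 2L)
    stop("fewer than 2 distinct env abundance values; correlation undefined")

  gene_ids <- built$truth$gene_ids
  mu <- setNames(rlnorm(cfg$n_genes, cfg$gene_mean_meanlog,
                        cfg$gene_mean_sdlog), gene_ids)
  module <- sort(sample(gene_ids, cfg$module_size))
  scale_s <- 1 + cfg$module_effect * (env / mean(env) - 1)
  mu_mat <- matrix(mu, nrow = cfg$n_genes, ncol = nrow(samples),
                   dimnames = list(gene_ids, samples$sample_id))
  mu_mat[module, ] <- sweep(mu_mat[module, , drop = FALSE], 2L, scale_s, "*")
  counts <- if (cfg$gene_dispersion > 0) {
    matrix(rnbinom(length(mu_mat), mu = mu_mat,
                   size = 1 / cfg$gene_dispersion),
           nrow = cfg$n_genes, dimnames = dimnames(mu_mat))
  } else mu_mat

  planted_term <- "TERM_PLANTED"
  decoy_in_term <- sample(setdiff(gene_ids, module), cfg$planted_term_decoys)
  term_map <- data.frame(gene = c(module, decoy_in_term),
                         term = planted_term, stringsAsFactors = FALSE)
  for (t in seq_len(cfg$n_terms)) {
    term_map <- rbind(term_map, data.frame(
      gene = sort(sample(gene_ids, cfg$term_size)),
      term = sprintf("TERM_%02d", t), stringsAsFactors = FALSE))
  }

  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths$fasta <- file.path(out_dir, "reference.fasta")
    paths$regions <- file.path(out_dir, "reference_regions.tsv")
    write_reference(ref, paths$fasta, paths$regions)
    paths$counts <- file.path(out_dir, "counts.tsv")
    write_count_matrix(counts, paths$counts)
    paths$env <- file.path(out_dir, "env_abundance.tsv")
    write.table(data.frame(sample_id = names(env), env_abundance = env),
                paths$env, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$groups <- file.path(out_dir, "groups.tsv")
    write.table(samples, paths$groups, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths$terms <- file.path(out_dir, "terms.tsv")
    write.table(term_map, paths$terms, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths$truth <- file.path(out_dir, "truth.tsv")
    write.table(data.frame(sample_id = names(env), group = samples$group,
                           true_env_abundance = env),
                paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$module <- file.path(out_dir, "truth_module_genes.tsv")
    write.table(data.frame(gene = module, term = planted_term),
                paths$module, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$config <- file.path(out_dir, "config.yaml")
    cfg_plain <- unclass(cfg)
    cfg_plain$samples <- as.list(samples)
    writeLines(yaml::as.yaml(cfg_plain), paths$config)
  }

  tag_truth <- NULL
  fastq_paths <- NULL
  if (write_fastq) {
    tag_truth <- list()
    fastq_paths <- character(0)
    base_mix <- cfg$herv_family_mixture
    for (i in seq_len(nrow(samples))) {
      sid <- samples$sample_id[i]
      fam_mix <- base_mix
      if ("HERV-K" %in% names(fam_mix))
        fam_mix["HERV-K"] <- fam_mix["HERV-K"] * env[[sid]]
      fq <- if (is.null(out_dir)) NULL else
        file.path(out_dir, paste0(sid, ".fastq"))
      sim <- simulate_tags(ref, cfg, sid, fastq_path = fq,
                           gene_weights = counts[, sid],
                           family_mixture = fam_mix,
                           motif_interval = built$truth$motif_interval)
      tag_truth[[sid]] <- sim$truth
      if (!is.null(fq)) fastq_paths[sid] <- fq
    }
  }

  list(ref = ref, ref_truth = built$truth, counts = counts, env = env,
       samples = samples, term_map = term_map,
       planted = list(module_genes = module, term = planted_term),
       tag_truth = tag_truth, fastq_paths = fastq_paths, paths = paths)
}
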