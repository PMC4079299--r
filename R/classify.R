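# Hierarchical tag classification: seed-and-extend Hamming alignment against
# the labeled reference universe, source-class triage in a fixed tier order,
# and unambiguous HERV family assignment with an explicit mismatch margin.

#' Classifier parameters
#'
#' @param seed_length Exact-seed length in nt used to index the references.
#'   When `max_mismatches * seed_length >= tag length` the configured seed
#'   cannot guarantee that every valid placement retains a mismatch-free
#'   seed, so the effective seed is shortened to
#'   `floor(tag_length / (max_mismatches + 1))`; by pigeonhole the search is
#'   then exhaustive (identical to an all-positions Hamming scan).
#' @param max_mismatches Maximum Hamming distance of a reported hit.
#' @param ambiguity_margin Minimum mismatch gap `d2 - d1` between the best
#'   and second-best HERV family for an assignment to count as unambiguous;
#'   the default 1 makes any tie ambiguous (the strictest reading).
#' @return An object of class `classifier_params`.
#' @export
classifier_params <- function(seed_length = 18L, max_mismatches = 2L,
                              ambiguity_margin = 1L) {
  seed_length <- as.integer(seed_length)
  max_mismatches <- as.integer(max_mismatches)
  ambiguity_margin <- as.integer(ambiguity_margin)
  if (is.na(seed_length) || seed_length < 1L)
    stop("seed_length must be a positive integer")
  if (is.na(max_mismatches) || max_mismatches < 0L)
    stop("max_mismatches must be >= 0")
  if (is.na(ambiguity_margin) || ambiguity_margin < 1L)
    stop("ambiguity_margin must be >= 1")
  structure(list(seed_length = seed_length, max_mismatches = max_mismatches,
                 ambiguity_margin = ambiguity_margin),
            class = "classifier_params")
}

# effective index k-mer size: never longer than what pigeonhole needs
effective_seed <- function(params, min_tag_len) {
  k <- min(params$seed_length, min_tag_len %/% (params$max_mismatches + 1L))
  max(1L, min(k, 31L))
}

ref_class_codes <- function(ref) {
  match(ref$meta$source_class, SOURCE_CLASSES) - 1L
}

#' Align one tag against the reference universe
#'
#' Reports every placement of the tag, on both strands of every reference in
#' `class_filter`, with Hamming distance at most `max_mismatches`. Hits are
#' sorted by mismatch count, ties broken by (ref_id, position, strand) for
#' determinism. Equivalent to an exhaustive all-positions Hamming scan (see
#' [classifier_params()] for how the seed guarantees this).
#'
#' @param tag Nucleotide string, at least `seed_length` long.
#' @param ref A [reference_set()].
#' @param class_filter Character vector of source classes to search
#'   (default: all).
#' @param params [classifier_params()].
#' @return Data frame with columns `ref_id`, `position` (0-based),
#'   `strand` (`"+"`/`"-"`), `mismatches`.
#' @export
align_tag <- function(tag, ref, class_filter = SOURCE_CLASSES,
                      params = classifier_params()) {
  stopifnot(inherits(ref, "reference_set"), is.character(tag), length(tag) == 1L)
  tag <- toupper(tag)
  if (nchar(tag) < params$seed_length)
    stop("tag shorter than seed_length (", nchar(tag), " < ",
         params$seed_length, ")")
  if (!all(class_filter %in% SOURCE_CLASSES))
    stop("unknown source class in class_filter")
  allowed <- SOURCE_CLASSES %in% class_filter
  k <- effective_seed(params, nchar(tag))
  hits <- cpp_align_tags(unname(ref$sequences), ref_class_codes(ref),
                         tag, k, params$max_mismatches, allowed)
  data.frame(ref_id = ref$meta$id[hits$ref],
             position = hits$pos,
             strand = c("+", "-")[hits$strand + 1L],
             mismatches = hits$mm,
             stringsAsFactors = FALSE)
}

# shared batch classifier over a character vector of tags
classify_tags <- function(tags, ref, params = classifier_params()) {
  stopifnot(inherits(ref, "reference_set"))
  tags <- toupper(tags)
  if (!length(tags)) stop("no tags to classify")
  if (any(nchar(tags) < params$seed_length))
    stop("tag shorter than seed_length")
  fams <- herv_families(ref)
  if (!length(fams)) stop("reference set contains no HERV family")
  fam_code <- match(ref$meta$family, fams)
  fam_code[is.na(fam_code)] <- 0L
  ann <- ref$annotations
  k <- effective_seed(params, min(nchar(tags)))
  out <- cpp_classify_tags(unname(ref$sequences), ref_class_codes(ref),
                           fam_code, length(fams),
                           match(ann$ref_id, ref$meta$id), ann$start, ann$end,
                           match(ann$label, REGION_LABELS),
                           tags, k, params$max_mismatches,
                           params$ambiguity_margin)
  data.frame(
    tag_id = if (is.null(names(tags))) sprintf("tag_%06d", seq_along(tags))
             else names(tags),
    category = TAG_CATEGORIES[out$category + 1L],
    family = fams[out$family],
    region = REGION_LABELS[out$region],
    ref_id = ref$meta$id[out$ref],
    position = out$pos,
    strand = c("+", "-")[out$strand + 1L],
    mismatches = out$mm,
    stringsAsFactors = FALSE)
}

#' Classify a single tag
#'
#' Tiers are tried in the fixed order rRNA, host transcriptome (including
#' nuclear-genome-only, reported as its own `NUCLEAR` label), mtDNA,
#' microbial, HERV; the first tier with at least one hit decides the
#' category. Within the HERV tier the tag is assigned to the family with the
#' uniquely best mismatch count only when the second-best family is at least
#' `ambiguity_margin` mismatches worse; otherwise it is `HERV_AMBIGUOUS`.
#' The region label is the annotation containing the midpoint of the aligned
#' interval.
#'
#' @param tag Nucleotide string.
#' @inheritParams align_tag
#' @return One-row data frame with columns `tag_id`, `category`, `family`,
#'   `region`, `ref_id`, `position`, `strand`, `mismatches`.
#' @export
classify_tag <- function(tag, ref, params = classifier_params()) {
  classify_tags(setNames(as.character(tag), names(tag)), ref, params)
}

#' Classify every tag of a FASTQ sample
#'
#' @param fastq_path Path to a single-end FASTQ file (qualities ignored).
#' @inheritParams align_tag
#' @param sample_id Sample label for the breakdown (default: file base name).
#' @return List with `assignments` (the per-tag table, see [classify_tag()])
#'   and `breakdown` (data frame `sample_id`, `category`, `count`,
#'   `fraction`; fractions are percentages summing to 100).
#' @export
classify_sample <- function(fastq_path, ref, params = classifier_params(),
                            sample_id = NULL) {
  reads <- tryCatch(
    Biostrings::readDNAStringSet(fastq_path, format = "fastq"),
    error = function(e) stop("malformed FASTQ '", fastq_path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!length(reads)) stop("empty FASTQ: ", fastq_path)
  if (is.null(sample_id))
    sample_id <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq_path))
  tags <- setNames(as.character(reads), sub("\\s.*$", "", names(reads)))
  assignments <- classify_tags(tags, ref, params)
  list(assignments = assignments,
       breakdown = category_breakdown(assignments, sample_id))
}

#' Tabulate the source-class triage of a tag assignment table
#'
#' @param assignments Assignment table from [classify_sample()].
#' @param sample_id Sample label.
#' @return Data frame `sample_id`, `category`, `count`, `fraction` covering
#'   all of [TAG_CATEGORIES]; fractions are percentages of all tags.
#' @export
category_breakdown <- function(assignments, sample_id = "sample") {
  counts <- table(factor(assignments$category, levels = TAG_CATEGORIES))
  data.frame(sample_id = sample_id,
             category = TAG_CATEGORIES,
             count = as.integer(counts),
             fraction = 100 * as.integer(counts) / nrow(assignments),
             stringsAsFactors = FALSE)
}
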