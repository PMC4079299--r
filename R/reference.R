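# Labeled reference universe: sequences tagged with a source class (and, for
# HERV, a family), plus env/gag-pol/LTR interval annotations in 0-based
# half-open (BED) coordinates.

#' Construct a validated reference set
#'
#' Builds the labeled reference universe the tag classifier maps against.
#' Sequences are uppercased; any character outside `A/C/G/T` is rejected
#' (the Hamming scorer needs a fixed four-letter alphabet). Annotations use
#' 0-based half-open coordinates and may not overlap within a reference;
#' every HERV reference must carry at least one annotation and a family
#' label, non-HERV references must carry neither.
#'
#' @param sequences Named character vector of nucleotide sequences; names are
#'   the reference ids and must be unique.
#' @param source_class Character vector (one per sequence) over
#'   [SOURCE_CLASSES].
#' @param family Character vector (one per sequence); `NA` except for HERV
#'   references, where it names the HERV family (e.g. `"HERV-K"`).
#' @param annotations Data frame with columns `ref_id`, `start`, `end`,
#'   `label` (`label` over [REGION_LABELS], case-insensitive).
#' @return An object of class `reference_set` with elements `sequences`
#'   (id-sorted named character vector), `meta` (id, source_class, family,
#'   length) and `annotations`.
#' @seealso [load_reference()], [region_lengths()]
#' @export
reference_set <- function(sequences, source_class, family = NA_character_,
                          annotations = NULL) {
  ids <- names(sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("every reference sequence must be named")
  if (anyDuplicated(ids))
    stop("duplicated reference id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGT]", sequences)
  if (any(bad))
    stop("non-ACGT characters in reference: ",
         paste(ids[bad], collapse = ", "))
  if (any(nchar(sequences) == 0L)) stop("zero-length reference sequence")

  source_class <- rep_len(as.character(source_class), length(sequences))
  if (!all(source_class %in% SOURCE_CLASSES))
    stop("unknown source_class: ",
         paste(setdiff(source_class, SOURCE_CLASSES), collapse = ", "))
  family <- rep_len(as.character(family), length(sequences))
  herv <- source_class == "HERV"
  if (any(herv & (is.na(family) | family == "")))
    stop("HERV reference without a family: ",
         paste(ids[herv & (is.na(family) | family == "")], collapse = ", "))
  if (any(!herv & !is.na(family)))
    stop("non-HERV reference with a family label: ",
         paste(ids[!herv & !is.na(family)], collapse = ", "))

  if (is.null(annotations))
    annotations <- data.frame(ref_id = character(), start = integer(),
                              end = integer(), label = character())
  annotations <- as.data.frame(annotations)
  need <- c("ref_id", "start", "end", "label")
  if (!all(need %in% names(annotations)))
    stop("annotations need columns ", paste(need, collapse = ", "))
  annotations <- annotations[need]
  annotations$ref_id <- as.character(annotations$ref_id)
  annotations$start <- as.integer(annotations$start)
  annotations$end <- as.integer(annotations$end)
  annotations$label <- toupper(as.character(annotations$label))
  if (!all(annotations$label %in% REGION_LABELS))
    stop("unknown region label: ",
         paste(setdiff(annotations$label, REGION_LABELS), collapse = ", "))
  unknown <- setdiff(annotations$ref_id, ids)
  if (length(unknown))
    stop("annotation for unknown reference: ", paste(unknown, collapse = ", "))
  lens <- setNames(nchar(sequences), ids)
  bad <- annotations$start < 0L | annotations$start >= annotations$end |
    annotations$end > lens[annotations$ref_id]
  if (any(bad))
    stop("annotation outside sequence bounds on: ",
         paste(unique(annotations$ref_id[bad]), collapse = ", "))
  for (id in unique(annotations$ref_id)) {
    a <- annotations[annotations$ref_id == id, ]
    a <- a[order(a$start), ]
    if (nrow(a) > 1L && any(a$start[-1L] < a$end[-nrow(a)]))
      stop("overlapping annotations on reference: ", id)
  }
  no_ann <- herv & !(ids %in% annotations$ref_id)
  if (any(no_ann))
    stop("HERV reference without region annotations: ",
         paste(ids[no_ann], collapse = ", "))

  ord <- order(ids, method = "radix")   # locale-independent id order
  sequences <- sequences[ord]
  meta <- data.frame(id = ids[ord], source_class = source_class[ord],
                     family = family[ord], length = unname(lens[ids[ord]]),
                     stringsAsFactors = FALSE)
  annotations <- annotations[order(annotations$ref_id, annotations$start,
                                   method = "radix"), , drop = FALSE]
  rownames(annotations) <- NULL
  structure(list(sequences = sequences, meta = meta, annotations = annotations),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set:", nrow(x$meta), "sequences,",
      nrow(x$annotations), "region annotations\n")
  tab <- table(x$meta$source_class)
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  fams <- unique(x$meta$family[x$meta$source_class == "HERV"])
  if (length(fams)) cat("  HERV families:", paste(fams, collapse = " "), "\n")
  invisible(x)
}

#' Load a reference set from FASTA plus a regions table
#'
#' The regions file is a TSV with header
#' `ref_id start end label family source_class`; `label` is one of
#' `env`/`gag_pol`/`ltr` (case-insensitive) for HERV interval rows, and
#' `na` for the single carrier row of each non-HERV reference. Coordinates
#' are 0-based half-open.
#'
#' @param fasta_path Path to a FASTA file (wrapped or unwrapped).
#' @param regions_path Path to the regions TSV.
#' @return A [reference_set()].
#' @export
load_reference <- function(fasta_path, regions_path) {
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(fasta_path),
    error = function(e) stop("malformed FASTA '", fasta_path, "': ",
                             conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicated FASTA id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sequences <- setNames(toupper(as.character(seqs)), ids)

  reg <- read.delim(regions_path, stringsAsFactors = FALSE)
  need <- c("ref_id", "start", "end", "label", "family", "source_class")
  if (!all(need %in% names(reg)))
    stop("regions file needs columns ", paste(need, collapse = ", "))
  reg$label <- toupper(as.character(reg$label))
  reg$label[is.na(reg$label)] <- "NA"
  reg$family[is.na(reg$family) | reg$family == ""] <- NA_character_
  missing_ref <- setdiff(reg$ref_id, ids)
  if (length(missing_ref))
    stop("regions reference sequences absent from FASTA: ",
         paste(missing_ref, collapse = ", "))
  uncovered <- setdiff(ids, reg$ref_id)
  if (length(uncovered))
    stop("FASTA sequences absent from regions file: ",
         paste(uncovered, collapse = ", "))

  first <- !duplicated(reg$ref_id)
  cls <- setNames(reg$source_class[first], reg$ref_id[first])
  fam <- setNames(as.character(reg$family[first]), reg$ref_id[first])
  consistent <- tapply(paste(reg$source_class, reg$family), reg$ref_id,
                       function(v) length(unique(v)) == 1L)
  if (!all(consistent))
    stop("inconsistent class/family rows for: ",
         paste(names(consistent)[!consistent], collapse = ", "))

  ann <- reg[reg$label != "NA", c("ref_id", "start", "end", "label")]
  reference_set(sequences, source_class = unname(cls[ids]),
                family = unname(fam[ids]), annotations = ann)
}

#' Write a reference set to FASTA plus a regions table
#'
#' Inverse of [load_reference()]: the FASTA is written unwrapped and the
#' regions TSV carries one row per annotation plus one `na` carrier row per
#' non-HERV reference, so a round trip preserves every field.
#'
#' @param ref A [reference_set()].
#' @param fasta_path,regions_path Output paths.
#' @return Invisibly, `ref`.
#' @export
write_reference <- function(ref, fasta_path, regions_path) {
  stopifnot(inherits(ref, "reference_set"))
  dna <- Biostrings::DNAStringSet(ref$sequences)
  Biostrings::writeXStringSet(dna, fasta_path, width = max(nchar(ref$sequences)))
  ann <- ref$annotations
  m <- ref$meta
  ann$family <- m$family[match(ann$ref_id, m$id)]
  ann$source_class <- m$source_class[match(ann$ref_id, m$id)]
  ann$label <- tolower(ann$label)
  plain <- m[!(m$id %in% ann$ref_id), , drop = FALSE]
  if (nrow(plain)) {
    ann <- rbind(ann, data.frame(
      ref_id = plain$id, start = 0L, end = plain$length, label = "na",
      family = plain$family, source_class = plain$source_class))
  }
  ann <- ann[order(ann$ref_id, ann$start, method = "radix"), ]
  ann$family[is.na(ann$family)] <- ""
  write.table(ann, regions_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ref)
}

#' Total annotated length per region label for one HERV family
#'
#' Sums `end - start` per label over all of the family's references; the
#' denominators for length-normalized region frequencies.
#'
#' @param ref A [reference_set()].
#' @param family HERV family name present in `ref`.
#' @return Named integer vector over the labels present (absent labels are
#'   omitted), in [REGION_LABELS] order.
#' @export
region_lengths <- function(ref, family) {
  stopifnot(inherits(ref, "reference_set"))
  ids <- ref$meta$id[ref$meta$source_class == "HERV" &
                       !is.na(ref$meta$family) & ref$meta$family == family]
  if (!length(ids)) stop("unknown HERV family: ", family)
  a <- ref$annotations[ref$annotations$ref_id %in% ids, ]
  lens <- tapply(a$end - a$start, factor(a$label, levels = REGION_LABELS), sum)
  lens <- lens[!is.na(lens)]
  setNames(as.integer(lens), names(lens))
}

#' HERV families present in a reference set
#' @param ref A [reference_set()].
#' @return Character vector of family names.
#' @export
herv_families <- function(ref) {
  stopifnot(inherits(ref, "reference_set"))
  unique(ref$meta$family[ref$meta$source_class == "HERV"])
}
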