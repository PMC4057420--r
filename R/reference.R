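#' Read a germline V/D/J reference set
#'
#' Loads germline segments from a FASTA file together with a tab-separated
#' metadata sidecar. The sidecar carries what FASTA headers cannot express
#' unambiguously: the chain (`heavy`, `lambda`, `kappa`), the segment class
#' (`V`, `D`, `J`), and the optional CDR3 anchor. Anchors are 0-based
#' offsets into the germline sequence: for a V gene the first base after
#' the conserved-Cys codon, for a J gene the first base of the conserved
#' Trp/Phe codon. D segments carry no anchor.
#'
#' Every FASTA record must have a sidecar entry; lowercase bases are
#' upper-cased with a warning; ambiguity codes are rejected (germline
#' references are expected to be fully resolved).
#'
#' @param fasta_path path to the reference FASTA.
#' @param sidecar_path path to a TSV with columns `id`, `chain`, `class`,
#'   `anchor` (empty/NA where not applicable) and `note`.
#' @return An object of class `ig_reference_set`: a data frame with one row
#'   per segment (`id`, `chain`, `class`, `anchor`, `note`, `sequence`,
#'   `length`) plus an id index for constant-time lookup.
#' @seealso [validate_reference()], [write_reference()], [get_segment()]
#' @export
read_reference <- function(fasta_path, sidecar_path) {
  ## BStringSet keeps arbitrary letters so alphabet validation is ours
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0L) stop("no segments loaded from '", fasta_path, "'")
  meta <- read.delim(sidecar_path, stringsAsFactors = FALSE,
                     colClasses = c(anchor = "integer"))
  required <- c("id", "chain", "class", "anchor", "note")
  if (!all(required %in% names(meta)))
    stop("sidecar must have columns: ", paste(required, collapse = ", "))
  ids <- names(seqs)
  ids <- sub("\\s.*$", "", ids)  # FASTA description after first whitespace
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate id in reference FASTA: ", paste(unique(dup), collapse = ", "))
  missing_meta <- setdiff(ids, meta$id)
  if (length(missing_meta))
    stop("missing sidecar entry for: ", paste(missing_meta, collapse = ", "))
  extra <- setdiff(meta$id, ids)
  if (length(extra))
    warning("sidecar entries without FASTA record ignored: ",
            paste(extra, collapse = ", "))
  meta <- meta[match(ids, meta$id), , drop = FALSE]

  sequence <- as.character(seqs)
  low <- grepl("[acgt]", sequence)
  if (any(low)) {
    warning("lowercase bases upper-cased in: ",
            paste(ids[low], collapse = ", "))
    sequence <- toupper(sequence)
  }
  for (i in seq_along(sequence)) {
    bad <- regexpr("[^ACGT]", sequence[[i]])
    if (bad > 0L)
      stop("non-ACGT character in record '", ids[i], "' at position ",
           bad - 1L, " (0-based)")
  }
  new_reference_set(data.frame(
    id = ids,
    chain = meta$chain,
    class = meta$class,
    anchor = as.integer(meta$anchor),
    note = as.character(meta$note),
    sequence = unname(sequence),
    length = nchar(sequence),
    stringsAsFactors = FALSE
  ))
}

new_reference_set <- function(df) {
  stopifnot(!anyDuplicated(df$id))
  if (!all(df$chain %in% c("heavy", "lambda", "kappa")))
    stop("chain must be one of heavy, lambda, kappa")
  if (!all(df$class %in% c("V", "D", "J")))
    stop("class must be one of V, D, J")
  bad_anchor <- !is.na(df$anchor) & (df$anchor < 0L | df$anchor > df$length)
  if (any(bad_anchor))
    stop("cdr3_anchor outside [0, length] for: ",
         paste(df$id[bad_anchor], collapse = ", "))
  if (any(!is.na(df$anchor) & df$class == "D"))
    stop("D segments must not carry a cdr3_anchor: ",
         paste(df$id[!is.na(df$anchor) & df$class == "D"], collapse = ", "))
  rownames(df) <- df$id
  structure(df, class = c("ig_reference_set", "data.frame"))
}

#' Build a reference set from in-memory segments
#'
#' Programmatic constructor used by tests and simulations; applies the same
#' invariants as [read_reference()].
#'
#' @param id,chain,class,sequence parallel vectors describing each segment.
#' @param anchor optional integer vector of 0-based CDR3 anchors (NA where
#'   absent).
#' @param note optional provenance strings.
#' @return An `ig_reference_set`.
#' @export
reference_set <- function(id, chain, class, sequence, anchor = NA_integer_,
                          note = "") {
  df <- data.frame(id = id, chain = chain, class = class,
                   anchor = as.integer(anchor), note = note,
                   sequence = toupper(sequence),
                   length = nchar(sequence), stringsAsFactors = FALSE)
  if (any(grepl("[^ACGT]", df$sequence)))
    stop("sequences must be over ACGT")
  new_reference_set(df)
}

#' Look up one germline segment by id
#'
#' @param refs an `ig_reference_set`.
#' @param id segment id.
#' @return A one-row data frame (the segment record).
#' @export
get_segment <- function(refs, id) {
  stopifnot(inherits(refs, "ig_reference_set"))
  if (!id %in% refs$id) stop("unknown segment id: ", id)
  refs[id, , drop = FALSE]
}

subset_segments <- function(refs, chain, class) {
  refs[refs$chain == chain & refs$class == class, , drop = FALSE]
}

#' Write a reference set back to FASTA + sidecar
#'
#' Byte-identical round trip with [read_reference()] (sequences and
#' metadata).
#'
#' @param refs an `ig_reference_set`.
#' @param fasta_path,sidecar_path output paths.
#' @return Invisibly, `refs`.
#' @export
write_reference <- function(refs, fasta_path, sidecar_path) {
  stopifnot(inherits(refs, "ig_reference_set"))
  ss <- Biostrings::DNAStringSet(setNames(refs$sequence, refs$id))
  Biostrings::writeXStringSet(ss, fasta_path)
  write.table(refs[, c("id", "chain", "class", "anchor", "note")],
              sidecar_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(refs)
}

#' Validate a reference set and report per-chain composition
#'
#' Report-only: lists segment counts per (chain, class) and any anchor
#' inconsistencies (V/J without an anchor cannot support CDR3 delimitation
#' and are reported, not rejected). The report passes iff the structural
#' invariants hold: ids unique, each chain has at least one V and one J,
#' and the heavy chain (when present) at least one D.
#'
#' @param refs an `ig_reference_set`.
#' @return An object of class `ig_reference_report` with elements `counts`
#'   (chain x class), `issues` (character vector) and `pass` (logical).
#' @export
validate_reference <- function(refs) {
  stopifnot(inherits(refs, "ig_reference_set"))
  counts <- table(chain = refs$chain, class = refs$class)
  issues <- character()
  for (ch in rownames(counts)) {
    for (cl in c("V", "J"))
      if (!cl %in% colnames(counts) || counts[ch, cl] == 0L)
        issues <- c(issues, sprintf("chain %s has no %s segment", ch, cl))
    if (ch == "heavy" && (!"D" %in% colnames(counts) || counts[ch, "D"] == 0L))
      issues <- c(issues, "heavy chain has no D segment")
  }
  no_anchor <- refs$class %in% c("V", "J") & is.na(refs$anchor)
  if (any(no_anchor))
    issues <- c(issues, sprintf("missing cdr3_anchor: %s",
                                paste(refs$id[no_anchor], collapse = ", ")))
  structure(list(counts = counts,
                 issues = issues,
                 pass = !any(grepl("has no", issues))),
            class = "ig_reference_report")
}

#' @export
print.ig_reference_set <- function(x, ...) {
  cat("Germline reference set:", nrow(x), "segments\n")
  print(table(chain = x$chain, class = x$class))
  invisible(x)
}

#' @export
print.ig_reference_report <- function(x, ...) {
  cat("Reference validation:", if (x$pass) "PASS" else "FAIL", "\n")
  print(x$counts)
  if (length(x$issues)) cat("Issues:\n ", paste(x$issues, collapse = "\n  "), "\n")
  invisible(x)
}
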