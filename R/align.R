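#' Alignment parameters for germline segment assignment
#'
#' The scoring used for assigning germline segments to cDNA reads:
#' Smith-Waterman local alignment with match +1, mismatch -1, and an affine
#' gap scheme in which a gap of length L costs `gap_open + L * gap_extend`
#' (so a single-base gap costs -9 against V/J references and -4.3 against
#' D references). The D-specific extension penalty is kept marginal because
#' diversity genes share short repetitive motifs and the D alignment must
#' be allowed to span them; only nontemplated and palindromic bases should
#' be left in the junctions.
#'
#' @param match,mismatch substitution scores.
#' @param gap_open gap opening penalty (negative).
#' @param gap_extend_vj per-base gap extension against V and J references.
#' @param gap_extend_d per-base gap extension against D references
#'   (fractional).
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(match = 1, mismatch = -1, gap_open = -4,
                             gap_extend_vj = -5, gap_extend_d = -0.3) {
  if (gap_open > 0 || gap_extend_vj > 0 || gap_extend_d > 0)
    stop("gap penalties must be <= 0 (scores, not costs)")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend_vj = gap_extend_vj, gap_extend_d = gap_extend_d,
                 mode = "local"),
            class = "alignment_params")
}

submat_for <- function(params) {
  Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                           mismatch = params$mismatch,
                                           baseOnly = TRUE)
}

#' Optimal local alignment of a read against one germline segment
#'
#' Thin wrapper around `Biostrings::pairwiseAlignment` exposing the
#' quantities junction bookkeeping needs: the score (possibly fractional),
#' 0-based half-open spans on query and reference, the aligned strings,
#' and the exonuclease counts (`exo5`/`exo3`: germline bases at each end
#' absent from the alignment).
#'
#' A query with no positive-scoring local alignment is reported as no hit
#' (`hit = FALSE`).
#'
#' @param query read sequence (character).
#' @param reference germline sequence (character).
#' @param params an [alignment_params()].
#' @param gap_extend which extension penalty to use; defaults to the V/J
#'   value, pass `params$gap_extend_d` for diversity genes.
#' @return A list of class `segment_hit`: `hit`, `score`, `query_span`,
#'   `ref_span` (0-based half-open), `exo5`, `exo3`, `q_aln`, `r_aln`.
#' @export
align_local <- function(query, reference, params = alignment_params(),
                        gap_extend = params$gap_extend_vj) {
  if (!nzchar(query) || !nzchar(reference)) stop("empty input sequence")
  b <- align_batch(query, reference, params, gap_extend)
  h <- batch_hit(b, 1L, nchar(reference))
  h
}

## Vectorized alignment of many queries against one reference.
## Returns a list with per-query vectors plus aligned strings.
align_batch <- function(queries, reference, params, gap_extend) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(queries),
    subject = Biostrings::DNAString(reference),
    substitutionMatrix = submat_for(params),
    gapOpening = abs(params$gap_open),
    gapExtension = abs(gap_extend),
    type = "local")
  list(score = BiocGenerics::score(aln),
       qstart = BiocGenerics::start(Biostrings::pattern(aln)),
       qend = BiocGenerics::end(Biostrings::pattern(aln)),
       rstart = BiocGenerics::start(Biostrings::subject(aln)),
       rend = BiocGenerics::end(Biostrings::subject(aln)),
       q_aln = as.character(Biostrings::pattern(aln)),
       r_aln = as.character(Biostrings::subject(aln)))
}

## Extract one query's result from align_batch output as a segment_hit.
batch_hit <- function(b, i, ref_len, gene = NA_character_) {
  if (b$score[i] <= 0) {
    return(structure(list(hit = FALSE, gene = gene, score = 0,
                          query_span = span0(0L, 0L), ref_span = span0(0L, 0L),
                          exo5 = NA_integer_, exo3 = NA_integer_,
                          q_aln = "", r_aln = ""),
                     class = "segment_hit"))
  }
  rs <- b$rstart[i]; re <- b$rend[i]
  structure(list(hit = TRUE, gene = gene, score = b$score[i],
                 query_span = span0(b$qstart[i] - 1L, b$qend[i]),
                 ref_span = span0(rs - 1L, re),
                 exo5 = rs - 1L, exo3 = ref_len - re,
                 q_aln = unname(b$q_aln[i]), r_aln = unname(b$r_aln[i])),
            class = "segment_hit")
}

#' @export
print.segment_hit <- function(x, ...) {
  if (!x$hit) { cat("segment_hit: no hit\n"); return(invisible(x)) }
  cat(sprintf("segment_hit %s score=%.1f query=[%d,%d) ref=[%d,%d) exo5=%d exo3=%d\n",
              x$gene %||% "?", x$score, x$query_span$start, x$query_span$end,
              x$ref_span$start, x$ref_span$end, x$exo5, x$exo3))
  invisible(x)
}

## Column map of an alignment: for each column, the 1-based query and
## reference positions (NA at gap columns). Used to truncate hits at a
## query boundary while keeping reference bookkeeping exact.
hit_colmap <- function(qstart1, rstart1, q_aln, r_aln) {
  qc <- chartokens(q_aln); rc <- chartokens(r_aln)
  qpos <- ifelse(qc != "-", cumsum(qc != "-"), NA)
  rpos <- ifelse(rc != "-", cumsum(rc != "-"), NA)
  list(qpos = ifelse(is.na(qpos), NA, qpos + qstart1 - 1L),
       rpos = ifelse(is.na(rpos), NA, rpos + rstart1 - 1L))
}

## Truncate a hit so its query span does not extend past max_qend1 (1-based
## inclusive) / before min_qstart1; reference span and exo recomputed.
truncate_hit <- function(hit, ref_len, min_qstart1 = NULL, max_qend1 = NULL) {
  cm <- hit_colmap(hit$query_span$start + 1L, hit$ref_span$start + 1L,
                   hit$q_aln, hit$r_aln)
  keep <- rep(TRUE, length(cm$qpos))
  if (!is.null(max_qend1)) keep <- keep & (is.na(cm$qpos) | cm$qpos <= max_qend1)
  if (!is.null(min_qstart1)) keep <- keep & (is.na(cm$qpos) | cm$qpos >= min_qstart1)
  ## drop leading/trailing gap-only columns left dangling by the cut
  qcols <- which(keep & !is.na(cm$qpos))
  if (!length(qcols)) {
    hit$hit <- FALSE; hit$score <- 0
    hit$query_span <- span0(0L, 0L); hit$ref_span <- span0(0L, 0L)
    hit$exo5 <- NA_integer_; hit$exo3 <- NA_integer_
    hit$q_aln <- ""; hit$r_aln <- ""
    return(hit)
  }
  first <- min(qcols); last <- max(qcols)
  cols <- first:last
  rcols <- cm$rpos[cols]
  qcols2 <- cm$qpos[cols]
  hit$query_span <- span0(min(qcols2, na.rm = TRUE) - 1L,
                          max(qcols2, na.rm = TRUE))
  hit$ref_span <- span0(min(rcols, na.rm = TRUE) - 1L,
                        max(rcols, na.rm = TRUE))
  hit$exo5 <- hit$ref_span$start
  hit$exo3 <- ref_len - hit$ref_span$end
  hit$q_aln <- substr(hit$q_aln, first, last)
  hit$r_aln <- substr(hit$r_aln, first, last)
  hit
}

## Map a 1-based reference position to the 1-based query position through
## the alignment columns (NA if the reference position is not aligned to a
## query base).
map_ref_to_query <- function(hit, rpos1) {
  cm <- hit_colmap(hit$query_span$start + 1L, hit$ref_span$start + 1L,
                   hit$q_aln, hit$r_aln)
  i <- which(!is.na(cm$rpos) & cm$rpos == rpos1 & !is.na(cm$qpos))
  if (!length(i)) NA_integer_ else cm$qpos[i[1]]
}
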