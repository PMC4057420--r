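#' Select reads supporting a candidate D segment across recombinations
#'
#' A consensus for an uncatalogued D segment is only trustworthy when the
#' supporting cDNAs arise from distinct recombinations; distinctness is
#' defined as unique (V gene, CDR3 length) pairs. Returns the supporting
#' subset only when the distinct count reaches `min_distinct`, otherwise an
#' empty subset with a shortfall report attached.
#'
#' @param annotations an `ig_annotations` data frame.
#' @param d_gene_id the D assignment shared by the candidate reads.
#' @param min_distinct minimum number of distinct recombinations
#'   (default 20).
#' @return The supporting rows (possibly empty), with attributes
#'   `distinct` (count of unique pairs) and `shortfall` (how many more
#'   distinct recombinations would be needed; 0 when satisfied).
#' @export
select_candidates <- function(annotations, d_gene_id, min_distinct = 20L) {
  known <- unique(annotations$d_gene[!is.na(annotations$d_gene)])
  if (!d_gene_id %in% known) stop("unknown d_gene_id: ", d_gene_id)
  sub <- annotations[!is.na(annotations$d_gene) &
                       annotations$d_gene == d_gene_id &
                       annotations$qc_pass, , drop = FALSE]
  pairs <- unique(paste(sub$v_gene, sub$cdr3_len))
  distinct <- length(pairs)
  if (distinct < min_distinct) {
    out <- sub[0, , drop = FALSE]
    attr(out, "distinct") <- distinct
    attr(out, "shortfall") <- min_distinct - distinct
    return(out)
  }
  attr(sub, "distinct") <- distinct
  attr(sub, "shortfall") <- 0L
  sub
}

#' Extract inter-V-J regions from annotated reads
#'
#' The read subsequence strictly between the V 3' and J 5' boundaries: the
#' raw material for deducing an uncatalogued D segment.
#'
#' @param annotations an `ig_annotations` data frame.
#' @param reads the named sequences the annotations were computed from.
#' @return Named character vector of inter-V-J sequences (empty strings
#'   dropped).
#' @export
inter_vj_regions <- function(annotations, reads) {
  if (is(reads, "DNAStringSet")) reads <- as.character(reads)
  out <- character(0)
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    if (!isTRUE(a$qc_pass)) next
    s <- reads[[a$read_id]]
    if (a$orientation == "-") s <- revcomp(s)
    if (a$j_qstart >= a$v_qend + 1L) {
      out[a$read_id] <- substr(s, a$v_qend + 1L, a$j_qstart)
    }
  }
  out[nzchar(out)]
}

IUPAC_AMBIG <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AC" = "M", "AG" = "R", "AT" = "W", "CG" = "S", "CT" = "Y", "GT" = "K",
  "ACG" = "V", "ACT" = "H", "AGT" = "D", "CGT" = "B", "ACGT" = "N")

#' Deduce a consensus segment from shared inter-V-J regions
#'
#' Default alignment construction is reference-anchored stacking: the
#' longest member anchors the columns and every other member is aligned to
#' it pairwise with the local engine; member bases are placed at anchor
#' columns (insertions relative to the anchor are ignored). An explicit
#' multiple alignment (character matrix or equal-width character vector,
#' gaps as `-`) can be supplied instead, keeping the MSA algorithm
#' pluggable.
#'
#' Per column the plurality base among non-gap entries is called (ties
#' become IUPAC ambiguity codes); a column is flagged conserved only under
#' unanimity. Columns with coverage below `min_coverage` of the members
#' are dropped from the consensus; contiguous dropped columns at the
#' flanks are reported separately as low-support extensions.
#'
#' @param sequences character vector of inter-V-J regions (>= 2).
#' @param alignment optional explicit alignment (matrix of single
#'   characters or equal-width strings).
#' @param min_coverage minimum fraction of members with a base at a column
#'   (default 0.5).
#' @param trim_unconserved_flanks additionally trim terminal columns that
#'   are not fully conserved. Junction bases flanking a shared core are
#'   essentially random across members and are never unanimous, while the
#'   core itself is (absent mutation), so this reports the maximal
#'   conserved core — the right setting when deducing a germline segment
#'   exactly. Default FALSE.
#' @param params,gap_extend alignment engine settings for the default
#'   stacking construction.
#' @return An object of class `ig_consensus`: `consensus` (string),
#'   `conserved` (logical per retained column), `coverage` (count per
#'   retained column), `n_members`, `low_support` (left/right dropped
#'   flank consensus strings).
#' @export
derive_consensus <- function(sequences, alignment = NULL, min_coverage = 0.5,
                             trim_unconserved_flanks = FALSE,
                             params = alignment_params(),
                             gap_extend = params$gap_extend_vj) {
  if (is.null(alignment)) {
    if (length(sequences) < 2L) stop("need >= 2 sequences for a consensus")
    anchor_i <- order(-nchar(sequences))[1]
    anchor <- sequences[[anchor_i]]
    W <- nchar(anchor)
    mat <- matrix("-", nrow = length(sequences), ncol = W)
    mat[anchor_i, ] <- chartokens(anchor)
    for (i in seq_along(sequences)) {
      if (i == anchor_i) next
      h <- align_local(sequences[[i]], anchor, params, gap_extend)
      if (!h$hit) next
      cm <- hit_colmap(h$query_span$start + 1L, h$ref_span$start + 1L,
                       h$q_aln, h$r_aln)
      qc <- chartokens(h$q_aln)
      ok <- !is.na(cm$rpos) & qc != "-"
      mat[i, cm$rpos[ok]] <- qc[ok]
    }
  } else {
    mat <- if (is.matrix(alignment)) alignment else {
      w <- unique(nchar(alignment))
      if (length(w) != 1L) stop("alignment rows must have equal width")
      do.call(rbind, lapply(alignment, chartokens))
    }
    if (nrow(mat) < 2L) stop("need >= 2 sequences for a consensus")
  }
  nmem <- nrow(mat)
  W <- ncol(mat)
  cov <- colSums(mat != "-")
  call_col <- function(j) {
    b <- mat[, j]; b <- b[b != "-"]
    if (!length(b)) return(c("", "FALSE"))
    tab <- table(b)
    top <- names(tab)[tab == max(tab)]
    call <- if (length(top) == 1L) top else
      IUPAC_AMBIG[[paste(sort(top), collapse = "")]]
    c(call, as.character(length(tab) == 1L))
  }
  calls <- vapply(seq_len(W), call_col, character(2))
  keep <- cov >= min_coverage * nmem & cov > 0
  ## all-gap columns never contribute
  retained <- which(keep)
  if (!length(retained)) stop("no column passes the coverage floor")
  if (trim_unconserved_flanks) {
    cons <- as.logical(calls[2, retained])
    if (!any(cons)) stop("no fully conserved column to anchor the core")
    retained <- retained[min(which(cons)):max(which(cons))]
  }
  lo <- seq_len(min(retained) - 1L)
  hi <- if (max(retained) < W) (max(retained) + 1L):W else integer()
  structure(list(
    consensus = paste(calls[1, retained], collapse = ""),
    conserved = as.logical(calls[2, retained]),
    coverage = unname(cov[retained]),
    n_members = nmem,
    low_support = list(
      left = paste(calls[1, lo[cov[lo] > 0]], collapse = ""),
      right = paste(calls[1, hi[cov[hi] > 0]], collapse = ""))),
    class = "ig_consensus")
}

#' @export
print.ig_consensus <- function(x, ...) {
  cat("Consensus over", x$n_members, "members,", nchar(x$consensus),
      "columns (", sum(x$conserved), "fully conserved )\n")
  cat(" ", x$consensus, "\n")
  star <- paste(ifelse(x$conserved, "*", " "), collapse = "")
  cat(" ", star, "\n")
  invisible(x)
}
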