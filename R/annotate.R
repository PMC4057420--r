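#' Decompose a junction into P, N and P nucleotides
#'
#' Implements the junction-calling rule for coding joints. Palindromic (P)
#' nucleotides can exist only where the donor gene end was not trimmed by
#' exonuclease activity (`exo == 0`): the reverse complement of the donor
#' end is compared base by base with the junction, moving outward from the
#' boundary, and the run of matches is called P. Everything not assigned
#' to a P run is nontemplated (N). If the left and right P claims would
#' overlap, the left (upstream) side is satisfied first and the right P is
#' truncated to the remaining bases.
#'
#' @param junction_seq bases strictly between the two assigned gene spans.
#' @param upstream_end_seq germline sequence of the upstream gene up to its
#'   aligned 3' end (only its terminal bases are used).
#' @param upstream_exo trimmed-base count at the upstream 3' end.
#' @param downstream_start_seq germline sequence of the downstream gene
#'   from its aligned 5' start (only its leading bases are used).
#' @param downstream_exo trimmed-base count at the downstream 5' end.
#' @return A list of class `junction_decomposition` with `p_left`, `n`,
#'   `p_right`; their concatenation always equals `junction_seq`.
#' @examples
#' decompose_junction("GTACCT", "TACTAC", 0, "GATC", 2)
#' # p_left "GTA" (revcomp of "TAC" read outward), n "CCT", p_right ""
#' @export
decompose_junction <- function(junction_seq, upstream_end_seq, upstream_exo,
                               downstream_start_seq, downstream_exo) {
  jl <- nchar(junction_seq)
  p_left_len <- 0L
  if (!is.na(upstream_exo) && upstream_exo == 0L && jl > 0L &&
      nzchar(upstream_end_seq)) {
    up <- chartokens(toupper(upstream_end_seq))
    jc <- chartokens(toupper(junction_seq))
    kmax <- min(jl, length(up))
    while (p_left_len < kmax &&
           jc[p_left_len + 1L] ==
             COMPLEMENT[[up[length(up) - p_left_len]]]) {
      p_left_len <- p_left_len + 1L
    }
  }
  p_right_len <- 0L
  if (!is.na(downstream_exo) && downstream_exo == 0L && jl > 0L &&
      nzchar(downstream_start_seq)) {
    dn <- chartokens(toupper(downstream_start_seq))
    jc <- chartokens(toupper(junction_seq))
    kmax <- min(jl, length(dn))
    while (p_right_len < kmax &&
           jc[jl - p_right_len] == COMPLEMENT[[dn[p_right_len + 1L]]]) {
      p_right_len <- p_right_len + 1L
    }
    ## left side satisfied first; right P truncated to remaining bases
    p_right_len <- min(p_right_len, jl - p_left_len)
  }
  structure(list(
    p_left = substr(junction_seq, 1L, p_left_len),
    n = substr(junction_seq, p_left_len + 1L, jl - p_right_len),
    p_right = if (p_right_len > 0L)
      substr(junction_seq, jl - p_right_len + 1L, jl) else ""),
    class = "junction_decomposition")
}

#' Flag reads with high exonuclease activity at the D segment
#'
#' A heavy-chain read is flagged when more than `threshold` nucleotides are
#' inferred excised from either end of its assigned D segment; such D
#' assignments rest on little remaining sequence and are unreliable.
#' Light-chain reads and reads without a D hit are never flagged.
#'
#' @param annotations an `ig_annotations` data frame (or one row of it).
#' @param threshold strict cutoff; the flag fires for counts `> threshold`.
#' @return Logical vector, one element per read.
#' @export
flag_high_exonuclease <- function(annotations, threshold = 29L) {
  d5 <- annotations$d_exo5
  d3 <- annotations$d_exo3
  out <- !is.na(d5) & !is.na(d3) & (d5 > threshold | d3 > threshold)
  out[is.na(annotations$d_gene)] <- FALSE
  out
}

## Pick per-read best gene: highest score, then longest aligned query
## length, then lexicographically smallest gene id.
pick_best <- function(scores, qlens, ids) {
  ord <- order(-scores, -qlens, ids)
  ord[1]
}

#' Annotate a cDNA repertoire with germline segments and junction calls
#'
#' The pipeline stage that turns reads into junction decompositions.
#' For each read: (1) best-scoring V and J are chosen over all germline
#' V/J of the chain using the V/J gap-extension penalty; (2) any V-J
#' overlap on the read is resolved to the midpoint (upstream segment keeps
#' the extra base of an odd overlap) with exonuclease counts recomputed
#' from the truncated alignments; (3) for heavy chains the read
#' subsequence strictly between the V 3' and J 5' boundaries is queried
#' against all D genes with the marginal D gap-extension penalty, best
#' score wins subject to a minimum-evidence floor; (4) VD and DJ (or VJ)
#' junctions are decomposed into P/N/P; (5) the CDR3 span is delimited by
#' the reference anchors when the alignments cover them.
#'
#' Reads with no positive-scoring V hit are retried once as reverse
#' complements. Reads lacking a V or J hit fail QC with a reason.
#'
#' @param reads named character vector or `DNAStringSet` of sense-strand
#'   cDNAs.
#' @param refs an `ig_reference_set` covering the chain.
#' @param chain `"heavy"`, `"lambda"` or `"kappa"`.
#' @param params an [alignment_params()].
#' @param d_min_score minimum D score accepted (worth of consecutive
#'   matches; default 5).
#' @param v_min_score V score below which a read is considered unmatched
#'   and retried as a reverse complement (a local alignment almost always
#'   finds a few chance matches, so "no V hit" must mean "no convincing V
#'   hit"; default 20).
#' @param high_exo_threshold passed to [flag_high_exonuclease()].
#' @param try_revcomp retry weakly matched reads as reverse complements,
#'   keeping the better orientation.
#' @return An `ig_annotations` data frame, one row per read, holding gene
#'   ids, scores, 0-based half-open query/reference spans, per-end
#'   exonuclease counts, P/N/P strings per junction, CDR3 span/length,
#'   `high_exo`, `qc_pass` and `qc_reason`.
#' @export
annotate_repertoire <- function(reads, refs, chain = c("heavy", "lambda", "kappa"),
                                params = alignment_params(), d_min_score = 5,
                                v_min_score = 20, high_exo_threshold = 29L,
                                try_revcomp = TRUE) {
  chain <- match.arg(chain)
  stopifnot(inherits(refs, "ig_reference_set"))
  if (is(reads, "DNAStringSet")) reads <- as.character(reads)
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  vrefs <- subset_segments(refs, chain, "V")
  jrefs <- subset_segments(refs, chain, "J")
  drefs <- if (chain == "heavy") subset_segments(refs, chain, "D") else
    refs[0, , drop = FALSE]
  if (!nrow(vrefs) || !nrow(jrefs))
    stop("reference set lacks V or J segments for chain ", chain)

  n <- length(reads)
  reads <- toupper(reads)
  orientation <- rep("+", n)

  best_stage <- function(seqs, generefs, gap_extend) {
    ## returns list of per-read best segment_hit (or no-hit)
    nonempty <- nzchar(seqs)
    batches <- lapply(seq_len(nrow(generefs)), function(g) {
      if (!any(nonempty)) return(NULL)
      b <- list(score = rep(0, length(seqs)), qstart = NA, qend = NA,
                rstart = NA, rend = NA, q_aln = NA, r_aln = NA)
      sub <- align_batch(seqs[nonempty], generefs$sequence[g], params, gap_extend)
      idx <- which(nonempty)
      for (f in names(sub)) b[[f]] <- replace(rep(if (f == "score") 0 else NA,
                                                  length(seqs)), idx, sub[[f]])
      b
    })
    lapply(seq_along(seqs), function(i) {
      if (!nonempty[i]) return(batch_hit(list(score = 0), 1L, 0L))
      scores <- vapply(batches, function(b) b$score[i], 0)
      qlens <- vapply(batches, function(b)
        if (b$score[i] > 0) b$qend[i] - b$qstart[i] + 1L else 0L, 0)
      g <- pick_best(scores, qlens, generefs$id)
      batch_hit(batches[[g]], i, generefs$length[g], generefs$id[g])
    })
  }

  v_hits <- best_stage(reads, vrefs, params$gap_extend_vj)
  if (try_revcomp) {
    flip <- which(vapply(v_hits, function(h) !h$hit || h$score < v_min_score,
                         TRUE))
    if (length(flip)) {
      rc <- revcomp(reads[flip])
      rc_hits <- best_stage(rc, vrefs, params$gap_extend_vj)
      for (k in seq_along(flip)) {
        i <- flip[k]
        if (rc_hits[[k]]$hit && rc_hits[[k]]$score > v_hits[[i]]$score) {
          reads[i] <- rc[k]
          v_hits[[i]] <- rc_hits[[k]]
          orientation[i] <- "-"
        }
      }
    }
  }
  j_hits <- best_stage(reads, jrefs, params$gap_extend_vj)

  ## D stage, batched across reads: resolve V-J boundaries first, extract
  ## the inter-V-J windows, then align every window to each D gene in one
  ## vectorized call per gene.
  d_hits <- vector("list", n)
  if (chain == "heavy" && nrow(drefs)) {
    pre <- lapply(seq_len(n), function(i)
      resolve_vj(reads[[i]], v_hits[[i]], j_hits[[i]], vrefs, jrefs))
    windows <- vapply(pre, function(p) p$window %||% "", "")
    dd <- best_stage(windows, drefs, params$gap_extend_d)
    for (i in seq_len(n)) {
      h <- dd[[i]]
      if (h$hit && h$score >= d_min_score) {
        off <- pre[[i]]$v_qend1 %||% 0L
        h$query_span <- span0(h$query_span$start + off, h$query_span$end + off)
        d_hits[[i]] <- h
      }
      v_hits[[i]] <- pre[[i]]$vh %||% v_hits[[i]]
      j_hits[[i]] <- pre[[i]]$jh %||% j_hits[[i]]
    }
  } else if (chain == "heavy") {
    stop("reference set lacks D segments for heavy chain")
  } else {
    pre <- lapply(seq_len(n), function(i)
      resolve_vj(reads[[i]], v_hits[[i]], j_hits[[i]], vrefs, jrefs))
    for (i in seq_len(n)) {
      v_hits[[i]] <- pre[[i]]$vh %||% v_hits[[i]]
      j_hits[[i]] <- pre[[i]]$jh %||% j_hits[[i]]
    }
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- annotate_one(names(reads)[i], reads[[i]], chain,
                              v_hits[[i]], j_hits[[i]], d_hits[[i]],
                              pre[[i]], vrefs, jrefs, drefs,
                              params, orientation[i])
  }
  ann <- do.call(rbind, rows)
  ann$high_exo <- flag_high_exonuclease(ann, high_exo_threshold)
  rownames(ann) <- ann$read_id
  structure(ann, class = c("ig_annotations", "data.frame"))
}

## Order/overlap resolution for the V and J hits of one read; extracts the
## inter-V-J window queried against the D database.
resolve_vj <- function(seq, vh, jh, vrefs, jrefs) {
  if (!vh$hit) return(list(status = "no V hit"))
  if (!jh$hit) return(list(status = "no J hit", vh = vh))
  vlen <- get_segment(vrefs, vh$gene)$length
  jlen <- get_segment(jrefs, jh$gene)$length
  if (jh$query_span$end <= vh$query_span$start)
    return(list(status = "J upstream of V", vh = vh))
  v_qend1 <- vh$query_span$end          # 1-based inclusive end
  j_qstart1 <- jh$query_span$start + 1L # 1-based start
  if (v_qend1 >= j_qstart1) {
    ov <- v_qend1 - j_qstart1 + 1L
    new_v_end <- j_qstart1 + as.integer(ceiling(ov / 2)) - 1L  # upstream keeps extra base
    vh <- truncate_hit(vh, vlen, max_qend1 = new_v_end)
    jh <- truncate_hit(jh, jlen, min_qstart1 = new_v_end + 1L)
    if (!vh$hit) return(list(status = "V lost in overlap resolution"))
    if (!jh$hit) return(list(status = "J lost in overlap resolution", vh = vh))
    v_qend1 <- vh$query_span$end
    j_qstart1 <- jh$query_span$start + 1L
  }
  window <- if (j_qstart1 - 1L >= v_qend1 + 1L)
    substr(seq, v_qend1 + 1L, j_qstart1 - 1L) else ""
  list(status = "ok", vh = vh, jh = jh,
       v_qend1 = v_qend1, j_qstart1 = j_qstart1, window = window)
}

annotate_one <- function(read_id, seq, chain, vh, jh, dh, pre,
                         vrefs, jrefs, drefs, params, orientation) {
  na_row <- function(reason) {
    data.frame(read_id = read_id, chain = chain, orientation = orientation,
               v_gene = NA_character_, v_score = NA_real_,
               v_qstart = NA_integer_, v_qend = NA_integer_,
               v_rstart = NA_integer_, v_rend = NA_integer_,
               v_exo3 = NA_integer_,
               d_gene = NA_character_, d_score = NA_real_,
               d_qstart = NA_integer_, d_qend = NA_integer_,
               d_rstart = NA_integer_, d_rend = NA_integer_,
               d_exo5 = NA_integer_, d_exo3 = NA_integer_,
               j_gene = NA_character_, j_score = NA_real_,
               j_qstart = NA_integer_, j_qend = NA_integer_,
               j_rstart = NA_integer_, j_rend = NA_integer_,
               j_exo5 = NA_integer_,
               vd_p_left = NA_character_, vd_n = NA_character_,
               vd_p_right = NA_character_,
               dj_p_left = NA_character_, dj_n = NA_character_,
               dj_p_right = NA_character_,
               cdr3_start = NA_integer_, cdr3_end = NA_integer_,
               cdr3_len = NA_integer_,
               no_d = NA, high_exo = FALSE,
               qc_pass = FALSE, qc_reason = reason,
               stringsAsFactors = FALSE)
  }
  if (pre$status != "ok") {
    r <- na_row(pre$status)
    if (!is.null(pre$vh) || vh$hit) r <- fill_v(r, pre$vh %||% vh, vrefs)
    return(r)
  }
  v_qend1 <- pre$v_qend1
  j_qstart1 <- pre$j_qstart1
  window <- pre$window

  vseq <- get_segment(vrefs, vh$gene)$sequence
  jseq <- get_segment(jrefs, jh$gene)$sequence

  no_d <- NA
  vd <- dj <- NULL
  if (chain == "heavy") {
    no_d <- is.null(dh)
    dseq <- if (!no_d) get_segment(drefs, dh$gene)$sequence else ""
    if (!no_d) {
      d_qstart1 <- dh$query_span$start + 1L
      d_qend1 <- dh$query_span$end
      vd_seq <- if (d_qstart1 - 1L >= v_qend1 + 1L)
        substr(seq, v_qend1 + 1L, d_qstart1 - 1L) else ""
      dj_seq <- if (j_qstart1 - 1L >= d_qend1 + 1L)
        substr(seq, d_qend1 + 1L, j_qstart1 - 1L) else ""
      vd <- decompose_junction(vd_seq,
                               substr(vseq, 1L, vh$ref_span$end), vh$exo3,
                               substr(dseq, dh$ref_span$start + 1L, nchar(dseq)),
                               dh$exo5)
      dj <- decompose_junction(dj_seq,
                               substr(dseq, 1L, dh$ref_span$end), dh$exo3,
                               substr(jseq, jh$ref_span$start + 1L, nchar(jseq)),
                               jh$exo5)
    } else {
      ## whole V-to-J insert reported as one junction (flagged via no_d)
      vd <- decompose_junction(window,
                               substr(vseq, 1L, vh$ref_span$end), vh$exo3,
                               substr(jseq, jh$ref_span$start + 1L, nchar(jseq)),
                               jh$exo5)
      dj <- NULL
    }
  } else {
    vj_seq <- if (j_qstart1 - 1L >= v_qend1 + 1L)
      substr(seq, v_qend1 + 1L, j_qstart1 - 1L) else ""
    vd <- decompose_junction(vj_seq,
                             substr(vseq, 1L, vh$ref_span$end), vh$exo3,
                             substr(jseq, jh$ref_span$start + 1L, nchar(jseq)),
                             jh$exo5)
    dj <- NULL
  }

  ## CDR3 delimitation from anchors (0-based offsets in the references)
  v_anchor <- get_segment(vrefs, vh$gene)$anchor
  j_anchor <- get_segment(jrefs, jh$gene)$anchor
  cdr3_start <- cdr3_end <- NA_integer_
  if (!is.na(v_anchor) && !is.na(j_anchor)) {
    qs <- map_ref_to_query(vh, v_anchor + 1L)
    qe <- map_ref_to_query(jh, j_anchor + 1L)
    if (!is.na(qs) && !is.na(qe) && qe > qs) {
      cdr3_start <- qs - 1L       # 0-based start (first CDR3 base)
      cdr3_end <- qe - 1L         # 0-based half-open end (base before Trp)
    }
  }

  data.frame(read_id = read_id, chain = chain, orientation = orientation,
             v_gene = vh$gene, v_score = vh$score,
             v_qstart = vh$query_span$start, v_qend = vh$query_span$end,
             v_rstart = vh$ref_span$start, v_rend = vh$ref_span$end,
             v_exo3 = vh$exo3,
             d_gene = if (!is.null(dh)) dh$gene else NA_character_,
             d_score = if (!is.null(dh)) dh$score else NA_real_,
             d_qstart = if (!is.null(dh)) dh$query_span$start else NA_integer_,
             d_qend = if (!is.null(dh)) dh$query_span$end else NA_integer_,
             d_rstart = if (!is.null(dh)) dh$ref_span$start else NA_integer_,
             d_rend = if (!is.null(dh)) dh$ref_span$end else NA_integer_,
             d_exo5 = if (!is.null(dh)) dh$exo5 else NA_integer_,
             d_exo3 = if (!is.null(dh)) dh$exo3 else NA_integer_,
             j_gene = jh$gene, j_score = jh$score,
             j_qstart = jh$query_span$start, j_qend = jh$query_span$end,
             j_rstart = jh$ref_span$start, j_rend = jh$ref_span$end,
             j_exo5 = jh$exo5,
             vd_p_left = vd$p_left, vd_n = vd$n, vd_p_right = vd$p_right,
             dj_p_left = if (!is.null(dj)) dj$p_left else NA_character_,
             dj_n = if (!is.null(dj)) dj$n else NA_character_,
             dj_p_right = if (!is.null(dj)) dj$p_right else NA_character_,
             cdr3_start = cdr3_start, cdr3_end = cdr3_end,
             cdr3_len = if (!is.na(cdr3_start)) cdr3_end - cdr3_start else NA_integer_,
             no_d = no_d, high_exo = FALSE,
             qc_pass = TRUE, qc_reason = "",
             stringsAsFactors = FALSE)
}

fill_v <- function(row, vh, vrefs) {
  row$v_gene <- vh$gene; row$v_score <- vh$score
  row$v_qstart <- vh$query_span$start; row$v_qend <- vh$query_span$end
  row$v_rstart <- vh$ref_span$start; row$v_rend <- vh$ref_span$end
  row$v_exo3 <- vh$exo3
  row
}

#' Annotate a single read
#'
#' Convenience wrapper over [annotate_repertoire()].
#'
#' @inheritParams annotate_repertoire
#' @param read one sequence (character).
#' @param read_id id used in the output row.
#' @return One-row `ig_annotations` data frame.
#' @export
annotate_read <- function(read, refs, chain = c("heavy", "lambda", "kappa"),
                          params = alignment_params(), d_min_score = 5,
                          read_id = "read1", ...) {
  annotate_repertoire(setNames(read, read_id), refs, chain, params,
                      d_min_score, ...)
}

#' Retain reads whose alignments cover the entire CDR3 region
#'
#' A read is retained when its V alignment reaches the V CDR3 anchor (the
#' first base after the conserved-Cys codon) and its J alignment covers the
#' whole conserved Trp/Phe codon at the J anchor. Reads failing QC are
#' excluded as well.
#'
#' @param annotations an `ig_annotations` data frame.
#' @param refs the `ig_reference_set` used for annotation (anchors must be
#'   present for every assigned V and J gene).
#' @return The retained subset, with an attribute `excluded` giving read
#'   ids and reasons.
#' @export
filter_covering_cdr3 <- function(annotations, refs) {
  stopifnot(inherits(refs, "ig_reference_set"))
  keep <- logical(nrow(annotations))
  reason <- character(nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    if (!isTRUE(a$qc_pass)) { reason[i] <- a$qc_reason; next }
    va <- get_segment(refs, a$v_gene)$anchor
    ja <- get_segment(refs, a$j_gene)$anchor
    if (is.na(va)) stop("reference gene ", a$v_gene, " has no cdr3_anchor")
    if (is.na(ja)) stop("reference gene ", a$j_gene, " has no cdr3_anchor")
    v_ok <- a$v_rstart <= va && a$v_rend >= va
    j_ok <- a$j_rstart <= ja && a$j_rend >= ja + 3L
    if (v_ok && j_ok) keep[i] <- TRUE
    else reason[i] <- if (!v_ok) "V alignment does not reach CDR3 anchor"
                      else "J alignment does not cover conserved codon"
  }
  out <- annotations[keep, , drop = FALSE]
  attr(out, "excluded") <- data.frame(read_id = annotations$read_id[!keep],
                                      reason = reason[!keep],
                                      stringsAsFactors = FALSE)
  out
}

#' @export
print.ig_annotations <- function(x, ...) {
  cat("ig_annotations:", nrow(x), "reads;",
      sum(x$qc_pass), "passing QC\n")
  if (any(!is.na(x$d_gene)))
    cat("  D assigned:", sum(!is.na(x$d_gene)),
        " high-exo flagged:", sum(x$high_exo), "\n")
  invisible(x)
}

#' Write an annotation table to TSV
#'
#' @param annotations an `ig_annotations` data frame.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_annotations <- function(annotations, path) {
  write.table(annotations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
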