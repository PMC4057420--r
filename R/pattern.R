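#' Parse a PROSITE-style fuzzy nucleotide pattern
#'
#' Grammar: literal bases `A C G T`; `N` a fixed wildcard position;
#' `[XY]` a fixed position allowing any listed base; `N(a)` a run of `a`
#' wildcard positions; `N(a,b)` a variable-length gap of `a` to `b`
#' arbitrary bases. Whitespace is ignored. Variable gaps match any bases
#' and never contribute mismatches; the mismatch budget applies globally
#' across all fixed positions (fuzznuc semantics).
#'
#' The pattern used to mine diversity-segment loci places a candidate D
#' gene in the central variable gap between two recombination-signal
#' heptamers; the central gap is taken to be the variable gap with the
#' largest maximum length (override with `core_gap`).
#'
#' @param pattern_string the pattern.
#' @param max_mismatch global mismatch budget over fixed positions.
#' @param core_gap index (among variable gaps, in pattern order) of the gap
#'   holding the candidate segment; default picks the widest gap.
#' @return An object of class `fuzzy_pattern`: a list of elements, each
#'   either `list(type = "fixed", allowed = <character vector>)` or
#'   `list(type = "gap", min, max)`, plus the budget and core-gap index.
#' @examples
#' p <- parse_pattern("GGTTTTTGTN(11,13)CACNGTGN(6,160)CACNGTGN(11,13)ACAAAAACC",
#'                    max_mismatch = 4)
#' length(p$elements)
#' @export
parse_pattern <- function(pattern_string, max_mismatch = 0L, core_gap = NULL) {
  s <- gsub("\\s+", "", pattern_string)
  chars <- chartokens(s)
  elements <- list()
  i <- 1L
  n <- length(chars)
  perr <- function(msg, at) stop("pattern parse error at offset ", at - 1L,
                                 " (0-based): ", msg)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("A", "C", "G", "T")) {
      elements[[length(elements) + 1L]] <- list(type = "fixed", allowed = ch)
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      cls <- character()
      while (j <= n && chars[j] != "]") {
        if (!chars[j] %in% c("A", "C", "G", "T"))
          perr(paste0("invalid base '", chars[j], "' in class"), j)
        cls <- c(cls, chars[j]); j <- j + 1L
      }
      if (j > n) perr("unbalanced '['", i)
      if (length(cls) == 0L) perr("empty class", i)
      elements[[length(elements) + 1L]] <- list(type = "fixed",
                                                allowed = unique(cls))
      i <- j + 1L
    } else if (ch == "N") {
      if (i < n && chars[i + 1L] == "(") {
        j <- i + 2L
        num <- character()
        while (j <= n && chars[j] != ")") { num <- c(num, chars[j]); j <- j + 1L }
        if (j > n) perr("unbalanced '('", i + 1L)
        spec <- paste(num, collapse = "")
        if (!grepl("^[0-9]+(,[0-9]+)?$", spec)) perr("bad repeat spec", i + 2L)
        bounds <- as.integer(strsplit(spec, ",", fixed = TRUE)[[1]])
        if (length(bounds) == 1L) {
          # N(a): fixed-length run of wildcard positions
          for (k in seq_len(bounds)) {
            elements[[length(elements) + 1L]] <-
              list(type = "fixed", allowed = c("A", "C", "G", "T"))
          }
        } else {
          if (bounds[1] > bounds[2])
            perr(sprintf("inverted gap bounds N(%d,%d)", bounds[1], bounds[2]),
                 i + 2L)
          elements[[length(elements) + 1L]] <-
            list(type = "gap", min = bounds[1], max = bounds[2])
        }
        i <- j + 1L
      } else {
        elements[[length(elements) + 1L]] <-
          list(type = "fixed", allowed = c("A", "C", "G", "T"))
        i <- i + 1L
      }
    } else if (ch == "]") {
      perr("unbalanced ']'", i)
    } else {
      perr(paste0("unexpected character '", ch, "'"), i)
    }
  }
  types <- vapply(elements, `[[`, "", "type")
  n_fixed <- sum(types == "fixed")
  if (n_fixed == 0L) stop("pattern must contain at least one fixed position")
  if (types[1] == "gap" || types[length(types)] == "gap")
    stop("pattern must start and end with fixed positions")
  if (any(types[-1] == "gap" & types[-length(types)] == "gap"))
    stop("adjacent variable gaps are not supported")
  if (max_mismatch < 0L || max_mismatch > n_fixed)
    stop("mismatch budget must be in [0, number of fixed positions]")
  gap_idx <- which(types == "gap")
  core <- if (is.null(core_gap)) {
    if (length(gap_idx)) {
      widths <- vapply(elements[gap_idx], `[[`, 0L, "max")
      which.max(widths)  # index among gaps
    } else NA_integer_
  } else {
    if (core_gap < 1L || core_gap > length(gap_idx))
      stop("core_gap out of range")
    as.integer(core_gap)
  }
  structure(list(elements = elements, mismatch_budget = as.integer(max_mismatch),
                 n_fixed = n_fixed, core_gap = core),
            class = "fuzzy_pattern")
}

#' @export
print.fuzzy_pattern <- function(x, ...) {
  types <- vapply(x$elements, `[[`, "", "type")
  cat("Fuzzy pattern:", x$n_fixed, "fixed positions,",
      sum(types == "gap"), "variable gaps, budget", x$mismatch_budget, "\n")
  invisible(x)
}

## Collapse a fuzzy_pattern into alternating fixed blocks and gaps.
## Returns list(blocks = list of list(allowed = list per position),
##              gaps = list of c(min,max) between consecutive blocks,
##              core_gap = index into gaps or NA)
pattern_blocks <- function(pattern) {
  blocks <- list(); gaps <- list()
  cur <- list()
  for (el in pattern$elements) {
    if (el$type == "fixed") {
      cur[[length(cur) + 1L]] <- el$allowed
    } else {
      blocks[[length(blocks) + 1L]] <- cur
      cur <- list()
      gaps[[length(gaps) + 1L]] <- c(el$min, el$max)
    }
  }
  blocks[[length(blocks) + 1L]] <- cur
  list(blocks = blocks, gaps = gaps, core_gap = pattern$core_gap)
}

## Mismatch count of block `allowed` (list of allowed-base vectors) at every
## start position of subject char vector. Positions beyond the end get Inf.
block_mismatches <- function(subj_chars, allowed) {
  S <- length(subj_chars)
  L <- length(allowed)
  if (S < L) return(rep(Inf, max(S, 1L)))
  n_start <- S - L + 1L
  mism <- rep(0, n_start)
  for (j in seq_len(L)) {
    ok <- subj_chars[j:(j + n_start - 1L)] %in% allowed[[j]]
    mism <- mism + !ok
  }
  c(mism, rep(Inf, S - n_start))
}

scan_one_strand <- function(seq_string, pattern) {
  pb <- pattern_blocks(pattern)
  blocks <- pb$blocks
  gaps <- pb$gaps
  budget <- pattern$mismatch_budget
  subj <- chartokens(toupper(seq_string))
  S <- length(subj)
  lens <- vapply(blocks, length, 0L)
  min_tail <- rev(cumsum(rev(lens + c(vapply(gaps, `[`, 0, 1), 0))))
  if (S < min_tail[1]) return(list())

  bm <- lapply(blocks, function(b) block_mismatches(subj, b))
  nb <- length(blocks)

  hits <- list()
  ## DFS over block placements with budget pruning
  recurse <- function(bi, pos, mism, starts) {
    m <- bm[[bi]][pos]
    if (is.na(m) || is.infinite(m) || mism + m > budget) return()
    mism <- mism + m
    starts <- c(starts, pos)
    if (bi == nb) {
      hits[[length(hits) + 1L]] <<- list(starts = starts, mism = mism)
      return()
    }
    ## remaining minimum length after this block must fit
    nxt_min <- pos + lens[bi] + gaps[[bi]][1]
    nxt_max <- pos + lens[bi] + gaps[[bi]][2]
    if (nxt_min > S) return()
    for (np in nxt_min:min(nxt_max, S)) recurse(bi + 1L, np, mism, starts)
  }
  for (p in seq_len(S - min_tail[1] + 1L)) recurse(1L, p, 0, integer())
  if (!length(hits)) return(list())

  ## group by (start, end); keep combo minimizing mismatches, then
  ## lexicographically smallest block starts (deterministic)
  df <- do.call(rbind, lapply(hits, function(h) {
    st <- h$starts
    end <- st[nb] + lens[nb] - 1L
    data.frame(start = st[1], end = end, mism = h$mism,
               key = paste(st, collapse = ","), stringsAsFactors = FALSE)
  }))
  starts_list <- lapply(hits, `[[`, "starts")
  grp <- paste(df$start, df$end)
  keep <- tapply(seq_len(nrow(df)), grp, function(ix) {
    ix <- ix[df$mism[ix] == min(df$mism[ix])]
    ix[order(df$key[ix])][1]
  })
  keep <- sort(unlist(keep, use.names = FALSE))

  res <- lapply(keep, function(i) {
    st <- starts_list[[i]]
    core <- if (!is.na(pb$core_gap)) {
      g <- pb$core_gap
      c(st[g] + lens[g], st[g + 1L] - 1L)  # 1-based inclusive
    } else c(NA_integer_, NA_integer_)
    blk_spans <- cbind(st, st + lens - 1L)
    list(start = st[1], end = st[nb] + lens[nb] - 1L, mism = df$mism[i],
         core = core, blocks = blk_spans)
  })
  res
}

empty_match_df <- function() {
  data.frame(contig = character(), strand = character(),
             start = integer(), end = integer(), mismatches = integer(),
             core_start = integer(), core_end = integer(),
             core_seq = character(), stringsAsFactors = FALSE)
}

#' Scan sequences for fuzzy-pattern matches on one or both strands
#'
#' Reports every placement whose total mismatch count over fixed positions
#' is within the pattern's budget. Variable gaps match any bases. A subject
#' base `N` satisfies no fixed position (it always counts as a mismatch).
#' Overlapping matches are all reported; where several gap-length
#' combinations give the same (start, end), the one minimizing mismatches
#' is reported. Matches are sorted by (contig, start).
#'
#' Minus-strand matches are found by scanning the reverse complement;
#' coordinates are reported on the forward strand (0-based, half-open), and
#' `core_seq` always holds forward-strand bases.
#'
#' @param subject a named character vector, `DNAStringSet`, or single
#'   string of A/C/G/T/N bases.
#' @param pattern a [parse_pattern()] result.
#' @param strands subset of `c("+", "-")`.
#' @return A data frame with columns `contig`, `strand`, `start`, `end`,
#'   `mismatches`, `core_start`, `core_end`, `core_seq`.
#' @export
scan_fuzzy <- function(subject, pattern, strands = c("+", "-")) {
  stopifnot(inherits(pattern, "fuzzy_pattern"))
  if (!all(strands %in% c("+", "-"))) stop("strands must be subset of +, -")
  if (is(subject, "DNAStringSet")) subject <- as.character(subject)
  if (is.null(names(subject)))
    names(subject) <- if (length(subject) == 1L) "seq1" else
      paste0("seq", seq_along(subject))
  out <- empty_match_df()
  for (ci in seq_along(subject)) {
    s <- toupper(subject[[ci]])
    if (!nzchar(s)) next
    if (grepl("[^ACGTN]", s)) stop("subject must be over A,C,G,T,N")
    S <- nchar(s)
    for (str in strands) {
      scanned <- if (str == "+") s else revcomp(s)
      ms <- scan_one_strand(scanned, pattern)
      for (m in ms) {
        if (str == "+") {
          st0 <- m$start - 1L; en0 <- m$end
          cs0 <- m$core[1] - 1L; ce0 <- m$core[2]
        } else {
          st0 <- S - m$end; en0 <- S - m$start + 1L
          cs0 <- S - m$core[2]; ce0 <- S - m$core[1] + 1L
        }
        core_seq <- if (!is.na(cs0) && ce0 > cs0)
          substr(s, cs0 + 1L, ce0) else ""
        out <- rbind(out, data.frame(
          contig = names(subject)[ci], strand = str,
          start = st0, end = en0, mismatches = as.integer(m$mism),
          core_start = cs0, core_end = ce0, core_seq = core_seq,
          stringsAsFactors = FALSE))
      }
    }
  }
  out <- out[order(out$contig, out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract candidate D segments from RSS-motif matches
#'
#' One draft germline segment per match: the sequence between the paired
#' heptamers (reverse-complemented for minus-strand matches so candidates
#' read in coding orientation), auto-numbered ids, class `D`. Optionally
#' deduplicated by identical sequence.
#'
#' @param matches a [scan_fuzzy()] result.
#' @param dedup collapse drafts with identical sequence (default TRUE).
#' @param chain chain label for the drafts (default `"heavy"`).
#' @param prefix id prefix for auto-numbering.
#' @return An `ig_reference_set` of D-segment drafts (empty data frame if
#'   no matches).
#' @export
extract_d_candidates <- function(matches, dedup = TRUE, chain = "heavy",
                                 prefix = "Dcand") {
  keep <- !is.na(matches$core_start) & matches$core_end > matches$core_start
  matches <- matches[keep, , drop = FALSE]
  if (!nrow(matches)) return(NULL)
  seqs <- ifelse(matches$strand == "+", matches$core_seq,
                 revcomp(matches$core_seq))
  note <- sprintf("RSS scan %s:%d-%d(%s) mism=%d", matches$contig,
                  matches$core_start, matches$core_end, matches$strand,
                  matches$mismatches)
  if (dedup) {
    first <- !duplicated(seqs)
    seqs <- seqs[first]; note <- note[first]
  }
  reference_set(id = sprintf("%s%03d", prefix, seq_along(seqs)),
                chain = chain, class = "D", sequence = seqs,
                anchor = NA_integer_, note = note)
}
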