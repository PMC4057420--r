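# Independent oracles, deliberately written as plain dynamic programs /
# exhaustive enumeration so they share no code path with the package.

# Gotoh local alignment, score only. A gap of length L costs
# open + L * ext (open, ext passed as negative scores).
sw_oracle <- function(q, r, match = 1, mismatch = -1, open = -4, ext = -5) {
  qc <- strsplit(q, "")[[1]]
  rc <- strsplit(r, "")[[1]]
  n <- length(qc); m <- length(rc)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)     # best ending in a substitution column
  X <- matrix(NEG, n + 1, m + 1)   # best ending with gap in reference
  Y <- matrix(NEG, n + 1, m + 1)   # best ending with gap in query
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (qc[i] == rc[j]) match else mismatch
      M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + open + ext, X[i, j + 1] + ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + open + ext, Y[i + 1, j] + ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Exhaustive fuzzy-pattern scan on the forward strand: enumerate every
# start position and every combination of variable gap lengths, lay out
# the fixed positions, count mismatches. Returns the distinct
# (start0, end0) pairs with their minimum mismatch count, sorted.
scan_oracle <- function(subject, pattern) {
  subj <- strsplit(toupper(subject), "")[[1]]
  S <- length(subj)
  els <- pattern$elements
  gap_idx <- which(vapply(els, function(e) e$type == "gap", TRUE))
  gap_ranges <- lapply(els[gap_idx], function(e) e$min:e$max)
  combos <- if (length(gap_ranges)) expand.grid(gap_ranges) else
    data.frame(row.names = 1)
  out <- list()
  for (ci in seq_len(nrow(combos))) {
    gaps <- as.integer(combos[ci, ])
    # walk the elements once to get offsets of fixed positions
    offs <- integer(0); allowed <- list(); pos <- 0L; g <- 0L
    for (e in els) {
      if (e$type == "gap") { g <- g + 1L; pos <- pos + gaps[g] }
      else { offs <- c(offs, pos); allowed <- c(allowed, list(e$allowed)); pos <- pos + 1L }
    }
    span <- pos
    if (span > S) next
    for (st in 1:(S - span + 1L)) {
      ch <- subj[st + offs]
      mism <- sum(!mapply(function(c, a) c %in% a, ch, allowed))
      if (mism <= pattern$mismatch_budget) {
        key <- paste(st - 1L, st - 1L + span)
        if (is.null(out[[key]]) || out[[key]] > mism) out[[key]] <- mism
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      mismatches = integer()))
  }
  parts <- do.call(rbind, strsplit(names(out), " "))
  df <- data.frame(start = as.integer(parts[, 1]),
                   end = as.integer(parts[, 2]),
                   mismatches = as.integer(unlist(out)))
  df[order(df$start, df$end), , drop = FALSE]
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
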