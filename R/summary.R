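#' Cross-tabulate gene-segment usage
#'
#' Exact (V, D, J) cross-tabulation for heavy chains, (V, J) for light
#' chains. Rows (V genes) are ordered by descending total then id;
#' marginals and the grand total are carried along. Reads without an
#' assigned D are tabulated under the level `"(none)"`.
#'
#' @param x an `ig_annotations` data frame (QC-passing rows are used), or a
#'   counts data frame with columns `v_gene`, `j_gene`, optional `d_gene`,
#'   and `count` (e.g. a transcribed published table).
#' @return An object of class `ig_usage`: list with `counts` (tidy data
#'   frame), `chain_type` (`"VDJ"` or `"VJ"`), per-gene marginals and
#'   `total`.
#' @export
usage_table <- function(x) {
  if (inherits(x, "ig_annotations")) {
    x <- x[x$qc_pass, , drop = FALSE]
    if (!nrow(x)) {
      return(structure(list(counts = data.frame(), chain_type = "VDJ",
                            v_totals = integer(), d_totals = integer(),
                            j_totals = integer(), total = 0L),
                       class = "ig_usage"))
    }
    has_d <- "d_gene" %in% names(x) && any(!is.na(x$d_gene))
    df <- data.frame(v_gene = x$v_gene,
                     j_gene = x$j_gene, stringsAsFactors = FALSE)
    if (unique(x$chain)[1] == "heavy") {
      df$d_gene <- ifelse(is.na(x$d_gene), "(none)", x$d_gene)
    }
    agg <- if ("d_gene" %in% names(df))
      stats::aggregate(list(count = rep(1L, nrow(df))),
                       df[c("v_gene", "d_gene", "j_gene")], sum)
    else stats::aggregate(list(count = rep(1L, nrow(df))),
                          df[c("v_gene", "j_gene")], sum)
  } else {
    agg <- as.data.frame(x, stringsAsFactors = FALSE)
    stopifnot(all(c("v_gene", "j_gene", "count") %in% names(agg)))
    if (any(agg$count < 0)) stop("counts must be >= 0")
  }
  chain_type <- if ("d_gene" %in% names(agg)) "VDJ" else "VJ"
  margin <- function(by) {
    m <- tapply(agg$count, by, sum)
    setNames(as.integer(m), names(m))
  }
  v_totals <- margin(agg$v_gene)
  ## deterministic: descending total, ties by id
  v_totals <- v_totals[order(-v_totals, names(v_totals))]
  j_totals <- margin(agg$j_gene)
  d_totals <- if (chain_type == "VDJ") {
    d <- margin(agg$d_gene)
    d[order(-d, names(d))]
  } else integer()
  ord <- if (chain_type == "VDJ")
    order(match(agg$v_gene, names(v_totals)), agg$d_gene, agg$j_gene)
  else order(match(agg$v_gene, names(v_totals)), agg$j_gene)
  agg <- agg[ord, , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(counts = agg, chain_type = chain_type,
                 v_totals = v_totals, d_totals = d_totals,
                 j_totals = j_totals, total = sum(agg$count)),
            class = "ig_usage")
}

#' @export
print.ig_usage <- function(x, ...) {
  cat("Gene usage (", x$chain_type, "): ", x$total, " reads, ",
      length(x$v_totals), " V genes\n", sep = "")
  print(head(x$counts, 10))
  if (nrow(x$counts) > 10) cat("...\n")
  invisible(x)
}

#' Headline usage fractions from a usage table
#'
#' Computes (a) the percentage of reads in the modal V(-D)-J combination,
#' (b) the combined percentage of the `top_v` most-used V genes, and (c)
#' the combined percentage of reads using any gene in `long_d_ids`
#' (typically the long diversity segments, >100 nt). Exact fractions are
#' returned alongside percentages rounded half-away-from-zero to integers,
#' matching how repertoire tables are conventionally reported.
#'
#' @param usage an [usage_table()] result.
#' @param top_v how many top V genes to combine (default 5).
#' @param long_d_ids character vector of D gene ids counted as "long".
#' @return A list with elements `modal`, `top_v`, `long_d`, each holding
#'   `count`, `fraction` and `pct` (rounded), plus the modal combination.
#' @export
summarize_usage_percentages <- function(usage, top_v = 5, long_d_ids = NULL) {
  stopifnot(inherits(usage, "ig_usage"), usage$total > 0)
  cnt <- usage$counts
  mi <- which.max(cnt$count)
  modal <- list(combination = cnt[mi, setdiff(names(cnt), "count"), drop = FALSE],
                count = cnt$count[mi],
                fraction = cnt$count[mi] / usage$total,
                pct = round_half_away(100 * cnt$count[mi] / usage$total))
  tv <- sum(head(usage$v_totals, top_v))
  topv <- list(genes = names(head(usage$v_totals, top_v)), count = tv,
               fraction = tv / usage$total,
               pct = round_half_away(100 * tv / usage$total))
  longd <- NULL
  if (!is.null(long_d_ids)) {
    if (usage$chain_type != "VDJ") stop("long_d_ids requires a VDJ table")
    ld <- sum(cnt$count[cnt$d_gene %in% long_d_ids])
    longd <- list(genes = long_d_ids, count = ld,
                  fraction = ld / usage$total,
                  pct = round_half_away(100 * ld / usage$total))
  }
  list(modal = modal, top_v = topv, long_d = longd, total = usage$total)
}

#' Percentage of reads using one gene
#'
#' @param usage an [usage_table()] result.
#' @param gene gene id (any class).
#' @return List with `count`, `fraction`, `pct` (integer-rounded).
#' @export
gene_usage_pct <- function(usage, gene) {
  stopifnot(inherits(usage, "ig_usage"), usage$total > 0)
  cnt <- usage$counts
  k <- sum(cnt$count[cnt$v_gene == gene]) +
    sum(cnt$count[cnt$j_gene == gene]) +
    (if (usage$chain_type == "VDJ") sum(cnt$count[cnt$d_gene == gene]) else 0L)
  list(count = k, fraction = k / usage$total,
       pct = round_half_away(100 * k / usage$total))
}

junction_cols <- function(ann, type) {
  switch(type,
    VD = list(p = c("vd_p_left", "vd_p_right"), n = "vd_n",
              sel = ann$chain == "heavy" & !is.na(ann$d_gene)),
    DJ = list(p = c("dj_p_left", "dj_p_right"), n = "dj_n",
              sel = ann$chain == "heavy" & !is.na(ann$d_gene)),
    VJ = list(p = c("vd_p_left", "vd_p_right"), n = "vd_n",
              sel = ann$chain %in% c("lambda", "kappa")))
}

#' Junction statistics: N and P lengths, trimming medians
#'
#' Per junction type (VD and DJ for heavy chains, VJ for light chains):
#' number of sequences, median and range of N length, percentage of
#' sequences with at least one N, percentage with long N runs, median and
#' range of total P length, percentage with P, and median removed
#' (exonuclease-trimmed) bases per gene end.
#'
#' `long_n_inclusive` controls whether the "long N" percentage counts
#' lengths `>= long_n` (default, consistent with reported ranges starting
#' at the threshold) or strictly `> long_n`.
#'
#' @param annotations an `ig_annotations` data frame (QC-passing rows
#'   used).
#' @param long_n threshold for long N runs (default 10).
#' @param long_n_inclusive count `length >= long_n` (default TRUE).
#' @return A data frame of class `ig_junction_stats`, one row per junction
#'   type present, plus an `exo_medians` attribute (named per gene end).
#' @export
junction_stats <- function(annotations, long_n = 10L, long_n_inclusive = TRUE) {
  ann <- annotations[annotations$qc_pass, , drop = FALSE]
  if (!nrow(ann)) stop("no QC-passing annotations")
  types <- c(if (any(ann$chain == "heavy")) c("VD", "DJ"),
             if (any(ann$chain == "lambda")) "VJ_lambda",
             if (any(ann$chain == "kappa")) "VJ_kappa")
  rows <- list()
  for (ty in types) {
    base_ty <- sub("_.*$", "", ty)
    jc <- junction_cols(ann, base_ty)
    sel <- jc$sel
    if (ty == "VJ_lambda") sel <- sel & ann$chain == "lambda"
    if (ty == "VJ_kappa") sel <- sel & ann$chain == "kappa"
    sub <- ann[sel, , drop = FALSE]
    if (!nrow(sub)) next
    nlen <- nchar(sub[[jc$n]])
    plen <- nchar(sub[[jc$p[1]]]) + nchar(sub[[jc$p[2]]])
    longp <- if (long_n_inclusive) mean(nlen >= long_n) else mean(nlen > long_n)
    rows[[ty]] <- data.frame(
      junction = ty, n_sequences = nrow(sub),
      n_median = median(nlen), n_min = min(nlen), n_max = max(nlen),
      pct_with_n = 100 * mean(nlen >= 1L),
      pct_long_n = 100 * longp,
      p_median = median(plen), p_min = min(plen), p_max = max(plen),
      pct_with_p = 100 * mean(plen >= 1L),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  heavy <- ann[ann$chain == "heavy" & !is.na(ann$d_gene), , drop = FALSE]
  light <- ann[ann$chain != "heavy", , drop = FALSE]
  exo <- c(
    v3_heavy = if (nrow(heavy)) median(heavy$v_exo3) else NA_real_,
    d5 = if (nrow(heavy)) median(heavy$d_exo5) else NA_real_,
    d3 = if (nrow(heavy)) median(heavy$d_exo3) else NA_real_,
    j5_heavy = if (nrow(heavy)) median(heavy$j_exo5) else NA_real_,
    v3_light = if (nrow(light)) median(light$v_exo3) else NA_real_,
    j5_light = if (nrow(light)) median(light$j_exo5) else NA_real_)
  structure(out, exo_medians = exo,
            class = c("ig_junction_stats", "data.frame"))
}

#' Base composition of nontemplated (N) nucleotides
#'
#' Frequencies over the pooled N strings of the selected junction type;
#' P nucleotides and germline bases are excluded by construction.
#'
#' @param annotations an `ig_annotations` data frame.
#' @param junction `"VD"`, `"DJ"` or `"VJ"`.
#' @return Named numeric vector of percentages (A, C, G, T) summing to 100
#'   up to rounding.
#' @export
base_composition <- function(annotations, junction = c("VD", "DJ", "VJ")) {
  junction <- match.arg(junction)
  ann <- annotations[annotations$qc_pass, , drop = FALSE]
  jc <- junction_cols(ann, junction)
  pooled <- paste(ann[[jc$n]][jc$sel & !is.na(ann[[jc$n]])], collapse = "")
  if (!nzchar(pooled)) stop("no N bases in ", junction, " junctions")
  tab <- table(factor(chartokens(pooled), levels = c("A", "C", "G", "T")))
  100 * as.vector(tab) / sum(tab) -> pct
  setNames(pct, c("A", "C", "G", "T"))
}

#' CDR3 length spectratype (Gaussian kernel density)
#'
#' Kernel-smoothed signal density of CDR3 lengths, the in-silico analogue
#' of capillary-electrophoresis spectratyping. Gaussian kernel on a
#' uniform grid spanning `[min - 3h, max + 3h]`; default bandwidth is
#' Silverman's rule of thumb. Capillary fragment sizes include constant
#' primer flanks, so a constant `offset` (default 0) may be added to the
#' lengths.
#'
#' @param cdr3_lengths integer vector of CDR3 lengths (nt).
#' @param bandwidth kernel bandwidth `h`; default `stats::bw.nrd0`
#'   (requires at least 2 distinct lengths).
#' @param offset constant added to all lengths.
#' @param n_grid number of grid points (default 512).
#' @return An object of class `ig_spectratype`: `lengths`, `grid`,
#'   `density`, `bandwidth`. The density integrates to 1 (trapezoid rule).
#' @export
spectratype_density <- function(cdr3_lengths, bandwidth = NULL, offset = 0,
                                n_grid = 512L) {
  x <- cdr3_lengths[!is.na(cdr3_lengths)] + offset
  if (length(x) < 1L) stop("no CDR3 length observations")
  if (is.null(bandwidth)) {
    if (length(unique(x)) < 2L)
      stop("automatic bandwidth requires >= 2 distinct lengths")
    bandwidth <- bw.nrd0(x)
  }
  d <- density(x, bw = bandwidth, kernel = "gaussian", n = n_grid,
               from = min(x) - 3 * bandwidth, to = max(x) + 3 * bandwidth)
  ## renormalize: the finite window clips ~0.3% of Gaussian tail mass,
  ## and a signal density should integrate to 1 over its support
  area <- sum(diff(d$x) * (head(d$y, -1) + d$y[-1]) / 2)
  structure(list(lengths = x, grid = d$x, density = d$y / area,
                 bandwidth = bandwidth),
            class = "ig_spectratype")
}

#' @export
print.ig_spectratype <- function(x, ...) {
  cat("CDR3 spectratype:", length(x$lengths), "observations, bandwidth",
      signif(x$bandwidth, 3), "\n")
  cat("  modal length near", signif(x$grid[which.max(x$density)], 4), "nt\n")
  invisible(x)
}

#' @export
plot.ig_spectratype <- function(x, ...) {
  plot(x$grid, x$density, type = "l", xlab = "CDR3 length (nt)",
       ylab = "signal density", ...)
  invisible(x)
}
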