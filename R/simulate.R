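#' Configuration for the ground-truth repertoire simulator
#'
#' The generator emulates fetal cDNA libraries: random V/(D)/J picks,
#' per-end exonuclease trimming, P nucleotides at untrimmed ends, and
#' A/T-biased nontemplated (N) insertions, with optional uniform
#' point-mutation noise standing in for somatic hypermutation.
#'
#' Distributions (all stand-ins — the study this emulates measured, it did
#' not simulate):
#' * trimming per end: geometric, parameterized by its mean, truncated so
#'   at least `min_remnant` bases of each gene survive;
#' * N length per junction: hurdle geometric — zero with probability
#'   `pi0`, else `1 + Geom(q)`. This family can match a reported median,
#'   mean, fraction-with-N and fraction-of-long-runs simultaneously,
#'   which a plain geometric cannot;
#' * P at an untrimmed end with probability `p_prob`; P length
#'   `1 + Geom(p_len_q)` capped at `p_len_max`;
#' * N bases drawn from `n_base_probs` (A/T-rich by default).
#'
#' Defaults reproduce the fetal bovine heavy-chain junction statistics:
#' VD median N = 1, DJ median N = 2, ~65%/68% of junctions with N, ~90%
#' of reads with any N, N base profile A .31 / T .33 / G .19 / C .17,
#' trimming medians V3' 2, D5' 5, D3' 6, J5' 2.
#'
#' @param refs an `ig_reference_set`.
#' @param n number of reads.
#' @param chain `"heavy"`, `"lambda"` or `"kappa"`.
#' @param seed mandatory integer seed; each read derives its own
#'   substream so generation is reproducible read by read.
#' @param gene_weights optional named list `list(V=, D=, J=)` of weight
#'   vectors (default uniform).
#' @param trim_mean named vector of geometric means per end
#'   (`v3`, `d5`, `d3`, `j5`; light chains use `v3`, `j5`).
#' @param n_pi0,n_q hurdle-geometric N-length parameters per junction
#'   (`vd`, `dj` for heavy; `vj` for light).
#' @param p_prob probability an untrimmed end carries P nucleotides.
#' @param p_len_q,p_len_max P length distribution (1 + Geom(q), capped).
#' @param n_base_probs base probabilities for N nucleotides (A, C, G, T).
#' @param mutation_rate per-base substitution probability (default 0).
#' @param min_remnant minimum germline bases left per gene after trimming
#'   (default 10, so a D remnant always clears the annotator's
#'   minimum-evidence floor with margin).
#' @param identifiable resample junctions that would be ambiguous to the
#'   annotator (see [simulate_repertoire()]); turn off to stress-test the
#'   annotator's failure modes.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(refs, n, chain = c("heavy", "lambda", "kappa"),
                              seed,
                              gene_weights = NULL,
                              trim_mean = c(v3 = 3, d5 = 7.3, d3 = 9, j5 = 3),
                              n_pi0 = c(vd = 0.35, dj = 0.32, vj = 0.40),
                              n_q = c(vd = 0.26, dj = 0.25, vj = 0.45),
                              p_prob = 0.4,
                              p_len_q = 0.6, p_len_max = 6L,
                              n_base_probs = c(A = 0.31, C = 0.17,
                                               G = 0.19, T = 0.33),
                              mutation_rate = 0,
                              min_remnant = 10L,
                              identifiable = TRUE) {
  chain <- match.arg(chain)
  stopifnot(inherits(refs, "ig_reference_set"), n >= 1)
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  if (abs(sum(n_base_probs) - 1) > 1e-8)
    stop("n_base_probs must sum to 1")
  if (p_prob < 0 || p_prob > 1 || any(n_pi0 < 0 | n_pi0 > 1))
    stop("probabilities must be in [0, 1]")
  needed <- if (chain == "heavy") c("V", "D", "J") else c("V", "J")
  for (cl in needed) {
    segs <- subset_segments(refs, chain, cl)
    if (!nrow(segs)) stop("reference set lacks ", cl, " segments for ", chain)
    trims <- if (cl == "V") trim_mean["v3"] else if (cl == "J") trim_mean["j5"]
             else max(trim_mean[c("d5", "d3")])
    if (any(segs$length <= min_remnant))
      stop("segment shorter than min_remnant: ",
           paste(segs$id[segs$length <= min_remnant], collapse = ", "))
    if (trims >= min(segs$length))
      stop("trimming mean exceeds shortest ", cl, " gene length")
  }
  structure(list(refs = refs, n = as.integer(n), chain = chain,
                 seed = as.integer(seed), gene_weights = gene_weights,
                 trim_mean = trim_mean, n_pi0 = n_pi0, n_q = n_q,
                 p_prob = p_prob, p_len_q = p_len_q,
                 p_len_max = as.integer(p_len_max),
                 n_base_probs = n_base_probs,
                 mutation_rate = mutation_rate,
                 min_remnant = as.integer(min_remnant),
                 identifiable = isTRUE(identifiable)),
            class = "simulation_config")
}

rgeom_mean <- function(n, mean) {
  if (mean <= 0) return(rep(0L, n))
  rgeom(n, 1 / (1 + mean))
}

rhurdle_geom <- function(n, pi0, q) {
  z <- runif(n) < pi0
  ifelse(z, 0L, 1L + rgeom(n, q))
}

rand_bases <- function(n, probs) {
  if (n <= 0L) return("")
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

## Every prefix of the base-by-base comparison of read extension vs
## germline continuation must score strictly negative under match +1 /
## mismatch -1: a positive prefix would move the optimal local alignment
## past the true boundary, and a zero-sum prefix would tie it with a
## longer alignment (which the deterministic tie-break prefers).
extension_safe <- function(readext, cont) {
  k <- min(nchar(readext), nchar(cont))
  if (k == 0L) return(TRUE)
  a <- chartokens(substr(readext, 1L, k))
  b <- chartokens(substr(cont, 1L, k))
  all(cumsum(ifelse(a == b, 1, -1)) < 0)
}

revstring <- function(s) paste(rev(chartokens(s)), collapse = "")

## Anchored affine-gap extension check: every alignment extension that
## starts at the true gene boundary, consumes >= 1 junction (query) base
## and any number of germline continuation (ref) bases must score
## strictly negative, or the optimal local alignment would absorb
## junction bases past the boundary (a zero score ties with a longer
## alignment, which the tie-break prefers). A gap of length L costs
## open + L * ext, matching the annotation engine.
ext_dp_safe <- function(query, ref, open = 4, ext = 0.3) {
  qn <- nchar(query); rn <- nchar(ref)
  if (qn == 0L || rn == 0L) return(TRUE)
  q <- chartokens(query); r <- chartokens(ref)
  NEG <- -1e9
  ## states per column j = 0..rn: A sub-ending, B insertion-ending (query
  ## consumed), C deletion-ending (ref consumed)
  A <- rep(NEG, rn + 1); B <- rep(NEG, rn + 1); C <- rep(NEG, rn + 1)
  ## row 0: leading deletions only
  for (j in seq_len(rn)) C[j + 1] <- -(open + ext * j)
  V0 <- pmax(A, B, C); V0[1] <- 0           # V[0, j]
  for (i in seq_len(qn)) {
    Anew <- rep(NEG, rn + 1); Bnew <- rep(NEG, rn + 1); Cnew <- rep(NEG, rn + 1)
    Bnew[1] <- max(V0[1] - (open + ext), B[1] - ext)
    for (j in seq_len(rn)) {
      s <- if (q[i] == r[j]) 1 else -1
      Anew[j + 1] <- V0[j] + s
      Bnew[j + 1] <- max(V0[j + 1] - (open + ext), B[j + 1] - ext)
      Cnew[j + 1] <- max(max(Anew[j], Bnew[j]) - (open + ext), Cnew[j] - ext)
    }
    V0 <- pmax(Anew, Bnew, Cnew)
    if (max(V0) >= 0) return(FALSE)
    A <- Anew; B <- Bnew; C <- Cnew
  }
  TRUE
}

## Decomposition of a generated junction must reproduce the truth P/N
## strings, and no anchored extension into a trimmed germline
## continuation may score >= 0 under that side's gap scheme.
junction_identifiable <- function(junction, up_seq, up_trim, p_left,
                                  dn_seq, dn_trim, p_right,
                                  up_ext = 5, dn_ext = 5) {
  jl <- nchar(junction)
  up_kept <- nchar(up_seq) - up_trim
  dec <- decompose_junction(junction,
                            substr(up_seq, 1L, up_kept), up_trim,
                            substr(dn_seq, dn_trim + 1L, nchar(dn_seq)),
                            dn_trim)
  if (dec$p_left != p_left || dec$p_right != p_right) return(FALSE)
  ## gapped extensions only pay off when the junction can supply more
  ## matches than the minimum gap cost
  if (up_trim > 0L && jl > open_gap_floor(up_ext)) {
    cont <- substr(up_seq, up_kept + 1L, min(nchar(up_seq), up_kept + 40L))
    if (!ext_dp_safe(junction, cont, ext = up_ext)) return(FALSE)
  }
  if (dn_trim > 0L && jl > open_gap_floor(dn_ext)) {
    cont <- substr(dn_seq, max(1L, dn_trim - 39L), dn_trim)
    if (!ext_dp_safe(revstring(junction), revstring(cont), ext = dn_ext))
      return(FALSE)
  }
  TRUE
}

## minimum score a single-gap extension must beat before it can profit
open_gap_floor <- function(ext, open = 4) open + ext

## Junction generation. P and N lengths are drawn once so the
## identifiability resampling (which redraws only base content, and P/N
## lengths merely as a last resort) does not distort the configured length
## distributions.
make_junction <- function(cfg, up_seq, up_trim, dn_seq, dn_trim, jtype) {
  ## gap-extension penalties of the annotation engine per junction side
  ## (D alignments use the marginal penalty)
  up_ext <- if (jtype == "dj") 0.3 else 5
  dn_ext <- if (jtype == "vd") 0.3 else 5
  for (outer in 1:40) {
    p_left <- p_right <- ""
    if (up_trim == 0L && runif(1) < cfg$p_prob) {
      len <- min(1L + rgeom(1, cfg$p_len_q), cfg$p_len_max, nchar(up_seq))
      p_left <- revcomp(substr(up_seq, nchar(up_seq) - len + 1L, nchar(up_seq)))
    }
    if (dn_trim == 0L && runif(1) < cfg$p_prob) {
      len <- min(1L + rgeom(1, cfg$p_len_q), cfg$p_len_max, nchar(dn_seq))
      p_right <- revcomp(substr(dn_seq, 1L, len))
    }
    nlen <- rhurdle_geom(1L, cfg$n_pi0[[jtype]], cfg$n_q[[jtype]])
    for (inner in 1:50) {
      nstr <- rand_bases(nlen, cfg$n_base_probs)
      junction <- paste0(p_left, nstr, p_right)
      if (!cfg$identifiable ||
          junction_identifiable(junction, up_seq, up_trim, p_left,
                                dn_seq, dn_trim, p_right,
                                up_ext = up_ext, dn_ext = dn_ext))
        return(list(p_left = p_left, n = nstr, p_right = p_right,
                    junction = junction))
      if (nlen == 0L) break  # nothing to resample; redraw lengths
    }
  }
  stop("could not generate an identifiable junction")
}

#' Simulate a ground-truth-labelled V(D)J repertoire
#'
#' Generates exactly `n` reads by concatenating a chosen V (3'-trimmed),
#' a VD junction, a chosen D (both ends trimmed), a DJ junction, and a
#' chosen J (5'-trimmed) — or V + VJ junction + J for light chains —
#' recording the complete truth (genes, per-end trimming, P and N strings,
#' CDR3 span). The same seed yields byte-identical output.
#'
#' With `identifiable = TRUE` (default) junction strings are resampled
#' when they would be ambiguous to the annotator: when an N base would
#' extend the terminal complementarity run of an adjacent untrimmed end,
#' when a junction base adjacent to a trimmed end continues the trimmed
#' germline sequence, or when the junction shares a 5-mer with the trimmed
#' germline continuation (which a marginally penalized gap extension could
#' bridge). This is a simulation-side identifiability device that keeps
#' the truth recoverable; switch it off to probe the annotator's failure
#' modes.
#'
#' @param config a [simulation_config()].
#' @return An object of class `ig_simulation`: `reads` (named character
#'   vector) and `truth` (data frame keyed by `read_id`).
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  refs <- cfg$refs
  vrefs <- subset_segments(refs, cfg$chain, "V")
  jrefs <- subset_segments(refs, cfg$chain, "J")
  drefs <- if (cfg$chain == "heavy") subset_segments(refs, cfg$chain, "D")
           else NULL
  wts <- function(class, nseg) {
    w <- cfg$gene_weights[[class]]
    if (is.null(w)) rep(1, nseg) else w
  }
  heavy <- cfg$chain == "heavy"
  rows <- vector("list", cfg$n)
  reads <- character(cfg$n)
  gen_read <- function(i, round = 0L) {
    ## counter-based per-read substream: reproducible under any ordering;
    ## identifiability regeneration rounds shift the substream
    set.seed((cfg$seed %% 1000003L) * 2011L + i + round * 37537L)
    vi <- sample.int(nrow(vrefs), 1L, prob = wts("V", nrow(vrefs)))
    ji <- sample.int(nrow(jrefs), 1L, prob = wts("J", nrow(jrefs)))
    di <- if (heavy) sample.int(nrow(drefs), 1L, prob = wts("D", nrow(drefs)))
    vseq <- vrefs$sequence[vi]; jseq <- jrefs$sequence[ji]
    dseq <- if (heavy) drefs$sequence[di]
    trim_one <- function(mean, len) {
      min(rgeom_mean(1L, mean), len - cfg$min_remnant)
    }
    for (try in 1:500) {
      v3 <- trim_one(cfg$trim_mean[["v3"]], nchar(vseq))
      j5 <- trim_one(cfg$trim_mean[["j5"]], nchar(jseq))
      v_kept <- substr(vseq, 1L, nchar(vseq) - v3)
      j_kept <- substr(jseq, j5 + 1L, nchar(jseq))
      if (heavy) {
        d5 <- trim_one(cfg$trim_mean[["d5"]], nchar(dseq))
        d3 <- max(min(trim_one(cfg$trim_mean[["d3"]], nchar(dseq)),
                      nchar(dseq) - d5 - cfg$min_remnant), 0L)
        d_kept <- substr(dseq, d5 + 1L, nchar(dseq) - d3)
        vd <- make_junction(cfg, vseq, v3, dseq, d5, "vd")
        dj <- make_junction(cfg, dseq, d3, jseq, j5, "dj")
        seq <- paste0(v_kept, vd$junction, d_kept, dj$junction, j_kept)
        d_start0 <- nchar(v_kept) + nchar(vd$junction)
      } else {
        vd <- make_junction(cfg, vseq, v3, jseq, j5, "vj")
        dj <- NULL
        seq <- paste0(v_kept, vd$junction, j_kept)
        d_start0 <- NA_integer_
      }
      if (!cfg$identifiable) break
      ## Whole-read identifiability: no local-alignment extension past a
      ## true boundary may score positive anywhere along its prefix (a
      ## chance run of matches beyond a forced mismatch can otherwise
      ## outweigh it and shift the exonuclease counts).
      j_off <- nchar(seq) - nchar(j_kept)
      ok <- TRUE
      if (v3 > 0L)
        ok <- extension_safe(substr(seq, nchar(v_kept) + 1L, nchar(v_kept) + 60L),
                             substr(vseq, nchar(v_kept) + 1L,
                                    min(nchar(vseq), nchar(v_kept) + 60L)))
      if (ok && j5 > 0L)
        ok <- extension_safe(revstring(substr(seq, max(1L, j_off - 59L), j_off)),
                             revstring(substr(jseq, max(1L, j5 - 59L), j5)))
      if (ok && heavy && d5 > 0L)
        ok <- extension_safe(revstring(vd$junction),
                             revstring(substr(dseq, 1L, d5)))
      if (ok && heavy && d3 > 0L)
        ok <- extension_safe(dj$junction,
                             substr(dseq, nchar(dseq) - d3 + 1L, nchar(dseq)))
      if (ok) break
      if (try == 500L) stop("could not generate an identifiable read")
    }
    if (cfg$mutation_rate > 0) {
      ch <- chartokens(seq)
      hit <- runif(length(ch)) < cfg$mutation_rate
      if (any(hit)) {
        ch[hit] <- vapply(ch[hit], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        seq <- paste(ch, collapse = "")
      }
    }
    va <- vrefs$anchor[vi]; ja <- jrefs$anchor[ji]
    cdr3_start <- if (!is.na(va) && va < nchar(v_kept)) va else NA_integer_
    j_off <- nchar(seq) - nchar(j_kept)  # 0-based start of J part
    cdr3_end <- if (!is.na(ja) && ja >= j5) j_off + (ja - j5) else NA_integer_
    rid <- sprintf("sim%05d", i)
    data.frame(
      read_id = rid, chain = cfg$chain,
      v_gene = vrefs$id[vi],
      d_gene = if (heavy) drefs$id[di] else NA_character_,
      j_gene = jrefs$id[ji],
      v_exo3 = v3,
      d_exo5 = if (heavy) d5 else NA_integer_,
      d_exo3 = if (heavy) d3 else NA_integer_,
      j_exo5 = j5,
      vd_p_left = vd$p_left, vd_n = vd$n, vd_p_right = vd$p_right,
      dj_p_left = if (heavy) dj$p_left else NA_character_,
      dj_n = if (heavy) dj$n else NA_character_,
      dj_p_right = if (heavy) dj$p_right else NA_character_,
      d_start = d_start0,
      cdr3_start = cdr3_start, cdr3_end = cdr3_end,
      cdr3_len = if (!is.na(cdr3_start) && !is.na(cdr3_end))
        cdr3_end - cdr3_start else NA_integer_,
      sequence = seq,
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(cfg$n)) rows[[i]] <- gen_read(i)

  ## Identifiability also requires the D assignment itself to be unique:
  ## with a D remnant near the evidence floor, a chance gapped match
  ## against another D gene can tie or beat it. Verify with the
  ## annotation engine (true inter-V-J window vs every D gene) and
  ## regenerate offending reads on a shifted substream.
  if (cfg$identifiable && heavy && cfg$mutation_rate == 0) {
    params <- alignment_params()
    pending <- seq_len(cfg$n)
    for (round in 1:8) {
      windows <- vapply(pending, function(i) {
        tr <- rows[[i]]
        dlen <- drefs$length[match(tr$d_gene, drefs$id)]
        paste0(tr$vd_p_left, tr$vd_n, tr$vd_p_right,
               substr(drefs$sequence[match(tr$d_gene, drefs$id)],
                      tr$d_exo5 + 1L, dlen - tr$d_exo3),
               tr$dj_p_left, tr$dj_n, tr$dj_p_right)
      }, "")
      scores <- qlens <- matrix(0, length(pending), nrow(drefs))
      for (g in seq_len(nrow(drefs))) {
        b <- align_batch(windows, drefs$sequence[g], params,
                         params$gap_extend_d)
        scores[, g] <- b$score
        qlens[, g] <- ifelse(b$score > 0, b$qend - b$qstart + 1L, 0L)
      }
      called <- vapply(seq_along(pending), function(k)
        drefs$id[pick_best(scores[k, ], qlens[k, ], drefs$id)], "")
      truth_d <- vapply(pending, function(i) rows[[i]]$d_gene, "")
      bad <- pending[called != truth_d]
      if (!length(bad)) break
      if (round == 8L) stop("could not generate identifiable D assignments")
      for (i in bad) rows[[i]] <- gen_read(i, round)
      pending <- bad
    }
  }

  reads <- vapply(rows, `[[`, "", "sequence")
  names(reads) <- vapply(rows, `[[`, "", "read_id")
  truth <- do.call(rbind, rows)
  rownames(truth) <- truth$read_id
  structure(list(reads = reads, truth = truth, config = cfg),
            class = "ig_simulation")
}

#' @export
print.ig_simulation <- function(x, ...) {
  cat("Simulated repertoire:", length(x$reads), x$config$chain,
      "reads, seed", x$config$seed, "\n")
  invisible(x)
}

#' Compare annotations against simulation truth
#'
#' Per-field accuracies of the annotation pipeline on simulated reads:
#' gene-id match rates for V/D/J, exact-match rates for per-end trimming
#' counts, N strings and P strings, plus a confusion summary of D
#' assignments.
#'
#' @param truth truth data frame from [simulate_repertoire()].
#' @param annotations `ig_annotations` for the same reads.
#' @return A list of class `ig_recovery`: `n`, `accuracy` (named numeric,
#'   percentages), `d_confusion` (table truth x called).
#' @export
recovery_report <- function(truth, annotations) {
  if (!setequal(truth$read_id, annotations$read_id))
    stop("read ids differ between truth and annotations")
  ann <- annotations[match(truth$read_id, annotations$read_id), , drop = FALSE]
  heavy <- truth$chain[1] == "heavy"
  eqv <- function(a, b) {
    same <- (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
    100 * mean(same)
  }
  acc <- c(
    v_gene = eqv(truth$v_gene, ann$v_gene),
    j_gene = eqv(truth$j_gene, ann$j_gene),
    v_exo3 = eqv(truth$v_exo3, ann$v_exo3),
    j_exo5 = eqv(truth$j_exo5, ann$j_exo5))
  if (heavy) {
    acc <- c(acc,
      d_gene = eqv(truth$d_gene, ann$d_gene),
      d_exo5 = eqv(truth$d_exo5, ann$d_exo5),
      d_exo3 = eqv(truth$d_exo3, ann$d_exo3),
      vd_n = eqv(truth$vd_n, ann$vd_n),
      dj_n = eqv(truth$dj_n, ann$dj_n),
      vd_p = eqv(paste(truth$vd_p_left, truth$vd_p_right),
                 paste(ann$vd_p_left, ann$vd_p_right)),
      dj_p = eqv(paste(truth$dj_p_left, truth$dj_p_right),
                 paste(ann$dj_p_left, ann$dj_p_right)))
    conf <- table(truth = truth$d_gene,
                  called = ifelse(is.na(ann$d_gene), "(none)", ann$d_gene))
  } else {
    acc <- c(acc,
      vj_n = eqv(truth$vd_n, ann$vd_n),
      vj_p = eqv(paste(truth$vd_p_left, truth$vd_p_right),
                 paste(ann$vd_p_left, ann$vd_p_right)))
    conf <- NULL
  }
  structure(list(n = nrow(truth), accuracy = acc, d_confusion = conf),
            class = "ig_recovery")
}

#' @export
print.ig_recovery <- function(x, ...) {
  cat("Recovery over", x$n, "reads (% exact):\n")
  print(round(x$accuracy, 2))
  invisible(x)
}

#' Reconstruct read sequences from a junction-decomposition table
#'
#' Inverse of the annotation decomposition: concatenates per-read V
#' segment bases, VD junction (P/N/P), D bases, DJ junction and J bases
#' (or V + VJ + J) back into the read subsequence spanning V start to J
#' end. Used to re-analyze published per-read decomposition tables and in
#' conservation checks.
#'
#' @param table data frame with columns `v_seq`, `vd_p_left`, `vd_n`,
#'   `vd_p_right`, `d_seq`, `dj_p_left`, `dj_n`, `dj_p_right`, `j_seq`
#'   (light chains: `v_seq`, `vj_p_left`, `vj_n`, `vj_p_right`, `j_seq`).
#'   NA fields are treated as empty.
#' @return Character vector of reconstructed sequences.
#' @export
reconstruct_reads <- function(table) {
  gv <- function(col) {
    if (col %in% names(table)) ifelse(is.na(table[[col]]), "", table[[col]])
    else ""
  }
  if ("d_seq" %in% names(table)) {
    paste0(gv("v_seq"), gv("vd_p_left"), gv("vd_n"), gv("vd_p_right"),
           gv("d_seq"), gv("dj_p_left"), gv("dj_n"), gv("dj_p_right"),
           gv("j_seq"))
  } else {
    paste0(gv("v_seq"), gv("vj_p_left"), gv("vj_n"), gv("vj_p_right"),
           gv("j_seq"))
  }
}
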