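#' Gene-segment combination counts from fetal bovine cDNA libraries
#'
#' Published combination counts transcribed to tidy form: heavy-chain
#' V x D x J counts over 645 cDNA clones from fetal bone marrow, ileum and
#' spleen, and light-chain V x J counts (65 lambda, 83 kappa clones from
#' bone marrow and ileum). Useful as realistic usage inputs and for exact
#' table arithmetic.
#'
#' @param chain `"heavy"`, `"lambda"` or `"kappa"`.
#' @return A data frame with columns `v_gene`, (`d_gene`,) `j_gene`,
#'   `count`.
#' @export
study_usage_counts <- function(chain = c("heavy", "lambda", "kappa")) {
  chain <- match.arg(chain)
  f <- system.file("extdata",
                   sprintf("bovine_fetal_%s_usage.tsv", chain),
                   package = "igjunction", mustWork = TRUE)
  read.delim(f, stringsAsFactors = FALSE)
}

#' Published split of D-segment counts by exonuclease activity
#'
#' Per D gene, the number of heavy-chain cDNAs flagged for high
#' exonuclease activity (more than 29 nt excised from either D end)
#' versus the rest, over the same 645 clones.
#'
#' @return Data frame with columns `d_gene`, `high_exo`, `normal_exo`.
#' @export
study_d_exo_split <- function() {
  f <- system.file("extdata", "bovine_fetal_d_exo_split.tsv",
                   package = "igjunction", mustWork = TRUE)
  read.delim(f, stringsAsFactors = FALSE)
}

#' Generate a synthetic germline reference set
#'
#' Builds a labelled, fully synthetic germline set whose shape mirrors the
#' bovine loci: a handful of ~300 nt V genes with CDR3 anchors near their
#' 3' ends, D genes spanning the reported 31-154 nt length range (heavy
#' only), and ~50 nt J genes with the conserved-codon anchor in their
#' middle. Sequences are random (seeded), hence mutually non-homologous at
#' segment ends — the regime in which annotation is exactly recoverable.
#' These are stand-ins for real germline databases, not biological
#' sequences.
#'
#' @param seed integer seed.
#' @param chain `"heavy"`, `"lambda"` or `"kappa"`.
#' @param n_v,n_d,n_j segment counts (defaults 6 / 14 / 3 for heavy).
#' @param v_len,j_len segment lengths.
#' @param d_len integer vector of D lengths (recycled to `n_d`).
#' @return An `ig_reference_set`.
#' @export
synthetic_reference <- function(seed, chain = c("heavy", "lambda", "kappa"),
                                n_v = 6L, n_d = 14L, n_j = 3L,
                                v_len = 300L, j_len = 50L,
                                d_len = c(31L, 45L, 60L, 75L, 90L, 105L,
                                          120L, 135L, 148L, 154L, 40L, 55L,
                                          70L, 85L)) {
  chain <- match.arg(chain)
  set.seed(seed)
  rseq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                     replace = TRUE), collapse = "")
  pre <- switch(chain, heavy = "VH", lambda = "VL", kappa = "VK")
  v <- data.frame(id = sprintf("%sS%d", pre, seq_len(n_v)),
                  chain = chain, class = "V",
                  anchor = v_len - 12L,  # 12 nt of V inside the CDR3
                  note = "synthetic",
                  sequence = vapply(seq_len(n_v), function(i) rseq(v_len), ""),
                  stringsAsFactors = FALSE)
  jpre <- switch(chain, heavy = "JH", lambda = "JL", kappa = "JK")
  j <- data.frame(id = sprintf("%sS%d", jpre, seq_len(n_j)),
                  chain = chain, class = "J",
                  anchor = 20L,          # conserved codon 20 nt into J
                  note = "synthetic",
                  sequence = vapply(seq_len(n_j), function(i) rseq(j_len), ""),
                  stringsAsFactors = FALSE)
  segs <- rbind(v, j)
  if (chain == "heavy" && n_d > 0L) {
    dl <- rep_len(d_len, n_d)
    d <- data.frame(id = sprintf("DHS%d", seq_len(n_d)),
                    chain = chain, class = "D",
                    anchor = NA_integer_, note = "synthetic",
                    sequence = vapply(dl, rseq, ""),
                    stringsAsFactors = FALSE)
    segs <- rbind(segs, d)
  }
  reference_set(segs$id, segs$chain, segs$class, segs$sequence,
                segs$anchor, segs$note)
}
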