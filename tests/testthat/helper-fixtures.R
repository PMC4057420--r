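# Shared in-code fixtures. Everything is generated, nothing read from disk
# except the transcribed published tables under inst/extdata.

heavy_refs <- function(seed = 42) synthetic_reference(seed)

# A genomic subject with one embedded D-RSS locus (nonamer - spacer -
# heptamer - core - heptamer - spacer - nonamer), optionally with
# substitutions planted in the nonamers.
make_rss_subject <- function(seed, mutate_nonamers = 0) {
  set.seed(seed)
  non1 <- "GGTTTTTGT"; hep <- "CACAGTG"; non2 <- "ACAAAAACC"
  if (mutate_nonamers > 0) {
    flip <- function(s, k) {
      ch <- strsplit(s, "")[[1]]
      idx <- sample(seq_along(ch), k)
      ch[idx] <- vapply(ch[idx], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      paste(ch, collapse = "")
    }
    k1 <- ceiling(mutate_nonamers / 2); k2 <- mutate_nonamers - k1
    non1 <- flip(non1, k1); if (k2 > 0) non2 <- flip(non2, k2)
  }
  core <- random_dna(20)
  list(subject = paste0(non1, random_dna(12), hep, core, hep,
                        random_dna(12), non2),
       core = core)
}

# Minimal annotation-shaped data frame for summary-level unit tests that
# do not need the full pipeline.
fake_annotations <- function(chain = "heavy", n = 3,
                             vd_n = c("", "A", "GT"), dj_n = vd_n,
                             vd_p_left = "", vd_p_right = "",
                             dj_p_left = "", dj_p_right = "",
                             v_gene = "VHS1", d_gene = "DHS1",
                             j_gene = "JHS1",
                             v_exo3 = 0L, d_exo5 = 0L, d_exo3 = 0L,
                             j_exo5 = 0L, cdr3_len = 60L) {
  df <- data.frame(
    read_id = sprintf("r%03d", seq_len(n)), chain = chain,
    orientation = "+",
    v_gene = rep_len(v_gene, n), v_score = 100,
    v_qstart = 0L, v_qend = 100L, v_rstart = 0L, v_rend = 100L,
    v_exo3 = rep_len(v_exo3, n),
    d_gene = if (chain == "heavy") rep_len(d_gene, n) else NA_character_,
    d_score = 20, d_qstart = 110L, d_qend = 150L,
    d_rstart = 0L, d_rend = 40L,
    d_exo5 = rep_len(d_exo5, n), d_exo3 = rep_len(d_exo3, n),
    j_gene = rep_len(j_gene, n), j_score = 40,
    j_qstart = 160L, j_qend = 200L, j_rstart = 0L, j_rend = 40L,
    j_exo5 = rep_len(j_exo5, n),
    vd_p_left = rep_len(vd_p_left, n), vd_n = rep_len(vd_n, n),
    vd_p_right = rep_len(vd_p_right, n),
    dj_p_left = if (chain == "heavy") rep_len(dj_p_left, n) else NA,
    dj_n = if (chain == "heavy") rep_len(dj_n, n) else NA,
    dj_p_right = if (chain == "heavy") rep_len(dj_p_right, n) else NA,
    cdr3_start = 90L, cdr3_end = 90L + rep_len(cdr3_len, n),
    cdr3_len = rep_len(cdr3_len, n),
    no_d = FALSE, high_exo = FALSE, qc_pass = TRUE, qc_reason = "",
    stringsAsFactors = FALSE)
  structure(df, class = c("ig_annotations", "data.frame"))
}
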