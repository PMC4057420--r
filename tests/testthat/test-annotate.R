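test_that("junction decomposition follows the P/N calling rule", {
  # revcomp of upstream end "TACTAC" is "GTAGTA": matching prefix "GTA"
  d <- decompose_junction("GTACCT", "TACTAC", 0L, "GATC", 2L)
  expect_equal(d$p_left, "GTA")
  expect_equal(d$n, "CCT")
  expect_equal(d$p_right, "")

  expect_equal(unlist(decompose_junction("", "ACGT", 0L, "ACGT", 0L),
                      use.names = FALSE), c("", "", ""))

  # P forbidden at trimmed ends
  d2 <- decompose_junction("AAAA", "TTTT", 3L, "CCCC", 1L)
  expect_equal(d2$n, "AAAA")
  expect_equal(c(d2$p_left, d2$p_right), c("", ""))

  # downstream P: suffix complementary to the downstream 5' start,
  # matched base by base outward from the boundary
  d3 <- decompose_junction("AATC", "GGGG", 1L, "GATC", 0L)
  expect_equal(d3$p_right, "ATC")  # revcomp("GAT") = "ATC"
  expect_equal(d3$n, "A")

  # overlapping P claims: left side satisfied first, right truncated
  up <- "AAAAAT"                    # revcomp end -> "A" then "T..."
  dn <- "TATTTT"                    # revcomp start "TA" = "TA"
  d4 <- decompose_junction("ATA", up, 0L, dn, 0L)
  expect_equal(paste0(d4$p_left, d4$n, d4$p_right), "ATA")
  expect_gt(nchar(d4$p_left), 0L)
})

test_that("an exact V+D+J concatenation is annotated with empty junctions", {
  refs <- heavy_refs()
  cfg <- simulation_config(refs, n = 8, chain = "heavy", seed = 31,
                           trim_mean = c(v3 = 0, d5 = 0, d3 = 0, j5 = 0),
                           n_pi0 = c(vd = 1, dj = 1, vj = 1),
                           p_prob = 0)
  sim <- simulate_repertoire(cfg)
  v <- get_segment(refs, sim$truth$v_gene[1])$sequence
  d <- get_segment(refs, sim$truth$d_gene[1])$sequence
  j <- get_segment(refs, sim$truth$j_gene[1])$sequence
  expect_equal(sim$reads[[1]], paste0(v, d, j))

  ann <- annotate_repertoire(sim$reads, refs, "heavy")
  expect_equal(ann$v_gene, sim$truth$v_gene)
  expect_equal(ann$d_gene, sim$truth$d_gene)
  expect_equal(ann$j_gene, sim$truth$j_gene)
  expect_true(all(ann$v_exo3 == 0 & ann$d_exo5 == 0 &
                    ann$d_exo3 == 0 & ann$j_exo5 == 0))
  expect_true(all(ann$vd_n == "" & ann$dj_n == ""))
  expect_true(all(ann$vd_p_left == "" & ann$dj_p_right == ""))
})

test_that("annotation recovers the full simulated truth", {
  refs <- heavy_refs()
  sim <- simulate_repertoire(simulation_config(refs, n = 80, chain = "heavy",
                                               seed = 97))
  ann <- annotate_repertoire(sim$reads, refs, "heavy")
  rec <- recovery_report(sim$truth, ann)
  expect_true(all(rec$accuracy == 100))
  # trimming and N calls are not degenerate in this regime
  expect_gt(sum(sim$truth$d_exo5), 0)
  expect_gt(sum(nchar(sim$truth$vd_n)), 0)
})

test_that("light chains are annotated with a single VJ junction", {
  refs <- synthetic_reference(11, chain = "lambda")
  sim <- simulate_repertoire(simulation_config(refs, n = 40, chain = "lambda",
                                               seed = 13))
  ann <- annotate_repertoire(sim$reads, refs, "lambda")
  rec <- recovery_report(sim$truth, ann)
  expect_true(all(rec$accuracy == 100))
  expect_true(all(is.na(ann$d_gene)))
  expect_true(all(is.na(ann$dj_n)))
})

test_that("reads are re-oriented once when given as reverse complements", {
  refs <- heavy_refs()
  sim <- simulate_repertoire(simulation_config(refs, n = 6, chain = "heavy",
                                               seed = 55))
  flipped <- sim$reads
  flipped[c(2, 4)] <- revcomp(flipped[c(2, 4)])
  ann <- annotate_repertoire(flipped, refs, "heavy")
  expect_equal(ann$orientation, c("+", "-", "+", "-", "+", "+"))
  expect_true(all(recovery_report(sim$truth, ann)$accuracy == 100))
})

test_that("missing segments fail QC with a reason", {
  # a V-only alphabet read cannot produce a positive-scoring J alignment
  refs <- reference_set(c("VX1", "JX1"), "kappa", c("V", "J"),
                        c(paste(rep("A", 60), collapse = ""),
                          paste(rep("C", 40), collapse = "")),
                        anchor = c(50L, 10L))
  ann <- annotate_repertoire(c(r1 = paste(rep("A", 50), collapse = "")),
                             refs, "kappa", try_revcomp = FALSE)
  expect_false(ann$qc_pass)
  expect_equal(ann$qc_reason, "no J hit")

  # J entirely upstream of V is rejected
  refs2 <- synthetic_reference(21, chain = "kappa")
  v <- get_segment(refs2, "VKS1")$sequence
  j <- get_segment(refs2, "JKS1")$sequence
  ann2 <- annotate_repertoire(c(r1 = paste0(j, v)), refs2, "kappa",
                              try_revcomp = FALSE)
  expect_false(ann2$qc_pass)
  expect_equal(ann2$qc_reason, "J upstream of V")
})

test_that("V-J overlaps resolve at the midpoint, upstream keeping the odd base", {
  set.seed(123)
  X <- random_dna(120); Y <- random_dna(40)
  for (ov in c(10L, 9L)) {
    M <- random_dna(ov)
    refs <- reference_set(c("VO1", "JO1"), "kappa", c("V", "J"),
                          c(paste0(X, M), paste0(M, Y)),
                          anchor = c(100L, ov + 5L))
    read <- c(r1 = paste0(X, M, Y))
    ann <- annotate_repertoire(read, refs, "kappa")
    keep_up <- as.integer(ceiling(ov / 2))
    expect_equal(ann$v_exo3, ov - keep_up)   # V keeps the extra base
    expect_equal(ann$j_exo5, keep_up)
    expect_equal(ann$v_qend, ann$j_qstart)   # spans no longer overlap
    expect_equal(ann$vd_n, "")               # nothing left in the junction
  }
})

test_that("segment spans and junctions tile the read exactly", {
  refs <- heavy_refs()
  sim <- simulate_repertoire(simulation_config(refs, n = 50, chain = "heavy",
                                               seed = 203))
  ann <- annotate_repertoire(sim$reads, refs, "heavy")
  for (i in seq_len(nrow(ann))) {
    a <- ann[i, ]
    read <- sim$reads[[a$read_id]]
    expect_true(a$v_qstart < a$v_qend)
    expect_true(a$v_qend <= a$d_qstart)
    expect_true(a$d_qend <= a$j_qstart)
    vd <- substr(read, a$v_qend + 1L, a$d_qstart)
    dj <- substr(read, a$d_qend + 1L, a$j_qstart)
    expect_equal(paste0(a$vd_p_left, a$vd_n, a$vd_p_right), vd)
    expect_equal(paste0(a$dj_p_left, a$dj_n, a$dj_p_right), dj)
    # P is impossible at a trimmed end
    if (a$v_exo3 > 0) expect_equal(a$vd_p_left, "")
    if (a$d_exo5 > 0) expect_equal(a$vd_p_right, "")
    if (a$d_exo3 > 0) expect_equal(a$dj_p_left, "")
    if (a$j_exo5 > 0) expect_equal(a$dj_p_right, "")
  }
})

test_that("high-exonuclease flag fires strictly above the threshold", {
  ann <- fake_annotations(n = 3, d_exo5 = c(30L, 29L, 0L))
  expect_equal(flag_high_exonuclease(ann), c(TRUE, FALSE, FALSE))
  ann$d_gene <- NA_character_
  expect_equal(flag_high_exonuclease(ann), c(FALSE, FALSE, FALSE))
  ann2 <- fake_annotations(n = 2, d_exo3 = c(35L, 12L))
  expect_equal(flag_high_exonuclease(ann2), c(TRUE, FALSE))
})

test_that("reads not covering the whole CDR3 are filtered out", {
  refs <- heavy_refs()
  sim <- simulate_repertoire(simulation_config(refs, n = 10, chain = "heavy",
                                               seed = 71))
  reads <- sim$reads
  # truncate three reads inside the J conserved codon
  for (i in c(2, 5, 9)) {
    a <- sim$truth[i, ]
    reads[i] <- substr(reads[i], 1, a$cdr3_end + 1L)
  }
  ann <- annotate_repertoire(reads, refs, "heavy")
  kept <- filter_covering_cdr3(ann, refs)
  expect_equal(nrow(kept), 7L)
  excl <- attr(kept, "excluded")
  expect_setequal(excl$read_id, sim$truth$read_id[c(2, 5, 9)])

  # missing anchors are a hard error naming the gene
  refs_na <- refs
  refs_na[refs_na$class == "J", "anchor"] <- NA_integer_
  expect_error(filter_covering_cdr3(ann, refs_na), "has no cdr3_anchor")
})

test_that("CDR3 span matches the simulated truth", {
  refs <- heavy_refs()
  sim <- simulate_repertoire(simulation_config(refs, n = 40, chain = "heavy",
                                               seed = 88))
  ann <- annotate_repertoire(sim$reads, refs, "heavy")
  ok <- !is.na(sim$truth$cdr3_start)
  expect_gt(sum(ok), 30)
  expect_equal(ann$cdr3_start[ok], sim$truth$cdr3_start[ok])
  expect_equal(ann$cdr3_end[ok], sim$truth$cdr3_end[ok])
  expect_equal(ann$cdr3_len[ok], sim$truth$cdr3_len[ok])
})
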