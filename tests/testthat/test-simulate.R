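test_that("degenerate configuration yields exact concatenations", {
  refs <- heavy_refs()
  cfg <- simulation_config(refs, n = 5, chain = "heavy", seed = 3,
                           trim_mean = c(v3 = 0, d5 = 0, d3 = 0, j5 = 0),
                           n_pi0 = c(vd = 1, dj = 1, vj = 1), p_prob = 0)
  sim <- simulate_repertoire(cfg)
  for (i in 1:5) {
    tr <- sim$truth[i, ]
    expect_equal(sim$reads[[i]],
                 paste0(get_segment(refs, tr$v_gene)$sequence,
                        get_segment(refs, tr$d_gene)$sequence,
                        get_segment(refs, tr$j_gene)$sequence))
  }
  expect_true(all(sim$truth$v_exo3 == 0 & nchar(sim$truth$vd_n) == 0))
})

test_that("the same seed reproduces the repertoire byte for byte", {
  refs <- heavy_refs()
  cfg <- simulation_config(refs, n = 30, chain = "heavy", seed = 17)
  s1 <- simulate_repertoire(cfg)
  s2 <- simulate_repertoire(cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_repertoire(simulation_config(refs, n = 30, chain = "heavy",
                                              seed = 18))
  expect_false(identical(s1$reads, s3$reads))
})

test_that("truth records reconstruct every emitted sequence", {
  refs <- heavy_refs()
  sim <- simulate_repertoire(simulation_config(refs, n = 40, chain = "heavy",
                                               seed = 23))
  for (i in seq_len(40)) {
    tr <- sim$truth[i, ]
    v <- get_segment(refs, tr$v_gene)$sequence
    d <- get_segment(refs, tr$d_gene)$sequence
    j <- get_segment(refs, tr$j_gene)$sequence
    rebuilt <- paste0(
      substr(v, 1, nchar(v) - tr$v_exo3),
      tr$vd_p_left, tr$vd_n, tr$vd_p_right,
      substr(d, tr$d_exo5 + 1, nchar(d) - tr$d_exo3),
      tr$dj_p_left, tr$dj_n, tr$dj_p_right,
      substr(j, tr$j_exo5 + 1, nchar(j)))
    expect_equal(rebuilt, sim$reads[[i]])
    # truth P strings obey the reverse-complement rule
    if (nchar(tr$vd_p_left) > 0) {
      k <- nchar(tr$vd_p_left)
      end <- substr(v, nchar(v) - k + 1, nchar(v))
      expect_equal(tr$vd_p_left, revcomp(end))
      expect_equal(tr$v_exo3, 0L)
    }
  }
})

test_that("hurdle-geometric N lengths match their analytic moments", {
  refs <- heavy_refs()
  ## identifiability resampling conditions the draws, so distributional
  ## fidelity is asserted on the unconstrained generator
  sim <- simulate_repertoire(simulation_config(refs, n = 800, chain = "heavy",
                                               seed = 47, identifiable = FALSE))
  nvd <- nchar(sim$truth$vd_n)
  # analytic values for pi0 = 0.35, q = 0.26: mean 2.5, F(0) = 0.35,
  # F(1) = 0.35 + 0.65 * 0.26 = 0.519 (hence a population median of 1)
  mean_an <- 0.65 * (1 + (1 - 0.26) / 0.26)
  se <- sd(nvd) / sqrt(length(nvd))
  expect_lt(abs(mean(nvd) - mean_an), 3 * se)
  bin_se <- function(p) sqrt(p * (1 - p) / 800)
  expect_lt(abs(mean(nvd == 0) - 0.35), 3 * bin_se(0.35))
  expect_lt(abs(mean(nvd <= 1) - 0.519), 3 * bin_se(0.519))
  ndj <- nchar(sim$truth$dj_n)
  expect_lt(abs(mean(ndj == 0) - 0.32), 3 * bin_se(0.32))  # pi0 = 0.32
  # ~90% of reads carry N somewhere (1 - 0.35 * 0.32 = 0.888)
  with_n <- mean(nvd > 0 | ndj > 0)
  expect_lt(abs(with_n - 0.888), 3 * bin_se(0.888))
})

test_that("mutation noise is applied at the configured rate", {
  refs <- heavy_refs()
  ## identifiability off so the two runs share every draw before the
  ## mutation step and differ only by the substitutions themselves
  cfg0 <- simulation_config(refs, n = 20, chain = "heavy", seed = 61,
                            identifiable = FALSE)
  cfg1 <- simulation_config(refs, n = 20, chain = "heavy", seed = 61,
                            mutation_rate = 0.02, identifiable = FALSE)
  s0 <- simulate_repertoire(cfg0)
  s1 <- simulate_repertoire(cfg1)
  diffs <- sum(mapply(function(a, b) {
    ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
    sum(ac != bc)
  }, s0$reads, s1$reads))
  total <- sum(nchar(s0$reads))
  expect_gt(diffs, 0)
  expect_lt(abs(diffs / total - 0.02), 3 * sqrt(0.02 * 0.98 / total))
})

test_that("invalid configurations are rejected", {
  refs <- heavy_refs()
  expect_error(simulation_config(refs, n = 5, chain = "heavy"),
               "seed is mandatory")
  expect_error(simulation_config(refs, n = 5, chain = "heavy", seed = 1,
                                 trim_mean = c(v3 = 3, d5 = 100, d3 = 9,
                                               j5 = 3)),
               "trimming mean exceeds")
  expect_error(simulation_config(refs, n = 5, chain = "heavy", seed = 1,
                                 n_base_probs = c(A = 1, C = 1, G = 0,
                                                  T = 0)),
               "sum to 1")
})

test_that("recovery report arithmetic and id checks", {
  refs <- heavy_refs()
  sim <- simulate_repertoire(simulation_config(refs, n = 50, chain = "heavy",
                                               seed = 73))
  ann <- annotate_repertoire(sim$reads, refs, "heavy")
  rec <- recovery_report(sim$truth, ann)
  expect_true(all(rec$accuracy == 100))

  ann_bad <- ann
  wrong <- setdiff(unique(refs$id[refs$class == "D"]), ann_bad$d_gene[1])[1]
  ann_bad$d_gene[1] <- wrong
  rec2 <- recovery_report(sim$truth, ann_bad)
  expect_equal(unname(rec2$accuracy["d_gene"]), 98)  # 49/50

  ann_missing <- ann[-1, ]
  expect_error(recovery_report(sim$truth, ann_missing), "read ids differ")
})

test_that("reconstruction inverts the junction decomposition", {
  refs <- heavy_refs()
  sim <- simulate_repertoire(simulation_config(refs, n = 25, chain = "heavy",
                                               seed = 101))
  tr <- sim$truth
  tab <- data.frame(
    v_seq = vapply(seq_len(nrow(tr)), function(i) {
      v <- get_segment(refs, tr$v_gene[i])$sequence
      substr(v, 1, nchar(v) - tr$v_exo3[i])
    }, ""),
    vd_p_left = tr$vd_p_left, vd_n = tr$vd_n, vd_p_right = tr$vd_p_right,
    d_seq = vapply(seq_len(nrow(tr)), function(i) {
      d <- get_segment(refs, tr$d_gene[i])$sequence
      substr(d, tr$d_exo5[i] + 1, nchar(d) - tr$d_exo3[i])
    }, ""),
    dj_p_left = tr$dj_p_left, dj_n = tr$dj_n, dj_p_right = tr$dj_p_right,
    j_seq = vapply(seq_len(nrow(tr)), function(i) {
      j <- get_segment(refs, tr$j_gene[i])$sequence
      substr(j, tr$j_exo5[i] + 1, nchar(j))
    }, ""),
    stringsAsFactors = FALSE)
  expect_equal(reconstruct_reads(tab), unname(sim$reads))
})
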