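test_that("total-abundance normalization equalizes columns and preserves proportions", {
  ab <- tibble::tibble(protein_id = c("p1", "p2"), s1 = c(1, 3), s2 = c(2, 6))
  out <- normalize_total_abundance(ab)
  # totals 4 and 8 -> both scaled to their mean, 6
  expect_equal(out$s1, c(1.5, 4.5))
  expect_equal(out$s2, c(1.5, 4.5))
  # idempotent on already equal-total input
  expect_equal(normalize_total_abundance(out), out)
  # single sample: total equals the mean of totals, values unchanged
  one <- tibble::tibble(protein_id = c("p1", "p2"), s1 = c(2, 5))
  expect_equal(normalize_total_abundance(one), one)
  # proportions preserved, totals equal within 1e-9 relative
  set.seed(1)
  big <- tibble::as_tibble(cbind(
    data.frame(protein_id = sprintf("p%d", 1:20)),
    as.data.frame(matrix(rexp(20 * 5), 20, 5, dimnames = list(NULL, paste0("s", 1:5))))))
  nb <- normalize_total_abundance(big)
  for (s in paste0("s", 1:5)) {
    expect_equal(nb[[s]] / sum(nb[[s]]), big[[s]] / sum(big[[s]]), tolerance = 1e-12)
  }
  tot <- colSums(as.matrix(nb[-1]))
  expect_lt(diff(range(tot)) / mean(tot), 1e-9)
  # zero column rejected, naming the sample
  bad <- tibble::tibble(protein_id = "p1", s1 = 0, s2 = 1)
  expect_error(normalize_total_abundance(bad), "s1", class = "polarscope_zero_total")
})

test_that("control-referenced log2 fold change follows the literal formula", {
  fix <- tiny_abundance()
  # p1: 2 / 1 -> 1; p2: 6 / 3 -> 1 after normalization ... use unnormalized direct values
  ab <- tibble::tibble(protein_id = c("a", "b"), c1 = c(1, 2), s1 = c(4, 2))
  fc <- log2_fold_change_vs_control(ab, tibble::tibble(
    sample_id = c("c1", "s1"), subtype = c("M0", "M1"),
    donor = "d1", is_control = c(TRUE, FALSE)))
  expect_equal(fc$s1, c(log2(4), 0))
  expect_false(is_centered(fc))
  # zero control mean: dropped and reported
  ab0 <- tibble::tibble(protein_id = c("a", "b"), c1 = c(0, 2), s1 = c(4, 2))
  expect_message(
    fc0 <- log2_fold_change_vs_control(ab0, tibble::tibble(
      sample_id = c("c1", "s1"), subtype = c("M0", "M1"),
      donor = "d1", is_control = c(TRUE, FALSE))),
    "zero control mean")
  expect_equal(fc0$protein_id, "b")
  expect_equal(dropped_proteins(fc0), "a")
  # no controls rejected
  expect_error(
    log2_fold_change_vs_control(ab, tibble::tibble(
      sample_id = c("c1", "s1"), subtype = c("M1", "M1"),
      donor = "d1", is_control = c(FALSE, FALSE))),
    class = "polarscope_no_controls")
})

test_that("median centering zeroes every column median exactly once", {
  ab <- tibble::tibble(protein_id = c("a", "b", "c"),
                       c1 = c(1, 1, 1), s1 = c(2, 4, 8))
  des <- tibble::tibble(sample_id = c("c1", "s1"), subtype = c("M0", "M1"),
                        donor = "d1", is_control = c(TRUE, FALSE))
  fc <- log2_fold_change_vs_control(ab, des)
  # column [1, 2, 3] -> [-1, 0, 1]
  expect_equal(fc$s1, c(1, 2, 3))
  cen <- median_center(fc)
  expect_equal(cen$s1, c(-1, 0, 1))
  expect_true(is_centered(cen))
  expect_lt(abs(stats::median(cen$s1)), 1e-9)
  # centering twice is an error
  expect_error(median_center(cen), class = "polarscope_already_centered")
})

test_that("subtype means average donors and flag partial coverage", {
  des <- tibble::tibble(sample_id = c("c1", "m1_a", "m1_b"),
                        subtype = c("M0", "M1", "M1"),
                        donor = c("d1", "d1", "d2"),
                        is_control = c(TRUE, FALSE, FALSE))
  ab <- tibble::tibble(protein_id = c("a", "b"), c1 = c(1, 1),
                       m1_a = c(2, 4), m1_b = c(8, NA))
  fc <- log2_fold_change_vs_control(ab, des)
  m <- mean_by_subtype(fc, des)
  expect_equal(m$M1, c((1 + 3) / 2, 2))       # mean of finite replicates
  inc <- incomplete_means(m)
  expect_equal(inc$protein_id, "b")
  expect_equal(inc$n_finite, 1)
  # unmapped fold-change sample rejected with its name
  expect_error(mean_by_subtype(fc, des[-2, ]), "m1_a",
               class = "polarscope_unmapped_sample")
})

test_that("the full chain matches a literal brute-force recomputation", {
  for (seed in 1:3) {
    set.seed(seed)
    values <- matrix(rexp(10 * 6, rate = 1 / 100), 10, 6,
                     dimnames = list(sprintf("p%d", 1:10), sprintf("s%d", 1:6)))
    design <- tibble::tibble(
      sample_id = sprintf("s%d", 1:6),
      subtype = c("M0", "M0", "M1", "M1", "M2a", "M2a"),
      donor = rep(c("d1", "d2"), 3),
      is_control = c(TRUE, TRUE, rep(FALSE, 4)))
    ab <- tibble::as_tibble(cbind(data.frame(protein_id = rownames(values)),
                                  as.data.frame(values)))
    res <- run_proteome_pipeline(ab, design)
    oracle <- brute_force_chain(values, design)
    expect_equal(unname(as.matrix(res$subtype_means[colnames(oracle$means)])),
                 unname(oracle$means), tolerance = 1e-12)
  }
})

test_that("per-sample rescaling leaves all downstream log2FC unchanged", {
  set.seed(42)
  values <- matrix(rexp(12 * 6, rate = 1 / 50), 12, 6,
                   dimnames = list(sprintf("p%d", 1:12), sprintf("s%d", 1:6)))
  design <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                           subtype = c("M0", "M0", "M1", "M1", "M2c", "M2c"),
                           donor = rep(c("d1", "d2"), 3),
                           is_control = c(TRUE, TRUE, rep(FALSE, 4)))
  ab <- tibble::as_tibble(cbind(data.frame(protein_id = rownames(values)),
                                as.data.frame(values)))
  scaled <- ab
  scaled$s1 <- scaled$s1 * 7.3
  scaled$s4 <- scaled$s4 * 0.002
  r1 <- run_proteome_pipeline(ab, design)
  r2 <- run_proteome_pipeline(scaled, design)
  expect_equal(as.matrix(r1$fc[-1]), as.matrix(r2$fc[-1]), tolerance = 1e-9)
  expect_equal(r1$subtype_means, r2$subtype_means, tolerance = 1e-9)
})
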