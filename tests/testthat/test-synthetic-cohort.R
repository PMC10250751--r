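# Forward simulators: stated forward models, ground-truth labelling,
# determinism.

test_that("gen_snp_profile implements the LRR/BAF forward model", {
  # identity case: diploid, no contamination, no noise
  sp <- genome_spec(data.frame(chrom = "chr1", start = 1, end = 20e6,
                               major = 1, minor = 1),
                    lrr_sd = 0, baf_sd = 0, snp_spacing = 5e5)
  snp <- gen_snp_profile(sp, seed = 1)
  expect_equal(snp$lrr, rep(0, nrow(snp)))
  expect_true(all(snp$baf[snp$het] == 0.5))
  expect_true(all(snp$baf[!snp$het] %in% c(0, 1)))

  # one (2,1) segment on a diploid background: LRR offset by the
  # length-weighted mean total, het BAF at 1/3 or 2/3
  segs <- data.frame(chrom = c("chr1", "chr1"), start = c(1, 30e6 + 1),
                     end = c(30e6, 40e6), major = c(1, 2), minor = c(1, 1))
  sp2 <- genome_spec(segs, lrr_sd = 0, baf_sd = 0, snp_spacing = 5e5)
  snp2 <- gen_snp_profile(sp2, seed = 2)
  psi <- (30e6 * 2 + 10e6 * 3) / 40e6
  expect_equal(attr(snp2, "psi"), psi)
  g <- snp2[snp2$true_seg == 2, ]
  expect_equal(unique(g$lrr), log2(3 / 2) - log2(psi / 2))
  expect_true(all(g$baf[g$het] %in% c(1 / 3, 2 / 3)))
  expect_true(all(c(1 / 3, 2 / 3) %in% g$baf[g$het])) # both mirror images

  # (1,0) at contamination 0.5: (0.5 + 0)/(1 + 0.5) = 1/3 or mirror
  sp3 <- genome_spec(data.frame(chrom = "chr1", start = 1, end = 20e6,
                                major = 1, minor = 0),
                     contamination = 0.5, lrr_sd = 0, baf_sd = 0,
                     snp_spacing = 5e5)
  snp3 <- gen_snp_profile(sp3, seed = 3)
  expect_true(all(abs(snp3$baf[snp3$het] - 1 / 3) < 1e-12 |
                    abs(snp3$baf[snp3$het] - 2 / 3) < 1e-12))
})

test_that("gen_snp_profile rejects unidentifiable inputs", {
  segs <- data.frame(chrom = "chr1", start = 1, end = 1e6,
                     major = 1, minor = 1)
  expect_error(genome_spec(segs, contamination = 0.95), "contamination")
  sp0 <- genome_spec(data.frame(chrom = "chr1", start = 1, end = 1e6,
                                major = 0, minor = 0))
  expect_error(gen_snp_profile(sp0, seed = 1), "zero total copies")
})

test_that("SNP and coverage generators are pure functions of (spec, seed)", {
  sp <- random_genome_spec(3, 0.2, seed = 9)
  expect_identical(gen_snp_profile(sp, seed = 4), gen_snp_profile(sp, seed = 4))
  expect_identical(gen_coverage_bins(sp, 1e6, seed = 4),
                   gen_coverage_bins(sp, 1e6, seed = 4))
  expect_false(identical(gen_snp_profile(sp, seed = 4)$lrr,
                         gen_snp_profile(sp, seed = 5)$lrr))
})

test_that("gen_coverage_bins emits centered contaminated log ratios", {
  sp <- genome_spec(data.frame(chrom = "chr1", start = 1, end = 20e6,
                               major = 1, minor = 1),
                    lrr_sd = 0, snp_spacing = 5e5)
  expect_equal(gen_coverage_bins(sp, 1e6, seed = 1)$log_ratio,
               rep(0, 20))

  # homozygous deletion under 10% contamination: log2(0.2/2) = -3.32
  # before centering; on a mostly diploid genome the center is 0
  segs <- rbind(data.frame(chrom = "chr1", start = 1, end = 50e6,
                           major = 1, minor = 1),
                data.frame(chrom = "chr1", start = 50e6 + 1, end = 52e6,
                           major = 0, minor = 0))
  sp2 <- genome_spec(segs, contamination = 0.1, lrr_sd = 0)
  cov <- gen_coverage_bins(sp2, 1e6, seed = 1)
  expect_equal(unique(cov$log_ratio[cov$true_total == 0]),
               log2(0.2 / 2), tolerance = 1e-12)

  # high amplification (8,1), no contamination: log2(9/2) = 2.17
  segs3 <- rbind(data.frame(chrom = "chr1", start = 1, end = 50e6,
                            major = 1, minor = 1),
                 data.frame(chrom = "chr1", start = 50e6 + 1, end = 52e6,
                            major = 8, minor = 1))
  cov3 <- gen_coverage_bins(genome_spec(segs3, lrr_sd = 0), 1e6, seed = 1)
  expect_equal(unique(cov3$log_ratio[cov3$true_total == 9]), log2(9 / 2),
               tolerance = 1e-12)
})

test_that("gen_variant_table labels pass/fail by construction", {
  expect_equal(nrow(gen_variant_table(0, 0, seed = 1)), 0)

  tab <- gen_variant_table(10, 1, seed = 1)
  expect_equal(nrow(tab), 16)
  expect_equal(sum(tab$truth_pass), 10)

  tab2 <- gen_variant_table(0, 2, seed = 2)
  expect_equal(nrow(tab2), 12)
  expect_equal(sum(tab2$truth_pass), 0)
  expect_equal(unname(table(tab2$truth_fail_rule)[c("qss", "depth", "vaf",
                                                    "gnomad", "inhouse",
                                                    "coding")]),
               rep(2L, 6), ignore_attr = TRUE)

  expect_identical(gen_variant_table(5, 2, seed = 7),
                   gen_variant_table(5, 2, seed = 7))

  # each failing record violates exactly its designated rule
  t <- filter_thresholds()
  viol <- function(d) {
    cbind(qss = d$qss < t$qss_min,
          depth = d$tumor_depth < t$depth_min,
          vaf = d$vaf_t < t$vaf_min | d$alt_reads < t$alt_reads_min,
          gnomad = d$gnomad_global_af >= t$gnomad_max,
          inhouse = d$inhouse_af >= t$inhouse_max,
          coding = !d$coding)
  }
  v <- viol(tab2)
  for (r in seq_len(nrow(tab2))) {
    expect_equal(names(which(v[r, ])), tab2$truth_fail_rule[r])
  }
})

test_that("gen_growth_study follows the exponential growth world", {
  # no treatment effect, no noise: arm mean curves identical
  d <- growth_study_design(n_per_arm = 50, treatment_effect = 1,
                           noise_cv = 0, ethical_volume = 1e9, max_day = 21,
                           seed = 1)
  st <- gen_growth_study(d)
  tv <- tumor_volume(st$length_mm, st$width_mm)
  m <- tapply(tv, list(st$arm, st$day), mean)
  expect_equal(unname(m["treated", ]) / unname(m["vehicle", ]),
               rep(1, ncol(m)), tolerance = 0.15) # finite-sample v0 draw

  # noise-free volumes are exactly V0 exp(k t)
  d2 <- growth_study_design(n_per_arm = 3, treatment_effect = -1,
                            noise_cv = 0, ethical_volume = 1e9,
                            max_day = 21, seed = 2)
  st2 <- gen_growth_study(d2)
  st2$tv <- tumor_volume(st2$length_mm, st2$width_mm)
  truth <- attr(st2, "truth")
  for (an in truth$animal) {
    rows <- st2[st2$animal == an, ]
    tr <- truth[truth$animal == an, ]
    expect_equal(rows$tv, tr$v0 * exp(tr$rate * rows$day),
                 tolerance = 1e-9)
  }
  # negative treated rate: strictly decreasing volumes
  tre <- st2[st2$arm == "treated", ]
  for (an in unique(tre$animal)) {
    expect_true(all(diff(tre$tv[tre$animal == an]) < 0))
  }

  expect_identical(gen_growth_study(d2), gen_growth_study(d2))

  # ethical censoring at generation: all days beyond the first
  # cap-exceeding measurement are dropped
  d3 <- growth_study_design(n_per_arm = 4, growth_rate = 0.2,
                            noise_cv = 0, ethical_volume = 1500,
                            max_day = 60, seed = 3)
  st3 <- gen_growth_study(d3)
  expect_false(is.na(attr(st3, "stop_day")))
  expect_true(max(st3$day) == attr(st3, "stop_day"))
  expect_true(max(st3$day) < 60)
})

test_that("gen_str_profiles controls allele divergence exactly", {
  p0 <- gen_str_profiles(16, 0, seed = 1)
  expect_equal(attr(p0, "expected_tanabe"), 100)
  expect_equal(match_score(p0$a, p0$b), 100)

  pall <- gen_str_profiles(16, 32, seed = 1)
  expect_equal(match_score(pall$a, pall$b), 0)

  p4 <- gen_str_profiles(16, 4, seed = 1)
  expect_equal(attr(p4, "expected_tanabe"), 87.5)
  expect_equal(match_score(p4$a, p4$b), 87.5)

  expect_error(gen_str_profiles(16, 33, seed = 1))

  pA <- gen_str_profiles(16, 2, seed = 5, include_amelogenin = TRUE)
  expect_true("AMEL" %in% names(pA$a$loci))
  expect_equal(match_score(pA$a, pA$b), attr(pA, "expected_tanabe"))
})

test_that("gen_expression produces a recoverable two-cluster world", {
  ex <- gen_expression(n_genes = 500, samples_per_cluster = c(3, 3),
                       n_signature_genes = 50, effect_log2fc = 4, seed = 1)
  expect_equal(dim(ex$counts), c(500, 6))
  expect_true(all(ex$length_kb > 0))
  expect_equal(unname(ex$cluster), rep(1:2, each = 3))
  expect_identical(ex$counts,
                   gen_expression(500, c(3, 3), 50, 4, seed = 1)$counts)

  # zero effect: signature genes do not separate the clusters beyond noise
  ex0 <- gen_expression(n_genes = 500, samples_per_cluster = c(4, 4),
                        n_signature_genes = 50, effect_log2fc = 0, seed = 2)
  lt <- log2(tpm_normalize(ex0$counts, ex0$length_kb) + 1)
  d <- rowMeans(lt[ex0$signature_genes, ex0$cluster == 2]) -
    rowMeans(lt[ex0$signature_genes, ex0$cluster == 1])
  expect_lt(max(abs(d)), 2.5) # well below any real effect size
  expect_lt(abs(mean(d)), 0.3)
})
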