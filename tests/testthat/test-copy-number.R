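# Allele-specific copy-number reconstruction: segmentation geometry,
# ploidy/contamination fit, threshold calls, aberration summaries.

test_that("segment_profile recovers segment geometry from both signals", {
  # uniform diploid: one segment per chromosome
  sp <- genome_spec(data.frame(chrom = c("chr1", "chr2"), start = 1,
                               end = 30e6, major = 1, minor = 1),
                    lrr_sd = 0.1, baf_sd = 0.02, snp_spacing = 3e5)
  segs <- segment_profile(gen_snp_profile(sp, seed = 1), n_perm = 300,
                          seed = 1)
  expect_equal(nrow(segs), 2)

  # a gain moves LRR and mBAF together: one merged breakpoint
  sp2 <- genome_spec(chrom_segs("chr1", c(0, 30e6, 60e6), c(1, 2), c(1, 1)),
                     lrr_sd = 0, baf_sd = 0, snp_spacing = 2e5)
  segs2 <- segment_profile(gen_snp_profile(sp2, seed = 2), n_perm = 300,
                           seed = 2)
  expect_equal(nrow(segs2), 2)
  expect_equal(segs2$mean_mbaf, c(0.5, 2 / 3), tolerance = 1e-9)

  # copy-neutral LOH is LRR-silent: the breakpoint comes from mBAF alone
  sp3 <- genome_spec(chrom_segs("chr1", c(0, 30e6, 60e6), c(1, 2), c(1, 0)),
                     lrr_sd = 0, baf_sd = 0, snp_spacing = 2e5)
  snp3 <- gen_snp_profile(sp3, seed = 3)
  expect_equal(length(unique(round(snp3$lrr, 9))), 1) # no LRR signal
  segs3 <- segment_profile(snp3, n_perm = 300, seed = 3)
  expect_equal(nrow(segs3), 2)
  expect_equal(segs3$mean_mbaf, c(0.5, 1), tolerance = 1e-9)
})

test_that("segment_profile works on chromosomes without heterozygous sites", {
  sp <- genome_spec(data.frame(chrom = "chr1", start = 1, end = 30e6,
                               major = 2, minor = 1),
                    lrr_sd = 0, baf_sd = 0, snp_spacing = 3e5,
                    het_fraction = 0)
  segs <- segment_profile(gen_snp_profile(sp, seed = 1), seed = 1)
  expect_equal(nrow(segs), 1)
  expect_true(is.na(segs$mean_mbaf))
})

test_that("noise-free profiles invert exactly for c in {0, 0.2, 0.4}", {
  for (cc in c(0, 0.2, 0.4)) {
    spec <- random_genome_spec(2, cc, seed = 100 + round(100 * cc),
                               lrr_sd = 0, baf_sd = 0, snp_spacing = 4e5)
    snp <- gen_snp_profile(spec, seed = 50)
    segs <- segment_profile(snp, n_perm = 300, seed = 51)
    fit <- gap_fit(segs, lrr_sd = 0, baf_sd = 0)
    expect_equal(fit$fit$contamination, cc, tolerance = 0.01)
    expect_equal(fit$fit$ploidy, 2)
    # per-segment states recovered exactly. Fitted boundaries can sit
    # anywhere inside the heterozygote-free gap around a true boundary, so
    # a few homozygous edge sites may cross over: compare against the
    # majority true state of the fitted segment.
    called <- call_allelic(fit$segments, fit$fit)
    majority <- function(x) as.integer(names(which.max(table(x))))
    for (r in seq_len(nrow(called))) {
      sel <- snp$chrom == called$chrom[r] & snp$pos >= called$start[r] &
        snp$pos <= called$end[r]
      expect_equal(called$major[r], majority(snp$true_major[sel]))
      expect_equal(called$minor[r], majority(snp$true_minor[sel]))
    }
    # LOH called exactly where the true minor copy is zero
    expect_equal(called$loh, called$minor == 0 & called$n_het >= 3)
  }
})

test_that("ploidy ambiguity resolves toward the lower solution", {
  sp4 <- genome_spec(data.frame(chrom = c("chr1", "chr2"), start = 1,
                                end = 40e6, major = 2, minor = 2),
                     lrr_sd = 0, baf_sd = 0, snp_spacing = 4e5)
  fit <- gap_fit(segment_profile(gen_snp_profile(sp4, 1), seed = 1),
                 lrr_sd = 0, baf_sd = 0)
  expect_equal(fit$fit$ploidy, 2) # Occam default, no allelic evidence
  expect_true(fit$fit$ambiguous)

  # an anchored tetraploid genome is identifiable and unambiguous
  spec <- random_genome_spec(4, 0.2, seed = 77, lrr_sd = 0, baf_sd = 0,
                             snp_spacing = 4e5)
  fit4 <- gap_fit(segment_profile(gen_snp_profile(spec, 2), n_perm = 300,
                                  seed = 3), lrr_sd = 0, baf_sd = 0)
  expect_equal(fit4$fit$ploidy, 4)
  expect_equal(fit4$fit$contamination, 0.2, tolerance = 0.01)
  expect_false(fit4$fit$ambiguous)
})

test_that("allelic status thresholds follow the ploidy +/- 0.5 rule", {
  segs <- data.frame(chrom = "chr1", start = c(1, 2, 3), end = c(10, 20, 30),
                     total = c(3, 2, 1), minor = c(1, 0, 0),
                     n_het = c(10, 10, 1))
  fit2 <- structure(list(ploidy = 2), class = "ploidy_fit")
  called <- call_allelic(segs, fit2)
  expect_equal(called$status, c("gain", "neutral", "loss"))
  # copy-neutral LOH: neutral status with loh flag (given het support)
  expect_equal(called$loh, c(FALSE, TRUE, FALSE)) # 3rd lacks het support

  fit4 <- structure(list(ploidy = 4), class = "ploidy_fit")
  seg36 <- data.frame(chrom = "c", start = 1, end = 2, total = 3.6,
                      minor = 1, n_het = 5)
  expect_equal(call_allelic(seg36, fit4)$status, "neutral")

  # scale consistency: +1 on every total and on ploidy leaves status fixed
  shifted <- segs
  shifted$total <- shifted$total + 1
  fit3 <- structure(list(ploidy = 3), class = "ploidy_fit")
  expect_equal(call_allelic(shifted, fit3)$status, called$status)
})

test_that("coverage calls implement zero-level and 5-sd rules", {
  # flat profile: zero level at 0, no calls
  set.seed(5)
  flat <- data.frame(chrom = "chr1", start = seq(1, by = 1e5, length = 150),
                     end = seq(1e5, by = 1e5, length = 150),
                     log_ratio = rnorm(150, 0, 0.02))
  cc <- call_coverage(flat, n_perm = 300, seed = 1)
  expect_equal(cc$zero_level, 0, tolerance = 0.02)
  expect_true(all(cc$segments$call == "neutral"))

  # +0.4 segment with normal sd 0.05: gain AND high amplification
  set.seed(6)
  lr <- c(rnorm(150, 0, 0.05), rnorm(30, 0.4, 0.05))
  amp <- data.frame(chrom = "chr1",
                    start = seq(1, by = 1e5, length = 180),
                    end = seq(1e5, by = 1e5, length = 180), log_ratio = lr)
  ca <- call_coverage(amp, n_perm = 300, seed = 2)
  hot <- ca$segments[ca$segments$start > 150e5, ]
  expect_true(all(hot$gain))
  expect_true(all(hot$high_amplification))
  expect_equal(ca$segments$call[1], "neutral")

  # homozygous deletion from the generator forward model (c = 0.1)
  segs <- rbind(data.frame(chrom = "chr1", start = 1, end = 30e6,
                           major = 1, minor = 1),
                data.frame(chrom = "chr1", start = 30e6 + 1, end = 33e6,
                           major = 0, minor = 0))
  sp <- genome_spec(segs, contamination = 0.1, lrr_sd = 0.05)
  cov <- gen_coverage_bins(sp, 2e5, seed = 3)
  ch <- call_coverage(cov, n_perm = 300, seed = 3)
  del <- ch$segments[ch$segments$start > 30e6, ]
  expect_true(all(del$deletion))
  expect_true(all(del$homozygous_deletion))
})

test_that("aberration summaries compute FAG and FAA", {
  neutral <- data.frame(chrom = rep(c("chr1", "chr2"), each = 2),
                        start = c(1, 51, 1, 51), end = c(50, 100, 50, 100),
                        status = "neutral", loh = FALSE)
  s0 <- summarize_aberration(neutral,
                             data.frame(chrom = c("chr1", "chr2"),
                                        centromere = c(50, 50)))
  expect_equal(s0$fag, 0)
  expect_equal(s0$faa, 0)

  gained <- neutral
  gained$status <- "gain"
  s1 <- summarize_aberration(gained,
                             data.frame(chrom = c("chr1", "chr2"),
                                        centromere = c(50, 50)))
  expect_equal(s1$fag, 1)
  expect_equal(s1$faa, 1)

  # one arm 60% lost: FAA = 1 / (2 * n_chrom); LOH counts into FAG
  segs <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                     start = c(1, 31, 51, 1), end = c(30, 50, 100, 100),
                     status = c("loss", "neutral", "neutral", "neutral"),
                     loh = c(TRUE, FALSE, FALSE, FALSE))
  s2 <- summarize_aberration(segs,
                             data.frame(chrom = c("chr1", "chr2"),
                                        centromere = c(50, 50)))
  expect_equal(s2$faa, 1 / 4)
  expect_equal(s2$fag, 30 / 200)

  # without an arm table FAA is absent, FAG still computed
  s3 <- summarize_aberration(segs)
  expect_true(is.na(s3$faa))
  expect_equal(s3$fag, 30 / 200)
})
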