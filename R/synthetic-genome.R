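#' Specify a synthetic tumor genome
#'
#' A `genome_spec` states the ground truth a SNP-array-style profile or a
#' coverage-bin profile is simulated from: the allele-specific copy-number
#' segments of the tumor, the fraction of contaminating normal (diploid)
#' cells, and the noise levels of the measurement platform.
#'
#' @param segments data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive bp), `major`, `minor` (non-negative integer copies,
#'   `major >= minor`). Segments must not overlap within a chromosome.
#' @param contamination Fraction of normal cells in `[0, 0.95)`. At 0.95 and
#'   above the tumor signal is unidentifiable and the spec is rejected.
#' @param lrr_sd Standard deviation of Gaussian noise added to LRR values
#'   (and to coverage log ratios). The platform noise level is not a
#'   biological quantity; 0.15 is a realistic array-like default.
#' @param baf_sd Standard deviation of Gaussian noise on BAF values.
#' @param snp_spacing Distance in bp between consecutive simulated SNP sites.
#' @param het_fraction Fraction of SNP sites that are heterozygous in the
#'   germline, in `[0, 1]`.
#' @return An object of class `genome_spec`.
#' @seealso [gen_snp_profile()], [gen_coverage_bins()]
#' @examples
#' segs <- data.frame(chrom = "chr1", start = 1, end = 50e6,
#'                    major = 1, minor = 1)
#' genome_spec(segs, contamination = 0.2)
#' @export
genome_spec <- function(segments, contamination = 0, lrr_sd = 0.15,
                        baf_sd = 0.03, snp_spacing = 5e4,
                        het_fraction = 1 / 3) {
  required <- c("chrom", "start", "end", "major", "minor")
  if (!is.data.frame(segments) || !all(required %in% names(segments))) {
    stop("`segments` must be a data.frame with columns ",
         paste(required, collapse = ", "))
  }
  segments <- segments[required]
  if (any(segments$start >= segments$end)) {
    stop("segment start must be < end")
  }
  if (any(segments$major < 0 | segments$minor < 0 |
            segments$major < segments$minor)) {
    stop("segments require major >= minor >= 0")
  }
  if (any(segments$major != round(segments$major)) ||
        any(segments$minor != round(segments$minor))) {
    stop("copy numbers must be integers")
  }
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      stop("overlapping segments on ", ch)
    }
  }
  if (contamination < 0 || contamination >= 0.95) {
    stop("contamination must be in [0, 0.95): at 0.95 the tumor signal is ",
         "unidentifiable")
  }
  stopifnot(lrr_sd >= 0, baf_sd >= 0, snp_spacing > 0,
            het_fraction >= 0, het_fraction <= 1)
  structure(
    list(segments = segments, contamination = contamination,
         lrr_sd = lrr_sd, baf_sd = baf_sd, snp_spacing = snp_spacing,
         het_fraction = het_fraction),
    class = "genome_spec"
  )
}

# Length-weighted mean total copy number of the specified tumor genome
# (the "psi" used for array-style median centering of LRR).
spec_psi <- function(spec) {
  s <- spec$segments
  weighted_mean_(s$major + s$minor, s$end - s$start + 1)
}

# Total copy ratio of a segment relative to a diploid reference, after
# dilution by a fraction c of normal cells.
contaminated_ratio <- function(major, minor, c) {
  (2 * c + (1 - c) * (major + minor)) / 2
}

# Expected BAF at a heterozygous site carrying `b_copies` of the B allele
# out of a (major, minor) tumor genotype, under contamination c.
expected_baf <- function(b_copies, major, minor, c) {
  (c + (1 - c) * b_copies) / (2 * c + (1 - c) * (major + minor))
}

#' Simulate a SNP LRR/BAF profile from a genome specification
#'
#' Forward model: a segment with allele-specific copies (a, b) diluted by a
#' fraction c of normal cells has total copy ratio
#' `r = (2c + (1 - c)(a + b)) / 2`; the emitted LRR is
#' `log2(r) - log2(psi / 2) + noise`, where psi is the length-weighted mean
#' total copy number of the whole specified genome — this reproduces the
#' median centering an array pipeline applies. Heterozygous sites emit BAF
#' `(c + (1 - c) b) / (2c + (1 - c)(a + b))` or its mirror (a fair seeded
#' coin per site, since arrays do not phase), homozygous sites a clipped
#' normal around 0 or 1. Ground-truth copies are attached to every site.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed; the generator is a pure function of
#'   `(spec, seed)`.
#' @return data.frame with columns `chrom`, `pos`, `lrr`, `baf`, `het`, and
#'   ground-truth columns `true_major`, `true_minor`, `true_total`,
#'   `true_seg`. Attributes `psi` and `contamination` carry the simulation
#'   truth.
#' @examples
#' spec <- genome_spec(data.frame(chrom = "chr1", start = 1, end = 10e6,
#'                                major = 2, minor = 1),
#'                     lrr_sd = 0, baf_sd = 0, snp_spacing = 1e6)
#' head(gen_snp_profile(spec, seed = 1))
#' @export
gen_snp_profile <- function(spec, seed) {
  stopifnot(inherits(spec, "genome_spec"))
  segs <- spec$segments
  c <- spec$contamination
  if (any(segs$major + segs$minor == 0) && c == 0) {
    stop("segment with zero total copies and no contamination: ",
         "log ratio undefined")
  }
  psi <- spec_psi(spec)
  with_seed(seed, {
    out <- vector("list", nrow(segs))
    for (k in seq_len(nrow(segs))) {
      a <- segs$major[k]; b <- segs$minor[k]
      pos <- seq(segs$start[k], segs$end[k], by = spec$snp_spacing)
      n <- length(pos)
      het <- runif(n) < spec$het_fraction
      r <- contaminated_ratio(a, b, c)
      lrr <- log2(r) - log2(psi / 2) + rnorm(n, sd = spec$lrr_sd)
      baf <- numeric(n)
      if (any(het)) {
        nh <- sum(het)
        mirror <- rbinom(nh, 1, 0.5) == 1
        eb <- ifelse(mirror, expected_baf(a, a, b, c),
                     expected_baf(b, a, b, c))
        baf[het] <- clip01(eb + rnorm(nh, sd = spec$baf_sd))
      }
      if (any(!het)) {
        nh <- sum(!het)
        base <- rbinom(nh, 1, 0.5)
        baf[!het] <- clip01(base + rnorm(nh, sd = spec$baf_sd))
      }
      out[[k]] <- data.frame(
        chrom = segs$chrom[k], pos = pos, lrr = lrr, baf = baf, het = het,
        true_major = a, true_minor = b, true_total = a + b, true_seg = k
      )
    }
    res <- do.call(rbind, out)
    res <- res[order(match(res$chrom, unique(segs$chrom)), res$pos), ]
    rownames(res) <- NULL
    attr(res, "psi") <- psi
    attr(res, "contamination") <- c
    res
  })
}

#' Simulate exon-bait coverage log-ratio bins
#'
#' Each bin emits `log2((2c + (1 - c) T) / 2)` for segment total T under
#' contamination c, median-centered across the genome, plus Gaussian noise
#' (`lrr_sd` of the spec). This is the coverage-track counterpart of
#' [gen_snp_profile()]; it has no allelic information but a finer grid, and
#' is what the focal amplification / homozygous-deletion caller consumes.
#'
#' @param spec A [genome_spec()].
#' @param bin_size Bin width in bp (> 0).
#' @param seed Integer seed.
#' @return data.frame with `chrom`, `start`, `end`, `log_ratio` and
#'   ground-truth columns; attribute `center` holds the subtracted median.
#' @export
gen_coverage_bins <- function(spec, bin_size = 1e5, seed = 1) {
  stopifnot(inherits(spec, "genome_spec"), bin_size > 0)
  segs <- spec$segments
  c <- spec$contamination
  if (any(segs$major + segs$minor == 0) && c == 0) {
    stop("segment with zero total copies and no contamination: ",
         "log ratio undefined")
  }
  with_seed(seed, {
    out <- vector("list", nrow(segs))
    for (k in seq_len(nrow(segs))) {
      starts <- seq(segs$start[k], segs$end[k], by = bin_size)
      ends <- pmin(starts + bin_size - 1, segs$end[k])
      raw <- log2(contaminated_ratio(segs$major[k], segs$minor[k], c))
      out[[k]] <- data.frame(
        chrom = segs$chrom[k], start = starts, end = ends, raw = raw,
        true_major = segs$major[k], true_minor = segs$minor[k],
        true_total = segs$major[k] + segs$minor[k], true_seg = k
      )
    }
    res <- do.call(rbind, out)
    center <- median(res$raw)
    res$log_ratio <- res$raw - center + rnorm(nrow(res), sd = spec$lrr_sd)
    res$raw <- NULL
    res <- res[c("chrom", "start", "end", "log_ratio", "true_major",
                 "true_minor", "true_total", "true_seg")]
    res <- res[order(match(res$chrom, unique(segs$chrom)), res$start), ]
    rownames(res) <- NULL
    attr(res, "center") <- center
    res
  })
}
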