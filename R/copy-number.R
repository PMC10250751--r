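#' Segment a SNP LRR/BAF profile into homogeneous pieces
#'
#' Runs circular binary segmentation per chromosome on two signals: the LRR
#' of all sites and the mirrored BAF (`max(baf, 1 - baf)`) of heterozygous
#' sites only — homozygous sites carry no allelic information and are
#' excluded from the BAF track. Breakpoints from the two tracks are merged;
#' a BAF breakpoint is dropped when an LRR breakpoint falls in the same
#' heterozygote-free gap (both signals then mark the same boundary, which
#' the denser LRR track localizes better). A chromosome without enough
#' heterozygous sites is segmented on LRR alone and its `mean_mbaf` is NA.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `lrr`, `baf`, `het`
#'   (position-sorted within chromosome).
#' @param alpha,n_perm,min_width,seed CBS parameters, see [cbs_segment()].
#' @return data.frame of segments: `chrom`, `start`, `end`, `n_sites`,
#'   `n_het`, `mean_lrr`, `mean_mbaf` (NA without het support).
#' @examples
#' spec <- genome_spec(data.frame(chrom = "chr1", start = c(1, 20e6 + 1),
#'                                end = c(20e6, 40e6), major = c(1, 2),
#'                                minor = c(1, 1)),
#'                     lrr_sd = 0.1, baf_sd = 0.02, snp_spacing = 2e5)
#' segs <- segment_profile(gen_snp_profile(spec, seed = 1), seed = 1)
#' @export
segment_profile <- function(sites, alpha = 0.01, n_perm = 1000,
                            min_width = 3, seed = NULL) {
  required <- c("chrom", "pos", "lrr", "baf", "het")
  stopifnot(all(required %in% names(sites)))
  chroms <- unique(sites$chrom)
  out <- vector("list", length(chroms))
  seed_k <- function(k, track) {
    if (is.null(seed)) NULL else derive_seed(seed, paste0(track, k))
  }
  for (k in seq_along(chroms)) {
    s <- sites[sites$chrom == chroms[k], , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    n <- nrow(s)
    lrr_brk <- cbs_segment(s$pos, s$lrr, alpha, n_perm, min_width,
                           seed = seed_k(k, "lrr"))
    het_idx <- which(s$het)
    baf_brk <- integer(0)
    if (length(het_idx) >= 2 * min_width) {
      mbaf <- pmax(s$baf[het_idx], 1 - s$baf[het_idx])
      bh <- cbs_segment(s$pos[het_idx], mbaf, alpha, n_perm, min_width,
                        seed = seed_k(k, "baf"))
      # map het-track after-indices to full-site after-indices, then drop
      # BAF boundaries that share a heterozygote-free gap with an LRR one
      for (b in bh) {
        full <- het_idx[b]
        nxt_het <- if (b < length(het_idx)) het_idx[b + 1] else n + 1
        if (!any(lrr_brk >= full & lrr_brk < nxt_het)) {
          baf_brk <- c(baf_brk, full)
        }
      }
    }
    brk <- sort(unique(c(lrr_brk, baf_brk)))
    bounds <- c(0, brk, n)
    segs <- lapply(seq_len(length(bounds) - 1), function(i) {
      idx <- (bounds[i] + 1):bounds[i + 1]
      piece <- s[idx, , drop = FALSE]
      hets <- piece[piece$het, , drop = FALSE]
      data.frame(
        chrom = chroms[k], start = piece$pos[1],
        end = piece$pos[nrow(piece)], n_sites = nrow(piece),
        n_het = nrow(hets), mean_lrr = mean(piece$lrr),
        mean_mbaf = if (nrow(hets)) mean(pmax(hets$baf, 1 - hets$baf))
                    else NA_real_
      )
    })
    out[[k]] <- do.call(rbind, segs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Integer lattice of allele-specific states (major a >= minor m >= 0,
# a <= max_copies), ordered so that for equal fit the lower-total and, at
# equal total, the more balanced state wins deterministic tie-breaks.
asc_lattice <- function(max_copies) {
  g <- expand.grid(minor = 0:max_copies, major = 0:max_copies)
  g <- g[g$major >= g$minor, c("major", "minor")]
  g$total <- g$major + g$minor
  g <- g[order(g$total, -g$minor), ]
  rownames(g) <- NULL
  g
}

#' Joint ploidy / contamination / allele-specific copy-number fit
#'
#' Grid search in the spirit of Genome Alteration Print: for each candidate
#' contamination c and LRR offset, every segment is assigned the integer
#' lattice state (a, m) minimizing a noise-scaled squared distance between
#' the observed (mean LRR, mean mirrored BAF) and the model expectations
#' `LRR = log2((2c + (1-c)(a+m)) / 2) - offset`,
#' `mBAF = (c + (1-c) a) / (2c + (1-c)(a+m))`. The searched offset absorbs
#' both the array baseline shift and the `log2(psi/2)` centering term (psi =
#' length-weighted mean fitted total), which makes the model linear in one
#' free scalar; the centering term is backed out after the fit. The offset
#' is polished by closed-form re-estimation once assignments stabilize.
#' Ploidy is the length-weighted median of fitted totals.
#'
#' The model family carries exact degeneracies — multiplying every state by
#' an integer (whole-genome doubling) or subtracting one copy of each
#' allele, with matching contamination shifts, reproduces the data exactly.
#' The fit therefore canonicalizes its solution toward the lowest-ploidy
#' equivalent, which is what identifies real tumor profiles: an LOH segment
#' (minor 0) blocks the subtraction and an odd-copy state blocks the
#' division, so anchored profiles resolve uniquely. A profile that still
#' admits such a transform after canonicalization (all-balanced or LOH-free
#' genomes) is flagged `ambiguous`.
#'
#' @param segments Segment table from [segment_profile()].
#' @param max_copies Largest major copy number on the lattice (focal events
#'   beyond it belong to the coverage track).
#' @param c_grid Candidate contamination values.
#' @param b_window,b_step Search window and step for the LRR offset. The
#'   window must cover `log2(psi/2)` plus the baseline shift; the default
#'   `[-1, 3]` spans ploidies ~1-8 with a +/-1 baseline.
#' @param lrr_sd,baf_sd Per-site platform noise levels. Residuals are
#'   weighted by the resulting per-segment standard errors
#'   (`lrr_sd / sqrt(n_sites)`, `baf_sd / sqrt(n_het)`), so long
#'   well-supported segments constrain the fit sharply; the mBAF
#'   expectation is also corrected for the upward bias that mirroring
#'   inflicts on near-balanced segments (folded-normal mean).
#' @param min_het Minimum heterozygous sites for a segment's mBAF to enter
#'   the fit.
#' @return list with `fit` (class `ploidy_fit`: `ploidy`, `contamination`,
#'   `baseline_shift`, `fit_score`, `ambiguous`, `psi`) and `segments` (the
#'   input plus `major`, `minor`, `total`).
#' @export
gap_fit <- function(segments, max_copies = 8,
                    c_grid = seq(0, 0.94, by = 0.01),
                    b_window = c(-1, 3), b_step = 0.02,
                    lrr_sd = 0.15, baf_sd = 0.03, min_het = 3) {
  stopifnot(nrow(segments) >= 1, lrr_sd >= 0, baf_sd >= 0,
            all(c("mean_lrr", "mean_mbaf", "n_sites", "n_het", "start",
                  "end") %in% names(segments)))
  # noise-free inputs (sd 0) keep exact residuals: no fold correction, and
  # a tiny weighting floor stands in for the zero standard error
  lrr_eff <- max(lrr_sd, 1e-6)
  baf_eff <- max(baf_sd, 1e-6)
  lat <- asc_lattice(max_copies)
  w <- as.numeric(segments$end - segments$start + 1)
  w <- w / sum(w)
  use_baf <- !is.na(segments$mean_mbaf) & segments$n_het >= min_het
  if (!any(use_baf)) {
    stop("no segment has heterozygous support: allele-specific fit ",
         "impossible")
  }
  mbaf_obs <- ifelse(use_baf, segments$mean_mbaf, 0)
  # inverse squared standard errors of the segment means
  inv_l <- segments$n_sites / lrr_eff^2
  inv_b <- ifelse(use_baf, segments$n_het, 0) / baf_eff^2
  b_grid <- seq(b_window[1], b_window[2], by = b_step)
  nS <- nrow(segments)

  # mean of the mirrored (folded at 0.5) per-site BAF for a site-level
  # expectation mu >= 0.5 under N(mu, sd) noise: near-balanced states sit
  # above 0.5 by up to sd * sqrt(2/pi)
  fold_mean <- function(mu, sd) {
    if (sd <= 0) return(mu)
    d <- mu - 0.5
    0.5 + sd * sqrt(2 / pi) * exp(-d^2 / (2 * sd^2)) +
      d * (1 - 2 * stats::pnorm(-d / sd))
  }

  model_at <- function(cc) {
    denom <- 2 * cc + (1 - cc) * lat$total
    lrr0 <- ifelse(denom > 0, log2(denom / 2), -Inf)
    mbaf0 <- ifelse(denom > 0, (cc + (1 - cc) * lat$major) / denom, Inf)
    ok <- is.finite(mbaf0)
    mbaf0[ok] <- fold_mean(mbaf0[ok], baf_sd)
    list(lrr0 = lrr0, mbaf0 = mbaf0,
         bad = !is.finite(lrr0) | !is.finite(mbaf0))
  }

  assign_score <- function(cc, bb) {
    md <- model_at(cc)
    A <- outer(segments$mean_lrr, md$lrr0, "-")
    Bm <- outer(mbaf_obs, md$mbaf0, "-")^2 * inv_b
    Bm[!use_baf, ] <- 0
    D <- (A + bb)^2 * inv_l + Bm
    if (any(md$bad)) D[, md$bad] <- .Machine$double.xmax
    D[!is.finite(D)] <- .Machine$double.xmax
    idx <- max.col(-D, ties.method = "first")
    list(idx = idx, score = sum(w * D[cbind(seq_len(nS), idx)]))
  }

  b_from_idx <- function(cc, idx) {
    denom <- pmax(2 * cc + (1 - cc) * lat$total[idx], 1e-12)
    lrr0 <- log2(denom / 2)
    -sum(w * inv_l * (segments$mean_lrr - lrr0)) / sum(w * inv_l)
  }
  polish <- function(cc, bb = NULL, start_idx = NULL) {
    if (!is.null(start_idx)) bb <- b_from_idx(cc, start_idx)
    for (it in 1:4) {
      as_ <- assign_score(cc, bb)
      bb_new <- b_from_idx(cc, as_$idx)
      if (abs(bb_new - bb) < 1e-9) break
      bb <- bb_new
    }
    as_ <- assign_score(cc, bb)
    totals <- lat$total[as_$idx]
    list(c = cc, b = bb, idx = as_$idx, score = as_$score,
         ploidy = weighted_median(totals, w),
         psi = weighted_mean_(totals, w))
  }
  refine_c <- function(sol) {
    lo <- max(0, sol$c - 0.02)
    hi <- min(0.949, sol$c + 0.02)
    opt <- stats::optimize(function(cc) polish(cc, sol$b)$score,
                           c(lo, hi), tol = 1e-4)
    cand <- polish(opt$minimum, sol$b)
    if (cand$score < sol$score) cand else sol
  }

  # exhaustive grid over (contamination, offset); per contamination the
  # offset is then re-estimated in closed form, removing grid quantization
  scores <- matrix(NA_real_, length(c_grid), length(b_grid))
  for (ci in seq_along(c_grid)) {
    md <- model_at(c_grid[ci])
    A <- outer(segments$mean_lrr, md$lrr0, "-")
    Bm <- outer(mbaf_obs, md$mbaf0, "-")^2 * inv_b
    Bm[!use_baf, ] <- 0
    for (bi in seq_along(b_grid)) {
      D <- (A + b_grid[bi])^2 * inv_l + Bm
      if (any(md$bad)) D[, md$bad] <- .Machine$double.xmax
      idx <- max.col(-D, ties.method = "first")
      scores[ci, bi] <- sum(w * D[cbind(seq_len(nS), idx)])
    }
  }
  per_c <- lapply(seq_along(c_grid), function(ci) {
    polish(c_grid[ci], b_grid[which.min(scores[ci, ])])
  })
  sol <- refine_c(per_c[[which.min(vapply(per_c, `[[`, numeric(1),
                                          "score"))]])

  # Canonicalization. The model admits exact lower-ploidy equivalents that
  # no data can distinguish: dividing all states by a common factor k
  # (valid when every fitted (a, m) is a multiple of k) at
  # c' = c / (k - (k - 1) c), and subtracting one copy of each allele
  # (valid when every fitted minor >= 1) at c' = (c + f) / (c + 2f),
  # f = 1 - c. Such transforms are applied while they reproduce the score,
  # implementing the lower-ploidy preference; a segment with minor = 0 (an
  # LOH anchor) blocks subtraction and an odd-total state blocks division,
  # which is what makes real tumor profiles identifiable. Validity is
  # judged on segments carrying at least 1% of the genome length, so CBS
  # micro-segments cannot block a transform. Any adopted transform marks
  # the fit ambiguous.
  idx_lookup <- matrix(NA_integer_, max_copies + 1, max_copies + 1)
  idx_lookup[cbind(lat$major + 1, lat$minor + 1)] <- seq_len(nrow(lat))
  map_idx <- function(a_new, m_new) {
    a_new <- pmin(pmax(round(a_new), 0), max_copies)
    m_new <- pmin(pmax(round(m_new), 0), a_new)
    idx_lookup[cbind(a_new + 1, m_new + 1)]
  }
  # a transform is proposed when the segments violating it carry < 5% of
  # the genome (CBS boundary micro-segments must not veto it)
  phi <- 0.05
  proposable <- function(idx) {
    a_all <- lat$major[idx]
    m_all <- lat$minor[idx]
    for (k in 4:2) {
      if (sum(w[a_all %% k != 0 | m_all %% k != 0]) <= phi) {
        return(list(kind = "divide", k = k))
      }
    }
    if (sum(w[m_all == 0]) <= phi) return(list(kind = "subtract"))
    NULL
  }
  repeat {
    a_all <- lat$major[sol$idx]
    m_all <- lat$minor[sol$idx]
    f <- 1 - sol$c
    prop <- proposable(sol$idx)
    if (is.null(prop)) break
    if (prop$kind == "divide") {
      k <- prop$k
      cand_c <- sol$c / (k - (k - 1) * sol$c)
      start <- map_idx(a_all / k, m_all / k)
    } else {
      cand_c <- (sol$c + f) / (sol$c + 2 * f)
      start <- map_idx(a_all - 1, m_all - 1)
    }
    if (cand_c >= 0.95) break
    alt <- refine_c(polish(cand_c, start_idx = start))
    if (alt$score <= sol$score * 1.05 + 1e-9 && alt$ploidy < sol$ploidy &&
          alt$ploidy >= 1) {
      sol <- alt
    } else break
  }
  # ambiguity = the final profile still lacks an anchor (an exact
  # lower-ploidy transform remains proposable, e.g. an all-balanced or
  # LOH-free genome); anchored profiles are identifiable and not flagged
  ambiguous <- !is.null(proposable(sol$idx))

  segments$major <- lat$major[sol$idx]
  segments$minor <- lat$minor[sol$idx]
  segments$total <- lat$total[sol$idx]
  fit <- structure(
    list(ploidy = sol$ploidy, contamination = sol$c,
         baseline_shift = sol$b - log2(sol$psi / 2),
         fit_score = sol$score, ambiguous = ambiguous, psi = sol$psi),
    class = "ploidy_fit"
  )
  list(fit = fit, segments = segments)
}

#' @export
print.ploidy_fit <- function(x, ...) {
  cat(sprintf(
    "ploidy %.2f, contamination %.2f, baseline shift %+.3f, score %.4g%s\n",
    x$ploidy, x$contamination, x$baseline_shift, x$fit_score,
    if (x$ambiguous) " (ambiguous)" else ""))
  invisible(x)
}

#' Call gains, losses and LOH on fitted segments
#'
#' Empirical threshold rules relative to sample ploidy: gain when the fitted
#' total exceeds ploidy + 0.5, loss when below ploidy - 0.5, otherwise
#' neutral; loss of heterozygosity when the fitted minor copy number is 0
#' and the segment has heterozygous support (copy-neutral LOH is therefore a
#' neutral segment with `loh = TRUE`).
#'
#' @param segments Fitted segment table (from [gap_fit()]`$segments`).
#' @param fit The corresponding `ploidy_fit`.
#' @param min_het Minimum het sites for an LOH call.
#' @return `segments` with `status` (gain / loss / neutral) and `loh`.
#' @export
call_allelic <- function(segments, fit, min_het = 3) {
  stopifnot(inherits(fit, "ploidy_fit"),
            all(c("total", "minor", "n_het") %in% names(segments)))
  segments$status <- ifelse(segments$total > fit$ploidy + 0.5, "gain",
                     ifelse(segments$total < fit$ploidy - 0.5, "loss",
                            "neutral"))
  segments$loh <- segments$minor == 0 & segments$n_het >= min_het
  segments
}

#' Coverage-track focal copy-number calls
#'
#' Smooths per-bait/bin log ratios with CBS, takes the most frequent
#' smoothed value (Gaussian kernel density argmax) as the zero level, and
#' calls gains above zero + `margin` and deletions below zero - `margin`.
#' High-level amplification and homozygous deletion use the mean +/-
#' `sd_mult` standard deviations of smoothed values in normal regions
#' (explicit `normal_regions`, else the bins within the neutral band);
#' labels are hierarchical, so an amplification is also a gain and a
#' homozygous deletion also a deletion.
#'
#' @param bins data.frame `chrom`, `start`, `end`, `log_ratio`.
#' @param normal_regions Optional data.frame `chrom`, `start`, `end` of
#'   known-normal regions used for the +/- `sd_mult` s.d. thresholds.
#' @param margin Gain/deletion margin around the zero level.
#' @param sd_mult Multiplier on the normal-region s.d.
#' @param zero_bw Kernel bandwidth for the zero-level density.
#' @param alpha,n_perm,min_width,seed CBS parameters.
#' @return list with `segments` (smoothed value, booleans `gain`,
#'   `deletion`, `high_amplification`, `homozygous_deletion` and a
#'   hierarchical `call` label), `bins` (input plus `smoothed`),
#'   `zero_level`, `normal_mean`, `normal_sd`.
#' @export
call_coverage <- function(bins, normal_regions = NULL, margin = 0.3,
                          sd_mult = 5, zero_bw = 0.05, alpha = 0.01,
                          n_perm = 1000, min_width = 3, seed = NULL) {
  stopifnot(all(c("chrom", "start", "end", "log_ratio") %in% names(bins)))
  chroms <- unique(bins$chrom)
  bins$smoothed <- NA_real_
  seg_rows <- list()
  for (k in seq_along(chroms)) {
    sel <- which(bins$chrom == chroms[k])
    b <- bins[sel, , drop = FALSE]
    o <- order(b$start)
    b <- b[o, , drop = FALSE]
    mid <- (b$start + b$end) / 2
    brk <- cbs_segment(mid, b$log_ratio, alpha, n_perm, min_width,
                       seed = if (is.null(seed)) NULL else
                         derive_seed(seed, paste0("cov", k)))
    bounds <- c(0, brk, nrow(b))
    sm <- numeric(nrow(b))
    for (i in seq_len(length(bounds) - 1)) {
      idx <- (bounds[i] + 1):bounds[i + 1]
      sm[idx] <- mean(b$log_ratio[idx])
      seg_rows[[length(seg_rows) + 1]] <- data.frame(
        chrom = chroms[k], start = b$start[idx[1]],
        end = b$end[idx[length(idx)]], n_bins = length(idx),
        smoothed = mean(b$log_ratio[idx])
      )
    }
    bins$smoothed[sel[o]] <- sm
  }
  segs <- do.call(rbind, seg_rows)

  d <- density(bins$smoothed, bw = zero_bw)
  zero <- d$x[which.max(d$y)]

  if (!is.null(normal_regions)) {
    norm_idx <- overlaps_any(bins, normal_regions)
  } else {
    norm_idx <- abs(bins$smoothed - zero) <= margin
  }
  if (!any(norm_idx)) {
    stop("no neutral region identifiable: supply explicit normal_regions")
  }
  nm <- mean(bins$smoothed[norm_idx])
  nsd <- sd(bins$smoothed[norm_idx])
  if (!is.finite(nsd) || nsd < 1e-8) {
    # degenerate (e.g. a single noise-free normal segment): fall back to
    # the raw bin noise in the normal regions
    nsd <- sd(bins$log_ratio[norm_idx])
    if (!is.finite(nsd)) nsd <- 0
  }

  segs$high_amplification <- segs$smoothed > nm + sd_mult * nsd
  segs$homozygous_deletion <- segs$smoothed < nm - sd_mult * nsd
  segs$gain <- segs$smoothed > zero + margin | segs$high_amplification
  segs$deletion <- segs$smoothed < zero - margin | segs$homozygous_deletion
  segs$call <- ifelse(segs$high_amplification, "high_amplification",
               ifelse(segs$homozygous_deletion, "homozygous_deletion",
               ifelse(segs$gain, "gain",
               ifelse(segs$deletion, "deletion", "neutral"))))
  rownames(segs) <- NULL
  list(segments = segs, bins = bins, zero_level = zero,
       normal_mean = nm, normal_sd = nsd)
}

overlaps_any <- function(bins, regions) {
  hit <- logical(nrow(bins))
  for (r in seq_len(nrow(regions))) {
    hit <- hit | (bins$chrom == regions$chrom[r] &
                    bins$start <= regions$end[r] &
                    bins$end >= regions$start[r])
  }
  hit
}

#' Genome aberration summaries (FAG and FAA)
#'
#' FAG is the fraction of genome length in segments that are non-neutral or
#' LOH. FAA is the fraction of chromosome arms counted aberrant; an arm is
#' aberrant when at least `arm_cutoff` of its covered length is aberrant.
#' The 50% arm cutoff is an explicit package assumption (configurable), not
#' an established constant.
#'
#' @param segments Called segment table (with `status` and `loh`).
#' @param arm_table Optional data.frame `chrom`, `centromere` (bp); without
#'   it FAA is NA.
#' @param arm_cutoff Aberrant-length fraction above which an arm counts as
#'   aberrant.
#' @return list of class `aberration_summary` with `fag` and `faa`.
#' @export
summarize_aberration <- function(segments, arm_table = NULL,
                                 arm_cutoff = 0.5) {
  stopifnot(all(c("chrom", "start", "end", "status", "loh") %in%
                  names(segments)))
  len <- as.numeric(segments$end - segments$start + 1)
  aberrant <- segments$status != "neutral" | segments$loh
  fag <- sum(len[aberrant]) / sum(len)
  faa <- NA_real_
  if (!is.null(arm_table)) {
    stopifnot(all(c("chrom", "centromere") %in% names(arm_table)))
    n_arm_aberrant <- 0
    for (r in seq_len(nrow(arm_table))) {
      ch <- arm_table$chrom[r]
      cen <- arm_table$centromere[r]
      s <- segments[segments$chrom == ch, , drop = FALSE]
      for (arm in c("p", "q")) {
        lo <- if (arm == "p") -Inf else cen
        hi <- if (arm == "p") cen else Inf
        ov <- pmax(0, pmin(s$end, hi) - pmax(s$start, lo) + 1)
        tot <- sum(ov)
        if (tot > 0) {
          frac <- sum(ov[s$status != "neutral" | s$loh]) / tot
          if (frac >= arm_cutoff) n_arm_aberrant <- n_arm_aberrant + 1
        }
      }
    }
    faa <- n_arm_aberrant / (2 * nrow(arm_table))
  }
  structure(list(fag = fag, faa = faa), class = "aberration_summary")
}

#' @export
print.aberration_summary <- function(x, ...) {
  cat(sprintf("FAG %.3f, FAA %s\n", x$fag,
              if (is.na(x$faa)) "NA" else sprintf("%.3f", x$faa)))
  invisible(x)
}
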