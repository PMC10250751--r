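# Synthetic genome builders shared across copy-number tests.

# Convenience: segment table from per-chromosome bounds and states.
chrom_segs <- function(chrom, bounds, majors, minors) {
  data.frame(chrom = chrom, start = bounds[-length(bounds)] + 1,
             end = bounds[-1], major = majors, minor = minors)
}

# A 3-chromosome, 10-segment tumor genome around a target ploidy. Every
# genome carries the two anchors that make allele-specific fits
# identifiable in practice: an LOH state (minor 0, blocks the
# subtract-germline degeneracy) and an odd-copy state (blocks
# whole-genome-halving). Remaining aberrations are drawn from a
# ploidy-appropriate pool.
random_genome_spec <- function(ploidy, contamination, seed,
                               lrr_sd = 0.15, baf_sd = 0.03,
                               snp_spacing = 2e5) {
  base <- switch(as.character(ploidy),
                 "2" = c(1, 1), "3" = c(2, 1), "4" = c(2, 2))
  anchors <- switch(as.character(ploidy),
                    "2" = list(c(2, 0), c(3, 1)),
                    "3" = list(c(2, 0), c(3, 1)),
                    "4" = list(c(4, 0), c(3, 1)))
  pool <- switch(as.character(ploidy),
                 "2" = list(c(2, 1), c(1, 0), c(3, 1), c(2, 2)),
                 "3" = list(c(2, 2), c(1, 1), c(3, 1), c(4, 2)),
                 "4" = list(c(4, 2), c(2, 1), c(3, 2), c(5, 3)))
  set.seed(seed)
  n_per_chrom <- c(4, 3, 3)
  aber_slots <- sort(sample(10, 4))
  states <- rep(list(base), 10)
  assign_states <- c(anchors, pool[sample(length(pool), 2, replace = TRUE)])
  for (i in seq_along(aber_slots)) {
    states[[aber_slots[i]]] <- assign_states[[i]]
  }
  segs <- list()
  k <- 0
  for (ch in 1:3) {
    pos <- 0
    for (j in seq_len(n_per_chrom[ch])) {
      k <- k + 1
      len <- if (k %in% aber_slots) 40e6 else 60e6
      segs[[k]] <- data.frame(chrom = paste0("chr", ch), start = pos + 1,
                              end = pos + len, major = states[[k]][1],
                              minor = states[[k]][2])
      pos <- pos + len
    }
  }
  genome_spec(do.call(rbind, segs), contamination = contamination,
              lrr_sd = lrr_sd, baf_sd = baf_sd, snp_spacing = snp_spacing)
}

# Per-site agreement between called and true gain/loss/neutral status,
# relative to the true ploidy.
site_status_accuracy <- function(snp, called, true_ploidy) {
  true_status <- ifelse(snp$true_total > true_ploidy + 0.5, "gain",
                 ifelse(snp$true_total < true_ploidy - 0.5, "loss",
                        "neutral"))
  fitted <- rep(NA_character_, nrow(snp))
  for (r in seq_len(nrow(called))) {
    sel <- snp$chrom == called$chrom[r] & snp$pos >= called$start[r] &
      snp$pos <= called$end[r]
    fitted[sel] <- called$status[r]
  }
  mean(fitted == true_status, na.rm = TRUE)
}

# Brute-force oracle for the CBS statistic: exhaustive enumeration of all
# arcs in the same scan order as the package's compiled scan.
brute_force_best_arc <- function(x, min_width = 3) {
  n <- length(x)
  s <- sd(x)
  if (n < 2 * min_width || s == 0) return(list(i = 0, j = 0, stat = 0))
  best <- -Inf
  bi <- 0
  bj <- 0
  for (i in 0:(n - min_width)) {
    for (j in (i + min_width):min(n, i + n - min_width)) {
      k <- j - i
      if (k == n) next
      inn <- x[(i + 1):j]
      out <- x[-((i + 1):j)]
      z <- abs(mean(inn) - mean(out)) / (s * sqrt(1 / k + 1 / (n - k)))
      if (z > best) {
        best <- z
        bi <- i
        bj <- j
      }
    }
  }
  list(i = bi, j = bj, stat = best)
}
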