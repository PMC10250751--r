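#' Simulate an annotated somatic variant table with known filter labels
#'
#' Emits `n_pass` records that satisfy all six somatic post-filter rules
#' (quality, tumor depth, VAF with supporting reads, population AF, in-house
#' AF, coding) and, for each rule, `n_fail_per_rule` records violating
#' exactly that rule. The ground-truth label and (for failures) the violated
#' rule are attached, so the filter can be checked record-by-record.
#'
#' @param n_pass Number of records passing every rule.
#' @param n_fail_per_rule Number of records violating exactly one rule, for
#'   each of the six rules.
#' @param seed Integer seed.
#' @param thresholds A [filter_thresholds()] object the table is constructed
#'   against.
#' @return data.frame of variant records with `truth_pass` (logical) and
#'   `truth_fail_rule` (character, NA for passing records).
#' @examples
#' tab <- gen_variant_table(10, 1, seed = 1)
#' table(tab$truth_pass)
#' @export
gen_variant_table <- function(n_pass, n_fail_per_rule, seed,
                              thresholds = filter_thresholds()) {
  stopifnot(n_pass >= 0, n_fail_per_rule >= 0)
  t <- thresholds
  rules <- c("qss", "depth", "vaf", "gnomad", "inhouse", "coding")
  n <- n_pass + 6 * n_fail_per_rule
  if (n == 0) {
    return(empty_variant_table())
  }
  genes <- c("AR", "TP53", "PTEN", "RB1", "BRCA2", "TMPRSS2", "KMT2D",
             "CDK12", "SPOP", "FOXA1", "MYC", "ATM", "CTNNB1", "ARID2",
             "MSH2", "ETV1", "PIK3R2", "USP7", "XPO1", "ATR")
  coding_csq <- c("missense_variant", "stop_gained", "frameshift_variant",
                  "inframe_deletion", "splice_acceptor_variant",
                  "stop_lost", "start_lost")
  noncoding_csq <- c("intron_variant", "synonymous_variant",
                     "3_prime_UTR_variant", "upstream_gene_variant")
  with_seed(seed, {
    base <- function(m) {
      depth <- sample(20:200, m, replace = TRUE)
      vaf <- runif(m, 0.1, 0.9)
      alt <- pmax(t$alt_reads_min, round(vaf * depth))
      alt <- pmin(alt, depth)
      data.frame(
        chrom = paste0("chr", sample(1:22, m, replace = TRUE)),
        pos = sample.int(2e8, m),
        ref = sample(c("A", "C", "G", "T"), m, replace = TRUE),
        alt = NA_character_,
        qss = runif(m, t$qss_min, 60),
        tumor_depth = depth,
        alt_reads = alt,
        vaf_t = alt / depth,
        gnomad_global_af = ifelse(runif(m) < 0.5, 0,
                                  runif(m, 0, t$gnomad_max * 0.9)),
        inhouse_af = ifelse(runif(m) < 0.5, 0,
                            runif(m, 0, t$inhouse_max * 0.9)),
        coding = TRUE,
        gene = sample(genes, m, replace = TRUE),
        consequence = sample(coding_csq, m, replace = TRUE)
      )
    }
    recs <- base(n)
    # distinct ref/alt per record
    recs$alt <- vapply(recs$ref, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1)
    }, character(1))
    recs$truth_pass <- rep(c(TRUE, FALSE),
                           c(n_pass, 6 * n_fail_per_rule))
    recs$truth_fail_rule <- c(rep(NA_character_, n_pass),
                              rep(rules, each = n_fail_per_rule))
    # violate exactly the designated rule
    idx <- function(rule) which(recs$truth_fail_rule %in% rule)
    i <- idx("qss")
    recs$qss[i] <- runif(length(i), 0, t$qss_min * 0.97)
    i <- idx("depth") # low coverage, but VAF/alt-read rule still satisfied
    d <- sample(seq(t$alt_reads_min, t$depth_min - 1), length(i),
                replace = TRUE)
    recs$tumor_depth[i] <- d
    recs$alt_reads[i] <- d
    recs$vaf_t[i] <- 1
    i <- idx("vaf") # few supporting reads at high depth
    d <- sample(100:200, length(i), replace = TRUE)
    a <- sample(0:(t$alt_reads_min - 1), length(i), replace = TRUE)
    recs$tumor_depth[i] <- d
    recs$alt_reads[i] <- a
    recs$vaf_t[i] <- a / d
    i <- idx("gnomad")
    recs$gnomad_global_af[i] <- runif(length(i), t$gnomad_max, 0.5)
    i <- idx("inhouse")
    recs$inhouse_af[i] <- runif(length(i), t$inhouse_max, 0.5)
    i <- idx("coding")
    recs$coding[i] <- FALSE
    recs$consequence[i] <- sample(noncoding_csq, length(i), replace = TRUE)
    rownames(recs) <- NULL
    recs
  })
}

empty_variant_table <- function() {
  data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), qss = numeric(), tumor_depth = integer(),
    alt_reads = integer(), vaf_t = numeric(), gnomad_global_af = numeric(),
    inhouse_af = numeric(), coding = logical(), gene = character(),
    consequence = character(), truth_pass = logical(),
    truth_fail_rule = character()
  )
}

#' Design of a synthetic in-vivo efficacy study
#'
#' States the world a caliper-measurement table is simulated from. Defaults
#' follow standard PDX efficacy practice: randomization at 65-270 mm^3
#' starting volume, 6-8 animals per arm, twice-weekly measurements, and a
#' 1500 mm^3 ethical cap on tumor volume.
#'
#' @param n_per_arm Animals per arm (>= 1).
#' @param v0_range Interval (mm^3) initial volumes are drawn from.
#' @param growth_rate Per-day exponential growth rate of control tumors.
#' @param treatment_effect Multiplier on the control growth rate for the
#'   treated arm: 1 = no effect, 0 = stasis, negative = regression.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   measurement noise on tumor volume (0 = noise-free).
#' @param ethical_volume Tumor-volume cap (mm^3); the whole study stops at
#'   the first measurement where any animal exceeds it.
#' @param max_day Last scheduled measurement day.
#' @param seed Integer seed.
#' @return An object of class `growth_study_design`.
#' @export
growth_study_design <- function(n_per_arm = 8, v0_range = c(65, 270),
                                growth_rate = 0.08, treatment_effect = 1,
                                noise_cv = 0.15, ethical_volume = 1500,
                                max_day = 60, seed = 1) {
  stopifnot(n_per_arm >= 1, length(v0_range) == 2, all(v0_range > 0),
            v0_range[1] <= v0_range[2], noise_cv >= 0, ethical_volume > 0,
            max_day > 0)
  structure(
    list(n_per_arm = n_per_arm, v0_range = v0_range,
         growth_rate = growth_rate, treatment_effect = treatment_effect,
         noise_cv = noise_cv, ethical_volume = ethical_volume,
         max_day = max_day, seed = seed),
    class = "growth_study_design"
  )
}

# Decompose a target tumor volume into a caliper (length, width) pair with
# shape factor s = width/length, so that length * width^2 * pi/6
# reconstructs the volume exactly.
decompose_volume <- function(tv, s) {
  len <- (6 * tv / (pi * s^2))^(1 / 3)
  data.frame(length_mm = len, width_mm = s * len)
}

#' Simulate a two-arm caliper growth study
#'
#' Per-animal tumor volumes follow `V0 * exp(k_arm * t)` with multiplicative
#' lognormal measurement noise; each observed volume is re-decomposed into a
#' caliper length/width pair (per-animal shape factor in `[0.7, 1]`) so that
#' the volume formula recovers it exactly. The whole study is truncated at
#' the first measurement day on which any animal exceeds the ethical cap.
#'
#' @param design A [growth_study_design()].
#' @return data.frame with columns `study`, `arm` (`vehicle` / `treated`),
#'   `animal`, `day`, `length_mm`, `width_mm`; attribute `truth` records the
#'   per-animal baseline volumes, shapes and arm rates, and `stop_day` the
#'   censoring day (NA if never capped).
#' @examples
#' d <- growth_study_design(n_per_arm = 3, noise_cv = 0, seed = 7)
#' head(gen_growth_study(d))
#' @export
gen_growth_study <- function(design) {
  stopifnot(inherits(design, "growth_study_design"))
  days <- measurement_days(design$max_day)
  rates <- c(vehicle = design$growth_rate,
             treated = design$growth_rate * design$treatment_effect)
  sdlog <- sqrt(log(1 + design$noise_cv^2))
  with_seed(design$seed, {
    rows <- list()
    truth <- list()
    for (arm in names(rates)) {
      for (i in seq_len(design$n_per_arm)) {
        v0 <- runif(1, design$v0_range[1], design$v0_range[2])
        s <- runif(1, 0.7, 1)
        tv <- v0 * exp(rates[[arm]] * days)
        if (design$noise_cv > 0) {
          tv <- tv * rlnorm(length(days), meanlog = 0, sdlog = sdlog)
        }
        lw <- decompose_volume(tv, s)
        animal <- sprintf("%s_%02d", arm, i)
        rows[[animal]] <- data.frame(
          study = "synthetic", arm = arm, animal = animal, day = days,
          length_mm = lw$length_mm, width_mm = lw$width_mm, tv = tv
        )
        truth[[animal]] <- data.frame(animal = animal, arm = arm, v0 = v0,
                                      shape = s, rate = rates[[arm]])
      }
    }
    study <- do.call(rbind, rows)
    # ethical censoring at generation time: drop days after the first
    # measurement at which any animal exceeds the cap
    over <- study$day[study$tv > design$ethical_volume]
    stop_day <- if (length(over)) min(over) else NA_real_
    if (!is.na(stop_day)) study <- study[study$day <= stop_day, ]
    study$tv <- NULL
    rownames(study) <- NULL
    attr(study, "truth") <- do.call(rbind, truth)
    attr(study, "stop_day") <- stop_day
    study
  })
}

measurement_days <- function(max_day) {
  # twice-weekly schedule: 0, 3, 7, 10, 14, ...
  d <- cumsum(c(0, rep(c(3, 4), length.out = ceiling(max_day / 3.5) + 2)))
  d[d <= max_day]
}

#' Simulate a pair of STR profiles with controlled divergence
#'
#' The first profile has `n_loci` diploid STR loci (PowerPlex-16-style locus
#' names); the second is identical except that exactly
#' `n_divergent_alleles` allele slots are replaced with novel alleles. The
#' expected Tanabe match score, `100 * (2 n_loci - k) / (2 n_loci)` (adjusted
#' when amelogenin is appended), is attached as ground truth.
#'
#' @param n_loci Number of diploid STR loci (16 in the standard kit).
#' @param n_divergent_alleles Number of allele slots to replace
#'   (`<= 2 * n_loci`).
#' @param seed Integer seed.
#' @param include_amelogenin Append an identical amelogenin locus (X/Y) to
#'   both profiles; it then participates in scoring.
#' @return list with `a` and `b` ([str_profile()] objects); attribute
#'   `expected_tanabe` is the ground-truth match percentage.
#' @examples
#' pr <- gen_str_profiles(16, 4, seed = 1)
#' attr(pr, "expected_tanabe") # 87.5
#' @export
gen_str_profiles <- function(n_loci = 16, n_divergent_alleles = 0, seed = 1,
                             include_amelogenin = FALSE) {
  stopifnot(n_loci >= 1, n_divergent_alleles >= 0,
            n_divergent_alleles <= 2 * n_loci)
  kit <- c("D3S1358", "TH01", "D21S11", "D18S51", "PentaE", "D5S818",
           "D13S317", "D7S820", "D16S539", "CSF1PO", "PentaD", "vWA",
           "D8S1179", "TPOX", "FGA")
  loci <- if (n_loci <= length(kit)) kit[seq_len(n_loci)] else {
    c(kit, sprintf("LOCUS%02d", seq_len(n_loci - length(kit))))
  }
  with_seed(seed, {
    a <- lapply(loci, function(l) {
      as.character(sort(sample(5:20, 2, replace = TRUE)))
    })
    names(a) <- loci
    b <- a
    if (n_divergent_alleles > 0) {
      slots <- sample.int(2 * n_loci, n_divergent_alleles)
      for (sl in slots) {
        l <- ceiling(sl / 2)
        pos <- ifelse(sl %% 2 == 1, 1, 2)
        taken <- unique(c(a[[l]], b[[l]]))
        b[[l]][pos] <- as.character(sample(setdiff(as.character(5:35),
                                                   taken), 1))
      }
    }
    total <- 2 * n_loci
    shared <- total - n_divergent_alleles
    if (include_amelogenin) {
      amel <- c("X", sample(c("X", "Y"), 1))
      a$AMEL <- amel
      b$AMEL <- amel
      total <- total + 2
      shared <- shared + 2
    }
    out <- list(a = str_profile("patient", a), b = str_profile("pdx", b))
    attr(out, "expected_tanabe") <- 100 * 2 * shared / (2 * total)
    out
  })
}

#' Simulate a two-cluster RNA-seq count matrix
#'
#' Negative-binomial counts with lognormal baseline means; a chosen set of
#' signature genes is shifted by `effect_log2fc` in cluster 2. Gene lengths
#' (kb) and ground-truth cluster labels are returned, so TPM normalization,
#' variance-ranked gene selection and clustering can be validated against a
#' known partition.
#'
#' @param n_genes Number of genes.
#' @param samples_per_cluster Integer pair: samples in cluster 1 and 2.
#' @param n_signature_genes Number of genes shifted in cluster 2
#'   (`<= n_genes`).
#' @param effect_log2fc Log2 fold change applied to signature genes in
#'   cluster 2.
#' @param seed Integer seed.
#' @param dispersion Negative-binomial dispersion (0 gives Poisson counts).
#' @return list with `counts` (genes x samples integer matrix), `length_kb`,
#'   `cluster` (ground-truth labels per sample), `signature_genes`.
#' @export
gen_expression <- function(n_genes = 2000, samples_per_cluster = c(4, 4),
                           n_signature_genes = 100, effect_log2fc = 4,
                           seed = 1, dispersion = 0.1) {
  stopifnot(n_signature_genes <= n_genes, length(samples_per_cluster) == 2,
            all(samples_per_cluster >= 1), dispersion >= 0)
  n_samples <- sum(samples_per_cluster)
  cluster <- rep(1:2, samples_per_cluster)
  with_seed(seed, {
    length_kb <- runif(n_genes, 0.2, 20)
    mu0 <- rlnorm(n_genes, meanlog = log(50), sdlog = 1.2)
    sig <- sort(sample.int(n_genes, n_signature_genes))
    mu <- matrix(mu0, n_genes, n_samples)
    mu[sig, cluster == 2] <- mu[sig, cluster == 2] * 2^effect_log2fc
    counts <- if (dispersion > 0) {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             n_genes, n_samples)
    } else {
      matrix(rpois(length(mu), lambda = mu), n_genes, n_samples)
    }
    rownames(counts) <- sprintf("G%05d", seq_len(n_genes))
    colnames(counts) <- sprintf("S%02d", seq_len(n_samples))
    names(length_kb) <- rownames(counts)
    names(cluster) <- colnames(counts)
    list(counts = counts, length_kb = length_kb, cluster = cluster,
         signature_genes = rownames(counts)[sig])
  })
}
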