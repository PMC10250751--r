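#' Percentages from printed cohort counts
#'
#' Turns a table of specimen counts (with explicit denominators) into the
#' whole-percent figures a cohort report prints. The package ships the
#' collection/first-growth counts of the reference prostate-PDX cohort as
#' `inst/extdata/cohort_counts.tsv`.
#'
#' @param counts data.frame with columns `stage`, `category`, `count`,
#'   `denominator`.
#' @return The input with a `percent` column (`round(100 * count /
#'   denominator)`).
#' @examples
#' cohort_percentages()
#' @export
cohort_percentages <- function(counts = read.delim(system.file(
  "extdata", "cohort_counts.tsv", package = "pdxforge"))) {
  counts <- check_cols_(counts, c("stage", "category", "count",
                                  "denominator"), "cohort count")
  stopifnot(all(counts$count >= 0), all(counts$denominator > 0),
            all(counts$count <= counts$denominator))
  counts$percent <- round(100 * counts$count / counts$denominator)
  counts
}

pipeline_stages <- c("variants", "copy_number", "str", "pharm",
                     "expression")

# The demo panel: five synthetic samples spanning the phenotypes a
# prostate-PDX panel exhibits (diploid low-burden, tetraploid high-burden
# with an MMR-gene homozygous deletion, a pre/post treatment pair sharing a
# mutation subset, and responder / non-responder growth arms).
build_demo_inputs <- function(seed) {
  sd_ <- function(label) derive_seed(seed, label)
  chr <- function(chrom, bounds, majors, minors) {
    data.frame(chrom = chrom,
               start = bounds[-length(bounds)] + 1, end = bounds[-1],
               major = majors, minor = minors)
  }
  # diploid genome with one CN-LOH stretch and a one-copy loss
  diploid <- genome_spec(rbind(
    chr("chr1", c(0, 40e6, 80e6, 120e6), c(1, 2, 1), c(1, 0, 1)),
    chr("chr2", c(0, 50e6, 70e6, 110e6), c(1, 1, 1), c(1, 0, 1)),
    chr("chr3", c(0, 60e6, 100e6), c(1, 2), c(1, 1))
  ), contamination = 0.2, snp_spacing = 2e5)
  # tetraploid genome; chr2 carries a homozygous deletion over an
  # MMR-gene-like interval, visible in the coverage track
  tetraploid <- genome_spec(rbind(
    chr("chr1", c(0, 40e6, 80e6, 120e6), c(2, 3, 2), c(2, 1, 2)),
    chr("chr2", c(0, 47e6, 48e6, 110e6), c(2, 0, 2), c(2, 0, 2)),
    chr("chr3", c(0, 30e6, 70e6, 100e6), c(2, 4, 2), c(2, 2, 2))
  ), contamination = 0.1, snp_spacing = 2e5)
  mmr_interval <- data.frame(chrom = "chr2", start = 47e6 + 1, end = 48e6,
                             gene = "MSH2_like")

  # paired pre/post variant tables sharing a subset (clonal ancestry)
  shared_pool <- gen_variant_table(60, 0, seed = sd_("shared"))
  pre_priv <- gen_variant_table(25, 2, seed = sd_("pre"))
  post_priv <- gen_variant_table(30, 2, seed = sd_("post"))
  pre <- rbind(shared_pool[1:45, ], pre_priv)
  post <- rbind(shared_pool[16:60, ], post_priv)

  list(
    diploid_spec = diploid,
    tetraploid_spec = tetraploid,
    mmr_interval = mmr_interval,
    variants = list(
      low_burden = gen_variant_table(40, 3, seed = sd_("low")),
      high_burden = gen_variant_table(300, 3, seed = sd_("high")),
      pre = pre, post = post
    ),
    str_pairs = list(
      conserved = gen_str_profiles(16, 0, seed = sd_("str1")),
      drifted = gen_str_profiles(16, 4, seed = sd_("str2"))
    ),
    studies = list(
      responder = gen_growth_study(growth_study_design(
        n_per_arm = 6, growth_rate = 0.11, treatment_effect = -0.5,
        noise_cv = 0.1, seed = sd_("resp"))),
      non_responder = gen_growth_study(growth_study_design(
        n_per_arm = 6, growth_rate = 0.11, treatment_effect = 0.9,
        noise_cv = 0.1, seed = sd_("nonresp")))
    ),
    expression = gen_expression(n_genes = 1500,
                                samples_per_cluster = c(2, 3),
                                n_signature_genes = 80, effect_log2fc = 4,
                                seed = sd_("expr"))
  )
}

#' Run the full pipeline on a synthetic cohort
#'
#' Orchestrates the stages in dependency order over a simulated input
#' panel: variant filtering + TMB + driver annotation + paired-sample
#' comparison, allele-specific and coverage copy-number calling, STR
#' authentication, growth-study pharmacodynamics, and expression
#' clustering. Stage parameters are fixed at module defaults; all
#' randomness derives from `config$seed` via [derive_seed()], so reports
#' are reproducible.
#'
#' @param config list with elements `seed` (integer, required), `out_dir`
#'   (optional: write stage outputs and a JSON run report there) and
#'   `stages` (subset of `r paste(pipeline_stages, collapse = ", ")`;
#'   default all). Unknown elements are rejected.
#' @return Run report list (per-stage summaries); written as
#'   `run_report.json` when `out_dir` is set.
#' @seealso [demo_cohort()] for the one-call demonstration run.
#' @export
run_pipeline <- function(config = list(seed = 1)) {
  known <- c("seed", "out_dir", "stages")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config element(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$seed)) stop("config$seed is required")
  stages <- if (is.null(config$stages)) pipeline_stages else config$stages
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  seed <- config$seed
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(name, writer) {
    if (!is.null(out_dir)) writer(file.path(out_dir, name))
  }
  inputs <- build_demo_inputs(seed)
  report <- list(seed = seed, stages = stages)

  if ("variants" %in% stages) {
    drivers <- read_driver_list()
    vsum <- lapply(names(inputs$variants), function(nm) {
      tab <- inputs$variants[[nm]]
      res <- apply_somatic_filters(tab)
      ann <- annotate_drivers(res$retained, drivers)
      emit(paste0("variants_", nm, ".tsv"),
           function(p) write_variant_table(res$retained, p))
      list(sample = nm, n_input = res$n_input,
           n_retained = nrow(res$retained),
           tmb = compute_tmb(nrow(res$retained)),
           tally = as.list(res$tally),
           n_driver_genes = nrow(ann$recurrence),
           multi_hit_genes = ann$recurrence$gene[ann$recurrence$multi_hit])
    })
    names(vsum) <- names(inputs$variants)
    fpre <- apply_somatic_filters(inputs$variants$pre)$retained
    fpost <- apply_somatic_filters(inputs$variants$post)$retained
    cmp <- compare_variant_sets(fpre, fpost)
    report$variants <- list(
      samples = vsum,
      paired = list(shared = cmp$shared, private_pre = cmp$private_a,
                    private_post = cmp$private_b))
  }

  if ("copy_number" %in% stages) {
    cn_one <- function(spec, label) {
      snp <- gen_snp_profile(spec, seed = derive_seed(seed, label))
      segs <- segment_profile(snp, seed = derive_seed(seed,
                                                      paste0(label, "s")))
      fit <- gap_fit(segs)
      called <- call_allelic(fit$segments, fit$fit)
      arm_table <- data.frame(chrom = unique(spec$segments$chrom),
                              centromere = 50e6)
      ab <- summarize_aberration(called, arm_table)
      emit(paste0("segments_", label, ".seg"),
           function(p) write_seg(called, label, p))
      list(ploidy = fit$fit$ploidy,
           contamination = fit$fit$contamination,
           ambiguous = fit$fit$ambiguous, fag = ab$fag, faa = ab$faa,
           n_segments = nrow(called))
    }
    cov <- gen_coverage_bins(inputs$tetraploid_spec, bin_size = 2e5,
                             seed = derive_seed(seed, "cov"))
    cov_calls <- call_coverage(cov, seed = derive_seed(seed, "covc"))
    hd <- cov_calls$segments[cov_calls$segments$homozygous_deletion, ,
                             drop = FALSE]
    mmr <- inputs$mmr_interval
    mmr_hit <- any(hd$chrom == mmr$chrom & hd$start <= mmr$end &
                     hd$end >= mmr$start)
    report$copy_number <- list(
      diploid = cn_one(inputs$diploid_spec, "diploid"),
      tetraploid = cn_one(inputs$tetraploid_spec, "tetraploid"),
      coverage = list(zero_level = cov_calls$zero_level,
                      n_homozygous_deletion = nrow(hd),
                      mmr_deletion_detected = mmr_hit))
  }

  if ("str" %in% stages) {
    report$str <- lapply(inputs$str_pairs, function(pair) {
      rep_ <- str_report(pair$a, pair$b)
      list(score = rep_$score, pass = rep_$auth$pass)
    })
  }

  if ("pharm" %in% stages) {
    report$pharm <- lapply(names(inputs$studies), function(nm) {
      st <- inputs$studies[[nm]]
      emit(paste0("study_", nm, ".csv"),
           function(p) write_growth_study(st, p))
      res <- analyze_growth_study(st)
      list(study = nm, dtc = res$per_arm$dtc,
           tgi_band = res$per_arm$tgi_band,
           stop_day = res$stop_day,
           mrecist = as.list(table(res$per_animal$mrecist[
             res$per_animal$arm == "treated"])))
    })
    names(report$pharm) <- names(inputs$studies)
  }

  if ("expression" %in% stages) {
    ex <- inputs$expression
    tpm <- tpm_normalize(ex$counts, ex$length_kb)
    top <- top_variant_genes(tpm, n = 500)
    cl <- hierarchical_cluster(tpm[top, ], k = 2)
    agree <- max(mean(cl$labels == ex$cluster),
                 mean(cl$labels == 3 - ex$cluster))
    ct <- contrast_clusters(tpm, cl$labels)
    report$expression <- list(
      n_top_genes = length(top),
      cluster_sizes = as.list(table(cl$labels)),
      label_agreement = agree,
      n_up = ct$n_up, n_down = ct$n_down)
  }

  if (!is.null(out_dir)) {
    write_json_report(report, file.path(out_dir, "run_report.json"))
  }
  report
}

#' One-command synthetic demonstration cohort
#'
#' Generates the five-sample synthetic panel, runs every pipeline stage and
#' writes all inputs, outputs and the JSON run report to `out_dir`.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory (created if absent).
#' @return The run report, invisibly.
#' @examples
#' \donttest{
#' report <- demo_cohort(seed = 7, out_dir = tempfile("pdx_demo_"))
#' report$copy_number$tetraploid$ploidy
#' }
#' @export
demo_cohort <- function(seed = 1, out_dir = tempfile("pdxforge_demo_")) {
  invisible(run_pipeline(list(seed = seed, out_dir = out_dir)))
}
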