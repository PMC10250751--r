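#' Somatic post-filter thresholds
#'
#' Defaults implement the six-rule post-filter used for reliable somatic
#' calls: base-quality score QSS >= 20, tumor coverage >= 10, VAF in the
#' tumor >= 0.05 with >= 5 mutated reads, gnomAD global AF strictly below
#' 1e-5, in-house database AF strictly below 0.01, and coding consequence
#' only. All ">=" bounds are inclusive; both population-AF bounds are
#' strict "<".
#'
#' @param qss_min Minimum average base quality of variant bases.
#' @param depth_min Minimum tumor read depth.
#' @param vaf_min Minimum tumor variant allele fraction.
#' @param alt_reads_min Minimum mutated read count (applied together with
#'   `vaf_min` as one rule).
#' @param gnomad_max Strict upper bound on gnomAD global allele frequency.
#' @param inhouse_max Strict upper bound on in-house database frequency.
#' @param coding_only Keep coding variants only.
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(qss_min = 20, depth_min = 10, vaf_min = 0.05,
                              alt_reads_min = 5, gnomad_max = 1e-5,
                              inhouse_max = 0.01, coding_only = TRUE) {
  stopifnot(qss_min >= 0, depth_min >= 0, vaf_min >= 0, alt_reads_min >= 0,
            gnomad_max >= 0, inhouse_max >= 0, is.logical(coding_only))
  structure(
    list(qss_min = qss_min, depth_min = depth_min, vaf_min = vaf_min,
         alt_reads_min = alt_reads_min, gnomad_max = gnomad_max,
         inhouse_max = inhouse_max, coding_only = coding_only),
    class = "filter_thresholds"
  )
}

filter_rule_names <- c("qss", "depth", "vaf", "gnomad", "inhouse", "coding")

validate_variant_records <- function(records) {
  required <- c("chrom", "pos", "ref", "alt", "qss", "tumor_depth",
                "alt_reads", "vaf_t", "coding")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    stop("variant records lack columns: ", paste(missing, collapse = ", "))
  }
  bad <- which(records$alt_reads > records$tumor_depth)
  if (length(bad)) {
    stop("malformed variant records (alt_reads > tumor_depth) at rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(records)
}

#' Apply the six-rule somatic post-filter
#'
#' A record is retained iff it passes every rule; each rejected record is
#' attributed to the first failing rule in the canonical order (qss, depth,
#' vaf, gnomad, inhouse, coding), giving deterministic per-rule tallies.
#' Absent population AFs (NA or missing column) count as 0: absence from a
#' population database cannot justify rejecting a novel somatic variant.
#'
#' @param records data.frame of variant records (see [gen_variant_table()]
#'   for the column contract).
#' @param thresholds A [filter_thresholds()] object.
#' @return list of class `somatic_filter` with `retained` (data.frame),
#'   `rejected` (data.frame with a `fail_rule` column), `tally` (named
#'   integer vector over the six rules) and `n_input`.
#' @examples
#' tab <- gen_variant_table(10, 1, seed = 1)
#' res <- apply_somatic_filters(tab)
#' res$tally
#' @export
apply_somatic_filters <- function(records, thresholds = filter_thresholds()) {
  t <- thresholds
  if (nrow(records) == 0) {
    return(structure(list(retained = records, rejected = records,
                          tally = setNames(integer(6), filter_rule_names),
                          n_input = 0L),
                     class = "somatic_filter"))
  }
  validate_variant_records(records)
  af0 <- function(col) {
    x <- if (col %in% names(records)) records[[col]] else
      rep(NA_real_, nrow(records))
    ifelse(is.na(x), 0, x)
  }
  pass <- cbind(
    qss = records$qss >= t$qss_min,
    depth = records$tumor_depth >= t$depth_min,
    vaf = records$vaf_t >= t$vaf_min & records$alt_reads >= t$alt_reads_min,
    gnomad = af0("gnomad_global_af") < t$gnomad_max,
    inhouse = af0("inhouse_af") < t$inhouse_max,
    coding = if (t$coding_only) records$coding else TRUE
  )
  keep <- rowSums(pass) == ncol(pass)
  first_fail <- apply(pass, 1, function(p) {
    w <- which(!p)
    if (length(w)) filter_rule_names[w[1]] else NA_character_
  })
  rejected <- records[!keep, , drop = FALSE]
  rejected$fail_rule <- first_fail[!keep]
  tally <- setNames(integer(6), filter_rule_names)
  tb <- table(rejected$fail_rule)
  tally[names(tb)] <- as.integer(tb)
  structure(
    list(retained = records[keep, , drop = FALSE], rejected = rejected,
         tally = tally, n_input = nrow(records)),
    class = "somatic_filter"
  )
}

#' @export
print.somatic_filter <- function(x, ...) {
  cat("Somatic post-filter:", nrow(x$retained), "of", x$n_input,
      "records retained\n")
  if (any(x$tally > 0)) {
    cat("rejections by first failing rule:\n")
    print(x$tally)
  }
  invisible(x)
}

#' Tumor mutational burden
#'
#' Retained somatic variant count per callable megabase, reported to two
#' decimals. The callable target size is study-specific and must be
#' supplied; 50 Mb is a conventional whole-exome default.
#'
#' @param n_retained Number of retained somatic variants.
#' @param callable_mb Callable target size in megabases (> 0).
#' @return Variants per Mb, rounded to two decimals.
#' @examples
#' compute_tmb(180, 50) # 3.6
#' @export
compute_tmb <- function(n_retained, callable_mb = 50) {
  if (!is.numeric(callable_mb) || callable_mb <= 0) {
    stop("callable_mb must be > 0")
  }
  stopifnot(n_retained >= 0)
  round(n_retained / callable_mb, 2)
}

#' Flag driver genes and tabulate recurrence
#'
#' Marks records whose gene symbol is in a user-supplied driver list
#' (case-insensitive exact match) and tabulates records per driver gene;
#' genes hit by two or more records are flagged `multi_hit`. The package
#' ships an editable example list of prostate-cancer driver symbols
#' (`system.file("extdata", "prostate_driver_genes_example.txt",
#' package = "pdxforge")`); it is a starting point, not an authority.
#'
#' @param records data.frame of variant records with a `gene` column.
#' @param driver_genes Character vector of driver gene symbols.
#' @return list with `records` (input plus a `driver` logical column) and
#'   `recurrence` (data.frame gene / n / multi_hit for flagged genes).
#' @export
annotate_drivers <- function(records, driver_genes) {
  drivers <- toupper(driver_genes)
  gene <- if ("gene" %in% names(records)) records$gene else
    rep(NA_character_, nrow(records))
  records$driver <- !is.na(gene) & toupper(gene) %in% drivers
  hit <- records[records$driver, , drop = FALSE]
  recurrence <- if (nrow(hit)) {
    tb <- table(toupper(hit$gene))
    data.frame(gene = names(tb), n = as.integer(tb),
               multi_hit = as.integer(tb) >= 2, row.names = NULL)
  } else {
    data.frame(gene = character(), n = integer(), multi_hit = logical())
  }
  recurrence <- recurrence[order(-recurrence$n, recurrence$gene), ,
                           drop = FALSE]
  rownames(recurrence) <- NULL
  list(records = records, recurrence = recurrence)
}

#' Read a driver gene list (one symbol per line, '#' comments)
#' @param path File path; defaults to the shipped example list.
#' @return Character vector of gene symbols.
#' @export
read_driver_list <- function(path = system.file("extdata",
                                                "prostate_driver_genes_example.txt",
                                                package = "pdxforge")) {
  x <- readLines(path)
  x <- trimws(sub("#.*", "", x))
  x[nzchar(x)]
}

#' Compare two post-filtered variant sets
#'
#' Variant identity is the (chrom, pos, ref, alt) key. Duplicate keys within
#' one set are deduplicated with a warning. Used to assess clonal ancestry
#' of paired samples via shared and private mutation counts.
#'
#' @param a,b data.frames of variant records.
#' @return list of class `variant_set_comparison` with counts `shared`,
#'   `private_a`, `private_b` and the corresponding key vectors.
#' @examples
#' x <- gen_variant_table(8, 0, seed = 1)
#' compare_variant_sets(x[1:6, ], x[3:8, ])
#' @export
compare_variant_sets <- function(a, b) {
  key <- function(d, label) {
    k <- paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
    if (anyDuplicated(k)) {
      warning("duplicate variant keys in set ", label, ": deduplicated")
      k <- unique(k)
    }
    k
  }
  ka <- key(a, "a")
  kb <- key(b, "b")
  shared <- intersect(ka, kb)
  structure(
    list(shared = length(shared),
         private_a = length(setdiff(ka, kb)),
         private_b = length(setdiff(kb, ka)),
         shared_keys = shared,
         private_a_keys = setdiff(ka, kb),
         private_b_keys = setdiff(kb, ka)),
    class = "variant_set_comparison"
  )
}

#' @export
print.variant_set_comparison <- function(x, ...) {
  cat("shared:", x$shared, " private A:", x$private_a,
      " private B:", x$private_b, "\n")
  invisible(x)
}
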