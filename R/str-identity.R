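#' Construct an STR profile
#'
#' @param sample_id Sample label.
#' @param loci Named list: locus name -> character vector of alleles (repeat
#'   counts as labels; amelogenin uses "X"/"Y"). A typed locus needs at
#'   least one allele; untyped loci are simply absent. Homozygous diploid
#'   loci are conventionally recorded as the allele repeated twice so that
#'   denominators stay consistent.
#' @return Object of class `str_profile`.
#' @examples
#' str_profile("patient", list(TH01 = c("6", "9"), vWA = c("17", "17")))
#' @export
str_profile <- function(sample_id, loci) {
  stopifnot(is.character(sample_id), length(sample_id) == 1,
            is.list(loci), length(loci) >= 1,
            !is.null(names(loci)), all(nzchar(names(loci))))
  if (any(vapply(loci, length, integer(1)) < 1)) {
    stop("every typed locus needs at least one allele")
  }
  loci <- lapply(loci, as.character)
  structure(list(sample_id = sample_id, loci = loci),
            class = "str_profile")
}

is_amelogenin <- function(locus) toupper(locus) %in% c("AMEL", "AMELOGENIN")

#' Allele match score between two STR profiles
#'
#' Over loci typed in both profiles, counts shared alleles respecting
#' multiplicity (a homozygous "12,12" shares two alleles with "12,12" but
#' one with "12,14"). Tanabe score: `100 * 2 * shared / (n_a + n_b)`
#' (symmetric); Masters (vs a): `100 * shared / n_a` (not symmetric). A
#' locus carrying more than two alleles in either profile — e.g. drift in a
#' tetraploid model — is compared on allele sets (duplicates collapsed)
#' with a warning.
#'
#' @param a,b [str_profile()] objects.
#' @param method `"tanabe"` (default, the cell-line authentication
#'   standard) or `"masters_a"`.
#' @param include_amelogenin Score the amelogenin sex marker when typed in
#'   both profiles (the kit amplifies it with the STR loci).
#' @return Percentage in `[0, 100]`.
#' @examples
#' p <- gen_str_profiles(16, 4, seed = 1)
#' match_score(p$a, p$b) # 87.5
#' @export
match_score <- function(a, b, method = c("tanabe", "masters_a"),
                        include_amelogenin = TRUE) {
  stopifnot(inherits(a, "str_profile"), inherits(b, "str_profile"))
  method <- match.arg(method)
  common <- intersect(names(a$loci), names(b$loci))
  if (!include_amelogenin) common <- common[!is_amelogenin(common)]
  if (!length(common)) stop("no locus typed in both profiles")
  shared <- 0L; n_a <- 0L; n_b <- 0L
  for (l in common) {
    aa <- a$loci[[l]]
    bb <- b$loci[[l]]
    if (length(aa) > 2 || length(bb) > 2) {
      warning("locus ", l, " carries >2 alleles (ploidy drift): ",
              "compared on allele sets")
      aa <- unique(aa)
      bb <- unique(bb)
    }
    ta <- table(aa)
    tb <- table(bb)
    vals <- intersect(names(ta), names(tb))
    shared <- shared + sum(pmin(ta[vals], tb[vals]))
    n_a <- n_a + length(aa)
    n_b <- n_b + length(bb)
  }
  switch(method,
         tanabe = 100 * 2 * shared / (n_a + n_b),
         masters_a = 100 * shared / n_a)
}

#' Authenticate a PDX against its patient by STR match score
#'
#' The authentication rule is strict: a model passes when the match score
#' exceeds the threshold (score > 80 by default; exactly 80 fails unless
#' `strict_gt = FALSE`).
#'
#' @param score Match percentage in `[0, 100]`.
#' @param threshold Pass threshold (percent).
#' @param strict_gt Require score strictly greater than the threshold.
#' @return list of class `str_auth`: `pass`, `score`, `threshold`,
#'   `strict_gt`.
#' @examples
#' authenticate(85)$pass  # TRUE
#' authenticate(80)$pass  # FALSE: the rule is strictly "> 80%"
#' @export
authenticate <- function(score, threshold = 80, strict_gt = TRUE) {
  stopifnot(is.numeric(score), score >= 0, score <= 100)
  pass <- if (strict_gt) score > threshold else score >= threshold
  structure(list(pass = pass, score = score, threshold = threshold,
                 strict_gt = strict_gt),
            class = "str_auth")
}

#' @export
print.str_auth <- function(x, ...) {
  cat(sprintf("STR match %.1f%% %s %s%% -> %s\n", x$score,
              if (x$strict_gt) ">" else ">=", x$threshold,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Full STR identity report
#'
#' @param a,b [str_profile()] objects.
#' @param method,threshold,strict_gt,include_amelogenin See [match_score()]
#'   and [authenticate()].
#' @return list with `score`, `method`, `auth` and a per-locus detail
#'   data.frame.
#' @export
str_report <- function(a, b, method = "tanabe", threshold = 80,
                       strict_gt = TRUE, include_amelogenin = TRUE) {
  common <- intersect(names(a$loci), names(b$loci))
  if (!include_amelogenin) common <- common[!is_amelogenin(common)]
  detail <- do.call(rbind, lapply(common, function(l) {
    ta <- table(a$loci[[l]])
    tb <- table(b$loci[[l]])
    vals <- intersect(names(ta), names(tb))
    data.frame(locus = l,
               alleles_a = paste(a$loci[[l]], collapse = ","),
               alleles_b = paste(b$loci[[l]], collapse = ","),
               shared = sum(pmin(ta[vals], tb[vals])))
  }))
  score <- match_score(a, b, method = method,
                       include_amelogenin = include_amelogenin)
  list(sample_a = a$sample_id, sample_b = b$sample_id, score = score,
       method = method, auth = authenticate(score, threshold, strict_gt),
       per_locus = detail)
}

#' Read / write STR profiles as two-column TSV (locus, comma-joined alleles)
#' @param path File path.
#' @param sample_id Sample label for the profile read.
#' @return `read_str_profile()` returns an [str_profile()].
#' @export
read_str_profile <- function(path, sample_id = basename(path)) {
  d <- read.delim(path, header = TRUE, colClasses = "character")
  stopifnot(all(c("locus", "alleles") %in% names(d)))
  loci <- lapply(strsplit(d$alleles, ","), trimws)
  names(loci) <- d$locus
  str_profile(sample_id, loci)
}

#' @rdname read_str_profile
#' @param profile An [str_profile()] to write.
#' @export
write_str_profile <- function(profile, path) {
  stopifnot(inherits(profile, "str_profile"))
  d <- data.frame(locus = names(profile$loci),
                  alleles = vapply(profile$loci, paste, character(1),
                                   collapse = ","))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
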