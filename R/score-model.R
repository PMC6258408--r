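#' Normalize a PHRED-like deleteriousness score to [0, 1)
#'
#' Maps a PHRED-scaled score C (e.g. CADD v1.3 PHRED) to the unit scale via
#' `s = 1 - 10^(-C/10)`, so C = 0 gives s = 0, C = 10 gives s = 0.9 and
#' C = 20 gives s = 0.99. The mapping is strictly increasing and never
#' reaches 1.
#'
#' @param C numeric vector of non-negative PHRED-like scores.
#' @return numeric vector of normalized scores in [0, 1).
#' @examples
#' normalizeScore(c(0, 10, 20))
#' @export
normalizeScore <- function(C) {
  if (!is.numeric(C) || any(is.na(C)))
    stop("C must be numeric and non-missing")
  if (any(C < 0))
    stop("PHRED-like scores must be non-negative")
  1 - 10^(-C / 10)
}

#' Recover the PHRED-like score from a normalized score
#'
#' Inverse of [normalizeScore()]: `C = -10 * log10(1 - s)`.
#'
#' @param s numeric vector in [0, 1).
#' @return numeric vector of PHRED-like scores.
#' @export
denormalizeScore <- function(s) {
  if (any(s < 0 | s >= 1)) stop("normalized scores must lie in [0, 1)")
  -10 * log10(1 - s)
}

#' Construct a ScoreTable from a data.frame
#'
#' @param df data.frame with columns chrom, pos, ref, alt and a score
#'   column named `raw`.
#' @param provenance origin label.
#' @param prenormalized `TRUE` when scores are already on a ranked
#'   0-1 scale (e.g. DANN, REVEL) and must bypass PHRED normalization.
#' @return a [ScoreTable]
#' @export
ScoreTable <- function(df, provenance = "unknown", prenormalized = FALSE) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$chrom <- normChrom(df$chrom)
  df$pos <- as.integer(df$pos)
  rownames(df) <- NULL
  new("ScoreTable", scores = df, provenance = provenance,
      prenormalized = prenormalized)
}

#' Load a variant score table from a TSV file
#'
#' Supported dialects: `"cadd-tsv"` (columns chrom, pos, ref, alt,
#' raw_score, phred_score; the PHRED column is kept), `"generic-tsv"`
#' (chrom, pos, ref, alt, score) and `"pre-normalized"` (generic layout,
#' scores already in [0, 1)). Header lines are optional for the CADD
#' dialect; `#`-prefixed lines are skipped. Gzipped files are read
#' transparently. Rows duplicating a key with an identical score are
#' deduplicated with a warning; conflicting duplicates are an error that
#' names the offending keys.
#'
#' @param path TSV file path (optionally gzipped).
#' @param dialect one of `"cadd-tsv"`, `"generic-tsv"`, `"pre-normalized"`.
#' @param provenance origin label; defaults to the dialect.
#' @return a [ScoreTable]
#' @export
loadScoreTable <- function(path,
                           dialect = c("cadd-tsv", "generic-tsv",
                                       "pre-normalized"),
                           provenance = NULL) {
  dialect <- match.arg(dialect)
  dt <- data.table::fread(path, sep = "\t", header = "auto",
                          data.table = TRUE, showProgress = FALSE)
  if (dialect == "cadd-tsv") {
    if (ncol(dt) < 6)
      stop("cadd-tsv requires 6 columns: chrom, pos, ref, alt, raw_score, phred_score")
    dt <- dt[, c(1:4, 6), with = FALSE]
  } else {
    if (ncol(dt) < 5)
      stop(dialect, " requires 5 columns: chrom, pos, ref, alt, score")
    dt <- dt[, 1:5, with = FALSE]
  }
  data.table::setnames(dt, c("chrom", "pos", "ref", "alt", "raw"))
  bad <- which(is.na(suppressWarnings(as.integer(dt$pos))) |
                 is.na(suppressWarnings(as.numeric(dt$raw))))
  if (length(bad))
    stop("unparseable rows at lines: ", paste(utils::head(bad, 10), collapse = ", "))
  df <- as.data.frame(dt)
  df$pos <- as.integer(df$pos)
  df$raw <- as.numeric(df$raw)
  key <- variantKey(df$chrom, df$pos, df$ref, df$alt)
  if (anyDuplicated(key)) {
    agg <- tapply(df$raw, key, function(v) length(unique(v)))
    conflict <- names(agg)[agg > 1]
    if (length(conflict))
      stop("conflicting scores for duplicated keys: ",
           paste(utils::head(conflict, 10), collapse = "; "))
    warning("deduplicated ", sum(duplicated(key)),
            " repeated key(s) with identical scores")
    df <- df[!duplicated(key), , drop = FALSE]
  }
  message("loaded score table: ", nrow(df), " variants")
  ScoreTable(df, provenance = provenance %||% dialect,
             prenormalized = dialect == "pre-normalized")
}

#' Look up raw scores for variant alleles
#'
#' Exact-match lookup on (chrom, pos, ref, alt). Absent keys return `NA`,
#' the missing-score marker routed through the missing-score policy of
#' [applyScoreTable()].
#'
#' @param table a [ScoreTable].
#' @param chrom,pos,ref,alt vectors describing the query alleles.
#' @return numeric vector of raw scores, `NA` where absent.
#' @export
lookupScore <- function(table, chrom, pos, ref, alt) {
  stopifnot(is(table, "ScoreTable"))
  if (length(chrom) != length(pos) || length(pos) != length(ref) ||
      length(ref) != length(alt) || any(is.na(pos)))
    stop("malformed lookup key")
  df <- table@scores
  tk <- variantKey(df$chrom, df$pos, df$ref, df$alt)
  qk <- variantKey(chrom, pos, ref, alt)
  df$raw[match(qk, tk)]
}

#' Annotate a cohort's calls with normalized scores from a table
#'
#' Attaches to each call the normalized score derived from the table (PHRED
#' scores pass through [normalizeScore()]; prenormalized tables are used
#' as-is). Variants absent from the table follow the missing-score policy:
#' `"drop"` removes them with a warning (default, matching pipelines that
#' analyse pre-annotated variants only), `"zero"` scores them 0, and
#' `"error"` aborts.
#'
#' @param cohort a [VariantCohort].
#' @param table a [ScoreTable].
#' @param missing missing-score policy: `"drop"`, `"zero"` or `"error"`.
#' @return the annotated [VariantCohort].
#' @export
applyScoreTable <- function(cohort, table,
                            missing = c("drop", "zero", "error")) {
  missing <- match.arg(missing)
  stopifnot(is(cohort, "VariantCohort"))
  calls <- cohort@calls
  raw <- lookupScore(table, calls$chrom, calls$pos, calls$ref, calls$alt)
  s <- rep(NA_real_, length(raw))
  have <- !is.na(raw)
  s[have] <- if (table@prenormalized) raw[have] else normalizeScore(raw[have])
  if (any(!have)) {
    n <- sum(!have)
    if (missing == "error")
      stop(n, " variant(s) absent from the score table")
    if (missing == "drop") {
      warning("dropped ", n, " variant(s) absent from the score table")
      calls <- calls[have, , drop = FALSE]
      s <- s[have]
    } else {
      warning("scored ", n, " unannotated variant(s) as 0")
      s[!have] <- 0
    }
  }
  calls$score <- s
  methods::initialize(cohort, calls = canonicalCalls(calls))
}
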