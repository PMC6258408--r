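# Internal helpers shared across modules.

# Canonical chromosome naming: strip a "chr" prefix, uppercase X/Y/MT.
normChrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  toupper(x)
}

.AUTOSOMES <- as.character(1:22)

# Chromosome scope of an inheritance model.
modelChroms <- function(model) {
  switch(model,
    AR = , AD = .AUTOSOMES,
    XR = , XD = "X",
    stop("unknown inheritance model: ", model)
  )
}

isRecessive <- function(model) model %in% c("AR", "XR")

# Canonical string key for a variant allele.
variantKey <- function(chrom, pos, ref, alt) {
  paste(normChrom(chrom), pos, ref, alt, sep = ":")
}

#' Deterministic replicate-seed derivation
#'
#' Derives the seed of stream `stream` from a master seed by one
#' Lehmer-style multiplicative step modulo 2^31 - 1, offset by the stream
#' index. All arithmetic is exact in double precision (products < 2^53)
#' and the result stays below 2^31, hence a valid R seed on every
#' platform. Used to give each simulation replicate its own independent,
#' reproducible stream.
#'
#' @param seed master seed (length-1 numeric).
#' @param stream non-negative stream index.
#' @return an integer seed.
#' @export
deriveSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  m <- 2147483647
  s <- (as.double(seed) %% m) + 1
  as.integer(((s * 48271) %% m + 104729 * as.double(stream)) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Columns every variant-call table carries, in canonical order.
.CALL_COLS <- c("individual", "gene", "chrom", "pos", "ref", "alt",
                "score", "alt_cov", "ref_cov", "phase_group")

# Coerce a data.frame of calls to the canonical schema, filling optional
# columns with NA.
canonicalCalls <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  n <- nrow(df)
  for (col in c("alt_cov", "ref_cov")) {
    if (is.null(df[[col]])) df[[col]] <- rep(NA_integer_, n)
  }
  if (is.null(df$phase_group)) df$phase_group <- rep(NA_character_, n)
  if (is.null(df$score)) df$score <- rep(NA_real_, n)
  missing <- setdiff(.CALL_COLS, names(df))
  if (length(missing))
    stop("variant call table lacks required columns: ",
         paste(missing, collapse = ", "))
  df <- df[, .CALL_COLS, drop = FALSE]
  df$individual <- as.character(df$individual)
  df$gene <- as.character(df$gene)
  df$chrom <- normChrom(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- as.character(df$ref)
  df$alt <- as.character(df$alt)
  df$score <- as.numeric(df$score)
  df$alt_cov <- suppressWarnings(as.integer(df$alt_cov))
  df$ref_cov <- suppressWarnings(as.integer(df$ref_cov))
  df$phase_group <- as.character(df$phase_group)
  rownames(df) <- NULL
  df
}
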