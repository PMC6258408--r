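# Programmatic fixtures: everything is built in code at test time.

# A call data.frame with sensible defaults for unspecified columns.
makeCalls <- function(individual, gene, chrom = "1",
                      pos = seq_along(individual) * 1000L,
                      ref = "A", alt = "T", score = 0.5,
                      alt_cov = NA_integer_, ref_cov = NA_integer_,
                      phase_group = NA_character_) {
  n <- length(individual)
  data.frame(individual = individual, gene = rep_len(gene, n),
             chrom = rep_len(chrom, n), pos = rep_len(pos, n),
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             score = rep_len(score, n), alt_cov = rep_len(alt_cov, n),
             ref_cov = rep_len(ref_cov, n),
             phase_group = rep_len(phase_group, n),
             stringsAsFactors = FALSE)
}

# A cached small synthetic panel shared by simulator tests.
smallPanel <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- makeSyntheticPanel(nGenes = 50, seed = 424)
    cache
  }
})
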