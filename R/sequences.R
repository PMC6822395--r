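# Small sequence helpers shared across modules.

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

#' Translate a nucleotide sequence with the standard genetic code
#' @param nt Nucleotide string whose length is a multiple of 3.
#' @return Amino-acid string (`*` for stop codons).
#' @keywords internal
translate_nt <- function(nt) {
  if (nchar(nt) %% 3L != 0L) stop("length not a multiple of 3")
  as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                     no.init.codon = TRUE))
}

# Run code with a private RNG stream, leaving the caller's stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
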