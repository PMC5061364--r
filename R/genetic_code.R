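# Genetic-code helpers. mtCOI is a protein-coding mitochondrial marker; all
# codon arithmetic in the package goes through these functions so the code
# table (default: invertebrate mitochondrial, where TGA = Trp and AGA/AGG =
# Ser) is applied consistently.

.code_cache <- new.env(parent = emptyenv())

#' Fetch a genetic code table
#'
#' Returns a named character vector mapping the 64 codons to one-letter amino
#' acids ("*" = stop), via [Biostrings::getGeneticCode()].
#'
#' @param code Code identifier: `"invertebrate_mito"` (NCBI translation
#'   table 5, the default for mitochondrial protein-coding genes of
#'   invertebrates such as copepods) or `"standard"`.
#' @return Named character vector of length 64.
#' @export
genetic_code <- function(code = "invertebrate_mito") {
  key <- match.arg(code, c("invertebrate_mito", "standard"))
  if (!is.null(.code_cache[[key]])) return(.code_cache[[key]])
  tab <- switch(key,
    invertebrate_mito = Biostrings::getGeneticCode("SGC4"),
    standard          = Biostrings::getGeneticCode("1")
  )
  out <- as.character(tab)
  names(out) <- names(tab)
  .code_cache[[key]] <- out
  out
}

#' Translate in-frame codons
#'
#' @param seq Character scalar, ungapped DNA over A/C/G/T, length a multiple
#'   of 3.
#' @param code Genetic code identifier, see [genetic_code()].
#' @return Character vector of one-letter amino acids, `"*"` for stops.
#' @export
translate_codons <- function(seq, code = "invertebrate_mito") {
  tab <- genetic_code(code)
  n <- nchar(seq)
  if (n %% 3L != 0L) abort("sequence length is not a multiple of 3")
  if (n == 0L) return(character(0))
  codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  unname(tab[codons])
}

#' @rdname translate_codons
#' @export
is_stop_codon <- function(codon, code = "invertebrate_mito") {
  unname(genetic_code(code)[codon] == "*")
}

# Synonymous site fraction per codon position: for codon `cod`, position
# `pos` (1..3), the fraction of the 3 possible single-base changes that
# preserve the amino acid. Changes to stop codons count as nonsynonymous
# (standard Nei-Gojobori bookkeeping).
.syn_fraction <- function(cod, pos, code = "invertebrate_mito") {
  tab <- genetic_code(code)
  aa <- tab[cod]
  bases <- c("A", "C", "G", "T")
  alt <- setdiff(bases, substr(cod, pos, pos))
  muts <- vapply(alt, function(b) {
    x <- cod
    substr(x, pos, pos) <- b
    x
  }, character(1))
  mean(tab[muts] == aa & tab[muts] != "*")
}

# 64 x 3 matrix of synonymous site fractions, cached per code.
syn_site_table <- function(code = "invertebrate_mito") {
  key <- paste0("syn_", code)
  if (!is.null(.code_cache[[key]])) return(.code_cache[[key]])
  codons <- names(genetic_code(code))
  m <- matrix(0, nrow = 64, ncol = 3, dimnames = list(codons, NULL))
  for (cod in codons) {
    for (pos in 1:3) m[cod, pos] <- .syn_fraction(cod, pos, code)
  }
  .code_cache[[key]] <- m
  m
}

# All sense (non-stop) codons for a code.
sense_codons <- function(code = "invertebrate_mito") {
  tab <- genetic_code(code)
  names(tab)[tab != "*"]
}
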