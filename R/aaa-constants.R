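# Bacterial/archaeal genetic code (translation table 11). The amino-acid
# assignments coincide with the standard code; the table differs only in
# permitted initiators, which do not affect translation of internal codons.
.codon_tables <- local({
  bases <- c("T", "C", "A", "G")
  codons <- sort(as.vector(outer(outer(bases, bases, paste0), bases, paste0)))
  code <- Biostrings::getGeneticCode("11")
  aa <- unname(code[codons])
  list(codons = codons, aa = setNames(aa, codons),
       sense = codons[aa != "*"], stops = codons[aa == "*"])
})

.CODONS <- .codon_tables$codons
.CODON_AA <- .codon_tables$aa
.SENSE_CODONS <- .codon_tables$sense
.STOP_CODONS <- .codon_tables$stops

.translate_codons <- function(codons) unname(.CODON_AA[codons])

# split an in-frame CDS string into codons
.split_codons <- function(nt) {
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3", call. = FALSE)
  substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.translate_cds <- function(nt) {
  codons <- .split_codons(toupper(nt))
  aa <- .translate_codons(codons)
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste0(aa, collapse = "")
}

# BLOSUM62 (from Biostrings) cached per session
.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})
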