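# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a nucleotide string
#'
#' Plain-character reverse complement over the alphabet A/C/G/T/N (case
#' preserved as upper case). Used throughout for minor-strand features.
#'
#' @param x a single nucleotide string
#' @return the reverse complement as a character scalar
#' @export
#' @examples
#' revcomp("ATGCC")
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  paste(rev(strsplit(chartr("ACGTacgt", "TGCATGCA", x), "")[[1]]), collapse = "")
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Genetic code: invertebrate mitochondrial (NCBI translation table 5),
# cached once per session.
.mc_env <- new.env(parent = emptyenv())

genetic_code5 <- function() {
  if (is.null(.mc_env$gc5)) {
    .mc_env$gc5 <- Biostrings::getGeneticCode("5")
  }
  .mc_env$gc5
}

sense_codons5 <- function() {
  gc5 <- genetic_code5()
  names(gc5)[gc5 != "*"]
}

stop_codons5 <- function() {
  gc5 <- genetic_code5()
  names(gc5)[gc5 == "*"]
}

translate_codon5 <- function(codon) {
  unname(genetic_code5()[codon])
}

# Circular substring extraction on a 1-based inclusive [start, end] window
# that may wrap past the end of the sequence.
circ_substr <- function(seq, start, end, genome_length = nchar(seq)) {
  start <- ((start - 1L) %% genome_length) + 1L
  end <- ((end - 1L) %% genome_length) + 1L
  if (start <= end) {
    substr(seq, start, end)
  } else {
    paste0(substr(seq, start, genome_length), substr(seq, 1L, end))
  }
}

is_nonempty_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
}

# Longest mononucleotide run in a string; returns list(base, length, start).
longest_run <- function(seq) {
  ch <- seq_chars(seq)
  r <- rle(ch)
  i <- which.max(r$lengths)
  start <- if (i == 1L) 1L else sum(r$lengths[seq_len(i - 1L)]) + 1L
  list(base = r$values[i], length = r$lengths[i], start = start)
}
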