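# Internal helpers shared across modules.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# codon -> amino acid lookup (standard nuclear code), stops mapped to "*"
codon_table <- function() {
  Biostrings::GENETIC_CODE
}

# all sense codons that are neither a stop nor ATG; used when the generator
# needs filler codons that must not open or close a reading frame
safe_codons <- function() {
  tab <- codon_table()
  names(tab)[!names(tab) %in% c(STOP_CODONS, "ATG")]
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# round half away from zero (printed-report convention; R's round() is
# round-half-even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

gc_percent <- function(x) {
  b <- strsplit(x, "")[[1]]
  100 * sum(b %in% c("G", "C")) / length(b)
}

# positions (1-based) of `pattern` in `subject`, allowing none
str_positions <- function(pattern, subject) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

# substring of a circular sequence: 0-based start, length len, wrapping
circ_substr <- function(seq, start, len) {
  L <- nchar(seq)
  stopifnot(len <= 2L * L)
  doubled <- paste0(seq, seq)
  substr(doubled, start + 1L, start + len)
}

is_dna <- function(x) {
  grepl("^[ACGTN]*$", x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
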