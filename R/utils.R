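#' @import data.table
#' @importFrom stats rpois rgeom rnorm rlnorm runif sd setNames quantile chisq.test
#' @importFrom utils head tail
NULL

# internal: stop with a formatted message, no call
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

STRANDS <- c("+", "-")

check_strand <- function(strand) {
  if (!all(strand %in% STRANDS)) {
    abort("strand must be one of '+'/'-', got: %s",
          paste(unique(setdiff(strand, STRANDS)), collapse = ", "))
  }
  invisible(strand)
}

# reverse complement of DNA character vector (keeps N)
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Phred+33 decoding of one quality string
phred33 <- function(qual) {
  if (!length(qual) || is.na(qual) || !nzchar(qual)) return(integer(0))
  utf8ToInt(qual) - 33L
}

# draw n random DNA bases as a single-string vector
random_dna <- function(n_strings, len) {
  if (n_strings == 0L) return(character(0))
  bases <- sample(c("A", "C", "G", "T"), n_strings * len, replace = TRUE)
  do.call(paste0, asplit(matrix(bases, nrow = n_strings), 2L))
}
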