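#' @importFrom rlang .data
#' @importFrom dplyr %>%
#' @import tibble
NULL

# Round to the nearest multiple of `base`, halves away from zero ("half-up").
# base::round() rounds half-to-even, which is wrong for the 10 bp breakpoint
# grid (1005 must go to 1010, not 1000).
round_to <- function(x, base = 10L) {
  as.integer(base * floor(x / base + 0.5))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# phred-scale a probability, capped like GATK-style GQs
phred <- function(p, cap = 99L) {
  q <- ifelse(p <= 0, cap, -10 * log10(p))
  as.integer(pmin(round(q), cap))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

csv_msg <- function(...) message("[clipsv] ", ...)

# shortest decimal representation that parses back to exactly `x`;
# keeps VCF fields readable while making write->read round trips exact
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(".")
    for (d in c(1:17)) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}
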