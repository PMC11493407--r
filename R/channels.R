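# 96-channel trinucleotide substitution conventions.
#
# Storage is always pyrimidine-centered: the six substitution classes are
# C>A, C>G, C>T, T>A, T>C, T>G, and within each class the 16 flank pairs run
# lexicographically (5' base fastest-varying last), giving the fixed COSMIC
# display order A[C>A]A, A[C>A]C, ..., T[T>G]T.

BASES <- c("A", "C", "G", "T")
SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse-complement a DNA string
#'
#' Vectorised reverse complement over the alphabet A/C/G/T/N.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @keywords internal
revcomp <- function(x) {
  comp <- c(COMPLEMENT, N = "N")
  vapply(strsplit(toupper(x), ""), function(b) {
    paste(rev(unname(comp[b])), collapse = "")
  }, character(1))
}

#' The 96 trinucleotide substitution channels
#'
#' Channel labels `"X[R>A]Y"` in the fixed catalog order: substitution
#' classes C>A, C>G, C>T, T>A, T>C, T>G, flanks lexicographic within each
#' class.
#'
#' @return character vector of length 96.
#' @export
#' @examples
#' head(sbs_channels())
sbs_channels <- function() {
  unlist(lapply(SUB_CLASSES, function(cls) {
    unlist(lapply(BASES, function(x5) {
      vapply(BASES, function(x3) sprintf("%s[%s]%s", x5, cls, x3), character(1))
    }))
  }), use.names = FALSE)
}

#' Map an SNV and its trinucleotide context to a spectrum channel
#'
#' Purine-reference SNVs are reverse-complemented (alleles and flanks) so the
#' stored channel is always pyrimidine-centered. Contexts containing `N` (or
#' any base outside A/C/G/T) return `"unassignable"` rather than erroring, so
#' callers can count and report them.
#'
#' @param ref,alt single reference/alternate bases of the SNV.
#' @param context 3-base uppercase string centered on the mutated base; its
#'   middle base must equal `ref`.
#' @return a channel label from [sbs_channels()], or `"unassignable"`.
#' @export
#' @examples
#' snv_channel("C", "A", "ACA")  # "A[C>A]A"
#' snv_channel("G", "T", "GGG")  # "C[C>A]C"
snv_channel <- function(ref, alt, context) {
  ref <- toupper(ref); alt <- toupper(alt); context <- toupper(context)
  if (nchar(context) != 3L)
    stop("context must be exactly 3 bases, got '", context, "'")
  if (substr(context, 2L, 2L) != ref)
    stop("context middle base ('", substr(context, 2L, 2L),
         "') does not match ref ('", ref, "')")
  if (ref == alt) stop("ref and alt are identical ('", ref, "')")
  bases <- strsplit(context, "")[[1]]
  if (!all(c(bases, alt) %in% BASES)) return("unassignable")
  if (ref %in% c("A", "G")) {
    context <- revcomp(context)
    ref <- unname(COMPLEMENT[ref])
    alt <- unname(COMPLEMENT[alt])
    bases <- strsplit(context, "")[[1]]
  }
  sprintf("%s[%s>%s]%s", bases[1L], ref, alt, bases[3L])
}

#' Substitution class of a channel label
#' @param channel character vector of channel labels.
#' @return character vector of classes, e.g. `"C>A"`.
#' @keywords internal
channel_class <- function(channel) {
  sub("^.\\[(.>.)\\].$", "\\1", channel)
}

#' Flank pair of a channel label
#' @param channel character vector of channel labels.
#' @return character vector like `"A,C"` (5' base, 3' base).
#' @keywords internal
channel_flanks <- function(channel) {
  paste(substr(channel, 1L, 1L), substr(channel, 7L, 7L), sep = ",")
}
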