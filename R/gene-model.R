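# Gene structure and nuclear geometry containers.
#
# Clock-gene structure enters the model only through lengths: the primary
# transcript length sets the transcription delay, the coding length sets the
# translation delay, and intron lengths are carried for bookkeeping (splicing
# delay is modelled as a fixed fraction of the clock period, not from intron
# length). Sequence itself is never parsed.

#' Gene model from published lengths
#'
#' Container for the structure of a segmentation-clock gene candidate, given
#' as lengths in nucleotides. Shipped examples: the *Xenopus laevis* clock
#' candidate *hes5.7L* (primary transcript 1,604 nt, CDS 465 nt, introns
#' 166 + 113 nt) and *Ambystoma mexicanum* *hes7* (primary 8,272 nt, CDS
#' 783 nt, introns 3,017 + 1,260 + 2,030 nt); see [make_gene_model()].
#'
#' @param name Gene name (text).
#' @param primary_length Primary (unspliced) transcript length, nt.
#' @param coding_length Coding-sequence length, nt.
#' @param intron_lengths Integer vector of intron lengths, nt (may be empty).
#' @return An object of class `gene_model`.
#' @export
#' @examples
#' gene_model("hes5.7L", 1604, 465, c(166, 113))
gene_model <- function(name, primary_length, coding_length,
                       intron_lengths = integer()) {
  check_positive(primary_length, "primary_length")
  check_nonnegative(coding_length, "coding_length")
  if (length(intron_lengths) && any(!is.finite(intron_lengths) | intron_lengths <= 0))
    stop_domain("all `intron_lengths` must be positive")
  if (primary_length < coding_length + sum(intron_lengths))
    stop_domain("`primary_length` must be >= coding_length + sum(intron_lengths)")
  structure(
    list(name = as.character(name),
         primary_length = primary_length,
         coding_length = coding_length,
         intron_lengths = as.numeric(intron_lengths)),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s\n", x$name))
  cat(sprintf("  primary: %d nt | CDS: %d nt | introns: %s nt\n",
              as.integer(x$primary_length), as.integer(x$coding_length),
              if (length(x$intron_lengths)) paste(as.integer(x$intron_lengths), collapse = " + ")
              else "none"))
  invisible(x)
}

#' Construct a gene model with explicit UTR padding
#'
#' Fixture-style constructor: the primary length is composed as
#' `coding_length + sum(intron_lengths) + utr_padding`, or padding is back-
#' computed when `primary_length` is given. Padding is plain filler so a
#' synthetic gene's primary length can hit a target total exactly; only the
#' lengths matter for delay arithmetic.
#'
#' @inheritParams gene_model
#' @param cds_length Coding-sequence length, nt.
#' @param utr_padding Non-coding, non-intronic nucleotides (default 0).
#' @param primary_length Optional explicit total; overrides `utr_padding`.
#' @return A `gene_model`.
#' @export
#' @examples
#' # reproduces the printed X. laevis hes5.7L structure
#' make_gene_model("hes5.7L", 465, c(166, 113), primary_length = 1604)
make_gene_model <- function(name, cds_length, intron_lengths = integer(),
                            utr_padding = 0, primary_length = NULL) {
  if (is.null(primary_length))
    primary_length <- cds_length + sum(intron_lengths) + utr_padding
  gene_model(name, primary_length, cds_length, intron_lengths)
}

#' Spherical nuclear geometry
#'
#' @param radius Nuclear radius in micrometres. PSM nuclei measure about
#'   4 um in *X. laevis* and 5.5 um in *A. mexicanum*.
#' @return An object of class `nuclear_geometry` with fields `radius` (um)
#'   and `volume` (um^3, \eqn{4/3 \pi r^3}).
#' @export
#' @examples
#' nuclear_geometry(4)$volume # ~268 um^3
nuclear_geometry <- function(radius) {
  check_positive(radius, "radius")
  structure(list(radius = radius, volume = 4 / 3 * pi * radius^3),
            class = "nuclear_geometry")
}

#' @export
print.nuclear_geometry <- function(x, ...) {
  cat(sprintf("<nuclear_geometry> r = %g um, V = %.2f um^3\n", x$radius, x$volume))
  invisible(x)
}
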