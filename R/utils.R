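#' @keywords internal
"_PACKAGE"

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; printed tables in the
#' clinical-genomics literature round half up. Used for all reported
#' percentages and Mbp sizes.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Canonical chromosome ordering: 1..22, X, Y. Unknown labels sort last.
chrom_rank <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom))
  ranks <- suppressWarnings(as.integer(chrom))
  ranks[chrom == "X"] <- 23L
  ranks[chrom == "Y"] <- 24L
  ranks[is.na(ranks)] <- 25L
  ranks
}

is_autosome <- function(chrom) {
  chrom_rank(chrom) <= 22L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Identify maximal runs of TRUE in a logical vector; returns a data.frame of
# (start, end) indices. NA counts as FALSE.
true_runs <- function(mask) {
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
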