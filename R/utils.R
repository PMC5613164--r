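#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (the convention used
#' in sequencing report tables), unlike [base::round()] which rounds half to
#' even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.125, 0.135), 2)
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # small epsilon guards against 0.5 landing just below itself in binary
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) {
  if (isTRUE(cond)) rlang::abort(msg)
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Convert 1-based inclusive intervals to BED (0-based half-open)
#'
#' Internal coordinates follow the VCF/GFF convention (1-based, inclusive);
#' BED exports are 0-based half-open. `start` is decremented by one, `end`
#' is unchanged.
#'
#' @param x A data frame with `chrom`, `start`, `end` (1-based inclusive).
#' @return A tibble with `chrom`, `start`, `end` in BED convention.
#' @export
to_bed <- function(x) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  abort_if(any(x$start < 1), "1-based start must be >= 1")
  tibble::tibble(chrom = x$chrom, start = x$start - 1L, end = x$end)
}

#' Convert BED intervals back to 1-based inclusive coordinates
#'
#' Inverse of [to_bed()].
#'
#' @param x A data frame with BED `chrom`, `start`, `end`.
#' @return A tibble in 1-based inclusive convention.
#' @export
from_bed <- function(x) {
  tibble::tibble(chrom = x$chrom, start = x$start + 1L, end = x$end)
}
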