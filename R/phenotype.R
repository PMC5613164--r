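#' Compute nitrogen-use efficiency (NUE)
#'
#' NUE (percent) is the fraction of applied nitrogen recovered in the
#' plant: `(tn_f - tn_0) / n_applied * 100`, where `tn_f` and `tn_0` are
#' total plant nitrogen under fertilized and zero-nitrogen treatment (any
#' common mass-per-area unit) and `n_applied` is the nitrogen applied in
#' the same unit. Negative values (fertilized plants accumulating less
#' nitrogen than unfertilized) are retained and flagged with a warning so
#' downstream ranking sees them.
#'
#' @param data A data frame with columns `tn_f`, `tn_0`, `n_applied`
#'   (and usually `id`).
#' @return The input as a tibble with an added `nue` column (percent).
#' @examples
#' compute_nue(data.frame(id = "p1", tn_f = 100, tn_0 = 50, n_applied = 326.1))
#' @export
compute_nue <- function(data) {
  stopifnot(all(c("tn_f", "tn_0", "n_applied") %in% names(data)))
  abort_if(any(data$n_applied <= 0), "nitrogen application must be positive")
  abort_if(any(data$tn_f < 0 | data$tn_0 < 0),
           "nitrogen contents must be non-negative")
  out <- tibble::as_tibble(data)
  out$nue <- (out$tn_f - out$tn_0) / out$n_applied * 100
  if (any(out$nue < 0)) {
    rlang::warn(sprintf("%d individual(s) have negative NUE (tn_f < tn_0); retained",
                        sum(out$nue < 0)))
  }
  out
}

#' Propagate F2:3 family means to F2 individuals
#'
#' Each F2 individual is phenotyped by the arithmetic mean of its selfed
#' F2:3 family, the standard way to phenotype an F2 genotype on a
#' heritable quantitative trait.
#'
#' @param data A data frame with `family` (F2 id) and `nue` (one row per
#'   F2:3 plant).
#' @return A tibble `id`, `nue` with one row per family.
#' @export
family_to_f2 <- function(data) {
  stopifnot(all(c("family", "nue") %in% names(data)))
  empty <- is.na(data$nue)
  abort_if(any(empty),
           paste("missing NUE in family:",
                 paste(unique(data$family[empty]), collapse = ", ")))
  abort_if(nrow(data) == 0, "no families supplied")
  data |>
    dplyr::group_by(id = .data$family) |>
    dplyr::summarise(nue = mean(.data$nue), .groups = "drop")
}

#' Summarize a phenotype distribution
#'
#' Reports n, mean, sample SD (n - 1 denominator), min, max, the max/min
#' ratio, and the Shapiro-Wilk W statistic as the normality measure
#' (requires n >= 3 and non-constant data; otherwise `normality_w` is `NA`
#' with a warning).
#'
#' @param values Numeric vector of phenotype values (percent), or a data
#'   frame with an `nue` column.
#' @return A one-row tibble: `n`, `mean`, `sd`, `min`, `max`, `range_ratio`,
#'   `normality_w`.
#' @export
summarize_phenotypes <- function(values) {
  if (is.data.frame(values)) values <- values$nue
  abort_if(length(values) == 0, "no phenotype values supplied")
  w <- NA_real_
  if (length(values) >= 3 && stats::sd(values) > 0) {
    w <- unname(stats::shapiro.test(values)$statistic)
  } else {
    rlang::warn("normality statistic undefined (n < 3 or constant data)")
  }
  tibble::tibble(
    n = length(values),
    mean = mean(values),
    sd = stats::sd(values),
    min = min(values),
    max = max(values),
    range_ratio = if (min(values) != 0) max(values) / min(values) else NA_real_,
    normality_w = w
  )
}
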