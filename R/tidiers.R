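# broom-style tidiers for fitted result objects.

#' Tidy a Kr estimate
#'
#' @param x A `kr_estimate` from [estimate_kr()].
#' @param ... Unused.
#' @return One row per direction: `direction`, `mean_shulen`, `p_hat`,
#'   `kr`.
#' @method tidy kr_estimate
#' @export
tidy.kr_estimate <- function(x, ...) x$directions

#' One-row summary of a Kr estimate
#'
#' @param x A `kr_estimate`.
#' @param ... Unused.
#' @return Tibble `kr`, `pi_hat`, `reliable`, `low_confidence`, `cap`.
#' @method glance kr_estimate
#' @export
glance.kr_estimate <- function(x, ...) {
  tibble(kr = x$kr, pi_hat = x$pi_hat, reliable = x$reliable,
         low_confidence = x$low_confidence, cap = x$cap)
}

#' Tidy a contig
#'
#' @param x A `contig` from [extend_contig()].
#' @param ... Unused.
#' @return The per-fixed-column tibble (`position`, `coverage`, `H`,
#'   `IC`, `base`).
#' @method tidy contig
#' @export
tidy.contig <- function(x, ...) x$columns

#' One-row summary of a contig
#'
#' @param x A `contig`.
#' @param ... Unused.
#' @return Tibble `length`, `circular`, `rounds`, `incomplete`,
#'   `median_coverage`.
#' @method glance contig
#' @export
glance.contig <- function(x, ...) {
  tibble(length = nchar(x$consensus), circular = x$circular,
         rounds = x$rounds, incomplete = x$incomplete,
         median_coverage = if (nrow(x$columns)) median(x$columns$coverage)
         else NA_real_)
}
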