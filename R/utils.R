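#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
NULL

# population z-score (divisor n); zero-variance vectors map to all zeros
zscore <- function(x) {
  mu <- mean(x, na.rm = TRUE)
  sdev <- sqrt(mean((x - mu)^2, na.rm = TRUE))
  if (!is.finite(sdev) || sdev == 0) return(rep(0, length(x)))
  (x - mu) / sdev
}

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
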