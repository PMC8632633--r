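#' @importFrom rlang .data %||%
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

# Deterministic per-subject seed derived from a design seed, so cohorts are
# extensible without reshuffling existing subjects. Stays below 2^31.
derive_seed <- function(seed, index) {
  s <- seed %% 2147483647
  as.integer((s * 48271 + index * 1299709) %% 2147483647)
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
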