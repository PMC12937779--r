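#' @keywords internal
#' Draw from the elements of `x` (never from `1:x` when `x` is a scalar).
sample_safe <- function(x, size = length(x), replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}
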