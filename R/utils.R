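#' @keywords internal
"_PACKAGE"

# Round half away from zero (so 61.2244.. -> 61.22 and 6.1224.. -> 6.12,
# and exact .xx5 cases go up, unlike base round()'s banker's rounding).
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Lightweight run-time notes.  Everything the pipeline considers part of its
# provenance is additionally echoed into the run log by run_pipeline().
ln_note <- function(...) message("locusnet: ", ...)

stop_ln <- function(...) stop(..., call. = FALSE)

#' @importFrom stats pt cor p.adjust phyper sd rnorm runif setNames
#' @importFrom utils read.delim write.table head
NULL
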