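#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
#' @importFrom tibble tibble
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Run code under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards so seeded helpers do not perturb the
# global stream. seed = NULL leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a stream-specific 31-bit sub-seed so nested seeded helpers do not
# reuse the parent stream
sub_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 7919L
}
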