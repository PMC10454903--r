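#' Derive a named RNG substream seed
#'
#' A run uses one master seed; each module draws from its own substream so
#' that adding or reordering modules never perturbs another module's draws.
#' The substream seed is a deterministic hash of the master seed and the
#' stream name, kept below 2^31 so it is always a valid R integer seed.
#'
#' @param seed integer master seed.
#' @param stream character stream name, e.g. `"cohort"` or `"images"`.
#' @return An integer seed.
#' @examples
#' substream_seed(1, "cohort")
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed),
            is.character(stream), length(stream) == 1, nzchar(stream))
  codes <- utf8ToInt(stream)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483629
  as.integer((abs(seed) %% 2147483629 * 48271 + h) %% 2147483629 + 1)
}

# Run code under a fixed seed without disturbing the caller's RNG state;
# seed = NULL means "use the ambient RNG stream".
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# shared contract check for sample alignment between an AER vector and a
# samples x proteins matrix; `samples` may be NULL (unnamed matrix rows)
align_aer <- function(aer, samples, n = length(samples)) {
  if (!is.null(names(aer)) && !is.null(samples)) {
    missing <- setdiff(samples, names(aer))
    if (length(missing)) {
      stop("no deformability value for sample(s): ",
           paste(missing, collapse = ", "))
    }
    aer <- aer[samples]
  }
  if (length(aer) != n) {
    stop("deformability vector length (", length(aer),
         ") does not match the number of samples (", n, ")")
  }
  unname(aer)
}
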