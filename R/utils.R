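# Internal helpers: classed conditions, seeded evaluation, small numerics.

stop_validation <- function(msg, ...) {
  stop(structure(
    class = c("sfamuscle_validation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_io <- function(msg, ...) {
  stop(structure(
    class = c("sfamuscle_io_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded to `seed`, restoring
#' the caller's RNG state afterwards, so generators never leak global state.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_scalar_positive <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0)
    stop_validation("`%s` must be a single finite number > 0 (got %s)",
                    name, paste(format(x), collapse = ", "))
  invisible(x)
}

# Reorder a DFT axis so DC lands at index floor(n/2) + 1.
fftshift_index <- function(n) {
  ((seq_len(n) - 1L + ceiling(n / 2)) %% n) + 1L
}

# Physical frequencies (per mm) of the shifted axis.
shifted_freq_axis <- function(n, spacing) {
  (seq_len(n) - 1L - floor(n / 2)) / (n * spacing)
}
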