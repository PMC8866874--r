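#' @keywords internal
"_PACKAGE"

# Small shared helpers: classed conditions and local RNG scoping.

scad_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "scad_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

stop_spec <- function(msg) scad_stop(msg, "scad_spec_error")
stop_numeric <- function(msg) scad_stop(msg, "scad_numeric_error")
stop_degenerate <- function(msg) scad_stop(msg, "scad_degenerate_error")
stop_no_evidence <- function(msg) scad_stop(msg, "scad_no_evidence_error")
stop_validation <- function(msg) scad_stop(msg, "scad_validation_error")

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded sub-computations (per-video
#' substreams, training runs) do not disturb the caller's RNG stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_spec("`seed` must be a single finite number or NULL")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream derivation: keeps derived seeds in [1, 2^31 - 2].
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 1009 * as.numeric(index)) %% 2147483646) + 1L
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

is_image <- function(img) {
  is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L &&
    is.numeric(img)
}

check_image <- function(img, what = "image") {
  if (!is_image(img)) stop_spec(sprintf("`%s` must be an H x W x 3 numeric array", what))
  if (anyNA(img) || any(!is.finite(img))) stop_numeric(sprintf("`%s` contains non-finite values", what))
  invisible(img)
}
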