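`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mechisto <- function(msg, class) {
  stop(structure(
    class = c(class, "mechisto_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Retained percentage after a filtering step
#'
#' Bookkeeping helper: the percentage of items kept by a filter, on the
#' 0-100 scale (e.g. probes retained by an expression-frequency filter).
#'
#' @param kept Number of items retained.
#' @param total Total number of items before filtering.
#' @return Percentage retained, `100 * kept / total`.
#' @examples
#' filter_retention(14364, 18677)
#' @export
filter_retention <- function(kept, total) {
  stopifnot(kept >= 0, total > 0, kept <= total)
  100 * kept / total
}
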