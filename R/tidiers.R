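#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy methods for result objects
#'
#' broom-style accessors: `tidy()` returns the per-term/per-comparison table,
#' `glance()` the one-row model summary.
#'
#' @param x a `doa_result`, `doc_result`, `kruskal_dunn` or
#'   `pipeline_report`.
#' @param ... unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy kruskal_dunn
#' @export
tidy.kruskal_dunn <- function(x, ...) {
  if (is.null(x$pairwise)) return(x$omnibus)
  x$pairwise
}

#' @rdname tidiers
#' @method glance kruskal_dunn
#' @export
glance.kruskal_dunn <- function(x, ...) {
  dplyr::mutate(x$omnibus, n_excluded = x$n_excluded)
}

#' @rdname tidiers
#' @method tidy doa_result
#' @export
tidy.doa_result <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname tidiers
#' @method tidy doc_result
#' @export
tidy.doc_result <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname tidiers
#' @method tidy pipeline_report
#' @export
tidy.pipeline_report <- function(x, ...) x$report

#' @rdname tidiers
#' @method glance pipeline_report
#' @export
glance.pipeline_report <- function(x, ...) {
  dplyr::select(x$report, "design", "seed", "doa", "doc", "n_grooves")
}
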