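# broom-style accessors for fitted model objects.

#' Tidy a fitted model
#'
#' One row per model parameter with estimate and standard error.
#'
#' @param x A `synaptrack_fit` (FCS, Hill or desensitization fit).
#' @param ... Unused.
#' @return A tibble with columns term, estimate, std.error.
#' @export
tidy.synaptrack_fit <- function(x, ...) {
  if (!is.null(x$nls)) {
    tab <- param_table(x$nls)
    # derived parameters (e.g. tau_des) have no standard error
    derived <- setdiff(names(x$params), c(tab$term, paste0(tab$term, "_s"),
                                          paste0(tab$term, "_ms"),
                                          paste0(tab$term, "_uM")))
    for (d in derived) {
      tab <- dplyr::bind_rows(tab, tibble::tibble(
        term = d, estimate = x$params[[d]], std.error = NA_real_))
    }
    return(tab)
  }
  tidyr::pivot_longer(x$params, dplyr::everything(),
                      names_to = "term", values_to = "estimate")
}

#' Glance at a fitted model
#'
#' @param x A `synaptrack_fit`.
#' @param ... Unused.
#' @return One-row tibble with fit-quality summaries and the convergence
#'   flag.
#' @export
glance.synaptrack_fit <- function(x, ...) {
  rss <- if (!is.null(x$nls)) sum(stats::resid(x$nls)^2) else NA_real_
  tibble::tibble(
    n = nrow(x$data), rss = rss,
    sigma = if (!is.null(x$nls)) stats::sigma(x$nls) else NA_real_,
    converged = x$converged
  )
}
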