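abort_config <- function(msg) rlang::abort(msg, class = "msc_config_error")
abort_data <- function(msg) rlang::abort(msg, class = "msc_data_error")

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_config(sprintf("`%s` must be a single finite number", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort_config(sprintf("`%s` = %s is outside the allowed range", name, format(x)))
  }
  invisible(x)
}

#' Derive reproducible per-stage seeds from one global seed
#'
#' A single pipeline seed fans out to one seed per named stage via a fixed
#' splitting rule (a seeded draw of integers), so every stage can also be run
#' standalone with the same stream it would see inside [run_pipeline()].
#'
#' @param seed Integer global seed.
#' @param labels Character vector of stage names.
#' @return Named integer vector of seeds, one per label.
#' @export
#' @examples
#' derive_seeds(1, c("simulate", "dea"))
derive_seeds <- function(seed, labels) {
  check_scalar_number(seed, "seed")
  stopifnot(is.character(labels), length(labels) >= 1L)
  s <- withr::with_seed(
    as.integer(seed),
    sample.int(.Machine$integer.max - 1L, length(labels))
  )
  stats::setNames(as.integer(s), labels)
}

# deterministic lexicographic pick among equally sized gene sets
lexicographic_min_set <- function(sets) {
  keys <- vapply(sets, function(s) paste(sort(s), collapse = "\r"), character(1))
  sets[[which.min(rank(keys, ties.method = "first"))]]
}
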