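# Evaluate code with a local, restored RNG state so seeded package
# operations do not disturb the caller's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Testis sampling schedule
#'
#' The recovery time course sampled testes on days 0, 3, 7, 10, 14, 17, 21,
#' 24, 28, 31, 35, 38, 42, 45, 48, 52, 56 and 59 post irradiation;
#' expression arrays were run from day 3 onward (17 sampling occasions).
#'
#' @param arrays_only If `TRUE` (default) return only the arrayed days
#'   (3..59); otherwise include day 0.
#' @return Integer vector of days post irradiation.
#' @export
sampling_schedule <- function(arrays_only = TRUE) {
  days <- c(0L, 3L, 7L, 10L, 14L, 17L, 21L, 24L, 28L, 31L, 35L, 38L, 42L,
            45L, 48L, 52L, 56L, 59L)
  if (arrays_only) days[-1L] else days
}
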