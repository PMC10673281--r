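#' Activity classes recognized by the pipeline
#'
#' Four behavioral classes are modeled: `mating`, `pupa_moving`,
#' `adult_walking`, and `resting` (background/noise-only audio).
#'
#' @return Character vector of the four class names, in canonical order.
#' @export
activity_levels <- function() c("mating", "pupa_moving", "adult_walking", "resting")

#' Per-activity frequency bands
#'
#' The frequency bands in which each sound-producing activity of the mango
#' pulp weevil concentrates its acoustic energy: mating 800--950 Hz, pupal
#' movement 1--4 kHz, adult walking 4--5 kHz. `resting` has no band (it is
#' broadband background).
#'
#' @param mating,pupa_moving,adult_walking Length-2 numeric `c(low, high)` band
#'   edges in Hz.
#' @return A tibble with columns `activity`, `f_lo`, `f_hi`.
#' @examples
#' band_scheme()
#' @export
band_scheme <- function(mating = c(800, 950),
                        pupa_moving = c(1000, 4000),
                        adult_walking = c(4000, 5000)) {
  bands <- tibble::tibble(
    activity = c("mating", "pupa_moving", "adult_walking"),
    f_lo = c(mating[1], pupa_moving[1], adult_walking[1]),
    f_hi = c(mating[2], pupa_moving[2], adult_walking[2])
  )
  assert_that(all(bands$f_lo > 0) && all(bands$f_lo < bands$f_hi),
              "each band must satisfy 0 < low < high")
  bands
}

# Validate a band table against a sampling rate (edges below Nyquist).
validate_bands <- function(bands, sample_rate) {
  assert_that(is.data.frame(bands) && all(c("activity", "f_lo", "f_hi") %in% names(bands)),
              "`bands` must have columns activity, f_lo, f_hi")
  assert_that(all(bands$f_lo < bands$f_hi),
              "each band must satisfy low < high")
  assert_that(all(bands$f_hi < sample_rate / 2),
              sprintf("band edges must lie below the Nyquist frequency (%g Hz)", sample_rate / 2))
  invisible(bands)
}
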