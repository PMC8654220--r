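# Named process substreams. Each annual random draw is addressed by
# (master seed, person id, stream, calendar year); see cb_runif_cpp.
.streams <- list(
  death = 1L, emigration = 2L, bmi = 3L, oa = 4L,
  med = c(acetaminophen = 10L, nsaid = 11L, coxib = 12L, opioid = 13L),
  gi = 20L, cvd = 21L, stroke = 22L, dyspepsia = 23L, overdose = 24L,
  gi_fatal = 25L, cvd_fatal = 26L, stroke_fatal = 27L,
  jrs_primary = 30L, jrs_revision = 31L, periop = 32L,
  jrs_pain = 33L, jrs_mobility = 34L,
  hui = 40L:47L,
  painfx = c(acetaminophen = 50L, nsaid = 51L, coxib = 52L, opioid = 53L),
  init = 60L # 60..79 reserved for initialization draws
)

#' Deterministic substream uniforms
#'
#' Draws uniforms from a counter-based generator keyed on
#' `(seed, id, stream, year)`. The same key always yields the same value,
#' independently of call order, which is what couples scenarios under common
#' random numbers.
#'
#' @param seed master seed (integer-valued scalar).
#' @param id integer vector of person ids.
#' @param stream integer process-stream identifier.
#' @param year calendar year of the draw.
#' @return numeric vector of uniforms in (0, 1), one per id.
#' @export
substream_uniform <- function(seed, id, stream, year) {
  cb_runif_cpp(as.numeric(seed), as.integer(id), as.integer(stream),
               as.integer(year))
}

# Matrix of uniforms, one column per stream.
substream_uniform_mat <- function(seed, id, streams, year) {
  cb_runif_mat_cpp(as.numeric(seed), as.integer(id), as.integer(streams),
                   as.integer(year))
}

# Standard-normal draws on a substream (inverse-CDF transform).
substream_normal <- function(seed, id, stream, year) {
  qnorm(substream_uniform(seed, id, stream, year))
}
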