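
# Internal helpers ------------------------------------------------------------

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

# Named substream seeds so every pipeline stage draws from its own stream,
# all derived from one root seed. Kept below 2^31 - 1.
substream_seed <- function(seed, stage) {
  stages <- c(simulate = 1L, curves = 2L, extract = 3L, screen = 4L,
              search = 5L, correlate = 6L, report = 7L)
  off <- stages[[stage]]
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483647)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x) && x >= 0

# two-level group factor used throughout: control is the reference level
as_group_factor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  assert_that(all(x %in% c("control", "stroke")),
              "`group` must contain only \"control\" and \"stroke\".")
  factor(x, levels = c("control", "stroke"))
}

group_indicator <- function(group) as.integer(as_group_factor(group) == "stroke")
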