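## Small internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for all reported percentages so
#' that printed proportions recompute exactly from integer counts.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` places.
#' @examples
#' round_half_up(14.3988, 2)  # 14.40
#' round_half_up(2.005, 2)    # 2.01 (base round() would give 2.00)
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage from a count and a denominator
#'
#' @param count numerator count.
#' @param denom denominator count; `0` or `NA` gives `NA` (undefined
#'   proportion flag).
#' @param digits decimal places (half-up rounding).
#' @return percentage on the 0-100 scale, or `NA_real_`.
#' @export
pct_of <- function(count, denom, digits = 2) {
  ifelse(is.na(denom) | denom == 0, NA_real_,
         round_half_up(100 * count / denom, digits))
}

## half-open window starts tiling [1, len]: full windows at `step`, plus one
## truncated terminal window when the tiling does not land on the end.
window_starts <- function(len, win_size, step) {
  if (len < 1) return(integer(0))
  if (win_size >= len) return(1L)
  last_full <- len - win_size + 1
  starts <- seq.int(1L, last_full, by = step)
  if ((last_full - 1) %% step != 0) {
    starts <- c(starts, starts[length(starts)] + step)
  }
  starts
}

## stop() with a class so callers/tests can distinguish failure modes
hb_stop <- function(msg, class) {
  stop(structure(class = c(class, "hapblocks_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

msg_log <- function(verbose, ...) {
  if (isTRUE(verbose)) message(sprintf(...))
}
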