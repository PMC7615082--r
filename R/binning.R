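# Discretization of continuous clinical measurements (blood pressure, BMI)
# into categorical tokens.  Values inside [lo, hi] fall into half-open bins
# [lo + k*step, lo + (k+1)*step); the upper boundary hi is kept and assigned
# to the last bin so that boundary readings are not silently dropped.
# Out-of-range or non-finite values are rejected (the record is dropped).

#' Define a binning scheme for a continuous measurement
#'
#' @param lo,hi inclusive range of plausible values (same units as the data)
#' @param step bin width; `hi - lo` must be an integer multiple of `step`
#' @param prefix token prefix, e.g. `"SBP"` emits tokens like `"SBP_90_95"`
#' @return an object of class `binning_scheme`
#' @examples
#' sc <- binning_scheme(80, 200, 5, "SBP")
#' bin_value(92, sc)     # "SBP_90_95"
#' count_bins(sc)        # 24
#' @export
binning_scheme <- function(lo, hi, step, prefix) {
  stopifnot(is.numeric(lo), is.numeric(hi), is.numeric(step),
            step > 0, hi > lo)
  k <- (hi - lo) / step
  if (abs(k - round(k)) > 1e-9)
    stop("(hi - lo) must be an integer multiple of step")
  structure(list(lo = lo, hi = hi, step = step, prefix = prefix),
            class = "binning_scheme")
}

#' Number of bins of a scheme
#' @param scheme a [binning_scheme()]
#' @return integer, `(hi - lo) / step`
#' @export
count_bins <- function(scheme) {
  as.integer(round((scheme$hi - scheme$lo) / scheme$step))
}

fmt_num <- function(x) {
  # plain decimal text: 85 -> "85", 22.50 -> "22.5"
  s <- format(x, trim = TRUE, scientific = FALSE)
  sub("\\.$", "", sub("(\\.[0-9]*?)0+$", "\\1", s))
}

#' Map a continuous value to its bin token
#'
#' Vectorized over `value`; out-of-range or non-finite values yield `NA`
#' (the caller drops the record).
#'
#' @param value numeric vector of measurements
#' @param scheme a [binning_scheme()]
#' @return character vector of tokens, `NA` where rejected
#' @export
bin_value <- function(value, scheme) {
  n_bins <- count_bins(scheme)
  idx <- floor((value - scheme$lo) / scheme$step)
  at_hi <- !is.na(value) & value == scheme$hi
  idx[at_hi] <- n_bins - 1  # closed upper boundary
  ok <- is.finite(value) & value >= scheme$lo & value <= scheme$hi
  idx[!ok] <- 0  # placeholder; token overwritten with NA below
  lo_k <- scheme$lo + idx * scheme$step
  tok <- paste0(scheme$prefix, "_", fmt_num(lo_k), "_",
                fmt_num(lo_k + scheme$step))
  tok[!ok] <- NA_character_
  tok
}

#' All tokens a scheme can emit, in bin order
#' @param scheme a [binning_scheme()]
#' @return character vector of length `count_bins(scheme)`
#' @export
bin_tokens <- function(scheme) {
  lo_k <- scheme$lo + (seq_len(count_bins(scheme)) - 1) * scheme$step
  paste0(scheme$prefix, "_", fmt_num(lo_k), "_", fmt_num(lo_k + scheme$step))
}

#' Default binning schemes for the value-bearing modalities
#'
#' Systolic BP 80-200 mmHg and diastolic BP 50-140 mmHg in 5-mmHg steps,
#' BMI 16-50 kg/m^2 in 1-unit steps.
#'
#' @return named list of [binning_scheme()]s keyed by modality
#' @export
default_schemes <- function() {
  list(systolic_bp  = binning_scheme(80, 200, 5, "SBP"),
       diastolic_bp = binning_scheme(50, 140, 5, "DBP"),
       bmi          = binning_scheme(16, 50, 1, "BMI"))
}
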