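#' Years-quit bins for former smokers
#'
#' Former smokers are tracked in six bins of years since quitting. The bin
#' width controls how fast survivors advance to the next bin (one bin
#' boundary per width-years, assuming a uniform within-bin distribution).
#'
#' @return A data frame with columns `bin` (label) and `width` (years;
#'   `Inf` for the open terminal bin).
#' @export
#' @examples
#' quit_bins()
quit_bins <- function() {
  data.frame(bin = QUIT_BINS, width = unname(QUIT_BIN_WIDTHS),
             stringsAsFactors = FALSE)
}

#' Excess-risk decay ladder for former smokers
#'
#' The excess mortality risk of a former smoker decays with years since
#' quitting on a log-linear scale: `former RR = exp(X * log(smoker RR))`,
#' where the exponent fraction `X` depends on the years-quit bin. The
#' default ladder sets X to 100% for quit < 1 year, 92% for 1-2 years,
#' 79% for 3-5 years, 58% for 6-10 years, 32.5% for 11-15 years and 8%
#' for more than 15 years.
#'
#' @param x Named numeric vector of exponent fractions, one per quit bin
#'   (names must match [quit_bins()]); values in (0, 1], strictly
#'   decreasing across bins.
#' @return An object of class `rr_ladder`.
#' @export
#' @examples
#' rr_ladder()
rr_ladder <- function(x = c(`<1` = 1, `1-2` = 0.92, `3-5` = 0.79,
                            `6-10` = 0.58, `11-15` = 0.325, `>15` = 0.08)) {
  if (!identical(names(x), QUIT_BINS)) {
    stop("ladder must be named by the quit bins: ",
         paste(QUIT_BINS, collapse = ", "))
  }
  if (any(x <= 0) || any(x > 1)) stop("ladder exponents must lie in (0, 1]")
  if (any(diff(x) >= 0)) {
    stop("ladder exponents must be strictly decreasing across bins")
  }
  structure(list(x = x), class = "rr_ladder")
}

#' @export
print.rr_ladder <- function(x, ...) {
  cat("Former-smoker relative-risk ladder (exponent X by years quit):\n")
  print(x$x)
  invisible(x)
}

#' Relative risk of death for former smokers
#'
#' Derives the former-smoker relative risk (vs never smokers) from the
#' current-smoker relative risk and a years-quit bin:
#' `exp(X(bin) * log(smoker_rr))`.
#'
#' @param smoker_rr Current-smoker relative risk (current/never death-rate
#'   ratio); must be > 0. Vectorized.
#' @param bin Quit bin label(s), see [quit_bins()].
#' @param ladder An [rr_ladder()].
#' @return Former-smoker relative risk(s), between 1 and `smoker_rr`.
#' @export
#' @examples
#' former_smoker_rr(20, "6-10")   # 20^0.58
#' former_smoker_rr(2.5, "<1")    # unchanged
former_smoker_rr <- function(smoker_rr, bin, ladder = rr_ladder()) {
  if (any(!is.finite(smoker_rr)) || any(smoker_rr <= 0)) {
    stop("smoker_rr must be positive and finite")
  }
  if (any(!bin %in% QUIT_BINS)) {
    stop("unknown quit bin; valid bins: ", paste(QUIT_BINS, collapse = ", "))
  }
  exp(unname(ladder$x[bin]) * log(smoker_rr))
}

#' Death rate for former smokers by years quit
#'
#' Former-smoker death rates are obtained from the never- and
#' current-smoker rates: the smoker RR (`d_current / d_never`) is decayed
#' through the quit-bin ladder and re-applied to the never-smoker rate,
#' equivalently `d_current * formerRR / smokerRR`.
#'
#' @param d_never,d_current Annual death probabilities with
#'   `0 <= d_never <= d_current <= 1`; `d_never` must be positive wherever
#'   `d_current` is (the RR is undefined otherwise). Vectorized.
#' @inheritParams former_smoker_rr
#' @return Annual death probability in `[d_never, d_current]`.
#' @export
#' @examples
#' former_death_rate(0.01, 0.02, "6-10")  # 0.01 * 2^0.58
former_death_rate <- function(d_never, d_current, bin, ladder = rr_ladder()) {
  if (any(d_never < 0 | d_never > 1 | d_current < 0 | d_current > 1)) {
    stop("death rates must lie in [0, 1]")
  }
  if (any(d_current < d_never)) {
    stop("d_current must be >= d_never")
  }
  out <- numeric(length(d_never))
  zero <- d_never == 0
  if (any(zero & d_current > 0)) {
    stop("d_never = 0 with d_current > 0: smoker RR undefined")
  }
  if (any(!zero)) {
    out[!zero] <- d_never[!zero] *
      former_smoker_rr(d_current[!zero] / d_never[!zero],
                       rep_len(bin, length(d_never))[!zero], ladder)
  }
  out
}
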