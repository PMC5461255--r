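#' Canonical names of the thirteen battery predictor variables
#'
#' The thirteen predictor variables entered into the PLS regression, in
#' canonical order: the Text Reception Threshold words-correct score
#' (\code{TRT}), the multiple-choice vocabulary test score (\code{WST}),
#' Operation Span letters recalled (\code{OperationSpan}), verbal-learning
#' sum over list-learning trials 1--5 (\code{Verbal_learning}), delayed
#' minus immediate recall (\code{Recall}), recognition hits
#' (\code{Recognition}), the lexical-decision non-word minus word reaction
#' time in ms (\code{RT_word}), the low- minus high-frequency word reaction
#' time in ms (\code{RT_freq}), the four trail-making switching costs in
#' seconds (\code{CTMT_1_2} .. \code{CTMT_1_5}, subtest k minus subtest 1),
#' and the Stroop interference minus bar-naming time in seconds
#' (\code{Distraction_sensitivity}).
#'
#' @return Character vector of length 13.
#' @export
#' @examples
#' battery_variables()
battery_variables <- function() {
  c("TRT", "WST", "OperationSpan", "Verbal_learning", "Recall",
    "Recognition", "RT_word", "RT_freq",
    "CTMT_1_2", "CTMT_1_3", "CTMT_1_4", "CTMT_1_5",
    "Distraction_sensitivity")
}

#' Name of the response column in a battery dataset
#' @return The string \code{"y_median"} (per-subject median words correct
#'   per sentence, 0--7).
#' @export
battery_response <- function() "y_median"

#' Published group calibration for the synthetic battery generator
#'
#' Per-age-group means and standard deviations of the thirteen predictor
#' variables and of the response (median vocoded-speech words correct per
#' seven-word sentence), as reported for the young (n = 21) and older
#' (n = 20) groups of the two-age-group study design the generator
#' emulates.  These constants are the default calibration of
#' [generator_config()]; the same values ship as a YAML file in
#' \code{system.file("extdata", "table1_calibration.yaml", package =
#' "vocopred")}.
#'
#' @return A list with elements \code{means} and \code{sds}, each a list
#'   with named numeric vectors \code{young} and \code{old} over
#'   \code{c(battery_variables(), battery_response())}.
#' @export
#' @examples
#' table1_calibration()$means$old[["TRT"]]
table1_calibration <- function() {
  vars <- c(battery_variables(), battery_response())
  young_mean <- c(62.76, 32.05, 59.62, 65.24, 0.05, 14.71, 302.86, 164.10,
                  3.71, 5.02, 0.23, 11.04, 20.95, 4.40)
  young_sd   <- c(13.21, 2.20, 9.16, 6.39, 0.67, 0.56, 153.20, 131.98,
                  6.37, 6.16, 6.83, 7.86, 6.54, 2.26)
  old_mean   <- c(42.20, 34.40, 41.89, 57.30, 1.45, 13.80, 180.25, 245.65,
                  -3.00, 5.80, -5.00, 20.95, 28.75, 2.50)
  old_sd     <- c(10.76, 2.22, 17.80, 9.48, 2.04, 1.47, 89.84, 241.06,
                  13.39, 9.58, 13.10, 14.75, 8.34, 1.93)
  names(young_mean) <- names(young_sd) <- vars
  names(old_mean) <- names(old_sd) <- vars
  list(means = list(young = young_mean, old = old_mean),
       sds   = list(young = young_sd,  old = old_sd))
}

#' Default latent-factor loadings of the generator
#'
#' Signed loadings of each predictor on the single latent
#' "cognitive efficiency" factor, on the standardized scale (so the
#' population correlation between predictor j and the latent factor is the
#' loading itself).  Reaction-time variables load negatively: larger times
#' mean worse performance.  The default magnitudes are chosen so that the
#' implied predictor-response correlations (loading times the response
#' loading, 0.75 by default) mirror the pattern of univariate correlations
#' observed in the study the generator emulates: strongest for TRT,
#' Operation Span and the subtest-5 trail-making cost, moderate for verbal
#' learning, weak for vocabulary and recognition.
#'
#' @return Named numeric vector over [battery_variables()], values in
#'   (-1, 1).
#' @export
default_latent_loadings <- function() {
  c(TRT = 0.65, WST = 0.15, OperationSpan = 0.60, Verbal_learning = 0.45,
    Recall = 0.10, Recognition = 0.30, RT_word = -0.15, RT_freq = -0.10,
    CTMT_1_2 = -0.25, CTMT_1_3 = -0.25, CTMT_1_4 = -0.25, CTMT_1_5 = -0.55,
    Distraction_sensitivity = -0.30)
}

#' Strong-signal loadings for recovery experiments
#'
#' A sparse loading pattern used to probe whether the selection pipeline
#' recovers known signal variables: five predictors carry a strong loading
#' (|0.85|, negative for the trail-making cost) and the remaining eight
#' carry none.  Variables with nonzero loading are the generator's "signal
#' variables" (see [signal_variables()]).
#'
#' @return Named numeric vector over [battery_variables()].
#' @export
strong_latent_loadings <- function() {
  l <- setNames(numeric(13), battery_variables())
  l[c("TRT", "OperationSpan", "Verbal_learning", "Recognition")] <- 0.85
  l["CTMT_1_5"] <- -0.85
  l
}

#' Signal variables of a generator configuration
#'
#' @param config A [generator_config()].
#' @param threshold Minimum absolute latent loading for a predictor to
#'   count as signal-bearing (default 0.5).
#' @return Character vector of predictor names.
#' @export
signal_variables <- function(config, threshold = 0.5) {
  l <- config$latent_loadings
  names(l)[abs(l) >= threshold]
}
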