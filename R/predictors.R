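#' Derive the thirteen canonical predictors from raw test records
#'
#' Maps one row of raw cognitive test results per subject onto the
#' thirteen predictor variables entering the PLS analysis:
#' \describe{
#'   \item{TRT}{words correctly identified in the Text Reception
#'     Threshold test (\code{trt_words}).}
#'   \item{WST}{correct target words of the multiple-choice vocabulary
#'     test (\code{wst_correct}, 0--42).}
#'   \item{OperationSpan}{letters recalled in the Operation Span test.}
#'   \item{Verbal_learning}{sum of list-learning trials 1--5.}
#'   \item{Recall}{trial 7 minus trial 5 (delayed minus immediate recall;
#'     flip with \code{recall_convention = "t5_minus_t7"}).}
#'   \item{Recognition}{targets recognized in trial 8.}
#'   \item{RT_word}{lexical-decision reaction time, non-words minus
#'     words (correct responses only, ms).}
#'   \item{RT_freq}{low- minus high-frequency words (ms).}
#'   \item{CTMT_1_2 .. CTMT_1_5}{trail-making subtest k minus subtest 1
#'     times (s).}
#'   \item{Distraction_sensitivity}{Stroop interference minus bar-naming
#'     median times (s).}
#' }
#' Missing raw fields propagate to missing predictors (they are never
#' imputed as zero); subjects with missing predictors are excluded later
#' by [validate_dataset()].
#'
#' @param raw Data frame, one row per subject, with columns
#'   \code{subject_id}, \code{vlrt_t1} .. \code{vlrt_t8},
#'   \code{ospan_letters}, \code{trt_words}, \code{wst_correct},
#'   \code{ldt_rt_word}, \code{ldt_rt_nonword}, \code{ldt_rt_high},
#'   \code{ldt_rt_low}, \code{stroop_reading}, \code{stroop_bar},
#'   \code{stroop_interference}, \code{ctmt_1} .. \code{ctmt_5}.
#' @param recall_convention \code{"t7_minus_t5"} (literal difference
#'   between trials 7 and 5, the default) or \code{"t5_minus_t7"}.
#' @return Data frame: \code{subject_id} plus the thirteen
#'   [battery_variables()] in canonical order.
#' @export
derive_predictors <- function(raw,
                              recall_convention = c("t7_minus_t5",
                                                    "t5_minus_t7")) {
  recall_convention <- match.arg(recall_convention)
  need <- c("subject_id", paste0("vlrt_t", 1:8), "ospan_letters",
            "trt_words", "wst_correct", "ldt_rt_word", "ldt_rt_nonword",
            "ldt_rt_high", "ldt_rt_low", "stroop_reading", "stroop_bar",
            "stroop_interference", paste0("ctmt_", 1:5))
  miss <- setdiff(need, names(raw))
  if (length(miss)) .stopf("raw records missing column(s): %s",
                           paste(miss, collapse = ", "))
  .check_range <- function(col, lo = 0, hi = Inf, strict_lo = FALSE) {
    v <- raw[[col]]
    bad <- !is.na(v) & (if (strict_lo) v <= lo else v < lo | v > hi)
    if (any(bad)) .stopf("invalid value in field '%s' (row %s)", col,
                         paste(which(bad), collapse = ", "))
  }
  for (k in 1:7) .check_range(paste0("vlrt_t", k), 0, 15)
  .check_range("vlrt_t8", 0, 15)
  .check_range("ospan_letters", 0)
  .check_range("trt_words", 0)
  .check_range("wst_correct", 0, 42)
  for (col in c("stroop_reading", "stroop_bar", "stroop_interference",
                paste0("ctmt_", 1:5))) {
    .check_range(col, 0, strict_lo = TRUE)
  }
  recall <- if (recall_convention == "t7_minus_t5") {
    raw$vlrt_t7 - raw$vlrt_t5
  } else {
    raw$vlrt_t5 - raw$vlrt_t7
  }
  out <- data.frame(
    subject_id = raw$subject_id,
    TRT = raw$trt_words,
    WST = raw$wst_correct,
    OperationSpan = raw$ospan_letters,
    Verbal_learning = raw$vlrt_t1 + raw$vlrt_t2 + raw$vlrt_t3 +
      raw$vlrt_t4 + raw$vlrt_t5,
    Recall = recall,
    Recognition = raw$vlrt_t8,
    RT_word = raw$ldt_rt_nonword - raw$ldt_rt_word,
    RT_freq = raw$ldt_rt_low - raw$ldt_rt_high,
    CTMT_1_2 = raw$ctmt_2 - raw$ctmt_1,
    CTMT_1_3 = raw$ctmt_3 - raw$ctmt_1,
    CTMT_1_4 = raw$ctmt_4 - raw$ctmt_1,
    CTMT_1_5 = raw$ctmt_5 - raw$ctmt_1,
    Distraction_sensitivity = raw$stroop_interference - raw$stroop_bar,
    stringsAsFactors = FALSE
  )
  stopifnot(identical(names(out)[-1], battery_variables()))
  out
}
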