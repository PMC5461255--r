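#' Score one open-set sentence repetition
#'
#' Counts accurately reported words: tokens are lower-cased and stripped
#' of punctuation, matching is order-free and exact at the surface level
#' (no lemmatization), and each target word can be credited at most once
#' — repeating a target twice earns a single credit.
#'
#' @param target_words Target sentence, as a character vector of tokens
#'   or a single whitespace-separated string (seven words in the standard
#'   sentence test).
#' @param reported_words The listener's report, same formats.
#' @return Integer count of correctly reported words.
#' @export
#' @examples
#' score_sentence("Der kleine Hund jagt die braune Katze",
#'                "die katze jagt den Hund")
score_sentence <- function(target_words, reported_words) {
  tgt <- .tokenize(target_words)
  rep_ <- .tokenize(reported_words)
  if (length(rep_) == 0 || length(tgt) == 0) return(0L)
  tt <- table(tgt)
  rt <- table(rep_)
  common <- intersect(names(tt), names(rt))
  as.integer(sum(pmin(tt[common], rt[common])))
}

.tokenize <- function(x) {
  if (length(x) == 1 && grepl("\\s", x)) x <- strsplit(x, "\\s+")[[1]]
  x <- tolower(x)
  x <- gsub("[[:punct:]]", "", x)
  x[nzchar(x)]
}

#' Per-subject median performance
#'
#' The subject-level response variable of the analysis: the median
#' words-correct over the test trials (practice excluded upstream).
#' Medians of an even number of integer scores live on the half-integer
#' lattice.
#'
#' @param trials Either a numeric vector of per-sentence scores for one
#'   subject, or a trial data frame with columns \code{subject_id} and
#'   \code{n_correct}.
#' @return A single median, or a named vector of per-subject medians.
#' @export
median_performance <- function(trials) {
  if (is.data.frame(trials)) {
    ids <- unique(trials$subject_id)
    out <- vapply(ids, function(s) {
      median(trials$n_correct[trials$subject_id == s])
    }, 0)
    names(out) <- ids
    return(out)
  }
  median(as.numeric(trials))
}

#' Block-wise learning curves
#'
#' Splits each subject's trials into consecutive blocks (default 10
#' sentences, so 60 trials give six blocks), takes the per-subject median
#' within each block, and aggregates across subjects within each group by
#' the median again.
#'
#' @param trials Trial data frame with \code{subject_id},
#'   \code{trial_index}, \code{n_correct}.
#' @param block_size Sentences per block (default 10).
#' @param groups Optional named vector or factor mapping
#'   \code{subject_id} to a group label; if omitted a single overall
#'   curve is returned.
#' @return Data frame: \code{group}, \code{block}, \code{median_score}.
#' @export
learning_curve <- function(trials, block_size = 10, groups = NULL) {
  ids <- unique(trials$subject_id)
  per_subject <- do.call(rbind, lapply(ids, function(s) {
    tr <- trials[trials$subject_id == s, ]
    tr <- tr[order(tr$trial_index), ]
    blk <- ceiling(seq_len(nrow(tr)) / block_size)
    data.frame(subject_id = s, block = unique(blk),
               m = vapply(unique(blk),
                          function(b) median(tr$n_correct[blk == b]), 0))
  }))
  grp <- if (is.null(groups)) {
    rep("all", nrow(per_subject))
  } else {
    as.character(groups[as.character(per_subject$subject_id)])
  }
  agg <- aggregate(m ~ grp + block,
                   data = cbind(per_subject, grp = grp), FUN = median)
  data.frame(group = agg$grp, block = agg$block, median_score = agg$m)
}

#' Group summary of the response with two-sample t statistics
#'
#' Means and SDs of the per-subject median performance per age group,
#' with both the pooled-variance and the Welch two-sample t test between
#' the two groups.
#'
#' @param dataset Battery data frame with \code{age_group} and
#'   \code{y_median}.
#' @return List with \code{summary} (data frame group/n/mean/sd),
#'   \code{t_pooled} and \code{t_welch} (\code{htest} objects).
#' @export
group_summary <- function(dataset) {
  # groups ordered by first appearance (young before old in canonical data)
  g <- factor(as.character(dataset$age_group),
              levels = unique(as.character(dataset$age_group)))
  if (nlevels(droplevels(g)) != 2) {
    .stopf("group_summary requires exactly 2 groups, found %d",
           nlevels(droplevels(g)))
  }
  y <- dataset[[battery_response()]]
  smry <- do.call(rbind, lapply(levels(droplevels(g)), function(l) {
    data.frame(group = l, n = sum(g == l), mean = mean(y[g == l]),
               sd = sd(y[g == l]))
  }))
  list(summary = smry,
       t_pooled = t.test(y ~ droplevels(g), var.equal = TRUE),
       t_welch = t.test(y ~ droplevels(g)))
}

#' Read a trial-level CSV
#'
#' Expected columns: \code{subject_id}, \code{trial_index}, and either
#' \code{n_correct} or the pair \code{target}/\code{report} (whitespace
#' separated word strings), in which case \code{n_correct} is computed
#' with [score_sentence()].
#'
#' @param path CSV file path.
#' @return Trial data frame with \code{n_correct} filled in.
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "trial_index")
  miss <- setdiff(need, names(tr))
  if (length(miss)) .stopf("trial CSV missing column(s): %s",
                           paste(miss, collapse = ", "))
  if (!"n_correct" %in% names(tr)) {
    if (!all(c("target", "report") %in% names(tr))) {
      .stopf("trial CSV needs either n_correct or target + report columns")
    }
    tr$n_correct <- mapply(score_sentence, tr$target, tr$report)
  }
  if (any(tr$n_correct < 0 | tr$n_correct > 7)) {
    .stopf("n_correct outside 0..7")
  }
  dup <- duplicated(tr[c("subject_id", "trial_index")])
  if (any(dup)) .stopf("duplicated trial_index within subject")
  tr
}
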