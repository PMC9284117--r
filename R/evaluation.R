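# Clinical evaluation of facial-weakness calls: majority-vote ground truth
# from Likert ratings, laterality-aware confusion counts and metrics,
# stratified patient-level bootstrap confidence intervals, Fisher's exact
# test, Fleiss' kappa, subject-grouped cross-validation and ROC curves.
#
# Scoring rules: a false negative is a truth-present video called absent OR
# called present with the wrong laterality (laterality errors are false
# negatives, not false positives); a false positive is calling weakness
# present when a normal smile is the ground truth.

#' Collapse 1-5 Likert ratings to absent / indeterminate / present
#'
#' Scores 1-2 collapse to `absent`, 3 to `indeterminate`, 4-5 to `present`
#' (laterality carried through). Laterality must be given exactly when the
#' score is 4 or 5.
#'
#' @param ratings data.frame with columns `rater_id`, `video_id`, `likert`
#'   (integer 1-5) and `laterality` (`"left"`, `"right"` or `NA`).
#' @return data.frame with columns `rater_id`, `video_id`, `call`,
#'   `laterality`.
#' @export
collapse_ratings <- function(ratings) {
  stopifnot(all(c("rater_id", "video_id", "likert") %in% names(ratings)))
  lik <- ratings$likert
  if (!all(lik %in% 1:5)) stop("likert scores must be integers 1-5")
  lat <- if ("laterality" %in% names(ratings))
    as.character(ratings$laterality) else rep(NA_character_, nrow(ratings))
  need <- lik >= 4
  if (any(need & (is.na(lat) | !lat %in% c("left", "right"))))
    stop("laterality (left/right) is required for likert scores 4 and 5")
  if (any(!need & !is.na(lat)))
    stop("laterality must be absent for likert scores 1-3")
  call <- c("absent", "absent", "indeterminate", "present", "present")[lik]
  data.frame(rater_id = ratings$rater_id, video_id = ratings$video_id,
             call = call,
             laterality = ifelse(need, lat, NA_character_),
             stringsAsFactors = FALSE)
}

#' Majority-vote ground truth across raters
#'
#' Truth per video is the modal collapsed call across raters; laterality is
#' the modal laterality among present-callers. A tie for the modal call or
#' laterality, or a modal call of `indeterminate`, yields an `unknown` truth
#' which is flagged and excluded with a warning.
#'
#' @param collapsed output of [collapse_ratings()].
#' @param n_raters expected (odd) number of raters per video.
#' @param subjects optional data.frame `video_id`, `subject_id` to carry
#'   subject identifiers into the truth table.
#' @return data.frame with columns `video_id`, `truth` (`absent`/`present`),
#'   `laterality`, `subject_id`; videos with unknown truth are dropped.
#' @export
majority_truth <- function(collapsed, n_raters = 3, subjects = NULL) {
  if (n_raters %% 2 == 0) stop("n_raters must be odd")
  sp <- split(collapsed, collapsed$video_id)
  bad <- names(sp)[vapply(sp, nrow, 0L) != n_raters]
  if (length(bad))
    stop("videos without exactly ", n_raters, " ratings: ",
         paste(utils::head(bad, 5), collapse = ", "))
  rows <- lapply(sp, function(d) {
    tab <- table(factor(d$call, c("absent", "indeterminate", "present")))
    mx <- max(tab)
    modal <- names(tab)[tab == mx]
    if (length(modal) != 1 || modal == "indeterminate")
      return(data.frame(video_id = d$video_id[1], truth = "unknown",
                        laterality = NA_character_, stringsAsFactors = FALSE))
    lat <- NA_character_
    if (modal == "present") {
      lt <- table(factor(d$laterality[d$call == "present"], c("left", "right")))
      lmx <- max(lt)
      lmodal <- names(lt)[lt == lmx]
      if (length(lmodal) != 1)
        return(data.frame(video_id = d$video_id[1], truth = "unknown",
                          laterality = NA_character_, stringsAsFactors = FALSE))
      lat <- lmodal
    }
    data.frame(video_id = d$video_id[1], truth = modal, laterality = lat,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$truth == "unknown")) {
    warning(sum(out$truth == "unknown"),
            " video(s) with unknown ground truth excluded")
    out <- out[out$truth != "unknown", , drop = FALSE]
  }
  if (!is.null(subjects)) {
    out$subject_id <- subjects$subject_id[match(out$video_id,
                                                subjects$video_id)]
  } else if (!"subject_id" %in% names(out)) {
    out$subject_id <- out$video_id
  }
  out
}

#' Convert algorithm labels to presence/laterality calls
#'
#' @param labels character vector in `normal`/`left`/`right`.
#' @param video_id matching video identifiers.
#' @param rater_id rater identifier for the calls table.
#' @return calls data.frame (`rater_id`, `video_id`, `call`, `laterality`).
#' @export
labels_to_calls <- function(labels, video_id, rater_id = "algorithm") {
  stopifnot(all(labels %in% FW_CLASSES))
  data.frame(rater_id = rater_id, video_id = video_id,
             call = ifelse(labels == "normal", "absent", "present"),
             laterality = ifelse(labels == "normal", NA_character_, labels),
             stringsAsFactors = FALSE)
}

#' Truth table from a synthetic cohort manifest
#' @param manifest cohort manifest (see [generate_cohort()]).
#' @return truth data.frame (`video_id`, `truth`, `laterality`, `subject_id`).
#' @export
truth_from_manifest <- function(manifest) {
  data.frame(video_id = manifest$video_id,
             truth = ifelse(manifest$true_label == "normal",
                            "absent", "present"),
             laterality = ifelse(manifest$true_label == "normal",
                                 NA_character_, manifest$true_label),
             subject_id = manifest$subject_id, stringsAsFactors = FALSE)
}

# score each (video, rater) pair; indeterminate calls denote no presence
# claim and are scored as absent calls.
.score_calls <- function(calls, truth, ignore_laterality = FALSE) {
  m <- match(calls$video_id, truth$video_id)
  if (anyNA(m)) stop("calls reference videos missing from the truth table")
  t_pres <- truth$truth[m] == "present"
  t_lat <- truth$laterality[m]
  c_pres <- calls$call == "present"
  lat_ok <- c_pres & t_pres &
    !is.na(calls$laterality) & calls$laterality == t_lat
  data.frame(
    rater_id = if ("rater_id" %in% names(calls)) calls$rater_id else "rater",
    video_id = calls$video_id,
    subject_id = truth$subject_id[m],
    truth_present = t_pres,
    tp = t_pres & c_pres & (lat_ok | ignore_laterality),
    fn = t_pres & (!c_pres | (c_pres & !lat_ok & !ignore_laterality)),
    fp = !t_pres & c_pres,
    tn = !t_pres & !c_pres,
    lat_correct = t_pres & c_pres & lat_ok,
    lat_incorrect = t_pres & c_pres & !lat_ok,
    stringsAsFactors = FALSE)
}

#' Laterality-aware confusion counts
#'
#' @param calls calls data.frame (`video_id`, `call` in
#'   `absent`/`indeterminate`/`present`, `laterality`, optional `rater_id`);
#'   see [labels_to_calls()] and [collapse_ratings()].
#' @param truth truth data.frame (see [majority_truth()] /
#'   [truth_from_manifest()]).
#' @param ignore_laterality score presence only (wrong-laterality present
#'   calls count as true positives) — the laterality-excluded sensitivity
#'   analysis.
#' @return an object of class `fw_confusion`: counts `tp`, `fp`, `tn`,
#'   `fn`, `laterality_correct`, `laterality_incorrect`, `n` (scored
#'   pairs), and `per_rater` breakdown.
#' @export
confusion <- function(calls, truth, ignore_laterality = FALSE) {
  sc <- .score_calls(calls, truth, ignore_laterality)
  cnt <- function(d) c(tp = sum(d$tp), fp = sum(d$fp), tn = sum(d$tn),
                       fn = sum(d$fn),
                       laterality_correct = sum(d$lat_correct),
                       laterality_incorrect = sum(d$lat_incorrect))
  tot <- cnt(sc)
  pr <- do.call(rbind, lapply(split(sc, sc$rater_id), cnt))
  structure(c(as.list(tot), list(n = nrow(sc), per_rater = pr,
                                 scored = sc)),
            class = "fw_confusion")
}

#' @export
print.fw_confusion <- function(x, ...) {
  cat(sprintf("<fw_confusion: TP %d FP %d TN %d FN %d (laterality errors %d) over %d pairs>\n",
              x$tp, x$fp, x$tn, x$fn, x$laterality_incorrect, x$n))
  invisible(x)
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Percentages: sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' accuracy = (TP+TN)/n. A zero denominator yields `NA` with a warning,
#' never 0.
#'
#' @param x an `fw_confusion`.
#' @return an object of class `fw_metrics` (named list of percentages).
#' @export
metrics <- function(x) {
  stopifnot(inherits(x, "fw_confusion"))
  safe <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined: zero denominator"); NA_real_ }
    else 100 * num / den
  }
  structure(list(
    accuracy = safe(x$tp + x$tn, x$n, "accuracy"),
    sensitivity = safe(x$tp, x$tp + x$fn, "sensitivity"),
    specificity = safe(x$tn, x$tn + x$fp, "specificity")),
    class = "fw_metrics")
}

#' @export
print.fw_metrics <- function(x, ...) {
  cat(sprintf("accuracy %s  sensitivity %s  specificity %s\n",
              fmt_pct(x$accuracy), fmt_pct(x$sensitivity),
              fmt_pct(x$specificity)))
  invisible(x)
}

#' Round a percentage for display (1 decimal, half away from zero)
#' @param x numeric percentage.
#' @param digits decimals.
#' @return character.
#' @export
fmt_pct <- function(x, digits = 1) {
  if (is.na(x)) return("NA")
  p <- 10^digits
  sprintf(paste0("%.", digits, "f%%"), sign(x) * floor(abs(x) * p + 0.5) / p)
}

#' Metrics with laterality designations excluded
#'
#' Recomputes the confusion with wrong-laterality present calls scored as
#' true positives (sensitivity analysis).
#'
#' @inheritParams confusion
#' @return an `fw_metrics`.
#' @export
metrics_no_laterality <- function(calls, truth) {
  metrics(confusion(calls, truth, ignore_laterality = TRUE))
}

# per-subject confusion count matrix and stratum assignment; the bootstrap
# resamples subjects (with all their attached ratings) within strata.
.subject_counts <- function(sc) {
  agg <- rowsum(cbind(tp = sc$tp, fp = sc$fp, tn = sc$tn, fn = sc$fn,
                      n = 1L), sc$subject_id)
  weak <- tapply(sc$truth_present, sc$subject_id, any)
  list(counts = agg, weak = as.logical(weak[rownames(agg)]))
}

.metric_from_counts <- function(v, metric) {
  switch(metric,
         accuracy = (v["tp"] + v["tn"]) / v["n"],
         sensitivity = v["tp"] / (v["tp"] + v["fn"]),
         specificity = v["tn"] / (v["tn"] + v["fp"]),
         stop("unknown metric: ", metric))
}

#' Stratified patient-level bootstrap confidence interval
#'
#' Resamples subjects with replacement, stratified into weakness-present
#' and weakness-absent subjects with each stratum resampled to its original
#' size (balancing videos with and without weakness and respecting repeated
#' measures per patient), and returns percentile 2.5/97.5 bounds of the
#' chosen metric.
#'
#' @inheritParams confusion
#' @param metric `"accuracy"`, `"sensitivity"` or `"specificity"`.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed (reproducible).
#' @return list with `point` (percentage), `lower`, `upper`, `n_boot`.
#' @export
bootstrap_ci <- function(calls, truth, metric = "accuracy", n_boot = 10000,
                         seed = 1, ignore_laterality = FALSE) {
  sc <- .score_calls(calls, truth, ignore_laterality)
  sj <- .subject_counts(sc)
  iw <- which(sj$weak); inw <- which(!sj$weak)
  if (!length(iw) || !length(inw))
    stop("both weakness-present and weakness-absent subjects are required")
  point <- .metric_from_counts(colSums(sj$counts), metric)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  reps <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- c(iw[sample.int(length(iw), length(iw), replace = TRUE)],
             inw[sample.int(length(inw), length(inw), replace = TRUE)])
    reps[b] <- .metric_from_counts(colSums(sj$counts[idx, , drop = FALSE]),
                                   metric)
  }
  q <- stats::quantile(reps, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  list(point = 100 * as.numeric(point), lower = 100 * q[1],
       upper = 100 * q[2], n_boot = n_boot)
}

#' Bootstrap comparison of two raters' performance
#'
#' Bootstraps the difference in a metric (A minus B) under the same
#' stratified subject-level resampling as [bootstrap_ci()] (the same
#' subjects are drawn for both raters in each replicate) and reports a
#' two-sided p-value from the position of the bootstrap distribution
#' relative to zero.
#'
#' @param calls_a,calls_b calls tables over the same videos.
#' @inheritParams bootstrap_ci
#' @return list with `difference` (percentage points), `lower`, `upper`,
#'   `p_value`, `n_boot`.
#' @export
compare_raters <- function(calls_a, calls_b, truth, metric = "accuracy",
                           n_boot = 10000, seed = 1) {
  sa <- .subject_counts(.score_calls(calls_a, truth))
  sb <- .subject_counts(.score_calls(calls_b, truth))
  if (!identical(rownames(sa$counts), rownames(sb$counts)))
    stop("the two raters must cover the same subjects")
  iw <- which(sa$weak); inw <- which(!sa$weak)
  if (!length(iw) || !length(inw))
    stop("both weakness-present and weakness-absent subjects are required")
  point <- 100 * (.metric_from_counts(colSums(sa$counts), metric) -
                    .metric_from_counts(colSums(sb$counts), metric))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  reps <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- c(iw[sample.int(length(iw), length(iw), replace = TRUE)],
             inw[sample.int(length(inw), length(inw), replace = TRUE)])
    reps[b] <- .metric_from_counts(colSums(sa$counts[idx, , drop = FALSE]),
                                   metric) -
      .metric_from_counts(colSums(sb$counts[idx, , drop = FALSE]), metric)
  }
  p <- 2 * min(mean(reps <= 0), mean(reps >= 0))
  q <- stats::quantile(reps, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  list(difference = as.numeric(point), lower = 100 * q[1], upper = 100 * q[2],
       p_value = min(p, 1), n_boot = n_boot)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value (sum of hypergeometric probabilities not
#' exceeding the observed table's probability).
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return the p-value.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  stats::fisher.test(tab)$p.value
}

#' Fleiss' kappa for fixed-rater categorical ratings
#'
#' @param x either a video x rater matrix/data.frame of categorical ratings,
#'   or (with `counts = TRUE`) a video x category count matrix with constant
#'   row sums.
#' @param counts whether `x` already holds category counts.
#' @return kappa (numeric scalar).
#' @export
fleiss_kappa <- function(x, counts = FALSE) {
  if (!counts) {
    x <- as.matrix(x)
    cats <- sort(unique(as.character(x)))
    N <- nrow(x)
    cnt <- matrix(0L, N, length(cats), dimnames = list(NULL, cats))
    for (j in seq_along(cats)) cnt[, j] <- rowSums(x == cats[j])
  } else {
    cnt <- as.matrix(x)
  }
  m <- unique(rowSums(cnt))
  if (length(m) != 1) stop("every video needs the same number of ratings")
  m <- m[1]
  if (m < 2) stop("at least 2 raters per video are required")
  N <- nrow(cnt)
  p_j <- colSums(cnt) / (N * m)
  Pe <- sum(p_j^2)
  if (1 - Pe < 1e-12)
    stop("chance agreement is 1 (a single category used everywhere); kappa undefined")
  Pi <- (rowSums(cnt^2) - m) / (m * (m - 1))
  (mean(Pi) - Pe) / (1 - Pe)
}

#' Subject-grouped, class-stratified k-fold cross-validation
#'
#' Subjects are stratified by class (a subject's class is its weak-side
#' label if it has any weak video, else normal) and dealt round-robin into
#' k folds, so no subject spans folds and fold sizes per stratum differ by
#' at most one. For each fold the template, PCA and pLDA are fitted on the
#' training folds only and the held-out videos are classified.
#'
#' @param videos list of `fw_face_video`.
#' @param manifest cohort manifest (see [generate_cohort()]).
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @param ... passed to [train_pipeline()].
#' @return list with `calls` (data.frame: `video_id`, `call`, `laterality`,
#'   `predicted`, `fraction_abnormal`, `fold`, `excluded`), `pooled`
#'   (`fw_confusion` over classified videos), `pooled_metrics`, `per_fold`
#'   metrics list, `truth`, and `n_excluded`.
#' @export
cross_validate <- function(videos, manifest, k = 5, seed = 1, ...) {
  truth <- truth_from_manifest(manifest)
  subj_class <- vapply(split(manifest$true_label, manifest$subject_id),
                       function(l) if (any(l != "normal"))
                         l[l != "normal"][1] else "normal", character(1))
  tab <- table(subj_class)
  if (any(tab < k))
    stop("every class needs at least k subjects (got ",
         paste(names(tab), tab, collapse = ", "), ")")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  fold_of <- integer(length(subj_class))
  names(fold_of) <- names(subj_class)
  for (cl in names(tab)) {
    sid <- sample(names(subj_class)[subj_class == cl])
    fold_of[sid] <- rep_len(sample(seq_len(k)), length(sid))
  }
  vid_fold <- fold_of[manifest$subject_id]

  all_calls <- list()
  per_fold <- vector("list", k)
  for (fd in seq_len(k)) {
    tr_idx <- which(vid_fold != fd)
    te_idx <- which(vid_fold == fd)
    pipe <- train_pipeline(videos[tr_idx],
                           labels = manifest$true_label[tr_idx], ...)
    rows <- lapply(te_idx, function(i) {
      res <- classify_video(videos[[i]], pipe)
      data.frame(video_id = manifest$video_id[i],
                 predicted = if (res$excluded) NA_character_ else res$class,
                 fraction_abnormal = if (res$excluded) NA_real_ else
                   1 - res$fractions[["normal"]],
                 fold = fd, excluded = res$excluded,
                 stringsAsFactors = FALSE)
    })
    fold_calls <- do.call(rbind, rows)
    all_calls[[fd]] <- fold_calls
    okc <- fold_calls[!fold_calls$excluded, , drop = FALSE]
    per_fold[[fd]] <- if (nrow(okc))
      metrics(confusion(labels_to_calls(okc$predicted, okc$video_id), truth))
    else NULL
  }
  calls <- do.call(rbind, all_calls)
  ok <- calls[!calls$excluded, , drop = FALSE]
  pooled <- confusion(labels_to_calls(ok$predicted, ok$video_id), truth)
  list(calls = calls, pooled = pooled, pooled_metrics = metrics(pooled),
       per_fold = per_fold, truth = truth, fold_of = fold_of,
       n_excluded = sum(calls$excluded))
}

#' ROC points and AUC from per-video abnormal-vote fractions
#'
#' Sweeps a threshold over the unique fractions (call positive when the
#' abnormal-vote fraction is >= threshold) and reports (1 - specificity,
#' sensitivity) points and the trapezoidal AUC.
#'
#' @param fractions per-video abnormal-vote fractions in `[0, 1]`.
#' @param truth_present logical, truth-present indicator per video.
#' @return list with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_points <- function(fractions, truth_present) {
  stopifnot(length(fractions) == length(truth_present),
            all(fractions >= 0 & fractions <= 1))
  truth_present <- as.logical(truth_present)
  np <- sum(truth_present); nn <- sum(!truth_present)
  if (np == 0 || nn == 0)
    stop("AUC undefined: both truth classes are required")
  thr <- c(sort(unique(fractions), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) sum(fractions >= t & truth_present) / np,
                0)
  fpr <- vapply(thr, function(t) sum(fractions >= t & !truth_present) / nn,
                0)
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}
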