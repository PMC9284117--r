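test_that("Likert scores collapse to absent/indeterminate/present", {
  r <- data.frame(rater_id = "a", video_id = sprintf("v%d", 1:5),
                  likert = 1:5,
                  laterality = c(NA, NA, NA, "left", "right"))
  cc <- collapse_ratings(r)
  expect_equal(cc$call, c("absent", "absent", "indeterminate", "present",
                          "present"))
  expect_equal(cc$laterality, c(NA, NA, NA, "left", "right"))
  expect_error(collapse_ratings(transform(r, likert = c(0, 2:5))), "1-5")
  expect_error(collapse_ratings(transform(r, laterality = NA)), "required")
  r_bad <- r; r_bad$laterality[1] <- "left"
  expect_error(collapse_ratings(r_bad), "absent for likert")
})

test_that("majority truth is the modal call with modal laterality", {
  mk <- function(calls, lats) data.frame(
    rater_id = paste0("r", seq_along(calls)), video_id = "v1",
    call = calls, laterality = lats, stringsAsFactors = FALSE)
  t1 <- majority_truth(mk(c("present", "present", "absent"),
                          c("left", "left", NA)))
  expect_equal(t1$truth, "present"); expect_equal(t1$laterality, "left")
  t2 <- majority_truth(mk(rep("absent", 3), rep(NA_character_, 3)))
  expect_equal(t2$truth, "absent"); expect_true(is.na(t2$laterality))
  # laterality tie among present-callers -> unknown, excluded with warning
  expect_warning(
    t3 <- majority_truth(mk(c("present", "present", "absent"),
                            c("left", "right", NA))), "unknown")
  expect_equal(nrow(t3), 0)
  expect_error(majority_truth(mk(c("present", "absent"), c("left", NA))),
               "exactly 3")
  expect_error(majority_truth(mk(rep("absent", 3), rep(NA_character_, 3)),
                              n_raters = 4), "odd")
})

test_that("confusion implements the laterality-as-false-negative rule", {
  # printed algorithm cross-tabulation: 84 correct-present, 12 false
  # positives, 9 missed, 84 correct-absent, 0 laterality errors
  fx <- counts_fixture(tp = 84, fp = 12, fn_absent = 9, tn = 84)
  cf <- confusion(fx$calls, fx$truth)
  expect_equal(cf$tp, 84); expect_equal(cf$fp, 12)
  expect_equal(cf$fn, 9); expect_equal(cf$tn, 84)
  expect_equal(cf$n, 189)
  expect_equal(cf$laterality_incorrect, 0)
  # a wrong-laterality present call is one FN and one laterality error
  fx2 <- counts_fixture(tp = 0, fp = 0, fn_absent = 0, tn = 1, fn_lat = 1)
  cf2 <- confusion(fx2$calls, fx2$truth)
  expect_equal(cf2$fn, 1); expect_equal(cf2$laterality_incorrect, 1)
  expect_equal(cf2$tp, 0)
  # perfect rater
  fx3 <- counts_fixture(tp = 10, fp = 0, fn_absent = 0, tn = 10)
  cf3 <- confusion(fx3$calls, fx3$truth)
  expect_equal(cf3$fp + cf3$fn + cf3$laterality_incorrect, 0)
})

test_that("metrics reproduce the printed algorithm performance", {
  fx <- counts_fixture(tp = 84, fp = 12, fn_absent = 9, tn = 84)
  m <- metrics(confusion(fx$calls, fx$truth))
  expect_equal(fmt_pct(m$accuracy), "88.9%")
  expect_equal(fmt_pct(m$sensitivity), "90.3%")
  expect_equal(fmt_pct(m$specificity), "87.5%")
  # degenerate denominators signal undefined, never 0
  fx0 <- counts_fixture(tp = 3, fp = 0, fn_absent = 1, tn = 0)
  expect_warning(m0 <- metrics(confusion(fx0$calls, fx0$truth)),
                 "specificity")
  expect_true(is.na(m0$specificity))
})

test_that("per-rater mean metrics aggregate as printed", {
  expect_equal(mean(c(95.70, 89.20, 78.50)), 87.80, tolerance = 1e-9)
  expect_equal(mean(c(94.70, 94.20, 88.90)), 92.60, tolerance = 1e-9)
})

test_that("excluding laterality converts laterality errors into hits", {
  # 50 present-truth videos, 3 wrong-laterality calls, rest correct
  fx <- counts_fixture(tp = 47, fp = 0, fn_absent = 0, tn = 50, fn_lat = 3)
  with_lat <- metrics(confusion(fx$calls, fx$truth))
  no_lat <- metrics_no_laterality(fx$calls, fx$truth)
  expect_equal(with_lat$sensitivity, 94)
  expect_equal(no_lat$sensitivity, 100)
  expect_equal(no_lat$sensitivity - with_lat$sensitivity, 6)
  expect_equal(no_lat$specificity, with_lat$specificity)
  # a rater with zero laterality errors is unaffected
  fx2 <- counts_fixture(tp = 40, fp = 5, fn_absent = 5, tn = 45)
  expect_equal(unlist(metrics_no_laterality(fx2$calls, fx2$truth)),
               unlist(metrics(confusion(fx2$calls, fx2$truth))))
})

test_that("wrong laterality lowers sensitivity but never specificity", {
  fx <- counts_fixture(tp = 30, fp = 2, fn_absent = 3, tn = 28)
  m0 <- metrics(confusion(fx$calls, fx$truth))
  # flip one correct-laterality TP into a wrong-laterality call
  fx$calls$laterality[1] <- setdiff(c("left", "right"),
                                    fx$calls$laterality[1])
  m1 <- metrics(confusion(fx$calls, fx$truth))
  expect_lt(m1$sensitivity, m0$sensitivity)
  expect_equal(m1$specificity, m0$specificity)
})

test_that("bootstrap CI is seeded, contains the point estimate, and degenerates cleanly", {
  set.seed(20)
  sim <- simulate_rater_calls(40, 40, sens = 0.85, spec = 0.95)
  ci1 <- bootstrap_ci(sim$calls, sim$truth, "sensitivity", n_boot = 500,
                      seed = 9)
  ci2 <- bootstrap_ci(sim$calls, sim$truth, "sensitivity", n_boot = 500,
                      seed = 9)
  expect_identical(ci1, ci2)
  expect_lte(ci1$lower, ci1$point)
  expect_gte(ci1$upper, ci1$point)
  # constant statistic -> zero-width interval at the point estimate
  sim_perf <- simulate_rater_calls(20, 20, sens = 1, spec = 1)
  ci0 <- bootstrap_ci(sim_perf$calls, sim_perf$truth, "accuracy",
                      n_boot = 200, seed = 1)
  expect_equal(ci0$lower, 100); expect_equal(ci0$upper, 100)
  expect_equal(ci0$point, 100)
})

test_that("rater comparison is antisymmetric and null for identical raters", {
  set.seed(21)
  sim <- simulate_rater_calls(30, 30, sens = 0.8, spec = 0.9)
  simB <- simulate_rater_calls(30, 30, sens = 0.95, spec = 0.9)
  simB$truth <- sim$truth  # same videos
  self <- compare_raters(sim$calls, sim$calls, sim$truth, n_boot = 200,
                         seed = 3)
  expect_equal(self$difference, 0)
  expect_equal(self$p_value, 1)
  ab <- compare_raters(sim$calls, simB$calls, sim$truth, n_boot = 200,
                       seed = 3)
  ba <- compare_raters(simB$calls, sim$calls, sim$truth, n_boot = 200,
                       seed = 3)
  expect_equal(ab$difference, -ba$difference)
})

test_that("a planted accuracy gap is detected by the bootstrap comparison", {
  set.seed(22)
  detections <- 0
  for (rep in 1:10) {
    a <- simulate_rater_calls(100, 100, sens = 0.95, spec = 0.95)
    b <- simulate_rater_calls(100, 100, sens = 0.60, spec = 0.70)
    b$truth <- a$truth
    p <- compare_raters(a$calls, b$calls, a$truth, n_boot = 400,
                        seed = rep)$p_value
    detections <- detections + (p < 0.05)
  }
  expect_gte(detections, 9)
})

test_that("Fisher's exact p matches hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact(matrix(c(3, 0, 0, 3), 2)), 0.1,
               tolerance = 1e-12)
  set.seed(23)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 5), 2)
    expect_equal(fisher_exact(tab), fisher_oracle(tab), tolerance = 1e-12)
  }
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})

test_that("Fleiss' kappa matches a hand-computed table and its limits", {
  # 4 videos x 3 raters, categories a/b
  x <- rbind(c("a", "a", "a"), c("a", "a", "b"),
             c("b", "b", "b"), c("a", "b", "b"))
  # hand calculation: counts per row (3,0),(2,1),(0,3),(1,2)
  # P_i = (9-3)/6, (5-3)/6, (9-3)/6, (5-3)/6 -> mean 2/3
  # p_a = 6/12, p_b = 6/12, Pe = 1/2 -> kappa = (2/3 - 1/2)/(1/2) = 1/3
  expect_equal(fleiss_kappa(x), 1 / 3, tolerance = 1e-10)
  # perfect agreement with >= 2 categories in use
  xp <- rbind(c("a", "a", "a"), c("b", "b", "b"))
  expect_equal(fleiss_kappa(xp), 1)
  # single category everywhere -> chance agreement 1, signalled
  expect_error(fleiss_kappa(rbind(c("a", "a"), c("a", "a"))), "undefined")
  # independent random ratings -> kappa ~ 0
  set.seed(24)
  xr <- matrix(sample(c("a", "b", "c"), 1000 * 3, TRUE,
                      prob = c(0.5, 0.3, 0.2)), 1000, 3)
  expect_lt(abs(fleiss_kappa(xr)), 0.05)
  # count-matrix interface agrees with the raw interface
  cnt <- t(apply(x, 1, function(r) c(sum(r == "a"), sum(r == "b"))))
  expect_equal(fleiss_kappa(cnt, counts = TRUE), fleiss_kappa(x))
})

test_that("ROC points and AUC match the rank-statistic oracle", {
  # perfectly separated fractions
  r1 <- roc_points(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r1$auc, 1)
  set.seed(25)
  for (i in 1:5) {
    truth <- runif(60) < 0.5
    frac <- pmin(1, pmax(0, runif(60) + 0.3 * truth))
    r <- roc_points(frac, truth)
    # Mann-Whitney identity: AUC = P(pos > neg) + 0.5 P(tie)
    pos <- frac[truth]; neg <- frac[!truth]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(r$auc, mean(cmp), tolerance = 1e-10)
  }
  # label-independent fractions -> AUC near 1/2
  set.seed(26)
  truth <- rep(c(TRUE, FALSE), 500)
  r0 <- roc_points(runif(1000), truth)
  expect_lt(abs(r0$auc - 0.5), 0.05)
  expect_error(roc_points(runif(5), rep(TRUE, 5)), "undefined")
})

test_that("cross-validation folds are subject-grouped and class-balanced", {
  co <- generate_cohort(10, 5, 5, seed = 31, n_frames_range = c(3, 4),
                        image_size = 64, paired = TRUE)
  cv <- cached("cv_small", cross_validate(co$videos, co$manifest, k = 5,
                                          seed = 7, lambda = 1e-3,
                                          out_size = 64))
  # no subject spans folds
  fold_by_video <- cv$calls$fold
  subj <- co$manifest$subject_id[match(cv$calls$video_id,
                                       co$manifest$video_id)]
  expect_true(all(tapply(fold_by_video, subj,
                         function(f) length(unique(f))) == 1))
  # per-class subject counts differ by at most 1 across folds
  sub_class <- tapply(co$manifest$true_label, co$manifest$subject_id,
                      function(l) if (any(l != "normal"))
                        l[l != "normal"][1] else "normal")
  for (cl in unique(sub_class)) {
    sizes <- table(cv$fold_of[names(sub_class)[sub_class == cl]])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_equal(nrow(cv$calls), nrow(co$manifest))
  expect_error(cross_validate(co$videos, co$manifest, k = 7), "at least k")
})
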