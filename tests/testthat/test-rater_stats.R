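test_that("alignment matches identical scorings completely", {
  a <- make_scored(c("N", "AT", "IE", "N"))
  al <- align_scorings(a, a)
  expect_equal(nrow(al$pairs), 4)
  expect_equal(nrow(al$unmatched_a), 0)
  expect_equal(nrow(al$unmatched_b), 0)
  # deleting one unit leaves exactly one unmatched on the other side
  b <- make_scored(c("N", "AT", "N"), onsets = c(1, 2, 4), duration = 5)
  al2 <- align_scorings(a, b)
  expect_equal(nrow(al2$pairs), 3)
  expect_equal(nrow(al2$unmatched_a), 1)
  expect_equal(al2$unmatched_a$label, "IE")
  expect_error(align_scorings(a, make_scored(c("N"), duration = 99)),
               "duration")
})

test_that("greedy alignment equals brute-force optimal matching under jitter", {
  set.seed(7)
  for (rep in 1:5) {
    onsets <- sort(runif(6, 0, 60))
    onsets <- onsets[c(TRUE, diff(onsets) > 2)]
    labels <- sample(c("N", "AT", "IE"), length(onsets), replace = TRUE)
    jit <- onsets + runif(length(onsets), -0.3, 0.3)
    a <- make_scored(labels, onsets = onsets, duration = 61)
    b <- make_scored(labels, onsets = jit, duration = 61)
    al <- align_scorings(a, b)
    oracle <- oracle_match(onsets, jit)
    expect_equal(nrow(al$pairs), nrow(oracle))
    expect_equal(al$pairs$ia, oracle[, 1])
    expect_equal(al$pairs$ib[order(al$pairs$ia)], oracle[, 2])
  }
})

test_that("per-class metrics come out of the confusion counts", {
  a <- make_scored(c(rep("IE", 9), "N", rep("N", 90)),
                   onsets = seq_len(100), duration = 101)
  b <- make_scored(c(rep("IE", 10), rep("N", 90)),
                   onsets = seq_len(100), duration = 101)
  m <- per_class_metrics(align_scorings(a, b), "IE")
  expect_equal(m$tp, 9); expect_equal(m$fn, 1); expect_equal(m$fp, 0)
  expect_equal(m$se, 0.90)
  expect_equal(m$sp, 1.00)
  expect_equal(m$ppv, 1.00)
  # identical scorings: all ones for a present class
  mi <- per_class_metrics(align_scorings(b, b), "IE")
  expect_equal(c(mi$se, mi$sp, mi$ppv), c(1, 1, 1))
  # absent class: sensitivity undefined, specificity 1
  ma <- per_class_metrics(align_scorings(b, b), "DT")
  expect_true(is.na(ma$se))
  expect_true(is.na(ma$ppv))
  expect_equal(ma$sp, 1)
})

test_that("agreement metrics reproduce a brute-force confusion oracle", {
  set.seed(19)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    la <- sample(c("N", "Bck", "DT", "AT", "IE"), n, replace = TRUE)
    lb <- la
    flip <- runif(n) < 0.3
    lb[flip] <- sample(c("N", "Bck", "DT", "AT", "IE"), sum(flip),
                       replace = TRUE)
    a <- make_scored(la, onsets = seq_len(n), duration = n + 1)
    b <- make_scored(lb, onsets = seq_len(n), duration = n + 1)
    al <- align_scorings(a, b)
    for (cl in c("N", "Bck", "DT", "AT", "IE")) {
      m <- per_class_metrics(al, cl)
      o <- oracle_confusion(al, cl)
      expect_equal(m[c("tp", "fp", "fn", "tn")], o)
    }
    expect_equal(agreement(al), mean(la == lb))
  }
})

test_that("Cohen's kappa matches hand-computed tables to 1e-12", {
  # 2x2 table [[20,5],[10,65]]: po = 0.85, pe = 0.6, kappa = 0.625
  la <- c(rep("A", 25), rep("B", 75))
  lb <- c(rep("A", 20), rep("B", 5), rep("A", 10), rep("B", 65))
  expect_equal(cohen_kappa(la, lb), 0.625, tolerance = 1e-12)
  # perfect agreement at 50/50: kappa 1
  lc <- rep(c("A", "B"), 10)
  expect_equal(cohen_kappa(lc, lc), 1)
  # both constant and equal: undefined
  expect_true(is.na(cohen_kappa(rep("A", 5), rep("A", 5))))
  # kappa is invariant under label permutation
  perm <- c(A = "B", B = "A")
  expect_equal(cohen_kappa(unname(perm[la]), unname(perm[lb])),
               cohen_kappa(la, lb))
})

test_that("independent random labels give near-zero kappa", {
  set.seed(123)
  la <- sample(c("N", "AT", "IE"), 10000, replace = TRUE)
  lb <- sample(c("N", "AT", "IE"), 10000, replace = TRUE)
  expect_lt(abs(cohen_kappa(la, lb)), 0.05)
})

test_that("agreement fraction counts label-identical matches over all units", {
  a <- make_scored(c(rep("N", 9), "AT"))
  b <- make_scored(c(rep("N", 9), "IE"))
  expect_equal(agreement(align_scorings(a, b)), 0.9)
  disjoint <- make_scored(rep("Bck", 10))
  expect_equal(agreement(align_scorings(a, disjoint)), 0)
})

test_that("the scorer rotation enumerates all ordered pairs", {
  a <- make_scored(c("N", "AT", "IE", "N", "Bck"))
  b <- a
  cset <- make_scored(c("N", "N", "IE", "N", "Bck"))
  rot <- inter_rater_rotation(list(a, b, cset))
  expect_equal(nrow(rot$comparisons), 6)   # 3 * 2 ordered pairs
  # two identical scorings only: means 1, SD 0
  rot2 <- inter_rater_rotation(list(a, b))
  agr <- rot2$summary[rot2$summary$metric == "agreement", ]
  expect_equal(agr$mean, 1)
  expect_equal(agr$sd, 0)
  # means equal brute-force enumeration over the 6 ordered pairs
  kaps <- sapply(list(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2)),
                 function(ij) {
                   sc <- list(a, b, cset)
                   compare_scorings(sc[[ij[1]]], sc[[ij[2]]])$agreement
                 })
  expect_equal(rot$summary$mean[rot$summary$metric == "agreement"],
               mean(kaps))
  expect_error(inter_rater_rotation(list(a)), "two scorings")
})

test_that("cohort summaries use the arithmetic mean and n-1 SD", {
  pub <- published_scores()
  s_ai <- pub$ai_printed[pub$scorer == "S"]
  e_ai <- pub$ai_printed[pub$scorer == "E"]
  cs <- summarize_cohort(s_ai)
  ce <- summarize_cohort(e_ai)
  expect_equal(round(cs$mean, 1), 18.9)
  expect_equal(round(cs$sd, 1), 17.7)
  expect_equal(round(ce$mean, 1), 12.8)
  expect_equal(round(ce$sd, 1), 9.4)
  expect_equal(summarize_cohort(rep(3.3, 5))$sd, 0)
  expect_true(is.na(summarize_cohort(7)$sd))
  # scale equivariance
  set.seed(2); v <- rnorm(9)
  expect_equal(summarize_cohort(3 * v)$mean, 3 * summarize_cohort(v)$mean)
  expect_equal(summarize_cohort(3 * v)$sd, 3 * summarize_cohort(v)$sd)
})

test_that("Student's t behaves at its edge and textbook cases", {
  x <- c(5.1, 4.9, 5.3, 5.2, 5.0)
  same <- students_t(x, x, paired = FALSE)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # closed-form pooled two-sample t for n1 = n2 = 9
  set.seed(31)
  a <- rnorm(9, 10, 2); b <- rnorm(9, 12, 2)
  sp2 <- (8 * var(a) + 8 * var(b)) / 16
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 9))
  got <- students_t(a, b, paired = FALSE)
  expect_equal(got$t, t_hand, tolerance = 1e-9)
  expect_equal(got$df, 16)
  # a huge shift gives a vanishing p-value
  shift <- students_t(a, a + 100 * sd(a), paired = FALSE)
  expect_lt(shift$p, 1e-6)
  # constant paired difference: infinite t, zero p
  deg <- students_t(a, a - 2, paired = TRUE)
  expect_equal(deg$t, Inf)
  expect_equal(deg$p, 0)
  expect_error(students_t(rep(1, 4), rep(1, 4), paired = TRUE),
               "zero variance")
})
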