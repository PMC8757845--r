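#' Align two scorings of the same recording
#'
#' Greedy nearest-onset matching of counted units within a time tolerance:
#' the closest pair is matched first, each unit at most once. Unmatched
#' units represent cycles one scorer added or removed.
#'
#' @param a,b Two [scored_recording()] objects over the same duration.
#' @param tol Matching tolerance on onsets in seconds (default 0.5).
#' @param drop_x Drop X-labelled (discarded) units before matching (default
#'   TRUE; discarded cycles are excluded from statistical analysis).
#' @return List with \code{pairs} (data frame: \code{ia}, \code{ib},
#'   \code{label_a}, \code{label_b}, \code{dt}), \code{unmatched_a} and
#'   \code{unmatched_b} (data frames of leftover units).
#' @export
align_scorings <- function(a, b, tol = 0.5, drop_x = TRUE) {
  stopifnot(inherits(a, "scored_recording"), inherits(b, "scored_recording"))
  if (abs(a$duration - b$duration) > 1e-6)
    stop("scorings cover different durations")
  ua <- a$units; ub <- b$units
  if (drop_x) {
    ua <- ua[ua$label != "X", , drop = FALSE]
    ub <- ub[ub$label != "X", , drop = FALSE]
  }
  na <- nrow(ua); nb <- nrow(ub)
  cand <- expand.grid(ia = seq_len(na), ib = seq_len(nb))
  if (nrow(cand)) {
    cand$dt <- abs(ua$onset[cand$ia] - ub$onset[cand$ib])
    cand <- cand[cand$dt <= tol, , drop = FALSE]
    cand <- cand[order(cand$dt, cand$ia, cand$ib), , drop = FALSE]
  }
  used_a <- logical(na); used_b <- logical(nb)
  sel <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$ia[r]; j <- cand$ib[r]
    if (!used_a[i] && !used_b[j]) { sel[r] <- TRUE; used_a[i] <- used_b[j] <- TRUE }
  }
  m <- cand[sel, , drop = FALSE]
  pairs <- data.frame(ia = m$ia, ib = m$ib,
                      label_a = ua$label[m$ia], label_b = ub$label[m$ib],
                      dt = m$dt)
  pairs <- pairs[order(pairs$ia), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unmatched_a = ua[!used_a, , drop = FALSE],
       unmatched_b = ub[!used_b, , drop = FALSE])
}

#' One-vs-rest confusion counts and Se/Sp/PPV for one class
#'
#' The second scoring (\code{b} in [align_scorings()]) is the reference.
#' Unmatched units count against an implicit non-event class: an unmatched
#' test unit of the class is a false positive, an unmatched reference unit a
#' false negative. Zero-denominator metrics are returned as NA (undefined),
#' never silently as 0 or 1.
#'
#' @param alignment Result of [align_scorings()].
#' @param class Label (one of N, Bck, DT, AT, IE).
#' @return List with \code{tp}, \code{fp}, \code{fn}, \code{tn}, \code{se},
#'   \code{sp}, \code{ppv}.
#' @export
per_class_metrics <- function(alignment, class) {
  p <- alignment$pairs
  tp <- sum(p$label_a == class & p$label_b == class)
  fp <- sum(p$label_a == class & p$label_b != class) +
    sum(alignment$unmatched_a$label == class)
  fn <- sum(p$label_a != class & p$label_b == class) +
    sum(alignment$unmatched_b$label == class)
  total <- nrow(p) + nrow(alignment$unmatched_a) +
    nrow(alignment$unmatched_b)
  tn <- total - tp - fp - fn
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       se = safe(tp, tp + fn), sp = safe(tn, tn + fp),
       ppv = safe(tp, tp + fp))
}

#' Cohen's kappa over matched units
#'
#' Chance-corrected agreement over the full label set:
#' kappa = (p_o - p_e) / (1 - p_e), with p_e from the product of marginal
#' label frequencies. Undefined (NA) when both scorings are constant and
#' identical (p_e = 1).
#'
#' @param labels_a,labels_b Equal-length label vectors (matched pairs).
#' @return Kappa, or NA when undefined.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  n <- length(labels_a)
  if (n < 1) stop("at least one matched pair required")
  lv <- union(labels_a, labels_b)
  po <- mean(labels_a == labels_b)
  pa <- table(factor(labels_a, lv)) / n
  pb <- table(factor(labels_b, lv)) / n
  pe <- sum(as.numeric(pa) * as.numeric(pb))
  if (abs(1 - pe) < 1e-15) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Raw agreement fraction
#'
#' Matched pairs with identical labels over all units (matched plus
#' added/removed).
#'
#' @param alignment Result of [align_scorings()].
#' @return Fraction in [0, 1]; NA when there are no units.
#' @export
agreement <- function(alignment) {
  p <- alignment$pairs
  total <- nrow(p) + nrow(alignment$unmatched_a) +
    nrow(alignment$unmatched_b)
  if (total == 0) return(NA_real_)
  sum(p$label_a == p$label_b) / total
}

#' Full agreement report between a test and a reference scoring
#'
#' @param test,reference [scored_recording()] objects over the same
#'   duration; \code{reference} plays the reference role.
#' @param tol Onset-matching tolerance (s).
#' @param classes Label classes to report (default N, Bck, DT, AT, IE).
#' @return An object of class \code{agreement_report}: list with
#'   \code{per_class} (data frame of confusion counts and Se/Sp/PPV),
#'   \code{kappa}, \code{agreement}, \code{n_mod} (matched units whose label
#'   differs), \code{n_added} (test units with no reference counterpart),
#'   \code{n_removed} (reference units with no test counterpart).
#' @export
compare_scorings <- function(test, reference, tol = 0.5,
                             classes = c("N", "Bck", "DT", "AT", "IE")) {
  al <- align_scorings(test, reference, tol = tol)
  per <- do.call(rbind, lapply(classes, function(cl) {
    m <- per_class_metrics(al, cl)
    data.frame(class = cl, tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn,
               se = m$se, sp = m$sp, ppv = m$ppv)
  }))
  kap <- if (nrow(al$pairs)) cohen_kappa(al$pairs$label_a, al$pairs$label_b)
         else NA_real_
  structure(list(per_class = per, kappa = kap, agreement = agreement(al),
                 n_mod = sum(al$pairs$label_a != al$pairs$label_b),
                 n_added = nrow(al$unmatched_a),
                 n_removed = nrow(al$unmatched_b),
                 alignment = al),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "—", sprintf("%.2f", v))
  cat("<agreement_report>\n")
  tab <- x$per_class
  cat(sprintf("  %-4s %11s %11s %6s\n", "AE", "Sensitivity", "Specificity",
              "PPV"))
  for (r in seq_len(nrow(tab)))
    cat(sprintf("  %-4s %11s %11s %6s\n", tab$class[r], fmt(tab$se[r]),
                fmt(tab$sp[r]), fmt(tab$ppv[r])))
  cat(sprintf("  kappa %s  agreement %s  N_mod %d (+%d added, -%d removed)\n",
              fmt(x$kappa), fmt(x$agreement), x$n_mod, x$n_added,
              x$n_removed))
  invisible(x)
}

#' Serialize an agreement report to JSON
#' @param report An \code{agreement_report}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_report <- function(report, path) {
  obj <- list(per_class = report$per_class, kappa = report$kappa,
              agreement = report$agreement, n_mod = report$n_mod,
              n_added = report$n_added, n_removed = report$n_removed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Rotating inter-rater comparison
#'
#' Every ordered (test, reference) pair of scorings with test != reference
#' is compared; the mean and sample SD of each summary metric over the
#' k(k-1) comparisons are reported.
#'
#' @param scorings List of at least two [scored_recording()] objects over
#'   the same recording.
#' @param tol Onset-matching tolerance (s).
#' @return List with \code{comparisons} (data frame: test, reference,
#'   kappa, agreement, and per-class se/sp/ppv columns) and \code{summary}
#'   (data frame of metric, mean, sd).
#' @export
inter_rater_rotation <- function(scorings, tol = 0.5) {
  k <- length(scorings)
  if (k < 2) stop("at least two scorings required")
  rows <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    rep <- compare_scorings(scorings[[i]], scorings[[j]], tol = tol)
    row <- data.frame(test = i, reference = j, kappa = rep$kappa,
                      agreement = rep$agreement)
    for (r in seq_len(nrow(rep$per_class))) {
      cl <- rep$per_class$class[r]
      row[[paste0("se_", cl)]] <- rep$per_class$se[r]
      row[[paste0("sp_", cl)]] <- rep$per_class$sp[r]
      row[[paste0("ppv_", cl)]] <- rep$per_class$ppv[r]
    }
    rows[[length(rows) + 1]] <- row
  }
  comparisons <- do.call(rbind, rows)
  metrics <- setdiff(names(comparisons), c("test", "reference"))
  summ <- do.call(rbind, lapply(metrics, function(m) {
    v <- comparisons[[m]]
    v <- v[!is.na(v)]
    data.frame(metric = m, mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }))
  list(comparisons = comparisons, summary = summ)
}

#' Cohort mean and sample standard deviation
#'
#' Arithmetic mean and n-1 standard deviation of a per-recording statistic
#' (for example the per-patient asynchrony index).
#'
#' @param values Numeric vector.
#' @return List with \code{mean}, \code{sd} (NA when n < 2) and \code{n}.
#' @export
summarize_cohort <- function(values) {
  values <- values[!is.na(values)]
  list(mean = mean(values),
       sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
       n = length(values))
}

#' Student's t-test
#'
#' Thin wrapper around the classical t statistic, paired or two-sample with
#' pooled variance, two-sided.
#'
#' @param x,y Numeric samples.
#' @param paired Paired test (default TRUE, appropriate for per-patient
#'   comparisons of two scorers over the same patients).
#' @return List with \code{t}, \code{p}, \code{df}.
#' @export
students_t <- function(x, y, paired = TRUE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && all(x == y))
    stop("zero variance in both samples: t undefined")
  if (paired && stats::sd(x - y) == 0) {
    # degenerate paired case: a constant difference
    d <- mean(x - y)
    t <- if (d == 0) 0 else sign(d) * Inf
    return(list(t = t, p = if (d == 0) 1 else 0, df = length(x) - 1))
  }
  ht <- stats::t.test(x, y, paired = paired, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Published per-patient scoring counts
#'
#' The per-patient event-count vectors of the validation study this scorer
#' is modelled on (nine 20-min pressure-support recordings): for each
#' patient the automatic ("S") counts N_tot, N_IE, N_AT, N_DT, the printed
#' AI, N_Bck, N_X and the breathing frequency, plus the expert-mean ("E")
#' rows. Stored as plain text under \code{inst/extdata}.
#'
#' @return Data frame, one row per patient and scorer.
#' @export
published_scores <- function() {
  path <- system.file("extdata", "published_scores.tsv",
                      package = "pvascore", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t")
}
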