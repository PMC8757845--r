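# Shared fixtures: tiny scored recordings and brute-force oracles that the
# agreement statistics are checked against.

make_scored <- function(labels, onsets = seq_along(labels), duration = NULL) {
  if (is.null(duration)) duration <- length(labels) + 1
  scored_recording(data.frame(onset = onsets, end = onsets + 0.5,
                              label = labels), duration)
}

# Brute-force one-vs-rest confusion counts from an alignment, by direct
# enumeration over every unit (independent of per_class_metrics).
oracle_confusion <- function(alignment, class) {
  tp <- fp <- fn <- tn <- 0L
  p <- alignment$pairs
  for (r in seq_len(nrow(p))) {
    a <- p$label_a[r] == class; b <- p$label_b[r] == class
    if (a && b) tp <- tp + 1L
    else if (a && !b) fp <- fp + 1L
    else if (!a && b) fn <- fn + 1L
    else tn <- tn + 1L
  }
  for (l in alignment$unmatched_a$label)
    if (l == class) fp <- fp + 1L else tn <- tn + 1L
  for (l in alignment$unmatched_b$label)
    if (l == class) fn <- fn + 1L else tn <- tn + 1L
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Brute-force optimal one-to-one onset matching (minimum total distance over
# all injective assignments within tol); feasible for <= 8 units.
oracle_match <- function(onsets_a, onsets_b, tol = 0.5) {
  na <- length(onsets_a); nb <- length(onsets_b)
  best <- NULL; best_cost <- Inf
  idx_b <- c(seq_len(nb), rep(NA, max(0, na - nb)))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  for (assign in perms(idx_b)) {
    cost <- 0; used <- 0; pairs <- NULL
    ok <- TRUE
    for (i in seq_len(na)) {
      j <- assign[i]
      if (is.na(j)) next
      d <- abs(onsets_a[i] - onsets_b[j])
      if (d <= tol) { cost <- cost + d; used <- used + 1
        pairs <- rbind(pairs, c(i, j)) }
    }
    # prefer more matches, then lower cost
    score <- -used * 1e6 + cost
    if (score < best_cost) { best_cost <- score; best <- pairs }
  }
  best
}

clean_settings <- function() ventilator_settings(4, 16, 12)
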