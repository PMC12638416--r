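# Shared fixtures and independent oracles used across the suite.

# tiny deterministic cohort data frame (3 subjects, all columns)
tiny_cohort_df <- function() {
  data.frame(
    subject_id = c("A1", "A2", "A3"),
    age = c(66, 71, 68),
    sex = c("female", "male", "female"),
    apoe4_carrier = c(FALSE, TRUE, NA),
    csf_ab42 = c(900, 470, 480),
    csf_ab40 = c(11500, 12500, 9600),
    csf_ttau = c(200, 480, 460),
    csf_ptau181 = c(37, 75, 10),
    direct_ab40 = c(303, 294, 310),
    direct_ab42 = c(29.0, 22.6, 23.5),
    direct_ptau181 = c(1.45, 2.55, 2.60),
    ip_ab40 = c(31.9, 32.2, 30.5),
    ip_ab42 = c(3.80, 3.10, 3.05),
    ip_ptau181 = c(0.38, 0.76, 0.74),
    stringsAsFactors = FALSE)
}

# group labels as used throughout: n_neg negatives then n_pos positives
make_groups <- function(n_neg, n_pos) {
  c(rep("abeta_neg", n_neg), rep("abeta_pos", n_pos))
}

# exhaustive pair-counting AUC oracle (ties count 1/2), higher-in-pos
auc_brute <- function(scores, pos) {
  xp <- scores[pos]; xn <- scores[!pos]
  s <- 0
  for (a in xp) for (b in xn) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(xp) * length(xn))
}

# exhaustive Youden oracle: best sens + spec - 1 over every possible cut of
# the oriented scores (positive call at score >= cut)
youden_brute <- function(scores, pos) {
  cuts <- c(-Inf, sort(unique(scores)), Inf)
  best <- -Inf
  for (ct in cuts) {
    pred <- scores >= ct
    sens <- sum(pred & pos) / sum(pos)
    spec <- sum(!pred & !pos) / sum(!pos)
    best <- max(best, sens + spec - 1)
  }
  best
}

# DeLong AUC variance from first principles: explicit double-loop placement
# values and textbook variance of the two placement samples
delong_var_brute <- function(scores, pos) {
  xp <- scores[pos]; xn <- scores[!pos]
  m <- length(xp); n <- length(xn)
  v10 <- numeric(m); v01 <- numeric(n)
  for (i in seq_len(m)) {
    s <- 0
    for (j in seq_len(n)) s <- s + (xp[i] > xn[j]) + 0.5 * (xp[i] == xn[j])
    v10[i] <- s / n
  }
  for (j in seq_len(n)) {
    s <- 0
    for (i in seq_len(m)) s <- s + (xp[i] > xn[j]) + 0.5 * (xp[i] == xn[j])
    v01[j] <- s / m
  }
  sum((v10 - mean(v10))^2) / (m - 1) / m +
    sum((v01 - mean(v01))^2) / (n - 1) / n
}

# perpendicular (lambda = 1) sum of squared distances from points to a line
perp_ss <- function(x, y, intercept, slope) {
  sum((y - intercept - slope * x)^2) / (1 + slope^2)
}
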