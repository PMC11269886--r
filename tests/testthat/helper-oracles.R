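# Independent oracles and fixture builders shared across the suite.
# Each oracle deliberately takes a different computational route than the
# package implementation it checks.

# Wilson interval by direct inversion of the score test: the bounds are the
# roots in p of (phat - p)^2 = z^2 p(1-p)/n, via the quadratic formula.
oracle_wilson <- function(k, n, alpha = 0.05) {
  z <- qnorm(1 - alpha / 2)
  phat <- k / n
  a <- n + z^2
  b <- -(2 * n * phat + z^2)
  c0 <- n * phat^2
  disc <- sqrt(b^2 - 4 * a * c0)
  sort(c((-b - disc) / (2 * a), (-b + disc) / (2 * a)))
}

# Bernoulli log-likelihood maximised by coarse-to-fine grid search; no
# derivatives, no weighted least squares.
oracle_logistic_grid <- function(y, x, centre = c(0, 0), span = 8,
                                 levels = 4, pts = 161) {
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  best <- centre
  for (lvl in seq_len(levels)) {
    b0s <- seq(best[1] - span, best[1] + span, length.out = pts)
    b1s <- seq(best[2] - span, best[2] + span, length.out = pts)
    ll <- outer(b0s, b1s, Vectorize(loglik))
    idx <- arrayInd(which.max(ll), dim(ll))
    best <- c(b0s[idx[1]], b1s[idx[2]])
    span <- span * 2 / (pts - 1) * 2  # a few grid cells around the argmax
  }
  best
}

# Textbook matrix closed form for simple OLS, including the slope SE.
oracle_ols_matrix <- function(x, y) {
  X <- cbind(1, x)
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (length(y) - 2)
  se <- sqrt(diag(s2 * XtX_inv))
  list(intercept = unname(beta[1]), slope = unname(beta[2]),
       slope_se = unname(se[2]))
}

# A deterministic fledgling table carrying the study's marginal counts:
# 89 ingested, 82 slimed, 89 cat, 14 other, 20 unknown, 167 censored
# (294 dead of 461 tracked), with evidence consistent with each fate and
# masses spread over the observed 60.5-86.3 g range.
make_study_fledglings <- function() {
  counts <- c(INGESTED = 89, SLIMED = 82, CAT = 89, OTHER = 14,
              UNKNOWN = 20, CENSORED = 167)
  evid <- c(INGESTED = "IN_SNAKE", SLIMED = "SALIVA_COATED",
            CAT = "CARCASS_REMAINS_CAT_PATTERN",
            OTHER = "OTHER_CAUSE_EVIDENCE",
            UNKNOWN = "NO_PREDATION_SIGNS",
            CENSORED = "ALIVE_AT_LAST_CHECK")
  fate <- rep(names(counts), counts)
  n <- sum(counts)
  # each fate group spans the whole mass range, so mass carries no signal
  mass <- unlist(lapply(counts, function(k)
    seq(60.5, 86.3, length.out = k)), use.names = FALSE)
  data.frame(
    bird_id = sprintf("B%03d", seq_len(n)),
    mass_g = round(mass, 1),
    fate = fate,
    evidence = unname(evid[fate]),
    notes = "",
    stringsAsFactors = FALSE
  )
}

# Snake capture-event tables carrying the study's deduplication structure.
make_survey_captures <- function() {
  ids <- sprintf("S%03d", 1:265)
  id <- c(ids, sprintf("S%03d", 1:89))  # 89 repeat events -> 354 rows
  data.frame(
    snake_id = id,
    event_id = sprintf("E%03d", seq_along(id)),
    svl_mm = round(seq(288, 1989, length.out = length(id))),
    mass_g = NA_real_,
    sex = "U",
    context = "SURVEY",
    date = as.character(as.Date("2020-01-01") + seq_along(id)),
    stringsAsFactors = FALSE
  )
}

make_consumer_captures <- function() {
  ids <- sprintf("C%02d", 1:52)
  id <- c(ids, sprintf("C%02d", 1:3))  # 3 individuals captured twice -> 55
  data.frame(
    snake_id = id,
    event_id = sprintf("CE%02d", seq_along(id)),
    svl_mm = round(seq(1023, 1593, length.out = length(id))),
    mass_g = round(seq(90, 410, length.out = length(id))),
    sex = "U",
    context = "CONSUMER",
    date = as.character(as.Date("2021-01-01") + seq_along(id)),
    stringsAsFactors = FALSE
  )
}

write_fixture_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
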