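# From-the-definition brute-force oracles. Deliberately naive (explicit
# loops, no shared code with the package) so they stay independent of the
# implementations they check.

oracle_concordance <- function(times, events, risks) {
  conc <- 0; comp <- 0
  n <- length(times)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (times[i] == times[j]) next
      s <- if (times[i] < times[j]) i else j  # shorter observed time
      l <- if (s == i) j else i
      if (events[s] != 1) next
      comp <- comp + 1
      if (risks[s] > risks[l]) conc <- conc + 1
      else if (risks[s] == risks[l]) conc <- conc + 0.5
    }
  }
  if (comp == 0) return(0.5)
  conc / comp
}

oracle_logrank <- function(t1, e1, t2, e2) {
  tt <- c(t1, t2); ev <- c(e1, e2)
  grp <- c(rep(1, length(t1)), rep(2, length(t2)))
  omE <- 0; V <- 0
  for (ti in sort(unique(tt[ev == 1]))) {
    n_at <- sum(tt >= ti); n1_at <- sum(tt >= ti & grp == 1)
    d <- sum(tt == ti & ev == 1); d1 <- sum(tt == ti & ev == 1 & grp == 1)
    omE <- omE + d1 - d * n1_at / n_at
    if (n_at > 1)
      V <- V + d * (n1_at / n_at) * (1 - n1_at / n_at) * (n_at - d) / (n_at - 1)
  }
  stat <- if (V == 0) 0 else omE^2 / V
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

oracle_km <- function(times, events) {
  s <- 1; out_t <- c(); out_s <- c()
  for (ti in sort(unique(times))) {
    n_at <- sum(times >= ti)
    d <- sum(times == ti & events == 1)
    s <- s * (1 - d / n_at)
    out_t <- c(out_t, ti); out_s <- c(out_s, s)
  }
  data.frame(time = out_t, surv = out_s)
}

oracle_purity <- function(points, labels, k) {
  n <- nrow(points)
  acc <- 0
  for (i in seq_len(n)) {
    d <- rep(Inf, n)
    for (j in seq_len(n)) if (j != i) d[j] <- sqrt(sum((points[i, ] - points[j, ])^2))
    nb <- order(d)[seq_len(k)]
    acc <- acc + mean(labels[nb] == labels[i])
  }
  acc / n
}

oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- 0; s00 <- 0; s10 <- 0; s01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (!sa && !sb) s00 <- s00 + 1
      else if (sa) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  tot <- s11 + s00 + s10 + s01
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

oracle_nmi <- function(a, b) {
  n <- length(a)
  ent <- function(x) {
    p <- table(x) / n
    -sum(p * log(p))
  }
  joint <- table(a, b) / n
  hj <- -sum(joint[joint > 0] * log(joint[joint > 0]))
  mi <- ent(a) + ent(b) - hj
  if (ent(a) == 0 && ent(b) == 0) return(1)
  mi / ((ent(a) + ent(b)) / 2)
}

oracle_silhouette <- function(points, cl) {
  n <- nrow(points)
  d <- function(i, j) sqrt(sum((points[i, ] - points[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(cl == cl[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(sapply(own, function(j) d(i, j)))
    b <- Inf
    for (g in setdiff(unique(cl), cl[i])) {
      b <- min(b, mean(sapply(which(cl == g), function(j) d(i, j))))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

oracle_dunn <- function(points, cl) {
  d <- function(i, j) sqrt(sum((points[i, ] - points[j, ])^2))
  ids <- unique(cl)
  diam <- 0
  for (g in ids) {
    for (i in which(cl == g)) for (j in which(cl == g))
      diam <- max(diam, d(i, j))
  }
  sep <- Inf
  for (gi in seq_along(ids)) for (gj in seq_along(ids)) {
    if (gi >= gj) next
    for (i in which(cl == ids[gi])) for (j in which(cl == ids[gj]))
      sep <- min(sep, d(i, j))
  }
  sep / diam
}

random_survival_table <- function(n, seed) {
  set.seed(seed)
  data.frame(
    time = sample(1:12, n, replace = TRUE),         # forces ties
    event = rbinom(n, 1, 0.7),
    risk = sample(seq(0, 2, 0.25), n, replace = TRUE))  # forces risk ties
}
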