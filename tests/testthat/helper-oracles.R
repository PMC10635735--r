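# Independent oracles, deliberately implemented by a different route than
# the package code they check.

# Eq.-style recurrence y[n] = m[n] + 2 y[n-1] - y[n-2], zero initial state.
oracle_resonator <- function(m) {
  n <- length(m)
  y <- numeric(n)
  y1 <- 0; y2 <- 0
  for (i in seq_len(n)) {
    y[i] <- m[i] + 2 * y1 - y2
    y2 <- y1
    y1 <- y[i]
  }
  y
}

# Windowed local-mean subtraction by explicit loops, clipped at boundaries.
oracle_local_mean <- function(y, n1) {
  n <- length(y)
  z <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - n1)
    hi <- min(n, i + n1)
    z[i] <- y[i] - mean(y[lo:hi])
  }
  z
}

# Connected-component labelling by iterative flood fill (stack-based),
# full neighbourhood (8 in 2-D, 26 in 3-D).
oracle_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  nd <- length(d)
  offs <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      co <- arrayInd(v, d)
      for (r in seq_len(nrow(offs))) {
        nb <- co + offs[r, ]
        if (all(nb >= 1L) && all(nb <= d)) {
          li <- nb[1L]
          mult <- 1L
          for (k in seq_len(nd)[-1L]) {
            mult <- mult * d[k - 1L]
            li <- li + (nb[k] - 1L) * mult
          }
          if (mask[li] && lab[li] == 0L) {
            lab[li] <- cur
            stack <- c(stack, li)
          }
        }
      }
    }
  }
  lab
}

# A noisy multi-event BOLD course with known impulse train.
make_noisy_course <- function(seed, n_time = 400, n_events = 20, tr = 2,
                              noise_frac = 0.2) {
  hrf <- canonical_hrf(tr = tr)
  withr::with_seed(seed, {
    train <- sort(sample.int(n_time, n_events) - 1L)
    clean <- synthesize_bold(train, hrf, n_time = n_time)$clean
    list(train = train,
         values = clean + rnorm(n_time, sd = noise_frac * max(abs(clean))),
         clean = clean, tr = tr)
  })
}
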