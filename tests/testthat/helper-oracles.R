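# Independent oracles used across the suite. These deliberately use different
# algorithms (scalar loops, exhaustive enumeration, textbook formulas) from
# the implementation paths they check.

# Scalar even-odd point-in-polygon with edge inclusion, one point at a time.
oracle_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  # on any closed edge?
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    d <- (vx[i] - vx[j]) * (py - vy[j]) - (vy[i] - vy[j]) * (px - vx[j])
    if (d == 0 &&
        px >= min(vx[i], vx[j]) && px <= max(vx[i], vx[j]) &&
        py >= min(vy[i], vy[j]) && py <= max(vy[i], vy[j])) {
      return(TRUE)
    }
  }
  crossings <- 0L
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    if ((vy[j] > py) != (vy[i] > py)) {
      xint <- vx[j] + (py - vy[j]) * (vx[i] - vx[j]) / (vy[i] - vy[j])
      if (px < xint) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# Exhaustive signed-rank distribution: all 2^n sign assignments.
# Returns V statistic and p-value with R's two-sided convention.
oracle_signed_rank <- function(x, y, alternative = "two.sided") {
  d <- x - y
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  p <- switch(alternative,
    two.sided = min(1, 2 * (if (v_obs > n * (n + 1) / 4) p_ge else p_le)),
    greater = p_ge,
    less = p_le)
  list(statistic = v_obs, p_value = p)
}

# Exhaustive Mann-Whitney distribution: all choose(n+m, n) group assignments.
oracle_rank_sum <- function(x, y, alternative = "two.sided") {
  stopifnot(!anyDuplicated(c(x, y)))
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2   # U statistic, R's W
  combs <- utils::combn(n + m, n)
  w_all <- apply(combs, 2, function(idx) sum(r[idx])) - n * (n + 1) / 2
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  p <- switch(alternative,
    two.sided = min(1, 2 * (if (w_obs > n * m / 2) p_ge else p_le)),
    greater = p_ge,
    less = p_le)
  list(statistic = w_obs, p_value = p)
}

# Textbook tie-free Spearman rho: 1 - 6*sum(d^2)/(n(n^2-1)).
oracle_spearman_rho <- function(x, y) {
  stopifnot(!anyDuplicated(x), !anyDuplicated(y))
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Random event table for gating-engine checks.
random_event_table <- function(n = 1000, seed = NULL) {
  make <- function() {
    event_table(data.frame(
      FSC_A = runif(n, 0, 100), FSC_H = runif(n, 0, 100),
      SSC_A = runif(n, 0, 100),
      CD3 = rlnorm(n, log(100), 1), CD14 = rlnorm(n, log(100), 1)
    ))
  }
  if (is.null(seed)) make() else withr::with_seed(seed, make())
}

# Random gate over a random kind, geometry spanning the table's ranges.
random_gate <- function(table) {
  kind <- sample(c("interval", "threshold", "rectangle", "polygon", "quadrant"), 1)
  ch <- sample(channels(table), 2)
  rng1 <- range(table[[ch[1]]]); rng2 <- range(table[[ch[2]]])
  switch(kind,
    interval = {
      b <- sort(runif(2, rng1[1], rng1[2]))
      gate("g", "interval", ch[1], lo = b[1], hi = b[2])
    },
    threshold = gate("g", "threshold", ch[1], at = runif(1, rng1[1], rng1[2]),
                     side = sample(c("above", "below"), 1)),
    rectangle = {
      bx <- sort(runif(2, rng1[1], rng1[2])); by <- sort(runif(2, rng2[1], rng2[2]))
      gate("g", "rectangle", ch, xlim = bx, ylim = by)
    },
    polygon = {
      k <- sample(3:8, 1)
      gate("g", "polygon", ch,
           vertices = cbind(runif(k, rng1[1], rng1[2]), runif(k, rng2[1], rng2[2])))
    },
    quadrant = gate("g", "quadrant", ch, x_at = runif(1, rng1[1], rng1[2]),
                    y_at = runif(1, rng2[1], rng2[2]))
  )
}

# Brute-force gate evaluation: per-event scalar predicate.
oracle_apply_gate <- function(table, g) {
  x <- table[[g$channels[1]]]
  y <- if (length(g$channels) > 1) table[[g$channels[2]]] else NULL
  geo <- g$geometry
  keep <- switch(g$kind,
    interval = vapply(x, function(v) v >= geo$lo && v < geo$hi, logical(1)),
    threshold = vapply(x, function(v) if (geo$side == "above") v >= geo$at else v < geo$at,
                       logical(1)),
    rectangle = mapply(function(a, b) {
      a >= geo$xlim[1] && a < geo$xlim[2] && b >= geo$ylim[1] && b < geo$ylim[2]
    }, x, y),
    polygon = mapply(function(a, b) {
      oracle_in_polygon(a, b, geo$vertices[, 1], geo$vertices[, 2])
    }, x, y),
    quadrant = NULL
  )
  if (g$kind == "quadrant") {
    xp <- x >= geo$x_at; yp <- y >= geo$y_at
    return(list("++" = table$event_id[xp & yp], "+-" = table$event_id[xp & !yp],
                "-+" = table$event_id[!xp & yp], "--" = table$event_id[!xp & !yp]))
  }
  table$event_id[keep]
}

# Composition with a simple three-population live pool (used by the
# binomial-oracle tests that pin f_T and f_M directly).
simple_composition <- function(f_T = 0.4, f_M = 0.1) {
  c(CD4_naive = f_T / 4, CD4_Tcm = f_T / 4, CD4_Tem = f_T / 4, CD4_Temra = f_T / 4,
    CD8 = 0, DNEG = 0, DPOS = 0,
    mono = f_M, other = 1 - f_T - f_M, debris = 0, dead = 0)
}
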