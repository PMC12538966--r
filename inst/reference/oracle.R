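# Independent brute-force implementation of the temporal wave-segmentation
# rules, written as plain loops directly from the rule statements. Used as
# the reference against which segment_position() is checked; it shares no
# code with the package implementation.

oracle_rho <- function(series, r, N) {
  tt <- nrow(series)
  out <- numeric(tt)
  for (t in seq_len(tt)) {
    vals <- c()
    for (tp in (t - N):(t + N)) {
      if (tp >= 1 && tp <= tt) {
        v <- series[tp, ]
        nv <- sqrt(sum(v^2))
        vals <- c(vals, if (nv > 0) sum((v / nv) * r) else 0)
      }
    }
    out[t] <- mean(vals)
  }
  # same 12-decimal quantization as the package's score (the plateau rule
  # compares score values for exact equality)
  round(out, 12)
}

# strict local extrema, plateaus resolved to their first frame, endpoints
# excluded; then each max paired with the immediately following min
oracle_pairs <- function(rho) {
  tt <- length(rho)
  ext <- list()
  t <- 1
  while (t <= tt) {
    e <- t
    while (e < tt && rho[e + 1] == rho[t]) e <- e + 1
    if (t > 1 && e < tt) {
      if (rho[t - 1] < rho[t] && rho[e + 1] < rho[t]) {
        ext[[length(ext) + 1]] <- list(frame = t, type = "max")
      } else if (rho[t - 1] > rho[t] && rho[e + 1] > rho[t]) {
        ext[[length(ext) + 1]] <- list(frame = t, type = "min")
      }
    }
    t <- e + 1
  }
  pairs <- list()
  for (i in seq_along(ext)) {
    if (ext[[i]]$type == "max" && i < length(ext) &&
        ext[[i + 1]]$type == "min") {
      pairs[[length(pairs) + 1]] <- c(ext[[i]]$frame, ext[[i + 1]]$frame)
    }
  }
  pairs
}

oracle_expand <- function(series, seed, theta, M_min, lo, hi) {
  cth <- cos(theta * pi / 180)
  passes <- function(t, set) {
    v <- series[t, ]
    m <- sqrt(sum(v^2))
    if (m == 0 || m < M_min) return(FALSE)
    avg <- colMeans(series[set, , drop = FALSE])
    na <- sqrt(sum(avg^2))
    if (na == 0) return(FALSE)
    sum((v / m) * (avg / na)) > cth
  }
  set <- seed
  left_open <- TRUE
  right_open <- TRUE
  dist <- 1
  while (left_open || right_open) {
    t_l <- seed - dist
    t_r <- seed + dist
    if (left_open) {
      if (t_l < lo) {
        left_open <- FALSE
      } else if (passes(t_l, set)) {
        set <- c(t_l, set)
      } else {
        left_open <- FALSE
      }
    }
    if (right_open) {
      if (t_r > hi) {
        right_open <- FALSE
      } else if (passes(t_r, set)) {
        set <- c(set, t_r)
      } else {
        right_open <- FALSE
      }
    }
    dist <- dist + 1
  }
  sort(set)
}

oracle_segment <- function(series, r, params, dorsal_axis = NULL) {
  tt <- nrow(series)
  if (all(series == 0)) return(list())
  rho <- oracle_rho(series, r, params$window_N)
  pairs <- oracle_pairs(rho)
  claimed <- rep(FALSE, tt)
  waves <- list()
  for (pr in pairs) {
    t_max <- pr[1]
    t_min <- pr[2]
    if (claimed[t_max] || claimed[t_min]) next
    v1 <- series[t_max, ]
    v2 <- series[t_min, ]
    n1 <- sqrt(sum(v1^2))
    n2 <- sqrt(sum(v2^2))
    if (n1 == 0 || n2 == 0) next
    if (!(sum((v1 / n1) * r) > cos(params$theta_r * pi / 180))) next
    if (!(sum((v1 / n1) * (v2 / n2)) < cos(params$theta_VD * pi / 180))) next
    if (params$enforce_dorsal_halfplane &&
        !(sum((v2 / n2) * dorsal_axis) > 0)) next

    lo_v <- 1
    for (t in seq_len(t_max)) if (claimed[t]) lo_v <- t + 1
    V <- oracle_expand(series, t_max, params$theta_V, params$M_min,
                       lo_v, t_min - 1)
    hi_d <- tt
    for (t in tt:t_min) if (claimed[t]) hi_d <- t - 1
    D <- oracle_expand(series, t_min, params$theta_D, params$M_min,
                       max(V) + 1, hi_d)

    g <- min(D) - max(V) - 1
    if (g > params$max_gap) next
    if (g > 0) {
      v_avg <- colMeans(series[V, , drop = FALSE])
      d_avg <- colMeans(series[D, , drop = FALSE])
      v_avg <- v_avg / sqrt(sum(v_avg^2))
      d_avg <- d_avg / sqrt(sum(d_avg^2))
      gap <- (max(V) + 1):(min(D) - 1)
      to_d <- FALSE
      for (t in gap) {
        v <- series[t, ]
        nv <- sqrt(sum(v^2))
        u <- if (nv > 0) v / nv else v * 0
        if (!to_d && sum(u * d_avg) > sum(u * v_avg)) to_d <- TRUE
        if (to_d) D <- c(t, D) else V <- c(V, t)
      }
      V <- sort(V)
      D <- sort(D)
    }
    mags <- sqrt(rowSums(series^2))
    if (!(mean(mags[V]) >= params$M_avg)) next
    if (!(sum(mags[c(V, D)]) >= params$M_total)) next
    claimed[c(V, D)] <- TRUE
    waves[[length(waves) + 1]] <- list(t_max = t_max, t_min = t_min,
                                       V = V, D = D)
  }
  waves
}

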