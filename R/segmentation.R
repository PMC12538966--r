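#' Sliding-window direction similarity score
#'
#' For each frame `t`, the mean over the window `[t - N, t + N]` (clipped to
#' the series bounds) of the dot product between the normalized vector at
#' each frame and the unit reference direction `r`. Zero (or invalid)
#' vectors contribute a zero summand, so quiescent stretches pull the score
#' toward 0 rather than being undefined. The score lies in `[-1, 1]`; its
#' local maxima mark candidate V-phase centres and its local minima
#' candidate D-phase centres.
#'
#' The score is quantized to 12 decimals before being returned: windows
#' whose contributions cancel exactly in real arithmetic must yield equal
#' score values (plateaus), and quantization keeps the plateau/extrema
#' detection of [find_candidate_pairs()] robust to floating-point
#' accumulation noise.
#'
#' @param series numeric `T x D` matrix, the vector time series at one grid
#'   position (see [vector_series()]).
#' @param r unit reference vector (length `D`).
#' @param window_N window half-width in frames (>= 1).
#' @return numeric vector of length `T`.
#' @export
direction_similarity <- function(series, r, window_N = 2) {
  if (is.null(dim(series))) series <- matrix(series, ncol = 1)
  tt <- nrow(series)
  if (tt == 0) stop("empty series")
  if (window_N < 1) stop("window_N must be >= 1")
  if (abs(vec_norm(r) - 1) > 1e-9) stop("r must be unit-norm")
  mags <- sqrt(rowSums(series^2))
  unit <- series
  nz <- mags > 0
  unit[nz, ] <- series[nz, , drop = FALSE] / mags[nz]
  unit[!nz, ] <- 0
  dots <- as.numeric(unit %*% r)
  rho <- vapply(seq_len(tt), function(t) {
    w <- max(1, t - window_N):min(tt, t + window_N)
    mean(dots[w])
  }, numeric(1))
  round(rho, 12)
}

#' Candidate (t_max, t_min) pairs from the similarity score
#'
#' Finds strict interior local maxima and minima of the score (plateaus are
#' resolved to their first frame; series endpoints are never extrema) and
#' pairs each local maximum with the nearest subsequent local minimum that
#' has no intervening maximum. Unpaired extrema are dropped.
#'
#' @param rho numeric vector, a direction-similarity series (length >= 3).
#' @return Integer matrix with columns `t_max`, `t_min` (possibly 0 rows).
#' @export
find_candidate_pairs <- function(rho) {
  if (length(rho) < 3) stop("series too short for extrema detection")
  runs <- rle(rho)
  k <- length(runs$values)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  type <- integer(k)
  if (k >= 3) {
    for (i in 2:(k - 1)) {
      if (runs$values[i] > runs$values[i - 1] &&
          runs$values[i] > runs$values[i + 1]) {
        type[i] <- 1L
      } else if (runs$values[i] < runs$values[i - 1] &&
                 runs$values[i] < runs$values[i + 1]) {
        type[i] <- -1L
      }
    }
  }
  keep <- which(type != 0L)
  out <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("t_max", "t_min")))
  if (length(keep) < 2) return(out)
  frames <- starts[keep]
  types <- type[keep]
  for (i in seq_len(length(keep) - 1)) {
    if (types[i] == 1L && types[i + 1] == -1L) {
      out <- rbind(out, c(frames[i], frames[i + 1]))
    }
  }
  storage.mode(out) <- "integer"
  out
}

#' Angle-based screening of a candidate pair
#'
#' A candidate `(t_max, t_min)` pair is accepted when (a) the vector at
#' `t_max` points within `theta_r` of the reference direction, (b) the
#' vectors at `t_max` and `t_min` are separated by more than `theta_VD`,
#' and (c) — if the dorsal half-plane check is on — the vector at `t_min`
#' has a positive component along the dorsal axis. A zero vector at either
#' frame rejects the candidate.
#'
#' @param series numeric `T x D` matrix.
#' @param t_max,t_min candidate frames, `t_max < t_min`.
#' @param r unit reference vector.
#' @param params a [wave_params()].
#' @param dorsal_axis unit dorsal axis (required when the half-plane check
#'   is on).
#' @return list with elements `accept` (logical) and `reason` (character).
#' @export
check_candidate <- function(series, t_max, t_min, r, params,
                            dorsal_axis = NULL) {
  if (is.null(dim(series))) series <- matrix(series, ncol = 1)
  tt <- nrow(series)
  if (t_max < 1 || t_min > tt || t_max >= t_min) {
    stop("candidate frames out of range")
  }
  v1 <- series[t_max, ]
  v2 <- series[t_min, ]
  if (vec_norm(v1) == 0 || vec_norm(v2) == 0) {
    return(list(accept = FALSE, reason = "zero_vector"))
  }
  u1 <- unit_vec(v1)
  u2 <- unit_vec(v2)
  if (!(sum(u1 * r) > cos(deg2rad(params$theta_r)))) {
    return(list(accept = FALSE, reason = "reference_angle"))
  }
  if (!(sum(u1 * u2) < cos(deg2rad(params$theta_VD)))) {
    return(list(accept = FALSE, reason = "vd_separation"))
  }
  if (params$enforce_dorsal_halfplane) {
    if (is.null(dorsal_axis)) stop("dorsal_axis required for half-plane check")
    if (!(sum(u2 * dorsal_axis) > 0)) {
      return(list(accept = FALSE, reason = "dorsal_halfplane"))
    }
  }
  list(accept = TRUE, reason = "ok")
}

#' Grow a phase segmentation outward from a seed frame
#'
#' Starting from `{seed_t}`, frames are tested from nearest to farthest,
#' alternating sides (at each distance the earlier frame is tested before
#' the later one). A frame joins the set when its vector (i) points within
#' `theta_phase` of the normalized running average of the vectors already in
#' the set and (ii) has magnitude `>= M_min` (and `> 0`). A side closes at
#' its first failing frame or at `bounds`; the result is contiguous and
#' contains the seed.
#'
#' @param series numeric `T x D` matrix.
#' @param seed_t seed frame with a nonzero vector.
#' @param theta_phase intra-phase coherence angle, degrees.
#' @param M_min magnitude gate, per frame.
#' @param bounds integer `(lo, hi)` frame interval the set may not leave.
#' @return sorted integer vector of frames.
#' @export
expand_phase <- function(series, seed_t, theta_phase, M_min,
                         bounds = c(1L, nrow(series))) {
  if (is.null(dim(series))) series <- matrix(series, ncol = 1)
  if (seed_t < bounds[1] || seed_t > bounds[2]) stop("seed outside bounds")
  if (vec_norm(series[seed_t, ]) == 0) stop("zero vector at seed frame")
  cth <- cos(deg2rad(theta_phase))
  vsum <- series[seed_t, ]
  n_in <- 1L
  set <- seed_t

  joins <- function(t) {
    v <- series[t, ]
    mag <- vec_norm(v)
    if (mag == 0 || mag < M_min) return(FALSE)
    avg <- vsum / n_in
    na <- vec_norm(avg)
    if (na == 0) return(FALSE)
    sum((v / mag) * (avg / na)) > cth
  }

  left <- seed_t - 1L
  right <- seed_t + 1L
  left_open <- left >= bounds[1]
  right_open <- right <= bounds[2]
  while (left_open || right_open) {
    if (left_open) {
      if (joins(left)) {
        set <- c(left, set)
        vsum <- vsum + series[left, ]
        n_in <- n_in + 1L
        left <- left - 1L
        left_open <- left >= bounds[1]
      } else {
        left_open <- FALSE
      }
    }
    if (right_open) {
      if (joins(right)) {
        set <- c(set, right)
        vsum <- vsum + series[right, ]
        n_in <- n_in + 1L
        right <- right + 1L
        right_open <- right <= bounds[2]
      } else {
        right_open <- FALSE
      }
    }
  }
  sort(set)
}

#' Resolve the V/D interface
#'
#' When the V and D segmentations are not directly adjacent (e.g. the
#' interface vectors have very low magnitude), gap frames of size up to
#' `max_gap` are assigned to the phase whose (normalized) average vector
#' they match best; ties go to V. To keep both intervals contiguous the
#' boundary is placed at the first gap frame that matches D best: earlier
#' gap frames join V, that frame and all later ones join D. A gap larger
#' than `max_gap` rejects the candidate wave.
#'
#' @param series numeric `T x D` matrix.
#' @param V_set,D_set sorted integer frame sets, V strictly before D.
#' @param max_gap largest tolerated gap in frames.
#' @return list with `accept` (logical) and, when accepted, the adjusted
#'   `V` and `D` frame sets.
#' @export
assign_interface <- function(series, V_set, D_set, max_gap = 2) {
  if (is.null(dim(series))) series <- matrix(series, ncol = 1)
  if (length(intersect(V_set, D_set)) > 0) stop("V and D sets overlap")
  if (max(V_set) >= min(D_set)) stop("V must precede D")
  g <- min(D_set) - max(V_set) - 1L
  if (g == 0) return(list(accept = TRUE, V = V_set, D = D_set))
  if (g > max_gap) return(list(accept = FALSE, V = V_set, D = D_set))
  v_avg <- unit_vec(colMeans(series[V_set, , drop = FALSE]))
  d_avg <- unit_vec(colMeans(series[D_set, , drop = FALSE]))
  gap <- seq.int(max(V_set) + 1L, min(D_set) - 1L)
  split <- length(gap) + 1L  # default: everything joins V
  for (i in seq_along(gap)) {
    u <- unit_vec(series[gap[i], ])
    if (sum(u * d_avg) > sum(u * v_avg)) {  # strict: tie goes to V
      split <- i
      break
    }
  }
  list(accept = TRUE,
       V = c(V_set, head(gap, split - 1L)),
       D = c(tail(gap, length(gap) - split + 1L), D_set))
}

# Assemble a wave record from final V/D frame sets.
make_wave_record <- function(series, t_max, t_min, V_set, D_set) {
  mags <- sqrt(rowSums(series^2))
  list(
    t_max = as.integer(t_max), t_min = as.integer(t_min),
    V = as.integer(sort(V_set)), D = as.integer(sort(D_set)),
    V_avg = colMeans(series[V_set, , drop = FALSE]),
    D_avg = colMeans(series[D_set, , drop = FALSE]),
    mean_speed_V = mean(mags[V_set]),
    total_displacement = sum(mags[c(V_set, D_set)])
  )
}

#' Speed-based acceptance of a segmented wave
#'
#' A wave is kept when the mean speed of its V phase is at least `M_avg`
#' and the total displacement (sum of vector magnitudes over the V and D
#' phases) is at least `M_total`.
#'
#' @param record a wave record as produced internally by
#'   [segment_position()] (a list with `mean_speed_V` and
#'   `total_displacement`).
#' @param params a [wave_params()].
#' @return logical.
#' @export
filter_wave <- function(record, params) {
  record$mean_speed_V >= params$M_avg &&
    record$total_displacement >= params$M_total
}

#' Temporal wave segmentation of one vector time series
#'
#' Runs the full per-position pipeline: direction-similarity score ->
#' candidate `(t_max, t_min)` pairs -> angle screening -> V expansion from
#' `t_max` (bounded above by `t_min - 1` and below by previously accepted
#' waves) -> D expansion from `t_min` (bounded below by the end of V) ->
#' interface resolution -> speed filtering. Accepted waves are temporally
#' disjoint and sorted; candidates whose seed frames fall into already
#' claimed frames are skipped.
#'
#' @param series numeric `T x D` matrix with `T >= 2 * window_N + 1`.
#' @param r unit reference vector at this position.
#' @param params a [wave_params()].
#' @param dorsal_axis unit dorsal axis (needed when the half-plane check is
#'   on).
#' @return A tibble with one row per accepted wave: `t_max`, `t_min`,
#'   `v_start`, `v_end`, `d_start`, `d_end`, `mean_speed_v`,
#'   `total_displacement`, and list columns `v_avg`, `d_avg`.
#' @export
segment_position <- function(series, r, params = wave_params(),
                             dorsal_axis = NULL) {
  if (is.null(dim(series))) series <- matrix(series, ncol = 1)
  tt <- nrow(series)
  if (tt < 2 * params$window_N + 1) {
    stop("series shorter than the similarity window")
  }
  empty <- tibble::tibble(
    t_max = integer(0), t_min = integer(0),
    v_start = integer(0), v_end = integer(0),
    d_start = integer(0), d_end = integer(0),
    mean_speed_v = numeric(0), total_displacement = numeric(0),
    v_avg = list(), d_avg = list()
  )
  if (all(series == 0)) return(empty)
  rho <- direction_similarity(series, r, params$window_N)
  pairs <- find_candidate_pairs(rho)
  if (nrow(pairs) == 0) return(empty)

  claimed <- logical(tt)
  records <- list()
  for (i in seq_len(nrow(pairs))) {
    t_max <- pairs[i, 1]
    t_min <- pairs[i, 2]
    if (claimed[t_max] || claimed[t_min]) next
    chk <- check_candidate(series, t_max, t_min, r, params, dorsal_axis)
    if (!chk$accept) next

    before <- which(claimed[seq_len(t_max)])
    lo_v <- if (length(before)) max(before) + 1L else 1L
    V_set <- expand_phase(series, t_max, params$theta_V, params$M_min,
                          bounds = c(lo_v, t_min - 1L))

    after <- which(claimed)
    after <- after[after > t_min]
    hi_d <- if (length(after)) min(after) - 1L else tt
    D_set <- expand_phase(series, t_min, params$theta_D, params$M_min,
                          bounds = c(max(V_set) + 1L, hi_d))

    iface <- assign_interface(series, V_set, D_set, params$max_gap)
    if (!iface$accept) next
    rec <- make_wave_record(series, t_max, t_min, iface$V, iface$D)
    if (!filter_wave(rec, params)) next
    claimed[c(rec$V, rec$D)] <- TRUE
    records[[length(records) + 1]] <- rec
  }
  if (!length(records)) return(empty)
  tibble::tibble(
    t_max = vapply(records, `[[`, integer(1), "t_max"),
    t_min = vapply(records, `[[`, integer(1), "t_min"),
    v_start = vapply(records, function(r_) min(r_$V), integer(1)),
    v_end = vapply(records, function(r_) max(r_$V), integer(1)),
    d_start = vapply(records, function(r_) min(r_$D), integer(1)),
    d_end = vapply(records, function(r_) max(r_$D), integer(1)),
    mean_speed_v = vapply(records, `[[`, numeric(1), "mean_speed_V"),
    total_displacement = vapply(records, `[[`, numeric(1),
                                "total_displacement"),
    v_avg = lapply(records, `[[`, "V_avg"),
    d_avg = lapply(records, `[[`, "D_avg")
  )
}

#' Wave segmentation of a whole vector-field sequence
#'
#' Applies [segment_position()] independently to the vector time series at
#' every grid node and rasterizes the accepted waves into a label volume
#' (`0` = none, `1` = V phase, `2` = D phase) over `(t, <grid dims>)`.
#'
#' @param fields a `vector_field_sequence`.
#' @param refs a [reference_field()] (constant or per-node); must be defined
#'   on every valid node.
#' @param params a [wave_params()].
#' @return An object of class `wave_segmentation`: list with `waves` (a
#'   tibble of per-node wave records, node indices in columns `y`, `x`
#'   (and `z`)), `labels` (integer array `(t, <grid dims>)`) and the grid
#'   metadata of `fields`.
#' @export
segment_field <- function(fields, refs, params = wave_params()) {
  stopifnot(inherits(fields, "vector_field_sequence"),
            inherits(refs, "reference_field"))
  gs <- grid_shape(fields)
  nd <- field_ndim(fields)
  if (is.array(refs$r) && length(dim(refs$r)) >= 2) {
    if (!identical(dim(refs$r)[-length(dim(refs$r))], gs)) {
      stop("per-node reference field shape does not match the grid")
    }
  }
  tt <- n_steps(fields)
  labels <- array(0L, c(tt, gs))
  ax_names <- if (nd == 2) c("y", "x") else c("z", "y", "x")
  waves <- list()
  nodes <- as.matrix(expand.grid(lapply(gs, seq_len)))
  for (ni in seq_len(nrow(nodes))) {
    pos <- nodes[ni, ]
    if (all(do.call(`[`, c(list(fields$validity),
                           c(list(seq_len(tt)), as.list(pos)))) == 0)) next
    series <- vector_series(fields, pos)
    if (all(series == 0)) next
    w <- segment_position(series, ref_at(refs, pos), params,
                          dorsal_axis = refs$dorsal_axis)
    if (nrow(w) == 0) next
    for (k in seq_len(nrow(w))) {
      vi <- cbind(w$v_start[k]:w$v_end[k],
                  matrix(pos, nrow = w$v_end[k] - w$v_start[k] + 1,
                         ncol = nd, byrow = TRUE))
      di <- cbind(w$d_start[k]:w$d_end[k],
                  matrix(pos, nrow = w$d_end[k] - w$d_start[k] + 1,
                         ncol = nd, byrow = TRUE))
      labels[vi] <- 1L
      labels[di] <- 2L
    }
    for (j in seq_len(nd)) w[[ax_names[j]]] <- pos[j]
    waves[[length(waves) + 1]] <- w
  }
  waves <- if (length(waves)) do.call(rbind, waves) else {
    w0 <- segment_position(matrix(0, 2 * params$window_N + 1, nd),
                           c(1, rep(0, nd - 1)), params)
    for (j in seq_len(nd)) w0[[ax_names[j]]] <- integer(0)
    w0
  }
  structure(
    list(waves = waves, labels = labels,
         grid_step = fields$grid_step, grid_origin = fields$grid_origin,
         params = params),
    class = "wave_segmentation"
  )
}

#' @export
print.wave_segmentation <- function(x, ...) {
  dl <- dim(x$labels)
  cat(sprintf(
    "<wave_segmentation> %d waves at %d positions; label volume %s\n",
    nrow(x$waves),
    nrow(unique(x$waves[, intersect(c("z", "y", "x"), names(x$waves))])),
    paste(dl, collapse = " x ")
  ))
  invisible(x)
}
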