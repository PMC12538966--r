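# The exhaustive rule-by-rule reference implementation ships with the
# package so the acceptance script can use it too.
source(system.file("reference", "oracle.R", package = "waveseg"))

# convert a segment_position() tibble into the oracle's list form
waves_as_list <- function(w) {
  lapply(seq_len(nrow(w)), function(i) {
    list(t_max = w$t_max[i], t_min = w$t_min[i],
         V = w$v_start[i]:w$v_end[i], D = w$d_start[i]:w$d_end[i])
  })
}

# random short series from an 8-direction alphabet
random_alphabet_series <- function(len, ndim = 2) {
  dirs <- seq(0, 315, by = 45) * pi / 180
  mags <- c(0, 0.3, 0.8, 2, 3)
  m <- sample(mags, len, replace = TRUE)
  a <- sample(dirs, len, replace = TRUE)
  cbind(m * sin(a), m * cos(a))
}
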