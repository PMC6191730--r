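# Shared fixture builders: everything is generated in code at test time.

# a dynamic study whose frames are supplied directly (counts per pixel)
make_study <- function(frames, frame_seconds = 15, posture = "upright",
                       protocol = acquisition_protocol()) {
  structure(list(posture = posture, frames = frames,
                 frame_times = (seq_along(frames) - 1) * frame_seconds,
                 protocol = protocol),
            class = "dynamic_study")
}

uniform_frames <- function(n_frames, level, n = 64L) {
  lapply(seq_len(n_frames), function(i) matrix(level, n, n))
}

# a study with a constant organ excess over a uniform background
excess_study <- function(roi_zone, excess, bg_level, n_frames = 8,
                         frame_seconds = 15, n = 64L) {
  frames <- lapply(seq_len(n_frames), function(i) {
    f <- matrix(bg_level, n, n)
    f[(roi_zone$row0:roi_zone$row1) + 1L, (roi_zone$col0:roi_zone$col1) + 1L] <-
      bg_level + excess
    f
  })
  make_study(frames, frame_seconds)
}

make_tac <- function(times_s, values, roi = "pharynx", posture = "supine") {
  structure(list(roi_name = roi, posture = posture, times = times_s,
                 values = values), class = "tac")
}

make_delayed <- function(pixels, protocol = acquisition_protocol()) {
  structure(list(pixels = pixels, acquisition_time_minutes = 120,
                 protocol = protocol), class = "delayed_image")
}

# exhaustive hypergeometric enumeration oracle for the two-sided Fisher p,
# using binomial coefficients directly (independent of dhyper)
fisher_oracle <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, function(k)
    choose(c1, k) * choose(n - c1, r1 - k) / choose(n, r1), numeric(1))
  p_obs <- probs[support == m[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# brute-force pairwise-concordance AUC oracle
auc_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# closed-form least-squares slope and standard error
slope_oracle <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  b <- sum(xc * yc) / sum(xc^2)
  res <- yc - b * xc
  se <- sqrt(sum(res^2) / (length(x) - 2) / sum(xc^2))
  c(slope = b, se = se)
}
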