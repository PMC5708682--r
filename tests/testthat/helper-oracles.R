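# Independent double-loop oracles, kept free of the package's vectorized path.

oracle_contacts <- function(xyz, res, cutoff = 8, separation = 2) {
  out <- NULL
  for (a in seq_along(res)) {
    for (b in seq_along(res)) {
      if (b <= a || res[b] - res[a] < separation) next
      d <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
      if (d <= cutoff) out <- rbind(out, c(res[a], res[b], d))
    }
  }
  out
}

oracle_qnc <- function(frame_xyz, res, contacts) {
  s <- 0
  for (k in seq_len(nrow(contacts$pairs))) {
    i <- contacts$pairs$i[k]; j <- contacts$pairs$j[k]
    a <- match(i, res); b <- match(j, res)
    d <- sqrt(sum((frame_xyz[a, ] - frame_xyz[b, ])^2))
    sg <- abs(i - j)^0.15
    s <- s + exp(-(contacts$native_distances[k] - d)^2 / (2 * sg^2))
  }
  s / nrow(contacts$pairs)
}

oracle_qsim <- function(frame_xyz, ref_xyz, res) {
  s <- 0; n_terms <- 0
  for (a in seq_along(res)) {
    for (b in seq_along(res)) {
      if (b <= a || res[b] - res[a] < 2) next
      dr <- sqrt(sum((ref_xyz[a, ] - ref_xyz[b, ])^2))
      df <- sqrt(sum((frame_xyz[a, ] - frame_xyz[b, ])^2))
      sg <- abs(res[a] - res[b])^0.15
      s <- s + exp(-(dr - df)^2 / sg^2)
      n_terms <- n_terms + 1
    }
  }
  s / n_terms
}
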