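# Independent brute-force oracles, written directly from the defining
# formulas with plain loops/tables; deliberately share no code with the
# package internals they check.

ncc_oracle <- function(f, m) {
  fb <- mean(f)
  mb <- mean(m)
  num <- 0
  d1 <- 0
  d2 <- 0
  for (i in seq_along(f)) {
    num <- num + (f[i] - fb) * (m[i] - mb)
    d1 <- d1 + (f[i] - fb)^2
    d2 <- d2 + (m[i] - mb)^2
  }
  num / sqrt(d1 * d2)
}

hard_bin_oracle <- function(x, bins) {
  r <- range(x)
  w <- diff(r) / bins
  if (w <= 0) return(rep(0L, length(x)))
  pmin(pmax(floor((x - r[1]) / w), 0), bins - 1)
}

entropy_oracle <- function(p) {
  h <- 0
  for (v in p) if (v > 0) h <- h - v * log(v)
  h
}

# Hard-binned MI/NMI from first principles: joint cell counts, then
# H(F) + H(M) - H(F, M) and (H(F) + H(M)) / H(F, M).
mi_nmi_oracle <- function(f, m, bins) {
  fb <- hard_bin_oracle(f, bins)
  mb <- hard_bin_oracle(m, bins)
  joint <- matrix(0, bins, bins)
  for (i in seq_along(fb))
    joint[fb[i] + 1, mb[i] + 1] <- joint[fb[i] + 1, mb[i] + 1] + 1
  p <- joint / sum(joint)
  hf <- entropy_oracle(rowSums(p))
  hm <- entropy_oracle(colSums(p))
  hj <- entropy_oracle(as.numeric(p))
  list(mi = hf + hm - hj, nmi = (hf + hm) / hj)
}

verr_oracle <- function(ref, test, mask) {
  acc <- 0
  n <- 0
  for (i in seq_along(ref)) {
    if (mask[i]) {
      acc <- acc + (ref[i] - test[i])^2
      n <- n + 1
    }
  }
  sqrt(acc / n)
}

mae_by_bin_oracle <- function(ref, test, mask, width = 20) {
  sums <- list()
  ns <- list()
  for (i in seq_along(ref)) {
    if (!mask[i]) next
    ctr <- as.character(floor((ref[i] + width / 2) / width) * width)
    sums[[ctr]] <- (sums[[ctr]] %||% 0) + abs(ref[i] - test[i])
    ns[[ctr]] <- (ns[[ctr]] %||% 0) + 1
  }
  ctrs <- sort(as.numeric(names(sums)))
  data.frame(bin_center = ctrs,
             mae = vapply(as.character(ctrs),
                          function(k) sums[[k]] / ns[[k]], numeric(1)),
             n = vapply(as.character(ctrs), function(k) ns[[k]],
                        numeric(1)),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Smooth random test volume on a small grid.
random_volume <- function(d, spacing = c(1, 1, 1), smooth = 1.5,
                          scale = 300) {
  v <- image_volume(array(stats::rnorm(prod(d)), d), spacing)
  v$data <- array(cbcthm:::cpp_gauss_smooth(as.numeric(v$data), d,
                                            rep(smooth, 3)) * scale, d)
  v
}
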