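# shared small fixtures and the frozen chi*Cm product used by the tissue
# tests (the calibrated value; the calibration itself is exercised in the
# acceptance tests)
CHI_CM <- 2.17

tissueConfig <- function(...) solverConfig(chiCm = CHI_CM, ...)

smallStrand <- function(length_mm = 12, dx = 0.4, fiberAxis = "x") {
  g <- buildFixture("strand", size = c(length_mm, dx, dx), dx = dx,
                    fiberAxis = fiberAxis)
  applyConductivities(g)
}

# brute-force two-threshold scan used as the SD-classification oracle
oracleSdScan <- function(volume, masks) {
  v <- volume@data
  d <- dim(v)
  lab <- array(1L, d)
  for (k in seq_len(d[3])) {
    infk <- masks@infarct[, , k]
    if (!any(infk)) next
    remk <- masks@remote[, , k]
    mu <- mean(v[, , k][remk])
    s <- sd(v[, , k][remk])
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      if (!infk[i, j]) next
      x <- v[i, j, k]
      lab[i, j, k] <- if (x >= mu + 3 * s) 2L else if (x >= mu + 2 * s) 3L
                      else 1L
    }
  }
  lab
}
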