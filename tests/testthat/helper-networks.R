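# Shared fixtures: tiny networks with analytically known structure.

# gene 1 driven only by gene 3 (strong, centred activation); all other
# genes unregulated and relaxing towards 0.5
singleRegulatorNetwork4 <- function() {
    w <- matrix(0, 4, 4)
    w[1, 3] <- 15
    RNNetwork(w, bias = c(-7.5, 0, 0, 0), tau = rep(10, 4))
}

# gene 3 sits exactly at its unregulated fixed point 0.5 while genes 1
# and 2 sweep different ramps
constantGeneDataset <- function(nSeries = 2, nTimepoints = 10) {
    mats <- lapply(seq_len(nSeries), function(k) {
        m <- matrix(0.5, nTimepoints, 3)
        m[, 1] <- seq(0.1, 0.9, length.out = nTimepoints) * k / nSeries
        m[, 2] <- seq(0.9, 0.2, length.out = nTimepoints) * k / nSeries
        m
    })
    ExpressionTimeSeries(mats)
}

# frozen edge list of the 30-gene benchmark: (target, regulator, weight)
benchmarkEdgeTable <- function() {
    matrix(c(
         1, 14, -15,  5,  1,  10,  6,  1, -20,  7,  2,  15,
         7,  3,  10,  8,  4,  20,  9,  5, -20,  9,  6,  10,
         9, 17,  10, 10,  7, -10, 11,  4, -15, 11,  7,  15,
        11, 22, -15, 12, 23,  10, 13,  8,  20, 14,  9,  15,
        15, 10, -10, 16, 11,  15, 16, 12, -15, 17, 13, -20,
        19, 14, -15, 20, 15,  10, 21, 16, -20, 23, 17, -10,
        24, 15, -15, 24, 18, -20, 24, 19,  15, 25, 20, -10,
        26, 11,  20, 26, 28,  20, 27, 24, -15, 27, 25,  10,
        27, 30,  15, 28, 25, -15, 29, 26,  10, 30, 27,  15
    ), ncol = 3, byrow = TRUE)
}
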