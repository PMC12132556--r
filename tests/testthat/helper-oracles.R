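# Independent oracles used across the suite.

eulerRotation <- function(a) {
    ca <- cos(a); sa <- sin(a)
    Rz <- matrix(c(ca[1], sa[1], 0, -sa[1], ca[1], 0, 0, 0, 1), 3)
    Ry <- matrix(c(ca[2], 0, -sa[2], 0, 1, 0, sa[2], 0, ca[2]), 3)
    Rx <- matrix(c(1, 0, 0, 0, ca[3], sa[3], 0, -sa[3], ca[3]), 3)
    Rz %*% Ry %*% Rx
}

# Numerical rotation-search oracle for the minimal superposition RMSD:
# optimal translation is centroid alignment for any rotation, so minimise
# over Euler angles from many starts with tight tolerance.
oracleSuperposeRMSD <- function(mobile, reference, nStarts = 12L) {
    X <- sweep(mobile, 2, colMeans(mobile))
    Y <- sweep(reference, 2, colMeans(reference))
    f <- function(a) sqrt(mean(rowSums((X %*% eulerRotation(a) - Y)^2)))
    starts <- rbind(c(0, 0, 0),
                    as.matrix(expand.grid(c(0, pi), c(0, pi / 2), c(0, pi))),
                    matrix(stats::runif(3 * nStarts, -pi, pi), ncol = 3))
    best <- Inf
    for (i in seq_len(nrow(starts))) {
        o <- stats::optim(starts[i, ], f, method = "Nelder-Mead",
                          control = list(reltol = 1e-15, maxit = 5000))
        o <- stats::optim(o$par, f, method = "Nelder-Mead",
                          control = list(reltol = 1e-15, maxit = 5000))
        best <- min(best, o$value)
    }
    best
}

randomCloud <- function(n = 6L) matrix(stats::rnorm(3 * n, sd = 5), n, 3)

randomRigidMotion <- function(coords) {
    a <- stats::runif(3, -pi, pi)
    sweep(coords %*% eulerRotation(a), 2, stats::runif(3, -30, 30), "+")
}

# Brute-force nearest-centre assignment by direct Hamming scan.
bruteAssign <- function(rows, centerIdx) {
    vapply(seq_along(rows), function(i) {
        d <- vapply(centerIdx, function(c) hammingDistance(rows[i], rows[c]),
                    numeric(1))
        which.min(d)   # which.min takes the first (lowest centre index) tie
    }, integer(1))
}

randomMSA <- function(n, L) {
    alpha <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")
    rows <- vapply(seq_len(n), function(i)
        paste(sample(alpha, L, replace = TRUE), collapse = ""), character(1))
    MSA(c("target", sprintf("seq%d", seq_len(n - 1))), rows)
}

expect_msa_equal <- function(a, b) {
    expect_identical(msaIds(a), msaIds(b))
    expect_identical(msaRows(a), msaRows(b))
}
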