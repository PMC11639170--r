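# One-sample Kolmogorov-Smirnov machinery.
#
# The clustering test needs a KS p-value with controlled behaviour at both
# small and large n: an exact distribution below EXACT_N points
# (Marsaglia-Tsang-Wang matrix-power evaluation of P(D_n < d)) and the
# asymptotic Kolmogorov distribution above. Discreteness of site ordinals is
# ignored; with thousands of sites the effect is negligible.

EXACT_N <- 50L

# sup-norm distance between the ECDF of x and Uniform(0,1)
.ksStatUnif <- function(x) {
    n <- length(x)
    x <- sort(x)
    i <- seq_len(n)
    max(i / n - x, x - (i - 1) / n)
}

# P(sqrt(n) D_n > lambda) under the Kolmogorov limit law.
# Two standard series: the alternating series for large lambda and the
# theta-function form for small lambda (better convergence).
.kolmogorovTail <- function(lambda) {
    if (lambda < 0.2) return(1)
    if (lambda < 1) {
        k <- 1:20
        p <- sqrt(2 * pi) / lambda *
            sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * lambda^2)))
        return(max(0, min(1, 1 - p)))
    }
    k <- 1:100
    max(0, min(1, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
}

# exact P(D_n >= d) for the one-sample statistic (Marsaglia-Tsang-Wang)
.ksExactTail <- function(d, n) {
    if (d <= 0) return(1)
    if (d >= 1) return(0)
    k <- ceiling(n * d)
    h <- k - n * d
    m <- 2L * k - 1L
    H <- matrix(0, m, m)
    for (i in seq_len(m))
        for (j in seq_len(m))
            if (i - j + 1L >= 0L) H[i, j] <- 1
    for (i in seq_len(m)) {
        H[i, 1] <- H[i, 1] - h^i
        H[m, i] <- H[m, i] - h^(m - i + 1L)
    }
    H[m, 1] <- H[m, 1] + if (2 * h - 1 > 0) (2 * h - 1)^m else 0
    for (i in seq_len(m))
        for (j in seq_len(m))
            if (i - j + 1L > 0L)
                H[i, j] <- H[i, j] / factorial(i - j + 1L)
    # H^n with decimal scaling to avoid overflow
    eH <- 0
    Q <- diag(m); eQ <- 0
    P <- H
    nn <- n
    while (nn > 0) {
        if (nn %% 2 == 1) {
            Q <- Q %*% P
            eQ <- eQ + eH
            if (Q[k, k] > 1e140) { Q <- Q * 1e-140; eQ <- eQ + 140 }
        }
        P <- P %*% P
        eH <- 2 * eH
        if (P[k, k] > 1e140) { P <- P * 1e-140; eH <- eH + 140 }
        nn <- nn %/% 2
    }
    s <- Q[k, k]
    for (i in seq_len(n)) {
        s <- s * i / n
        if (s < 1e-140) { s <- s * 1e140; eQ <- eQ - 140 }
    }
    s <- s * 10^eQ
    max(0, min(1, 1 - s))
}

# p-value for the one-sample uniform KS test used by the clustering test
.ksPvalue <- function(d, n) {
    if (n < EXACT_N) .ksExactTail(d, n) else .kolmogorovTail(sqrt(n) * d)
}
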