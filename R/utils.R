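# Internal numerical helpers.

# trapezoid integral of f tabulated at x
trapint <- function(x, fx) {
    sum((fx[-1] + fx[-length(fx)]) / 2 * diff(x))
}

# cumulative trapezoid integral, same length as x, starting at 0
cumtrapint <- function(x, fx) {
    c(0, cumsum((fx[-1] + fx[-length(fx)]) / 2 * diff(x)))
}

logit <- function(p) log(p / (1 - p))

invlogit <- function(x) 1 / (1 + exp(-x))

# population variance (denominator n): realized variance of a finite cohort
popVar <- function(v) mean((v - mean(v))^2)

# default proportion grid: 1000 points on (0,1), endpoints excluded by half a step
defaultGrid <- function(n = 1000L) (seq_len(n) - 0.5) / n

# symmetrize tiny asymmetries from floating-point cross-products
symmetrize <- function(M) (M + t(M)) / 2
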