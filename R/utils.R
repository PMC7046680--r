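# internal numerics shared by the samplers

# log density of rows of y under N(mu, sigma); mu a matrix of row means or a
# single vector
.dmvnormLog <- function(y, mu, sigma) {
    if (is.vector(mu)) mu <- matrix(mu, nrow(y), length(mu), byrow = TRUE)
    R <- chol(sigma)
    z <- backsolve(R, t(y - mu), transpose = TRUE)
    -0.5 * colSums(z^2) - sum(log(diag(R))) -
        0.5 * ncol(y) * log(2 * pi)
}

# one draw from inverse-Wishart(Psi, nu) via Wishart on the inverse scale
.rinvwishart <- function(nu, Psi) {
    W <- stats::rWishart(1L, df = nu, Sigma = chol2inv(chol(Psi)))[, , 1L]
    chol2inv(chol(W))
}

.logit <- function(p) log(p / (1 - p))

# symmetrize to wash out tiny asymmetries from repeated inversions
.sym <- function(A) (A + t(A)) / 2
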