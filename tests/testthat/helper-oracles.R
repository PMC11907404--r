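# Independent oracles used across tests: hand-written textbook formulas,
# kept free of the package's own implementation paths.

# normal-equations least squares for y = b x + a
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  b <- sxy / sxx
  a <- mean(y) - b * mean(x)
  syy <- sum(y^2) - sum(y)^2 / n
  r <- sxy / sqrt(sxx * syy)
  list(slope = b, intercept = a, r = r)
}

# pooled-variance two-sample t from raw textbook formula
t_oracle <- function(m1, s1, n1, m2, s2, n2) {
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# covariance-formula Pearson r
cor_oracle <- function(x, y) {
  mean((x - mean(x)) * (y - mean(y))) /
    sqrt(mean((x - mean(x))^2) * mean((y - mean(y))^2))
}

# printed-table helpers: a last-digit unit (ULP) of a printed value and the
# worst-case agreement deviation achievable from inputs rounded to their
# printed precision
printed_ulp <- function(x) {
  s <- format(x, trim = TRUE, scientific = FALSE)
  dec <- ifelse(grepl("\\.", s), nchar(sub(".*\\.", "", s)), 0)
  10^(-dec)
}
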