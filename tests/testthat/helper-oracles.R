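# Independent oracle implementations used only in tests: straight
# from-the-definition statistics, and a brute-force RK4 integrator for the
# two-compartment system. None of these call the package's own code paths.

naive_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

naive_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  list(statistic = t_stat, df = n - 1,
       p_two = 2 * pt(-abs(t_stat), n - 1))
}

naive_pearson_p_two <- function(x, y) {
  r <- naive_pearson(x, y)
  n <- length(x)
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * pt(-abs(t_stat), n - 2)
}

# fixed-step RK4 for dC1/dt = a(C2-C1), dC2/dt = b(C1-C2) - K C2
rk4_two_compartment <- function(Qb, V1, V2, K, c1_0, t_end, h) {
  a <- Qb / V1; b <- Qb / V2
  f <- function(s) c(a * (s[2] - s[1]), b * (s[1] - s[2]) - K * s[2])
  s <- c(c1_0, 0)
  n <- round(t_end / h)
  for (i in seq_len(n)) {
    k1 <- f(s)
    k2 <- f(s + h / 2 * k1)
    k3 <- f(s + h / 2 * k2)
    k4 <- f(s + h * k3)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  s
}

# per-patient clinical score triplets of the observed cohort, keyed by id
observed_pms <- list(`1` = c(8, 4, 4), `2` = c(8, 2, 2), `4` = c(6, 3, 4),
                     `7` = c(11, 1, 2), `9` = c(9, 3, 2), `10` = c(7, 3, 2),
                     `11` = c(6, 6, 4))
observed_hbi <- list(`3` = c(6, 6, 4), `5` = c(7, 5, 1), `6` = c(5, 4, 3),
                     `8` = c(10, 1, 0))
observed_rhi <- list(`1` = c(17, 8, 8), `2` = c(12, 6, 6), `3` = c(6, 6, 6),
                     `4` = c(14, 1, 1), `5` = c(12, 1, 1), `6` = c(6, 6, 6),
                     `7` = c(23, 6, 6), `8` = c(17, 6, 7), `9` = c(23, 11, 6),
                     `10` = c(23, 16, 9), `11` = c(19, 6, 6))
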