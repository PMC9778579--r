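# shared fixtures built in code

toy_table <- function(n = 40, seed = 1, groups = 4) {
  set.seed(seed)
  data.frame(
    y = rnorm(n),
    z = rbinom(n, 1, 0.5),
    g = factor(sample(letters[seq_len(groups)], n, TRUE)),
    x1 = rnorm(n),
    x2 = factor(sample(c("u", "v", "w"), n, TRUE)),
    stringsAsFactors = FALSE
  )
}

# varying-intercept linear DGP on a known scale
vi_data <- function(n = 200, G = 10, beta = 1, sd_g = 0.7, sigma = 1,
                    seed = 1) {
  set.seed(seed)
  g <- sample.int(G, n, TRUE)
  lam <- rnorm(G, 0, sd_g)
  x <- rnorm(n)
  y <- beta * x + lam[g] + rnorm(n, 0, sigma)
  list(d = data.frame(y = y, x = x, g = factor(g)), lam = lam,
       beta = beta, sd_g = sd_g, sigma = sigma)
}

# single-covariate tree fixture with known cutpoints
tree_fixture <- function(n = 10, seed = 7) {
  set.seed(seed)
  x <- matrix(sort(rnorm(n)), ncol = 1, dimnames = list(NULL, "x"))
  cuts <- list(x = as.numeric(quantile(x, c(0.3, 0.5, 0.75))))
  y <- 0.3 * (x[, 1] > cuts$x[2]) - 0.15 + rnorm(n, 0, 0.1)
  y <- (y - mean(range(y))) / diff(range(y))
  list(x = x, cuts = cuts, y = y)
}
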